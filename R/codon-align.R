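# Codon alignment support: genetic-code tables, protein->CDS back-translation,
# TrimAl-style codon-aware cleaning, empirical codon frequencies, FASTA IO.
# Standard genetic code only; 61 sense codons.

codon_tables <- function() {
  if (!is.null(.lsx$codon)) return(.lsx$codon)
  gc_map <- Biostrings::GENETIC_CODE
  sense <- gc_map != "*"
  codons <- names(gc_map)[sense]
  aa <- unname(gc_map[sense])
  nt <- do.call(rbind, strsplit(codons, ""))
  n <- length(codons)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  d <- vapply(1:3, function(k) nt[idx$i, k] != nt[idx$j, k],
              logical(nrow(idx)))
  ndiff <- rowSums(d)
  sel <- which(ndiff == 1L)
  pos <- max.col(d[sel, , drop = FALSE])
  from <- nt[cbind(idx$i[sel], pos)]
  to <- nt[cbind(idx$j[sel], pos)]
  pair_key <- paste0(pmin(from, to), pmax(from, to))
  tabs <- list(
    codons = codons,
    aa = aa,
    nt = nt,
    stops = names(gc_map)[!sense],
    pair_i = idx$i[sel],
    pair_j = idx$j[sel],
    is_transition = pair_key %in% c("AG", "CT"),
    is_synonymous = aa[idx$i[sel]] == aa[idx$j[sel]]
  )
  .lsx$codon <- tabs
  tabs
}

#' Codon alignments
#'
#' A codon alignment holds equal-length gapped coding sequences whose length
#' is divisible by three, with gaps in whole-codon units, no internal stop
#' codons, and a map from codon columns back to the protein-alignment columns
#' they derive from.
#'
#' @param sequences Named character vector of gapped CDS strings.
#' @param column_map Integer vector, codon column -> source protein column
#'   (defaults to the identity).
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(sequences, column_map = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (anyDuplicated(names(sequences))) abort("duplicate sequence ids")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) abort("sequences must all have equal length")
  if (len %% 3L != 0L) abort("alignment length must be divisible by 3")
  ncod <- len %/% 3L
  column_map <- column_map %||% seq_len(ncod)
  if (length(column_map) != ncod) abort("column_map length must equal codon count")
  cm <- codon_matrix_chr(sequences)
  gap <- cm == "---"
  part <- grepl("-", cm) & !gap
  if (any(part)) abort("gaps must occupy whole codons")
  tabs <- codon_tables()
  is_stop <- matrix(cm %in% tabs$stops, nrow = nrow(cm))
  if (any(is_stop)) {
    w <- which(is_stop, arr.ind = TRUE)[1L, ]
    abort(sprintf("internal stop codon in %s at codon column %d",
                  names(sequences)[w[1L]], w[2L]))
  }
  structure(list(sequences = sequences, column_map = column_map),
            class = "codon_alignment")
}

codon_matrix_chr <- function(sequences) {
  len <- nchar(sequences[[1L]])
  starts <- seq(1L, len, by = 3L)
  vals <- vapply(sequences, function(s) substring(s, starts, starts + 2L),
                 character(length(starts)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = 1L) # single codon column
  m <- t(vals)
  rownames(m) <- names(sequences)
  m
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d sequences x %d codons\n",
              length(x$sequences), length(x$column_map)))
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) {
  c(length(x$sequences), length(x$column_map))
}

# integer codon states (1..61), NA for gap/ambiguous codons
codon_states <- function(aln) {
  tabs <- codon_tables()
  cm <- codon_matrix_chr(aln$sequences)
  st <- match(cm, tabs$codons)
  dim(st) <- dim(cm)
  rownames(st) <- rownames(cm)
  st
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces every aligned amino acid by its source codon and every protein
#' gap by `---`, so that ungapping the output reproduces the input CDS
#' exactly. A terminal stop codon on a CDS is tolerated and stripped.
#'
#' @param protein_alignment Gapped protein sequences: named character vector,
#'   `AAStringSet`, or FASTA path.
#' @param cds Unaligned coding sequences for the same genes: named character
#'   vector, `DNAStringSet`, or FASTA path.
#' @return A [codon_alignment()] whose column map is the identity onto the
#'   protein alignment columns.
#' @examples
#' back_translate(c(g1 = "M-A", g2 = "MKA"),
#'                c(g1 = "ATGGCA", g2 = "ATGAAAGCA"))
#' @export
back_translate <- function(protein_alignment, cds) {
  prot <- as_named_seqs(protein_alignment, "AA")
  dna <- as_named_seqs(cds, "DNA")
  missing <- setdiff(names(prot), names(dna))
  if (length(missing) > 0L) {
    abort(paste0("CDS missing for: ", paste(utils::head(missing, 5L), collapse = ", ")))
  }
  tabs <- codon_tables()
  gc_map <- Biostrings::GENETIC_CODE
  out <- vapply(names(prot), function(id) {
    p <- toupper(prot[[id]])
    s <- toupper(chartr("U", "T", dna[[id]]))
    res <- gsub("-", "", p, fixed = TRUE)
    naa <- nchar(res)
    if (nchar(s) == 3L * (naa + 1L)) {
      last <- substr(s, nchar(s) - 2L, nchar(s))
      if (last %in% tabs$stops) s <- substr(s, 1L, nchar(s) - 3L)
    }
    if (nchar(s) != 3L * naa) {
      abort(sprintf(
        "%s: CDS length %d does not match 3 x %d ungapped residues",
        id, nchar(s), naa
      ))
    }
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    stop_at <- which(cods %in% tabs$stops)
    if (length(stop_at) > 0L) {
      abort(sprintf("%s: internal stop codon at codon %d", id, stop_at[1L]))
    }
    trans <- unname(gc_map[cods])
    res_chars <- strsplit(res, "")[[1L]]
    mism <- which(!is.na(trans) & trans != res_chars & res_chars != "X")
    if (length(mism) > 0L) {
      abort(sprintf(
        "%s: codon %s at position %d translates to %s, protein has %s",
        id, cods[mism[1L]], mism[1L], trans[mism[1L]], res_chars[mism[1L]]
      ))
    }
    p_chars <- strsplit(p, "")[[1L]]
    cod_out <- rep("---", length(p_chars))
    cod_out[p_chars != "-"] <- cods
    paste(cod_out, collapse = "")
  }, character(1))
  codon_alignment(out)
}

as_named_seqs <- function(x, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
               file.exists(x)) {
    set <- if (type == "AA") Biostrings::readAAStringSet(x) else {
      Biostrings::readDNAStringSet(x)
    }
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(out))
  } else if (is.character(x) && !is.null(names(x))) {
    out <- x
  } else {
    abort("sequences must be a named character vector, an XStringSet, or a FASTA path")
  }
  if (anyDuplicated(names(out))) abort("duplicate sequence ids")
  out
}

#' Clean a codon alignment (TrimAl-style thresholds, codon-aware)
#'
#' Two passes, both acting on whole codon columns: (1) drop codon columns in
#' which the fraction of non-gap sequences is below `gap_threshold`; (2) call
#' a residue "well overlapped" when the fraction of *other* sequences with a
#' non-gap codon in its column is at least `res_overlap`, and drop sequences
#' whose well-overlapped residues cover less than `seq_overlap` of the
#' alignment columns -- i.e. sequences without enough informative sites
#' (mostly-gap sequences score low because gap positions never count).
#'
#' @param aln A [codon_alignment()].
#' @param gap_threshold Minimum non-gap fraction for a column to be kept.
#' @param res_overlap Residue overlap threshold.
#' @param seq_overlap Sequence overlap threshold (fraction, 0.90 = 90%).
#' @return Cleaned `codon_alignment` with updated column map; removed columns
#'   and sequences are reported in attributes `removed_columns` and
#'   `removed_sequences`.
#' @export
clean_alignment <- function(aln, gap_threshold = 0.25, res_overlap = 0.25,
                            seq_overlap = 0.90) {
  stopifnot(inherits(aln, "codon_alignment"))
  cm <- codon_matrix_chr(aln$sequences)
  nongap <- cm != "---"
  nseq <- nrow(cm)

  keep_col <- colMeans(nongap) >= gap_threshold
  removed_cols <- aln$column_map[!keep_col]
  cm2 <- cm[, keep_col, drop = FALSE]
  ng2 <- nongap[, keep_col, drop = FALSE]

  if (ncol(cm2) == 0L) abort("cleaning removed all columns")

  keep_seq <- rep(TRUE, nseq)
  if (nseq > 1L) {
    col_nongap <- colSums(ng2)
    for (s in seq_len(nseq)) {
      res_cols <- which(ng2[s, ])
      if (length(res_cols) == 0L) {
        keep_seq[s] <- FALSE
        next
      }
      frac_other <- (col_nongap[res_cols] - 1L) / (nseq - 1L)
      good <- sum(frac_other >= res_overlap)
      keep_seq[s] <- good / ncol(ng2) >= seq_overlap
    }
  }
  removed_seqs <- rownames(cm)[!keep_seq]
  if (!any(keep_seq)) abort("cleaning removed all sequences")
  if (length(removed_seqs) > 0L) {
    inform(paste0("removed sequence(s) with insufficient overlap: ",
                  paste(removed_seqs, collapse = ", ")))
  }
  seqs <- apply(cm2[keep_seq, , drop = FALSE], 1L, paste, collapse = "")
  out <- codon_alignment(seqs, column_map = aln$column_map[keep_col])
  attr(out, "removed_columns") <- removed_cols
  attr(out, "removed_sequences") <- removed_seqs
  out
}

#' Empirical codon frequencies
#'
#' `F3x4`: stationary codon frequencies built from the empirical nucleotide
#' frequencies at each of the three codon positions (the codeml default),
#' restricted to the 61 sense codons and renormalized. `equal` gives uniform
#' frequencies 1/61. Position-wise nucleotide frequencies are floored at a
#' small value so every sense codon keeps positive mass.
#'
#' @param aln A [codon_alignment()].
#' @param method `"f3x4"` or `"equal"`.
#' @return Numeric vector of 61 codon frequencies summing to 1, named by
#'   codon.
#' @export
codon_frequencies <- function(aln, method = c("f3x4", "equal")) {
  method <- match.arg(method)
  tabs <- codon_tables()
  if (method == "equal") {
    return(setNames(rep(1 / 61, 61L), tabs$codons))
  }
  st <- codon_states(aln)
  obs <- tabs$nt[st[!is.na(st)], , drop = FALSE]
  nts <- c("A", "C", "G", "T")
  pos_freq <- vapply(1:3, function(k) {
    f <- table(factor(obs[, k], levels = nts))
    f <- pmax(as.numeric(f) / sum(f), 1e-4)
    f / sum(f)
  }, numeric(4))
  rownames(pos_freq) <- nts
  pi_cod <- pos_freq[tabs$nt[, 1L], 1L] *
    pos_freq[tabs$nt[, 2L], 2L] *
    pos_freq[tabs$nt[, 3L], 3L]
  pi_cod <- pi_cod / sum(pi_cod)
  setNames(unname(pi_cod), tabs$codons)
}

#' Write a codon alignment as FASTA or sequential PHYLIP
#'
#' @param aln A [codon_alignment()].
#' @param path Output file.
#' @param format `"fasta"` or `"phylip"` (sequential, as consumed by codon
#'   model software).
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(aln$sequences)
    Biostrings::writeXStringSet(set, path)
  } else {
    lines <- c(
      sprintf(" %d %d", length(aln$sequences), nchar(aln$sequences[[1L]])),
      sprintf("%s  %s", names(aln$sequences), unname(aln$sequences))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a gapped CDS FASTA as a codon alignment
#'
#' @param path FASTA file of equal-length, codon-aligned CDS.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path) {
  codon_alignment(as_named_seqs(path, "DNA"))
}
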