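## Pairwise comparison of parental coding sequences: ORF validation,
## translation, fixed-difference (diagnostic SNP) discovery and peptide
## region handling. Positions are 1-based throughout, as in the reports
## ("the 60th site") and everywhere else in R.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.check_nt <- function(seq, what = "seq", allow = "ACGT") {
  s <- .check_string(seq, what)
  bad <- regmatches(s, regexpr(sprintf("[^%s]", allow), s))
  if (length(bad) && nzchar(bad)) {
    abort(sprintf("`%s` contains non-nucleotide character '%s' (allowed: %s)",
                  what, bad, allow))
  }
  s
}

.codons <- function(seq) {
  n_full <- nchar(seq) %/% 3L
  if (n_full == 0L) return(character(0))
  substring(seq, 3L * seq_len(n_full) - 2L, 3L * seq_len(n_full))
}

#' Validate an open reading frame
#'
#' Checks a nucleotide sequence against the standard genetic code conventions
#' for a complete ORF: an ATG start codon, a length that is a multiple of
#' three, a terminal stop codon (TAA/TAG/TGA), and no internal stop codons.
#'
#' @param seq Single nucleotide string over A, C, G, T (case-insensitive).
#' @return An object of class `orf_check`: a list with logical flags
#'   `starts_with_start_codon`, `length_multiple_of_three`, `terminal_stop`,
#'   an integer vector `internal_stop_codons` of 1-based codon indices
#'   (excluding the terminal codon), and `valid`, TRUE when all checks pass.
#' @examples
#' validate_orf("ATGGGTTAA")$valid
#' validate_orf("ATGTAAGGTTAA")$internal_stop_codons  # codon 2
#' @export
validate_orf <- function(seq) {
  s <- .check_nt(seq, "seq")
  n <- nchar(s)
  codons <- .codons(s)
  k <- length(codons)
  mult3 <- n %% 3L == 0L
  terminal <- mult3 && k >= 1L && codons[k] %in% .STOP_CODONS
  # only the final complete codon of an in-frame sequence is "terminal"
  internal_idx <- if (mult3 && k >= 1L) seq_len(k - 1L) else seq_len(k)
  internal <- internal_idx[codons[internal_idx] %in% .STOP_CODONS]
  out <- list(
    starts_with_start_codon = substr(s, 1L, 3L) == "ATG",
    length_multiple_of_three = mult3,
    terminal_stop = terminal,
    internal_stop_codons = as.integer(internal)
  )
  out$valid <- out$starts_with_start_codon && mult3 && terminal &&
    length(internal) == 0L
  structure(out, class = "orf_check")
}

#' @export
print.orf_check <- function(x, ...) {
  cat("ORF check:",
      if (x$valid) "valid" else "invalid", "\n")
  cat("  start codon ATG:      ", x$starts_with_start_codon, "\n")
  cat("  length multiple of 3: ", x$length_multiple_of_three, "\n")
  cat("  terminal stop:        ", x$terminal_stop, "\n")
  if (length(x$internal_stop_codons)) {
    cat("  internal stops at codon(s):",
        paste(x$internal_stop_codons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Translate an open reading frame
#'
#' Standard-genetic-code translation, dropping the terminal stop codon. A
#' complete ORF of `3 * (p + 1)` nucleotides yields `p` residues. Only the 20
#' standard residues are ever produced; an internal stop is an error naming
#' the offending codon.
#'
#' @param seq Single nucleotide string; must start with ATG and have length a
#'   multiple of three.
#' @param require_terminal_stop If TRUE (default) a missing terminal stop
#'   codon is an error; if FALSE all codons are translated.
#' @return Protein string (single-letter residues).
#' @examples
#' translate_orf("ATGGGTTAA")  # "MG"
#' @export
translate_orf <- function(seq, require_terminal_stop = TRUE) {
  s <- .check_nt(seq, "seq")
  chk <- validate_orf(s)
  if (!chk$length_multiple_of_three) {
    abort("sequence length is not a multiple of three")
  }
  if (!chk$starts_with_start_codon) {
    abort("sequence does not start with the ATG start codon")
  }
  if (length(chk$internal_stop_codons)) {
    abort(sprintf("internal stop codon at codon index %d",
                  chk$internal_stop_codons[1L]))
  }
  if (require_terminal_stop && !chk$terminal_stop) {
    abort("sequence lacks a terminal stop codon")
  }
  codons <- .codons(s)
  if (chk$terminal_stop) codons <- codons[-length(codons)]
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) abort("untranslatable codon encountered")
  paste(aa, collapse = "")
}

#' Find fixed nucleotide differences between two parental sequences
#'
#' Position-by-position comparison of two equal-length, ungapped coding
#' sequences. Each mismatch is a candidate diagnostic SNP for allele-specific
#' expression, labelled maternal/paternal (e.g. "T/C"). The number of rows
#' equals the Hamming distance. Alignment is the caller's responsibility;
#' unequal lengths and IUPAC ambiguity letters are rejected.
#'
#' @param maternal,paternal Nucleotide strings of equal length (A/C/G/T only).
#' @return Tibble with one row per difference: `position` (1-based),
#'   `maternal_allele`, `paternal_allele`, `label`.
#' @examples
#' find_fixed_differences("ATGA", "ACGA")  # position 2, label "T/C"
#' @export
find_fixed_differences <- function(maternal, paternal) {
  m <- .check_nt(maternal, "maternal")
  p <- .check_nt(paternal, "paternal")
  if (nchar(m) != nchar(p)) {
    abort(sprintf("sequences differ in length (%d vs %d); align them first",
                  nchar(m), nchar(p)))
  }
  mb <- strsplit(m, "", fixed = TRUE)[[1L]]
  pb <- strsplit(p, "", fixed = TRUE)[[1L]]
  pos <- which(mb != pb)
  tibble(
    position = as.integer(pos),
    maternal_allele = mb[pos],
    paternal_allele = pb[pos],
    label = if (length(pos)) paste(mb[pos], pb[pos], sep = "/") else character(0)
  )
}

#' Residue differences between two equal-length proteins
#'
#' @param protein_a,protein_b Protein strings of equal length.
#' @return Tibble with `position` (1-based), `residue_a`, `residue_b` for
#'   every mismatching residue.
#' @examples
#' diff_peptides("MKTD", "MKTE")  # position 4, D vs E
#' @export
diff_peptides <- function(protein_a, protein_b) {
  a <- .check_string(protein_a, "protein_a")
  b <- .check_string(protein_b, "protein_b")
  if (nchar(a) != nchar(b)) {
    abort(sprintf("proteins differ in length (%d vs %d)", nchar(a), nchar(b)))
  }
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  pos <- which(av != bv)
  tibble(position = as.integer(pos), residue_a = av[pos], residue_b = bv[pos])
}

#' Extract signal- and mature-peptide regions from a precursor protein
#'
#' Intervals are 1-based inclusive `c(start, end)`; an empty region is
#' requested as `c(k + 1, k)`. Residue letters are passed through verbatim,
#' including non-standard letters used by convention for modified residues
#' (e.g. "O" marking an acylated serine in mature ghrelin); such letters are
#' never produced by [translate_orf()] itself.
#'
#' @param protein Precursor protein string.
#' @param signal,mature Integer vectors `c(start, end)`, 1-based inclusive;
#'   the two regions must lie within the protein and must not overlap.
#' @return List with elements `signal` and `mature`.
#' @export
extract_regions <- function(protein, signal, mature) {
  p <- .check_string(protein, "protein")
  np <- nchar(p)
  chk_iv <- function(iv, what) {
    if (!is.numeric(iv) || length(iv) != 2L || anyNA(iv)) {
      abort(sprintf("`%s` must be c(start, end)", what))
    }
    iv <- as.integer(iv)
    if (iv[1L] < 1L || iv[2L] > np || iv[1L] > iv[2L] + 1L) {
      abort(sprintf("`%s` interval [%d, %d] out of bounds for protein of length %d",
                    what, iv[1L], iv[2L], np))
    }
    iv
  }
  s <- chk_iv(signal, "signal")
  m <- chk_iv(mature, "mature")
  overlap <- max(s[1L], m[1L]) <= min(s[2L], m[2L])
  if (s[1L] <= s[2L] && m[1L] <= m[2L] && overlap) {
    abort("signal and mature regions overlap")
  }
  sub <- function(iv) if (iv[1L] > iv[2L]) "" else substr(p, iv[1L], iv[2L])
  list(signal = sub(s), mature = sub(m))
}
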