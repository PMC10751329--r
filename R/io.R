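## File formats: FASTA via Biostrings, Ct and allele-count tables as
## delimiter-sniffed CSV/TSV with validation. Readers preserve unknown
## columns; writers round-trip through the readers.

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Tibble with `id` (full header line) and `sequence` (uppercase),
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
    },
    # the parser skips invalid letters with a warning; treat that as fatal
    warning = function(w) {
      abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(w)))
    }
  )
  if (!length(set)) abort(sprintf("no sequences in %s", path))
  seqs <- toupper(unname(as.character(set)))
  ok <- paste(c(names(Biostrings::IUPAC_CODE_MAP), "N", "-"), collapse = "")
  bad <- grepl(sprintf("[^%s]", ok), seqs)
  if (any(bad)) {
    abort(sprintf("illegal sequence character in record '%s' of %s",
                  names(set)[which(bad)[1L]], path))
  }
  tibble(id = names(set), sequence = seqs)
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with `id` and `sequence`.
#' @param path Output path; lines wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- .check_df_cols(records, c("id", "sequence"), "records")
  set <- Biostrings::DNAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

## Sniff "," vs tab from the header line.
.read_delim_sniff <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (!length(header)) abort(sprintf("empty file: %s", path))
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

.check_numeric_col <- function(df, col, path) {
  x <- df[[col]]
  if (is.numeric(x)) return(df)
  xn <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(xn) & !is.na(x))
  if (length(bad)) {
    abort(sprintf("non-numeric `%s` value '%s' at data row %d of %s",
                  col, x[bad[1L]], bad[1L], path))
  }
  df[[col]] <- xn
  df
}

#' Read a qPCR Ct table (CSV or TSV)
#'
#' Requires columns `sample_id`, `group`, `gene`, `ct`; `condition` and
#' `time_h` default to `"none"` and 0 when absent. Unknown columns are
#' preserved. The delimiter is sniffed from the header line.
#'
#' @param path Path to the table.
#' @return Validated Ct tibble.
#' @export
read_ct_table <- function(path) {
  df <- .read_delim_sniff(path)
  missing <- setdiff(c("sample_id", "group", "gene", "ct"), names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  df <- .check_numeric_col(df, "ct", path)
  if (!"condition" %in% names(df)) df$condition <- "none"
  if (!"time_h" %in% names(df)) df$time_h <- 0
  df <- .check_numeric_col(df, "time_h", path)
  .check_ct_table(df)
}

#' Read an allele-count table (CSV or TSV)
#'
#' Requires `sample_id` and `site_label` plus either raw counts
#' (`maternal_count`, `paternal_count`) or percentages (`maternal_pct`,
#' summing with the paternal side to 100). Percentages are converted to
#' pseudo-counts at `depth` reads with a warning: exact binomial tests on
#' pseudo-counts are approximate.
#'
#' @param path Path to the table.
#' @param depth Nominal read depth for percentage conversion (default 500).
#' @return Validated allele-count tibble.
#' @export
read_allele_counts <- function(path, depth = 500L) {
  df <- .read_delim_sniff(path)
  missing <- setdiff(c("sample_id", "site_label"), names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  has_counts <- all(c("maternal_count", "paternal_count") %in% names(df))
  if (!has_counts) {
    if (!"maternal_pct" %in% names(df)) {
      abort(sprintf(
        "%s needs maternal_count/paternal_count or maternal_pct", path))
    }
    df <- .check_numeric_col(df, "maternal_pct", path)
    if (any(df$maternal_pct < 0 | df$maternal_pct > 100)) {
      abort("`maternal_pct` must lie in [0, 100]")
    }
    warn(sprintf(
      "converting percentages to pseudo-counts at depth %d; exact binomial tests on pseudo-counts are approximate",
      depth))
    df$maternal_count <- as.integer(round(depth * df$maternal_pct / 100))
    df$paternal_count <- as.integer(depth) - df$maternal_count
  }
  df <- .check_numeric_col(df, "maternal_count", path)
  df <- .check_numeric_col(df, "paternal_count", path)
  if (any(df$maternal_count < 0 | df$paternal_count < 0)) {
    abort("read counts must be non-negative")
  }
  if (any(df$maternal_count + df$paternal_count <= 0)) {
    abort("every record needs a positive total read count")
  }
  if (!"condition" %in% names(df)) df$condition <- "none"
  if (!"time_h" %in% names(df)) df$time_h <- 0
  df <- .check_numeric_col(df, "time_h", path)
  df
}

#' Write a simulated study to a directory
#'
#' Emits the same formats the analysis readers accept: `sequences.fasta`
#' (maternal parent first, then paternal), `snp_truth.tsv`, `ct_table.csv`,
#' `allele_counts.csv`, `timecourse_ct.csv`,
#' `timecourse_allele_counts.csv`, and `truth.json` with the planted ground
#' truth and config echo.
#'
#' @param study A `hybrid_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "hybrid_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(study$sequences, file.path(dir, "sequences.fasta"))
  snp <- study$snp_truth
  readr::write_tsv(
    tibble(position_1based = snp$position,
           maternal_allele = snp$maternal_allele,
           paternal_allele = snp$paternal_allele,
           label = snp$label),
    file.path(dir, "snp_truth.tsv"))
  readr::write_csv(study$ct, file.path(dir, "ct_table.csv"))
  readr::write_csv(study$allele_counts, file.path(dir, "allele_counts.csv"))
  readr::write_csv(study$timecourse$ct, file.path(dir, "timecourse_ct.csv"))
  readr::write_csv(study$timecourse$allele_counts,
                   file.path(dir, "timecourse_allele_counts.csv"))
  cfg <- study$config
  cfg$fasting_multipliers <- as.list(cfg$fasting_multipliers)
  jsonlite::write_json(
    list(A_true = study$truth$A_true, B_true = study$truth$B_true,
         category_true = study$truth$category_true,
         config = unclass(cfg)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
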