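## Diagnostic-marker validation against parental and hybrid genotype calls.
## Sequencing-trace genotypes arrive either as explicit allele sets ("T",
## "TC") or as single IUPAC ambiguity letters ("Y" = C/T), decoded here.

#' Decode genotype calls to allele sets
#'
#' Accepts explicit multi-letter calls ("T", "TC") and single IUPAC ambiguity
#' letters ("Y" -> C/T, "S" -> C/G, ...). Returns sorted unique allele sets.
#'
#' @param x Character vector of genotype calls.
#' @return List of character vectors, one allele set per call.
#' @examples
#' decode_iupac(c("Y", "TC", "T"))
#' @export
decode_iupac <- function(x) {
  if (!is.character(x) || !length(x)) abort("`x` must be a character vector")
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(toupper(x), function(g) {
    if (is.na(g) || !nzchar(g)) abort("empty genotype call")
    chars <- strsplit(g, "", fixed = TRUE)[[1L]]
    if (length(chars) == 1L && !chars %in% c("A", "C", "G", "T")) {
      if (!chars %in% names(map)) {
        abort(sprintf("unknown genotype letter '%s'", chars))
      }
      chars <- strsplit(map[[chars]], "", fixed = TRUE)[[1L]]
    }
    if (!all(chars %in% c("A", "C", "G", "T"))) {
      abort(sprintf("genotype call '%s' contains non-allele letters", g))
    }
    sort(unique(chars))
  })
}

#' Validate a diagnostic SNP marker against genotype calls
#'
#' A site is usable for allele-specific expression when every maternal-parent
#' call is homozygous for the maternal allele, every paternal-parent call is
#' homozygous for the paternal allele, and every hybrid call is heterozygous
#' carrying exactly both alleles. The first failing sample is named in the
#' reason.
#'
#' @param site One row of a SNP table (list or data frame) with
#'   `maternal_allele` and `paternal_allele`.
#' @param calls Data frame with columns `sample_id`, `role` (one of
#'   `maternal_parent`, `paternal_parent`, `hybrid`) and `alleles` (genotype
#'   call string, IUPAC letters accepted). At least one call per role.
#' @return Object of class `marker_status`: list with `usable` (flag) and
#'   `reason` (empty string when usable).
#' @export
validate_marker <- function(site, calls) {
  if (is.data.frame(site)) site <- as.list(site[1L, ])
  mat <- toupper(site$maternal_allele)
  pat <- toupper(site$paternal_allele)
  if (is.null(mat) || is.null(pat) || identical(mat, pat)) {
    abort("`site` must carry distinct maternal_allele and paternal_allele")
  }
  calls <- .check_df_cols(calls, c("sample_id", "role", "alleles"), "calls")
  roles <- c("maternal_parent", "paternal_parent", "hybrid")
  missing_roles <- setdiff(roles, unique(calls$role))
  if (length(missing_roles)) {
    abort(sprintf("no genotype calls for role(s): %s",
                  paste(missing_roles, collapse = ", ")))
  }
  sets <- decode_iupac(calls$alleles)
  expected <- list(
    maternal_parent = mat,
    paternal_parent = pat,
    hybrid = sort(c(mat, pat))
  )
  for (i in seq_len(nrow(calls))) {
    role <- calls$role[i]
    if (!role %in% roles) next
    if (!identical(sets[[i]], expected[[role]])) {
      reason <- sprintf(
        "sample %s (%s): observed {%s}, expected {%s}",
        calls$sample_id[i], role,
        paste(sets[[i]], collapse = ","),
        paste(expected[[role]], collapse = ","))
      return(structure(list(usable = FALSE, reason = reason),
                       class = "marker_status"))
    }
  }
  structure(list(usable = TRUE, reason = ""), class = "marker_status")
}

#' @export
print.marker_status <- function(x, ...) {
  if (x$usable) {
    cat("Marker usable for allele-specific expression\n")
  } else {
    cat("Marker NOT usable:", x$reason, "\n")
  }
  invisible(x)
}
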