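#' Read genotype, phenotype or Ct tables
#'
#' Reads delimited text (TSV or CSV, autodetected from the header line) with
#' a header row into typed tibbles.  Missing phenotype cells are preserved as
#' `NA`, never coerced to zero; genotype strings are normalised to unordered
#' allele pairs, so `"C/T"` and `"T/C"` are the same genotype class.
#'
#' Expected columns:
#' * genotype: `subject_id`, `group` (one of `case`, `control_longlived`,
#'   `control_healthy`), `genotype` (e.g. `"T/T"`, `"T/C"`, `"C/C"`).
#' * phenotype: `subject_id`, `pr_ms`, `rr_ms`, `qrs_ms`, `qt_ms`
#'   (milliseconds, optionally missing).
#' * ct: `sample_id`, `assay_id`, `role` (`target`, `spike_in` or
#'   `housekeeping`), `ct1`..`ct3` (cycles; `ct2`/`ct3` may be missing).
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema `"genotype"`, `"phenotype"` or `"ct"`.
#' @return A typed tibble, one row per input row.
#' @export
read_table_file <- function(path, schema = c("genotype", "phenotype", "ct")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("table file not found: ", path), class = "mirvar_io_error")
  }
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  names(raw) <- tolower(names(raw))
  switch(schema,
    genotype = .typed_genotypes(raw),
    phenotype = .typed_phenotypes(raw),
    ct = .typed_ct(raw)
  )
}

#' @rdname read_table_file
#' @export
read_genotype_table <- function(path) read_table_file(path, "genotype")

#' @rdname read_table_file
#' @export
read_phenotype_table <- function(path) read_table_file(path, "phenotype")

#' @rdname read_table_file
#' @export
read_ct_table <- function(path) read_table_file(path, "ct")

.groups_known <- c("case", "control_longlived", "control_healthy")

.typed_genotypes <- function(x) {
  .need_cols(x, c("subject_id", "group", "genotype"), "genotype")
  if (anyDuplicated(x$subject_id)) {
    abort("duplicate subject_id in genotype table", class = "mirvar_format_error")
  }
  bad <- setdiff(unique(x$group), .groups_known)
  if (length(bad)) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")),
          class = "mirvar_format_error")
  }
  tibble(
    subject_id = as.character(x$subject_id),
    group = as.character(x$group),
    genotype = normalize_genotype(x$genotype)
  )
}

#' Normalise genotype strings to an unordered allele pair
#'
#' `"C/T"`, `"T/C"`, `"t/c"` all normalise to the same class.  Alleles are
#' rendered in a fixed order (alphabetical, so `"C/T"`), which callers may
#' re-render reference-allele-first for display.
#'
#' @param g Character vector of genotype strings (`"X/Y"`).
#' @return Character vector of normalised `"X/Y"` strings.
#' @export
normalize_genotype <- function(g) {
  parts <- strsplit(toupper(trimws(g)), "/", fixed = TRUE)
  ok <- lengths(parts) == 2 &
    vapply(parts, function(p) all(p %in% c("A", "C", "G", "T")), logical(1))
  if (!all(ok)) {
    abort(paste0("unknown genotype string(s): ",
                 paste(unique(g[!ok]), collapse = ", ")),
          class = "mirvar_format_error")
  }
  vapply(parts, function(p) paste(sort(p), collapse = "/"), character(1))
}

.typed_phenotypes <- function(x) {
  cols <- c("pr_ms", "rr_ms", "qrs_ms", "qt_ms")
  .need_cols(x, c("subject_id", cols), "phenotype")
  out <- tibble(subject_id = as.character(x$subject_id))
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(x[[cl]]))
    if (any(!is.na(v) & (v <= 0 | !is.finite(v)))) {
      abort(paste0("non-positive or non-finite value in ", cl),
            class = "mirvar_format_error")
    }
    out[[cl]] <- v
  }
  out
}

.typed_ct <- function(x) {
  .need_cols(x, c("sample_id", "assay_id", "role", "ct1"), "ct")
  roles <- c("target", "spike_in", "housekeeping")
  if (!all(x$role %in% roles)) {
    abort(paste0("ct role must be one of: ", paste(roles, collapse = ", ")),
          class = "mirvar_format_error")
  }
  out <- tibble(
    sample_id = as.character(x$sample_id),
    assay_id = as.character(x$assay_id),
    role = as.character(x$role)
  )
  for (cl in c("ct1", "ct2", "ct3")) {
    v <- if (cl %in% names(x)) x[[cl]] else NA_real_
    v <- suppressWarnings(as.numeric(v))
    if ((cl %in% names(x)) && any(is.na(v) & !is.na(x[[cl]]) & x[[cl]] != "")) {
      abort(paste0("non-numeric Ct value in ", cl), class = "mirvar_format_error")
    }
    if (any(!is.na(v) & (v <= 0 | v > 45))) {
      abort(paste0("Ct outside (0, 45] in ", cl), class = "mirvar_format_error")
    }
    out[[cl]] <- v
  }
  out
}

.need_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    abort(paste0(what, " table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mirvar_format_error")
  }
  invisible(x)
}
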