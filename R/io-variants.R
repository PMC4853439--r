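#' Parse a 3'UTR single-nucleotide variant in c.* notation
#'
#' Accepts HGVS-like `c.*<pos><ref>><alt>` strings such as `"c.*28T>C"`,
#' where position 1 is the first base 3' of the stop codon (c.*1) and the
#' coordinate is 1-based.  Only single-nucleotide substitutions are
#' supported; indels are rejected.  When a UTR record is supplied the stated
#' reference base is validated against the sequence.
#'
#' @param text Variant string, e.g. `"c.*28T>C"`.
#' @param utr Optional one-row UTR tibble (from [read_utr_fasta()]) used to
#'   validate the reference base and attach `utr_id`.
#'
#' @return A one-row tibble with columns `utr_id`, `position`, `ref_base`,
#'   `alt_base`.
#' @export
#' @examples
#' utr <- tibble::tibble(utr_id = "u1", sequence = "ACGTACGT")
#' parse_variant("c.*4T>G", utr)
parse_variant <- function(text, utr = NULL) {
  m <- regmatches(text, regexec("^c\\.\\*(\\d+)([ACGTacgt])>([ACGTacgt])$", text))[[1]]
  if (length(m) != 4) {
    abort(
      paste0("malformed variant string '", text,
             "': expected c.*<pos><ref>><alt> with a single-base substitution"),
      class = "mirvar_parse_error"
    )
  }
  pos <- as.integer(m[2])
  ref <- toupper(m[3])
  alt <- toupper(m[4])
  if (pos < 1) {
    abort("variant position must be >= 1", class = "mirvar_parse_error")
  }
  if (ref == alt) {
    abort("reference and alternate base are identical", class = "mirvar_parse_error")
  }
  v <- tibble(utr_id = NA_character_, position = pos, ref_base = ref, alt_base = alt)
  if (!is.null(utr)) {
    utr <- .check_utr(utr)
    v$utr_id <- utr$utr_id
    .check_variant(utr, v)
  }
  v
}

#' Render a variant tibble back to c.* notation
#' @param v A one-row variant tibble.
#' @return A string like `"c.*28T>C"`.
#' @export
format_variant <- function(v) {
  sprintf("c.*%d%s>%s", v$position, v$ref_base, v$alt_base)
}

# -- shared input checks -------------------------------------------------

.check_utr <- function(utr) {
  if (is.character(utr) && length(utr) == 1) {
    utr <- tibble(utr_id = "utr", sequence = toupper(utr))
  }
  if (!is.data.frame(utr) || !all(c("utr_id", "sequence") %in% names(utr))) {
    abort("utr must be a tibble with columns utr_id and sequence",
          class = "mirvar_io_error")
  }
  if (nrow(utr) != 1) {
    abort("expected exactly one UTR record", class = "mirvar_io_error")
  }
  if (is.na(utr$sequence) || nchar(utr$sequence) == 0) {
    abort("UTR sequence is empty", class = "mirvar_format_error")
  }
  utr
}

.check_variant <- function(utr, v) {
  if (v$position > nchar(utr$sequence)) {
    abort(
      sprintf("variant position %d is beyond the UTR 3' end (length %d)",
              v$position, nchar(utr$sequence)),
      class = "mirvar_range_error"
    )
  }
  found <- substr(utr$sequence, v$position, v$position)
  if (found != v$ref_base) {
    abort(
      sprintf("reference mismatch at c.*%d: variant states '%s' but UTR '%s' has '%s'",
              v$position, v$ref_base, utr$utr_id, found),
      class = "mirvar_ref_mismatch_error"
    )
  }
  invisible(v)
}
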