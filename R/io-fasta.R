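#' Read a FASTA file into a sequence tibble
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file and normalises the
#' sequences to the requested alphabet: uppercase throughout, `T -> U` for
#' `alphabet = "rna"` (mature miRNA libraries) and `U -> T` for
#' `alphabet = "dna"` (3'UTR references).  The record id is the first
#' whitespace-delimited token of the header, as in miRBase-style files.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"rna"` or `"dna"`; controls the T/U normalisation.
#' @param species Optional id-prefix filter (e.g. `"hsa"`) applied after
#'   reading; `NULL` (default) keeps every record.
#'
#' @return A tibble with columns `id` (character) and `sequence` (character,
#'   uppercase, 5'->3'), one row per record, in file order.
#' @export
#' @examples
#' fa <- system.file("extdata", "mirnas_example.fa", package = "mirvar")
#' read_fasta(fa, alphabet = "rna")
read_fasta <- function(path, alphabet = c("rna", "dna"), species = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "mirvar_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("not a readable FASTA file: ", path, " (", conditionMessage(e), ")"),
            class = "mirvar_format_error")
    }
  )
  if (length(set) == 0) {
    abort(paste0("empty FASTA file: ", path), class = "mirvar_format_error")
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  seqs <- toupper(as.character(set))
  seqs <- if (alphabet == "rna") chartr("T", "U", seqs) else chartr("U", "T", seqs)
  ok_chars <- if (alphabet == "rna") "ACGUN" else "ACGTN"
  bad <- regexpr(paste0("[^", ok_chars, "]"), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(
      sprintf("record '%s' has invalid character '%s' at position %d",
              ids[i], substr(seqs[i], bad[i], bad[i]), bad[i]),
      class = "mirvar_format_error"
    )
  }
  out <- tibble(id = ids, sequence = unname(seqs))
  if (!is.null(species)) {
    out <- filter(out, startsWith(.data$id, species))
  }
  out
}

#' @rdname read_fasta
#' @export
read_mirna_fasta <- function(path, species = NULL) {
  rename(read_fasta(path, alphabet = "rna", species = species),
         mirna_id = "id")
}

#' @rdname read_fasta
#' @export
read_utr_fasta <- function(path) {
  rename(read_fasta(path, alphabet = "dna"), utr_id = "id")
}

#' Write a sequence tibble to FASTA
#'
#' @param x A tibble with an id column (`id`, `mirna_id` or `utr_id`) and a
#'   `sequence` column.
#' @param path Output file path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  id_col <- intersect(c("id", "mirna_id", "utr_id"), names(x))[1]
  if (is.na(id_col) || !"sequence" %in% names(x)) {
    abort("need an id column and a 'sequence' column", class = "mirvar_io_error")
  }
  set <- Biostrings::BStringSet(setNames(x$sequence, x[[id_col]]))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
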