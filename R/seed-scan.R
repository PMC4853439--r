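#' Extract the seed of a mature miRNA
#'
#' The seed is defined as miRNA nucleotides 2-7 counted 1-based from the 5'
#' end; perfect Watson-Crick complementarity of a UTR window to this 6-mer is
#' the minimal ("6mer") target-site match.
#'
#' @param mirna A one-row miRNA tibble (columns `mirna_id`, `sequence`) or a
#'   single RNA sequence string.
#' @return The 6-base seed (RNA alphabet, 5'->3').
#' @export
#' @examples
#' extract_seed("UAGCUUAUCAGACUGAUGUUGA")  # "AGCUUA"
extract_seed <- function(mirna) {
  seq <- if (is.data.frame(mirna)) mirna$sequence else mirna
  if (length(seq) != 1) abort("expected a single miRNA", class = "mirvar_io_error")
  if (nchar(seq) < 8) {
    abort(sprintf("miRNA must be at least 8 nt to define a seed (got %d nt)",
                  nchar(seq)),
          class = "mirvar_length_error")
  }
  substr(seq, 2, 7)
}

#' Apply a single-nucleotide variant to a UTR
#'
#' Returns the alternate-allele UTR: identical to the input except at the
#' variant position, which now carries the alternate base.  Applying the
#' reverse variant (`alt>ref`) restores the original sequence.
#'
#' @param utr One-row UTR tibble (columns `utr_id`, `sequence`).
#' @param v One-row variant tibble from [parse_variant()].
#' @return A one-row UTR tibble carrying the alternate allele.
#' @export
apply_variant <- function(utr, v) {
  utr <- .check_utr(utr)
  .check_variant(utr, v)
  seq <- utr$sequence
  substr(seq, v$position, v$position) <- v$alt_base
  mutate(utr, sequence = seq)
}

#' Scan a 3'UTR for miRNA seed-match target sites
#'
#' Exhaustive, allele-aware search: every UTR window that is the reverse
#' complement of some miRNA's seed (nt 2-7, with U == T across the
#' RNA/DNA boundary) yields one site.  Each match is classified by the
#' canonical upgrade rules:
#'
#' * `6mer` — the bare window pairing miRNA nt 2-7;
#' * `7mer-m8` — additionally, the UTR base immediately 5' of the window
#'   pairs miRNA nt 8;
#' * `7mer-A1` — additionally, the UTR base immediately 3' of the window
#'   satisfies the A1 rule (see `a1_rule`);
#' * `8mer` — both extensions hold.
#'
#' Each site reports the single highest type it attains, with footprint
#' coordinates (1-based, inclusive) matching that type, plus `match_len`:
#' the maximal contiguous run of perfect Watson-Crick pairs through the seed,
#' extended 5'-ward on the UTR against miRNA nt 8, 9, ... until the first
#' mismatch or a sequence end, and counting the A1 position when it actually
#' pairs miRNA nt 1.  `N` never pairs; G:U wobble is never counted
#' ("perfect complement" matching only).  Overlapping and duplicate-seed
#' sites are all reported, ordered by `start` then `mirna_id`.
#'
#' @param utr One-row UTR tibble (DNA alphabet, sense/mRNA strand).
#' @param mirnas miRNA library tibble (columns `mirna_id`, `sequence`, RNA).
#' @param allele Label attached to the output rows (`"ref"` or `"alt"`).
#' @param a1_rule `"adenine"` (canonical: the UTR base opposite miRNA nt 1
#'   must be an A, whether or not it pairs) or `"pair"` (it must
#'   Watson-Crick pair nt 1).
#' @return A tibble with columns `mirna_id`, `utr_id`, `start`, `end`,
#'   `site_type`, `match_len`, `allele`.
#' @export
scan_sites <- function(utr, mirnas, allele = c("ref", "alt"),
                       a1_rule = c("adenine", "pair")) {
  allele <- match.arg(allele)
  a1_rule <- match.arg(a1_rule)
  utr <- .check_utr(utr)
  if (!is.data.frame(mirnas) || nrow(mirnas) == 0 ||
      !all(c("mirna_id", "sequence") %in% names(mirnas))) {
    abort("mirnas must be a non-empty tibble with mirna_id and sequence",
          class = "mirvar_io_error")
  }
  useq <- utr$sequence
  ulen <- nchar(useq)
  if (ulen < 6) {
    abort("UTR shorter than a seed window (6 nt)", class = "mirvar_length_error")
  }
  uchars <- strsplit(useq, "", fixed = TRUE)[[1]]

  seeds <- vapply(mirnas$sequence, extract_seed, character(1), USE.NAMES = FALSE)
  targets <- vapply(seeds, .revcomp_dna, character(1), USE.NAMES = FALSE)
  valid <- !grepl("*", targets, fixed = TRUE)  # N in seed: never matches

  empty <- tibble(mirna_id = character(), utr_id = character(),
                  start = integer(), end = integer(),
                  site_type = character(), match_len = integer(),
                  allele = character())
  if (!any(valid)) return(empty)

  # overlapping exact matches of each seed target (lookahead regex; seeds
  # sharing a target are matched once and fanned back out)
  uniq <- unique(targets[valid])
  starts_by_target <- lapply(uniq, function(tg) {
    s <- gregexpr(paste0("(?=", tg, ")"), useq, perl = TRUE)[[1]]
    if (s[1] == -1) integer(0) else as.integer(s)
  })
  names(starts_by_target) <- uniq
  starts_by_pattern <- starts_by_target[targets[valid]]
  n_hits <- lengths(starts_by_pattern)
  if (sum(n_hits) == 0) return(empty)

  idx <- rep(which(valid), n_hits)
  win_starts <- unlist(starts_by_pattern, use.names = FALSE)
  mchar_list <- strsplit(mirnas$sequence, "", fixed = TRUE)

  hits <- bind_rows(purrr::map2(idx, win_starts, function(j, s) {
    .classify_site(uchars, s, mchar_list[[j]], a1_rule)
  }))
  hits$mirna_id <- mirnas$mirna_id[idx]

  hits %>%
    mutate(utr_id = utr$utr_id, allele = allele) %>%
    select("mirna_id", "utr_id", "start", "end", "site_type",
           "match_len", "allele") %>%
    arrange(.data$start, .data$mirna_id)
}

# Classify one seed-window match at UTR position s (window s..s+5 pairs
# miRNA nt 7..2).  Position s-1 sits opposite nt 8, position s+6 opposite
# nt 1 (the A1 position).
.classify_site <- function(uchars, s, mchars, a1_rule) {
  ulen <- length(uchars)
  mlen <- length(mchars)
  # 5'-ward extension against miRNA nt 8, 9, ...
  k <- 0L
  while (s - 1L - k >= 1L && 8L + k <= mlen &&
         uchars[s - 1L - k] == .complement_base(mchars[8L + k]) &&
         uchars[s - 1L - k] != "N") {
    k <- k + 1L
  }
  m8 <- k >= 1L
  a1_pos_ok <- s + 6L <= ulen
  a1_base <- if (a1_pos_ok) uchars[s + 6L] else NA_character_
  a1_pairs <- a1_pos_ok && a1_base != "N" && a1_base == .complement_base(mchars[1L])
  a1 <- if (a1_rule == "adenine") a1_pos_ok && a1_base == "A" else a1_pairs

  site_type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else if (a1) "7mer-A1" else "6mer"
  start <- if (m8 && a1) s - 1L else if (m8) s - 1L else s
  end <- if ((m8 && a1) || (!m8 && a1)) s + 6L else s + 5L
  tibble(
    start = as.integer(start), end = as.integer(end),
    site_type = site_type,
    match_len = as.integer(6L + k + as.integer(a1_pairs))
  )
}

#' Sites gained and lost between the two alleles of a UTR variant
#'
#' Scans both alleles of `utr` under `v` and compares the site lists under
#' the identity key (`mirna_id`, `start`, `site_type`): sites present only
#' on the alternate allele are `gained`, only on the reference allele
#' `lost`.  Because only single-nucleotide substitutions are supported, site
#' coordinates are directly comparable across alleles.  Swapping ref and alt
#' in the variant exchanges the gained and lost sets exactly.
#'
#' @inheritParams scan_sites
#' @param v One-row variant tibble from [parse_variant()].
#' @param report `"overlapping_only"` (default) keeps changed sites whose
#'   footprint covers the variant position; `"all"` reports every changed
#'   site plus allele-invariant sites with status `"unchanged"`.
#' @return A tibble with the [scan_sites()] columns plus `overlaps_variant`
#'   (logical) and `status` (`"gained"`, `"lost"` or `"unchanged"`).
#' @export
diff_sites <- function(utr, mirnas, v,
                       report = c("overlapping_only", "all"),
                       a1_rule = c("adenine", "pair")) {
  report <- match.arg(report)
  a1_rule <- match.arg(a1_rule)
  utr <- .check_utr(utr)
  .check_variant(utr, v)
  alt_utr <- apply_variant(utr, v)
  ref_sites <- scan_sites(utr, mirnas, allele = "ref", a1_rule = a1_rule)
  alt_sites <- scan_sites(alt_utr, mirnas, allele = "alt", a1_rule = a1_rule)

  key <- c("mirna_id", "start", "site_type")
  gained <- anti_join(alt_sites, ref_sites, by = key) %>% mutate(status = "gained")
  lost <- anti_join(ref_sites, alt_sites, by = key) %>% mutate(status = "lost")
  out <- bind_rows(gained, lost)
  if (report == "all") {
    unchanged <- dplyr::semi_join(ref_sites, alt_sites, by = key) %>%
      mutate(status = "unchanged")
    out <- bind_rows(out, unchanged)
  }
  out <- out %>%
    mutate(overlaps_variant = v$position >= .data$start & v$position <= .data$end,
           .before = "status")
  if (report == "overlapping_only") {
    out <- filter(out, .data$status == "unchanged" | .data$overlaps_variant)
  }
  arrange(out, .data$status, .data$start, .data$mirna_id)
}
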