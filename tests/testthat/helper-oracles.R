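# Independent oracles used across the suite.  These deliberately take the
# naive route (window-by-window enumeration, full hypergeometric sums) so
# they share no code path with the package implementation.

# Reverse complement of an RNA string into DNA, via chartr.
oracle_revcomp <- function(rna) {
  comp <- chartr("ACGUN", "TGCA*", rna)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Does UTR base u pair miRNA base m (perfect Watson-Crick, N never pairs)?
oracle_pairs <- function(u, m) {
  u == chartr("ACGUN", "TGCA*", m) && u != "N"
}

# Enumerate every 6-nt UTR window against every miRNA seed and classify.
# Returns a data frame with the scan_sites() site columns.
oracle_scan <- function(utr_seq, mirnas, a1_rule = "adenine") {
  ulen <- nchar(utr_seq)
  u <- strsplit(utr_seq, "")[[1]]
  starts <- seq_len(ulen - 5)
  windows <- substring(utr_seq, starts, starts + 5)
  rows <- list()
  for (j in seq_len(nrow(mirnas))) {
    mseq <- mirnas$sequence[j]
    m <- strsplit(mseq, "")[[1]]
    target <- oracle_revcomp(substr(mseq, 2, 7))
    if (grepl("*", target, fixed = TRUE)) next
    for (s in starts[windows == target]) {
      # 5'-ward extension against nt 8, 9, ...
      k <- 0
      while (s - 1 - k >= 1 && 8 + k <= length(m) &&
             oracle_pairs(u[s - 1 - k], m[8 + k])) k <- k + 1
      m8 <- k >= 1
      a1_ok <- s + 6 <= ulen
      a1_pair <- a1_ok && oracle_pairs(u[s + 6], m[1])
      a1 <- if (a1_rule == "adenine") a1_ok && u[s + 6] == "A" else a1_pair
      type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else if (a1) "7mer-A1" else "6mer"
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = mirnas$mirna_id[j],
        start = if (m8) s - 1 else s,
        end = if (a1) s + 6 else s + 5,
        site_type = type,
        match_len = 6 + k + as.integer(a1_pair)
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), start = integer(),
                      end = integer(), site_type = character(),
                      match_len = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$mirna_id), , drop = FALSE]
}

# Two-sided Fisher p by full hypergeometric enumeration (tables at most as
# probable as observed, conditional on margins; same 1e-7 relative fudge as
# the conventional implementation).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  pobs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

random_library <- function(n, len = 22) {
  tibble::tibble(
    mirna_id = sprintf("rand-miR-%03d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
    }, character(1))
  )
}

random_utr <- function(len, with_n = FALSE) {
  alph <- c("A", "C", "G", "T", if (with_n) "N")
  tibble::tibble(
    utr_id = "rand-utr",
    sequence = paste(sample(alph, len, replace = TRUE,
                            prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
                     collapse = "")
  )
}
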