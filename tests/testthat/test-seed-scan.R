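utr1 <- function(seq) tibble::tibble(utr_id = "u", sequence = seq)
lib1 <- function(seq, id = "m1") tibble::tibble(mirna_id = id, sequence = seq)

test_that("the seed is miRNA nt 2-7 and short miRNAs are rejected", {
  expect_equal(extract_seed("UAGCUUAUCAGACUGAUGUUGA"), "AGCUUA")
  expect_equal(extract_seed("AGGGACGG"), "GGGACG")  # 8 nt minimum
  expect_error(extract_seed("AGGGACG"), class = "mirvar_length_error")
})

test_that("applying a variant changes exactly one base and is an involution", {
  utr <- utr1("ACGT")
  v <- parse_variant("c.*2C>G", utr)
  alt <- apply_variant(utr, v)
  expect_equal(alt$sequence, "AGGT")
  back <- apply_variant(alt, tibble::tibble(utr_id = "u", position = 2L,
                                            ref_base = "G", alt_base = "C"))
  expect_equal(back$sequence, utr$sequence)
  expect_error(parse_variant("c.*5A>G", utr), class = "mirvar_range_error")
  expect_error(apply_variant(utr, tibble::tibble(utr_id = "u", position = 2L,
                                                 ref_base = "T", alt_base = "G")),
               class = "mirvar_ref_mismatch_error")
})

test_that("a perfect seed complement yields one site; one mismatch yields none", {
  # revcomp(AGCUUA) = TAAGCT at UTR positions 5-10
  utr <- utr1("AAAATAAGCTAAAA")
  lib <- lib1("UAGCUUAUCA")
  sites <- scan_sites(utr, lib)
  expect_equal(nrow(sites), 1)
  expect_equal(substr(utr$sequence, 5, 10), "TAAGCT")
  expect_true(sites$start <= 5 && sites$end >= 10)  # footprint contains the window
  expect_gte(sites$match_len, 6)

  mut <- utr1("AAAATACGCTAAAA")  # one base changed inside the window
  expect_equal(nrow(scan_sites(mut, lib)), 0)
})

test_that("a contiguous nt1-8 complement scores match_len >= 8 and 8mer class", {
  mirna <- "UGGGACGGACGAUCACGCAGGG"   # nt1 U so the A1 adenine also pairs
  # revcomp of nt 1-8 (UGGGACGG) in DNA: CCGTCCCA; pad with C's
  site8 <- "CCGTCCCA"
  utr <- utr1(paste0("CCCC", site8, "CCCC"))
  sites <- scan_sites(utr, lib1(mirna))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_type, "8mer")
  expect_gte(sites$match_len, 8)
  # 8mer footprint is 8 bases covering m8 and A1 positions
  expect_equal(sites$end - sites$start + 1L, 8L)
})

test_that("site classes carry the footprint widths of their type", {
  widths <- c(`6mer` = 6L, `7mer-A1` = 7L, `7mer-m8` = 7L, `8mer` = 8L)
  set.seed(21)
  for (type in names(widths)) {
    planted <- plant_gain_variant(lib1("UAGCUUAUCAGACUGAUGUUGA"),
                                  site_type = type, utr_length = 60,
                                  position = 28, seed = 301)
    alt <- apply_variant(planted$utr, planted$variant)
    s <- scan_sites(alt, lib1("UAGCUUAUCAGACUGAUGUUGA"))
    expect_equal(s$site_type, type)
    expect_equal(s$end - s$start + 1L, unname(widths[type]))
  }
})

test_that("every reported upgrade re-satisfies its defining conditions", {
  set.seed(31)
  for (rep in 1:20) {
    utr <- random_utr(120)
    lib <- random_library(20, len = 22)
    sites <- scan_sites(utr, lib)
    if (nrow(sites) == 0) next
    u <- strsplit(utr$sequence, "")[[1]]
    for (i in seq_len(nrow(sites))) {
      m <- strsplit(lib$sequence[lib$mirna_id == sites$mirna_id[i]], "")[[1]]
      # recover the 6mer window start from the footprint
      s <- if (sites$site_type[i] %in% c("7mer-m8", "8mer")) sites$start[i] + 1L else sites$start[i]
      if (sites$site_type[i] %in% c("7mer-m8", "8mer")) {
        expect_true(oracle_pairs(u[s - 1], m[8]))
      }
      if (sites$site_type[i] %in% c("7mer-A1", "8mer")) {
        expect_equal(u[s + 6], "A")
      }
      expect_gte(sites$match_len[i], 6)
    }
  }
})

test_that("scan_sites equals the naive window enumeration oracle on random inputs", {
  set.seed(41)
  for (rep in 1:150) {
    utr <- random_utr(sample(40:200, 1), with_n = rep %% 5 == 0)
    lib <- random_library(sample(5:50, 1), len = sample(18:24, 1))
    got <- scan_sites(utr, lib)
    want <- oracle_scan(utr$sequence, lib)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$mirna_id, want$mirna_id)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$site_type, want$site_type)
      expect_equal(got$match_len, want$match_len)
    }
  }
})

test_that("the pair variant of the A1 rule differs exactly where nt1 is not U", {
  # A opposite nt 1: adenine rule upgrades regardless, pair rule only if nt1 == U
  mirna_nonU <- "GAGCUUAUCAGACUGAUGUUGA"  # nt1 = G
  utr <- utr1("CCCCTAAGCTACCCC")          # window 5-10, A at position 11
  s_ad <- scan_sites(utr, lib1(mirna_nonU), a1_rule = "adenine")
  s_pr <- scan_sites(utr, lib1(mirna_nonU), a1_rule = "pair")
  expect_equal(s_ad$site_type, "7mer-A1")
  expect_equal(s_pr$site_type, "6mer")
})

test_that("windows containing N never match and N never extends a pairing run", {
  lib <- lib1("UAGCUUAUCA")
  expect_equal(nrow(scan_sites(utr1("AAAATANGCTAAAA"), lib)), 0)
  # N at the m8 position: site stays a 6mer/7mer-A1, never m8
  s <- scan_sites(utr1("CCCNTAAGCTGCCC"), lib)
  expect_equal(nrow(s), 1)
  expect_false(s$site_type %in% c("7mer-m8", "8mer"))
})

test_that("diff_sites reports a planted gain, filters by overlap, and is symmetric", {
  mirna <- lib1("UAGCUUAUCAGACUGAUGUUGA", id = "sim-miR-0001")
  planted <- plant_gain_variant(mirna, "8mer", utr_length = 100,
                                position = 28, seed = 7)
  delta <- diff_sites(planted$utr, mirna, planted$variant)
  expect_equal(delta$status, "gained")
  expect_true(all(delta$overlaps_variant))
  expect_equal(nrow(delta), 1)

  # swapping ref/alt exchanges gained and lost exactly
  alt_utr <- apply_variant(planted$utr, planted$variant)
  swapped <- dplyr::mutate(planted$variant, ref_base = alt_base,
                           alt_base = planted$variant$ref_base)
  rev_delta <- diff_sites(alt_utr, mirna, swapped)
  expect_equal(rev_delta$status, "lost")
  expect_equal(rev_delta[, c("mirna_id", "start", "end", "site_type")],
               delta[, c("mirna_id", "start", "end", "site_type")])
})

test_that("a variant outside every seed window gives an empty overlapping delta", {
  utr <- utr1("AAAATAAGCTAAAAGGGGGG")
  lib <- lib1("UAGCUUAUCA")
  v <- parse_variant("c.*18G>C", utr)
  delta <- diff_sites(utr, lib, v)
  expect_equal(nrow(delta), 0)
  # with report = "all" the untouched site shows up as unchanged
  all_delta <- diff_sites(utr, lib, v, report = "all")
  expect_true("unchanged" %in% all_delta$status)
})

test_that("scans are deterministic and ordered by start then mirna_id", {
  set.seed(51)
  utr <- random_utr(200)
  lib <- random_library(40)
  a <- scan_sites(utr, lib)
  b <- scan_sites(utr, lib)
  expect_identical(a, b)
  expect_false(is.unsorted(a$start))
})
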