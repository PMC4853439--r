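test_that("miRNA library generation is seeded, typed and seed-sensitive", {
  a <- make_mirna_library(5, 22, seed = 1)
  b <- make_mirna_library(5, 22, seed = 1)
  expect_identical(a, b)
  expect_true(all(nchar(a$sequence) == 22))
  expect_true(all(strsplit(paste(a$sequence, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "U")))
  expect_equal(a$mirna_id[1], "sim-miR-0001")
  c <- make_mirna_library(5, 22, seed = 2)
  expect_false(all(a$sequence == c$sequence))
  expect_error(make_mirna_library(5, 7), class = "mirvar_length_error")
})

test_that("planted gain variants close the loop through diff_sites", {
  mirna <- make_mirna_library(1, 22, seed = 5)
  for (type in c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
    planted <- plant_gain_variant(mirna, type, utr_length = 120,
                                  position = 28, seed = 9)
    delta <- diff_sites(planted$utr, mirna, planted$variant)
    expect_equal(delta$status, "gained")
    expect_equal(delta$site_type, type)
    expect_equal(nrow(delta), 1)
    # reverting the variant leaves zero sites for the miRNA
    expect_equal(nrow(scan_sites(planted$utr, mirna)), 0)
    alt <- apply_variant(planted$utr, planted$variant)
    back <- dplyr::mutate(planted$variant, ref_base = alt_base,
                          alt_base = planted$variant$ref_base)
    expect_equal(apply_variant(alt, back)$sequence, planted$utr$sequence)
  }
  # planted 6mer has a 6-base footprint
  p6 <- plant_gain_variant(mirna, "6mer", utr_length = 120, position = 28,
                           seed = 9)
  d6 <- diff_sites(p6$utr, mirna, p6$variant)
  expect_equal(d6$end - d6$start + 1L, 6L)
})

test_that("cohort simulation is seeded Bernoulli with the configured sizes", {
  cfg <- sim_config(rng_seed = 3)
  g <- simulate_cohort(cfg)
  expect_equal(nrow(g), 378 + 1870)
  expect_equal(sum(g$group == "case"), 378)
  expect_equal(sum(g$group == "control_longlived"), 1576)
  expect_equal(sum(g$group == "control_healthy"), 294)
  expect_identical(g, simulate_cohort(cfg))
  expect_true(all(g$genotype %in% c("C/T", "T/T")))

  none <- simulate_cohort(sim_config(rng_seed = 3, carrier_prob_cases = 0,
                                     carrier_prob_controls = 0))
  expect_true(all(none$genotype == "T/T"))
})

test_that("ECG simulation recovers the configured carrier PR shift", {
  cfg <- sim_config(rng_seed = 13, pr_shift_carrier = 30, pr_sd = 20)
  g <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:378),
    group = "case",
    genotype = c(rep("T/C", 15), rep("T/T", 363))
  )
  ph <- simulate_ecg(g, cfg)
  expect_identical(ph, simulate_ecg(g, cfg))
  carriers <- ph$pr_ms[1:15]
  expect_equal(mean(carriers), cfg$pr_mean_noncarrier + 30,
               tolerance = 3 * 20 / sqrt(15) / (cfg$pr_mean_noncarrier + 30))
  # RR/QRS/QT are genotype-independent: no systematic carrier shift
  tt <- two_sample_t(ph$rr_ms[1:15], ph$rr_ms[16:378])
  expect_gt(tt$p_value, 0.001)
})

test_that("null PR simulation gives uniform t-test p-values", {
  cfg0 <- sim_config(rng_seed = 17, pr_shift_carrier = 0,
                     n_cases = 120, n_controls = 120,
                     carrier_prob_cases = 0.5, carrier_prob_controls = 0.5)
  pvals <- vapply(1:200, function(i) {
    cfg_i <- cfg0
    cfg_i$rng_seed <- 1000L + i
    g <- simulate_cohort(cfg_i)
    ph <- simulate_ecg(g, cfg_i)
    carrier <- g$genotype == "C/T"
    two_sample_t(ph$pr_ms[carrier], ph$pr_ms[!carrier])$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("plasma Ct simulation yields the configured expression ratio", {
  # zero-noise limit: carrier/noncarrier ratio is exactly 1/3
  cfg0 <- sim_config(rng_seed = 23, ct_sd = 1e-12, ct_spike_sd = 1e-12,
                     ct_technical_sd = 0, n_cases = 40, n_controls = 40,
                     carrier_prob_cases = 0.5, carrier_prob_controls = 0.5)
  g <- simulate_cohort(cfg0)
  ct <- simulate_plasma_ct(g, cfg0)
  expect_identical(ct, simulate_plasma_ct(g, cfg0))
  expr <- relative_expression(ct, "spike_in") %>%
    dplyr::left_join(dplyr::select(g, sample_id = subject_id, genotype),
                     by = "sample_id") %>%
    dplyr::mutate(status = ifelse(genotype == "C/T", "carrier", "noncarrier"))
  fc <- expression_fold_change(expr, "status", reference = "noncarrier")
  expect_equal(fc$fold_change[fc$status == "carrier"], 1 / 3, tolerance = 1e-9)

  # no shift: ratio near 1 at n = 200 per group
  cfg1 <- sim_config(rng_seed = 29, ct_shift_carrier = 0, n_cases = 200,
                     n_controls = 200, carrier_prob_cases = 1,
                     carrier_prob_controls = 0)
  g1 <- simulate_cohort(cfg1)
  ct1 <- simulate_plasma_ct(g1, cfg1)
  expr1 <- relative_expression(ct1, "spike_in") %>%
    dplyr::left_join(dplyr::select(g1, sample_id = subject_id, group),
                     by = "sample_id") %>%
    dplyr::mutate(status = ifelse(group == "case", "carrier", "noncarrier"))
  fc1 <- expression_fold_change(expr1, "status", reference = "noncarrier")
  expect_equal(fc1$fold_change[fc1$status == "carrier"], 1, tolerance = 0.25)
})

test_that("the full simulated study closes the loop end to end", {
  cfg <- sim_config(rng_seed = 37, n_cases = 100, n_controls = 400,
                    carrier_prob_cases = 0.15, carrier_prob_controls = 0.05)
  study <- simulate_study(cfg)
  # (i) the planted gained site is recovered exactly
  delta <- diff_sites(study$utr, study$mirnas, study$variant)
  gained <- delta[delta$status == "gained" &
                    delta$mirna_id == study$mirnas$mirna_id[1], ]
  expect_equal(nrow(gained), 1)
  expect_equal(gained$site_type, cfg$planted_site_type)
  # (ii) association runs on the simulated genotypes
  fit <- test_association(study$genotypes)
  expect_gt(tidy(fit)$estimate, 1)
  # (iii) the PR shift is recovered with the right sign
  res <- phenotype_by_genotype(study$phenotypes, study$genotypes, "pr_ms")
  expect_gt(res$summary$mean[res$summary$group == "carrier"],
            res$summary$mean[res$summary$group == "noncarrier"])
})
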