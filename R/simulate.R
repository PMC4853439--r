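#' Simulation configuration for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generators.  The defaults
#' mirror the magnitudes of the motivating candidate-gene study: 378 cases
#' and 1870 pooled controls; carrier probabilities 15/378 and 32/1870
#' (generating carrier odds ratio 2.37); a PR-interval shift that puts
#' carrier means above the 200 ms prolongation threshold; and a plasma Ct
#' shift of log2(3) cycles in carriers, i.e. a threefold expression
#' decrease.  Exact cohort means/SDs are not published, so the continuous
#' defaults are illustrative values typical of adult ECGs.
#'
#' @param rng_seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_cases,n_controls Cohort sizes.
#' @param carrier_prob_cases,carrier_prob_controls Per-subject carrier
#'   (heterozygote) probabilities.
#' @param pr_mean_noncarrier,pr_shift_carrier,pr_sd PR-interval model (ms):
#'   carrier mean = noncarrier mean + shift.
#' @param rr_mean,rr_sd,qrs_mean,qrs_sd,qt_mean,qt_sd Genotype-independent
#'   ECG interval models (ms).
#' @param ct_base,ct_sd Plasma target-assay Ct model (cycles).
#' @param ct_shift_carrier Carrier shift of the target Ct (cycles);
#'   `log2(3)` gives an expected threefold expression decrease.
#' @param ct_spike_base,ct_spike_sd Spike-in assay Ct model.
#' @param ct_technical_sd Within-triplicate technical SD (cycles).
#' @param utr_length,n_mirnas,mirna_length,planted_site_type Sequence-side
#'   defaults for the planted-site generators.
#' @return A list of class `mirvar_sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_cases = 378L, n_controls = 1870L,
                       carrier_prob_cases = 15 / 378,
                       carrier_prob_controls = 32 / 1870,
                       pr_mean_noncarrier = 165, pr_shift_carrier = 45,
                       pr_sd = 25,
                       rr_mean = 900, rr_sd = 100,
                       qrs_mean = 95, qrs_sd = 10,
                       qt_mean = 400, qt_sd = 30,
                       ct_base = 30, ct_sd = 0.8,
                       ct_shift_carrier = log2(3),
                       ct_spike_base = 20, ct_spike_sd = 0.3,
                       ct_technical_sd = 0.1,
                       utr_length = 200L, n_mirnas = 50L,
                       mirna_length = 22L,
                       planted_site_type = "8mer") {
  cfg <- as.list(environment())
  stopifnot(
    cfg$carrier_prob_cases >= 0, cfg$carrier_prob_cases <= 1,
    cfg$carrier_prob_controls >= 0, cfg$carrier_prob_controls <= 1,
    cfg$pr_sd > 0, cfg$ct_sd >= 0, cfg$utr_length >= 20,
    cfg$mirna_length >= 8,
    cfg$planted_site_type %in% c("6mer", "7mer-A1", "7mer-m8", "8mer")
  )
  structure(cfg, class = "mirvar_sim_config")
}

#' Generate a random mature-miRNA library
#'
#' Uniform random RNA sequences with synthetic ids (`sim-miR-0001`, ...),
#' standing in for a real mature-miRNA library.  Seeded and reproducible.
#'
#' @param n Number of miRNAs (>= 1).
#' @param length Sequence length in nt (>= 8).
#' @param seed Integer seed.
#' @return A miRNA tibble (`mirna_id`, `sequence`).
#' @export
make_mirna_library <- function(n = 50L, length = 22L, seed = 1L) {
  if (length < 8) {
    abort("miRNA length must be >= 8", class = "mirvar_length_error")
  }
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    tibble(
      mirna_id = sprintf("sim-miR-%04d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
              collapse = "")
      }, character(1))
    )
  })
}

#' Plant a variant that creates a seed site for one miRNA
#'
#' Constructs a random-background UTR and a single-nucleotide variant such
#' that the alternate allele carries exactly one site of the requested type
#' for `mirna`, overlapping the variant, while the reference allele carries
#' no site of any type for that miRNA anywhere in the UTR.  The construction
#' is verified internally with [scan_sites()] on both alleles and the
#' background is resampled (bounded retries) until it holds — emulating a
#' regulatory variant whose alternate allele completes a seed match.
#'
#' @param mirna One-row miRNA tibble.
#' @param site_type Planted site class (`"6mer"`, `"7mer-A1"`, `"7mer-m8"`,
#'   `"8mer"`).
#' @param utr_length UTR length (nt, >= 20).
#' @param position Variant c.* position; the seed window is placed to cover
#'   it.  Defaults to 28.
#' @param seed Integer seed.
#' @param max_tries Background resampling bound.
#' @return A list: `utr` (reference-allele UTR tibble), `variant` (variant
#'   tibble), `site_type`.
#' @export
plant_gain_variant <- function(mirna, site_type = "8mer",
                               utr_length = 200L, position = 28L,
                               seed = 1L, max_tries = 100L) {
  stopifnot(site_type %in% c("6mer", "7mer-A1", "7mer-m8", "8mer"))
  if (is.data.frame(mirna) && nrow(mirna) != 1) {
    abort("expected a single miRNA", class = "mirvar_io_error")
  }
  mseq <- if (is.data.frame(mirna)) mirna$sequence else mirna
  mid <- if (is.data.frame(mirna)) mirna$mirna_id else "mirna"
  seed6 <- extract_seed(mseq)
  target <- .revcomp_dna(seed6)
  mchars <- strsplit(mseq, "", fixed = TRUE)[[1]]
  needs_m8 <- site_type %in% c("7mer-m8", "8mer")
  needs_a1 <- site_type %in% c("7mer-A1", "8mer")

  # window start s: window covers the variant, full footprint inside the UTR
  s <- min(max(2L, position - 2L), utr_length - 6L, position)
  s <- max(s, position - 5L)
  if (s < 2L || s + 6L > utr_length || position < s || position > s + 5L) {
    abort("position does not leave room for the site footprint",
          class = "mirvar_range_error")
  }

  comp8 <- .complement_base(mchars[8])
  comp1 <- .complement_base(mchars[1])
  bases <- c("A", "C", "G", "T")

  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      uchars <- sample(bases, utr_length, replace = TRUE)
      uchars[s:(s + 5L)] <- strsplit(target, "", fixed = TRUE)[[1]]
      uchars[s - 1L] <- if (needs_m8) comp8 else sample(setdiff(bases, comp8), 1)
      uchars[s + 6L] <- if (needs_a1) "A" else sample(setdiff(bases, c("A", comp1)), 1)
      # keep the planted duplex clean: no chance pairing past the footprint
      if (needs_m8 && s - 2L >= 1L && length(mchars) >= 9L) {
        uchars[s - 2L] <- sample(setdiff(bases, .complement_base(mchars[9])), 1)
      }
      alt_base <- uchars[position]
      ref_base <- sample(setdiff(bases, alt_base), 1)
      alt_seq <- paste(uchars, collapse = "")
      ref_chars <- uchars
      ref_chars[position] <- ref_base
      ref_utr <- tibble(utr_id = "sim-utr", sequence = paste(ref_chars, collapse = ""))
      alt_utr <- tibble(utr_id = "sim-utr", sequence = alt_seq)
      lib1 <- tibble(mirna_id = mid, sequence = mseq)
      ref_hits <- scan_sites(ref_utr, lib1, allele = "ref")
      alt_hits <- scan_sites(alt_utr, lib1, allele = "alt")
      ok <- nrow(ref_hits) == 0 && nrow(alt_hits) == 1 &&
        alt_hits$site_type == site_type &&
        position >= alt_hits$start && position <= alt_hits$end
      if (ok) {
        v <- tibble(utr_id = "sim-utr", position = as.integer(position),
                    ref_base = ref_base, alt_base = alt_base)
        return(list(utr = ref_utr, variant = v, site_type = site_type))
      }
    }
  })
  abort(sprintf("could not plant a clean %s site in %d tries", site_type, max_tries),
        class = "mirvar_generation_error")
}

#' Simulate a case-control genotype cohort
#'
#' Carrier status is Bernoulli with a group-specific probability; carriers
#' are heterozygous (homozygous-minor genotypes were not observed in the
#' motivating study and are off by default).  Controls are split between
#' the long-lived and healthy control groups in the study's 1576:294
#' proportion.
#'
#' @param cfg A [sim_config()].
#' @return A genotype tibble (`subject_id`, `group`, `genotype`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  withr::with_seed(cfg$rng_seed, {
    n_ll <- round(cfg$n_controls * 1576 / 1870)
    n_hc <- cfg$n_controls - n_ll
    groups <- c(rep("case", cfg$n_cases),
                rep("control_longlived", n_ll),
                rep("control_healthy", n_hc))
    probs <- ifelse(groups == "case",
                    cfg$carrier_prob_cases, cfg$carrier_prob_controls)
    carrier <- rbinom(length(groups), 1, probs) == 1
    tibble(
      subject_id = sprintf("sim%05d", seq_along(groups)),
      group = groups,
      genotype = ifelse(carrier, "C/T", "T/T")
    )
  })
}

#' Simulate ECG phenotypes for a genotyped cohort
#'
#' PR interval is normal with a carrier shift
#' (`pr_mean_noncarrier + pr_shift_carrier * is_carrier`, SD `pr_sd`);
#' RR, QRS and QT are genotype-independent normals.  All in milliseconds.
#'
#' @param genotypes Genotype tibble (carrier = any `C` allele).
#' @param cfg A [sim_config()].
#' @return A phenotype tibble (`subject_id`, `pr_ms`, `rr_ms`, `qrs_ms`,
#'   `qt_ms`).
#' @export
simulate_ecg <- function(genotypes, cfg = sim_config()) {
  withr::with_seed(cfg$rng_seed + 1L, {
    n <- nrow(genotypes)
    carrier <- .carries(normalize_genotype(genotypes$genotype), "C")
    tibble(
      subject_id = genotypes$subject_id,
      pr_ms = rnorm(n, cfg$pr_mean_noncarrier + cfg$pr_shift_carrier * carrier,
                    cfg$pr_sd),
      rr_ms = rnorm(n, cfg$rr_mean, cfg$rr_sd),
      qrs_ms = rnorm(n, cfg$qrs_mean, cfg$qrs_sd),
      qt_ms = rnorm(n, cfg$qt_mean, cfg$qt_sd)
    )
  })
}

#' Simulate plasma qPCR Ct triplicates for a genotyped cohort
#'
#' Per subject, the target-assay Ct is normal with mean
#' `ct_base + ct_shift_carrier * is_carrier`; the spike-in Ct is normal
#' around `ct_spike_base`.  Triplicates add technical noise
#' (`ct_technical_sd`).  With `ct_shift_carrier = log2(3)` the expected
#' carrier/non-carrier group expression ratio is 1/3 (a threefold
#' decrease), exactly so in the zero-noise limit.
#'
#' @param genotypes Genotype tibble.
#' @param cfg A [sim_config()].
#' @return A Ct tibble (`sample_id`, `assay_id`, `role`, `ct1`..`ct3`).
#' @export
simulate_plasma_ct <- function(genotypes, cfg = sim_config()) {
  withr::with_seed(cfg$rng_seed + 2L, {
    n <- nrow(genotypes)
    carrier <- .carries(normalize_genotype(genotypes$genotype), "C")
    ct_t <- rnorm(n, cfg$ct_base + cfg$ct_shift_carrier * carrier, cfg$ct_sd)
    ct_s <- rnorm(n, cfg$ct_spike_base, cfg$ct_spike_sd)
    trip <- function(ct) {
      vapply(ct, function(x) x + rnorm(3, 0, cfg$ct_technical_sd), numeric(3))
    }
    tt <- trip(ct_t); ts <- trip(ct_s)
    bind_rows(
      tibble(sample_id = genotypes$subject_id, assay_id = "sim-miR-target",
             role = "target", ct1 = tt[1, ], ct2 = tt[2, ], ct3 = tt[3, ]),
      tibble(sample_id = genotypes$subject_id, assay_id = "sim-spike-in",
             role = "spike_in", ct1 = ts[1, ], ct2 = ts[2, ], ct3 = ts[3, ])
    ) %>% arrange(.data$sample_id, .data$role)
  })
}

#' Simulate the full synthetic study
#'
#' Runs every generator under one config: miRNA library, a UTR with a
#' planted gain-of-site variant for the first library miRNA, the genotype
#' cohort, ECG phenotypes and plasma Ct tables.
#'
#' @param cfg A [sim_config()].
#' @return A list: `config`, `mirnas`, `utr`, `variant`, `genotypes`,
#'   `phenotypes`, `ct_table`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  mirnas <- make_mirna_library(cfg$n_mirnas, cfg$mirna_length,
                               seed = cfg$rng_seed + 3L)
  planted <- plant_gain_variant(mirnas[1, ], cfg$planted_site_type,
                                cfg$utr_length, seed = cfg$rng_seed + 4L)
  genotypes <- simulate_cohort(cfg)
  list(
    config = cfg,
    mirnas = mirnas,
    utr = planted$utr,
    variant = planted$variant,
    genotypes = genotypes,
    phenotypes = simulate_ecg(genotypes, cfg),
    ct_table = simulate_plasma_ct(genotypes, cfg)
  )
}
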