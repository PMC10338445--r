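small_cfg <- function(...) cohort_config(n_pregnancies = 20, ...)

test_that("simulation is deterministic under a fixed seed", {
  c1 <- simulate_cohort(small_cfg(), seed = 123)
  c2 <- simulate_cohort(small_cfg(), seed = 123)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$pregnancy_meta, c2$pregnancy_meta)
  expect_identical(c1$cytokines, c2$cytokines)
  c3 <- simulate_cohort(small_cfg(), seed = 124)
  expect_false(identical(c1$counts, c3$counts))
  expect_error(simulate_cohort(small_cfg()), "seed is mandatory")
})

test_that("compositional rows sum to their library sizes with consistent keys", {
  co <- simulate_cohort(small_cfg(), seed = 11)
  expect_equal(unname(rowSums(co$counts)), co$sample_meta$library_size)
  expect_equal(rownames(co$counts), co$sample_meta$sample_id)
  expect_equal(colnames(co$counts), co$taxonomy$asv_id)
  # gestational days negative, postpartum positive, strictly ordered per pregnancy
  by_preg <- split(co$sample_meta$day_vs_delivery, co$sample_meta$pregnancy_id)
  expect_true(all(vapply(by_preg, function(d) all(diff(d) > 0), logical(1))))
  expect_true(all(co$sample_meta$day_vs_delivery[co$sample_meta$phase == "gestation"] < 0))
  expect_true(all(co$sample_meta$day_vs_delivery[co$sample_meta$phase == "postpartum"] > 0))
})

test_that("gestational diversity of Lactobacillus-dominant states sits near the centroid", {
  co <- simulate_cohort(cohort_config(n_pregnancies = 40), seed = 21)
  st <- cohort_states(co)
  gest <- st[st$phase == "gestation", ]
  crisp <- gest[gest$pregnancy_id %in%
                  co$pregnancy_meta$pregnancy_id[co$pregnancy_meta$true_state ==
                                                   "L. crispatus"], ]
  cent <- co$config$panel$centroids["L. crispatus", ]
  cent_eff <- exp(-sum(cent[cent > 0] * log(cent[cent > 0])))
  expect_lt(abs(median(crisp$effective_asvs) - cent_eff), 1)
  # dominant-state samples designate to their generating state most of the time
  expect_gt(mean(crisp$label == "L. crispatus"), 0.9)
})

test_that("degenerate config: certain perturbation and zero hazards freeze the diverse state", {
  cfg <- small_cfg(p_delivery_perturbation = 1,
                   recovery_hazards = c("L. iners" = 0),
                   covariate_effects = c(contraception = 1))
  co <- simulate_cohort(cfg, seed = 31)
  st <- cohort_states(co, min_reads = 0)
  expect_true(all(st$label[st$phase == "postpartum"] == "diverse"))
  res <- cohort_time_to_dominance(co, "Lactobacillus", min_reads = 0)
  expect_equal(sum(res$km$n_event), 0)
  expect_true(all(res$km$survival == 1))
  expect_equal(res$incidence$probability, 0)
})

test_that("closed-form truths behave at the corners", {
  cfg0 <- small_cfg(recovery_hazards = c("L. iners" = 0))
  expect_equal(unname(truth_summary(cfg0)$taxon_incidence_1yr), 0)
  cfg_half <- small_cfg(recovery_hazards = c("L. iners" = log(2) / 365))
  tr <- truth_summary(cfg_half)
  expect_equal(unname(tr$taxon_incidence_1yr), 0.5)
  expect_equal(tr$lactobacillus_incidence_1yr, 0.5)
  # single cause: competing and single-cause incidences coincide
  expect_equal(unname(tr$taxon_incidence_competing), 0.5)
  # the visit-schedule estimand is below the continuous-time truth
  expect_lt(unname(tr$observable_incidence), 0.5)
  lam <- log(2) / 365
  expect_equal(unname(tr$observable_incidence),
               (exp(-lam * 30) - exp(-lam * 360)) / exp(-lam * 30),
               tolerance = 1e-12)
  # parity: equal odds across parity gives OR 1 for every state
  cfg_eq <- small_cfg(crispatus_parity_or = 1, long_interval_or = 1)
  expect_equal(unname(truth_summary(cfg_eq)$state_or),
               rep(1, 6), tolerance = 1e-12)
  # the configured crispatus OR is exact when the interval effect is off
  cfg_or <- small_cfg(crispatus_parity_or = 0.2, long_interval_or = 1)
  expect_equal(truth_summary(cfg_or)$state_or[["L. crispatus"]], 0.2,
               tolerance = 1e-12)
})

test_that("cytokine concentrations couple to diversity with LOD-censorable tails", {
  co <- simulate_cohort(cohort_config(n_pregnancies = 60), seed = 41)
  cens <- censor_lod(co$cytokines)
  expect_true(all(c("below", "in_range") %in% unique(cens$censor_flag)))
  # responsive analyte rises with measured SDI; flat analyte does not
  anchors <- co$sample_meta$sample_id[!is.na(co$sample_meta$anchor)]
  sdi <- designate_states(co$counts[anchors, ], co$taxonomy)$shannon
  wide <- cytokine_matrix(cens)
  wide <- wide[anchors, ]
  resp <- names(which(co$truth$cytokine_slopes > 0))[1]
  flat <- names(which(co$truth$cytokine_slopes == 0))[1]
  fit_resp <- stats::coef(stats::lm(log10(wide[, resp]) ~ sdi))[2]
  fit_flat <- stats::coef(stats::lm(log10(wide[, flat]) ~ sdi))[2]
  expect_equal(unname(fit_resp), co$truth$cytokine_slopes[[resp]],
               tolerance = 0.35)
  expect_lt(abs(fit_flat), 0.1)
})

test_that("KM confidence intervals are calibrated for the visit-schedule estimand", {
  # With monthly visits, transitions are seen only at visit days and cases
  # already dominated at the first visit are screened out; the pipeline's
  # estimand is therefore truth_summary()$observable_incidence, and the KM
  # CI should cover *that* quantity at its nominal rate.
  lam <- log(2) / 365
  cfg <- cohort_config(
    n_pregnancies = 200,
    recovery_hazards = c("L. iners" = lam / 2, "L. crispatus" = lam / 2),
    covariate_effects = c(contraception = 1, menses_resumption = 1,
                          lactation_end = 1),
    p_low_yield = 0)
  estimand <- truth_summary(cfg)$lactobacillus_observable
  n_rep <- 200
  covered <- logical(n_rep)
  est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(cfg, seed = 60000 + r)
    res <- cohort_time_to_dominance(co, "Lactobacillus")
    est[r] <- res$incidence$probability
    covered[r] <- res$incidence$ci_lower <= estimand &
      estimand <= res$incidence$ci_upper
  }
  expect_lt(abs(mean(est) - estimand), 0.02)
  expect_gte(mean(covered), 0.925)
  expect_lte(mean(covered), 0.975)
})

test_that("cohort files round-trip through the readers", {
  co <- simulate_cohort(small_cfg(), seed = 51)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  on.exit(unlink(dir, recursive = TRUE))
  counts <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(counts, co$counts)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax, co$taxonomy)
  meta <- read_metadata(file.path(dir, "sample_metadata.csv"))
  expect_equal(meta$sample_id, co$sample_meta$sample_id)
  cyto <- read_cytokines(file.path(dir, "cytokines.csv"))
  expect_equal(nrow(cyto), nrow(co$cytokines))
})
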