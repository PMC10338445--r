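# Synthetic longitudinal cohort generator. Emulates the study design the
# analysis assumes: weekly gestational and monthly postpartum self-sampling,
# Dirichlet-multinomial compositions around community-state centroids, a
# delivery perturbation to the diverse state, competing exponential
# postpartum recovery hazards (optionally modulated by time-dependent
# covariates), parity-dependent state odds, and diversity-coupled log-normal
# cytokines with detection limits. Every stochastic ingredient has a
# closed-form ground truth exposed by truth_summary().

#' Default ASV panel: taxonomy and community-state centroids
#'
#' Forty ASVs spanning the named vaginal Lactobacillus species (L. crispatus
#' carried by two ASVs so species-level aggregation is exercised),
#' Bifidobacterium, and the facultative/obligate anaerobes characteristic of
#' diverse postpartum communities.
#'
#' @return List with `taxonomy` (asv_id, genus, label) and `centroids`
#'   (states x ASVs composition matrix, rows sum to 1).
#' @export
default_asv_panel <- function() {
  tax <- data.frame(
    asv_id = paste0("asv", 1:40),
    genus = c("Lactobacillus", "Lactobacillus", "Lactobacillus",
              "Lactobacillus", "Lactobacillus", "Bifidobacterium",
              "Bifidobacterium", "Gardnerella", "Megasphaera",
              "Streptococcus", "Atopobium", "Lachnocurva", "Prevotella",
              "Prevotella", "Anaerococcus", "Finegoldia", "Peptoniphilus",
              "Prevotella", "Sneathia", "Dialister", "Ureaplasma",
              "Mobiluncus", "Corynebacterium", "Staphylococcus",
              "Enterococcus", "Escherichia", "Veillonella", "Fusobacterium",
              "Aerococcus", "Parvimonas", "Porphyromonas",
              "Peptostreptococcus", "Gemella", "Actinomyces", "Clostridium",
              "Bacteroides", "Fenollaria", "Murdochiella", "Varibaculum",
              "Howardella"),
    stringsAsFactors = FALSE)
  tax$label <- tax$genus
  tax$label[1:5] <- c("L. iners", "L. crispatus", "L. crispatus",
                      "L. gasseri", "L. jensenii")
  zero <- stats::setNames(rep(0, 40), tax$asv_id)
  # diverse postpartum state: an anaerobe bloom (Prevotella, Anaerococcus,
  # Finegoldia, Peptoniphilus, Streptococcus, Gardnerella, ...) with only
  # traces of Lactobacillus; centroid effective ASV number ~15
  diverse <- zero
  diverse[c("asv13", "asv15", "asv16", "asv17", "asv10", "asv8", "asv11",
            "asv20", "asv14", "asv27", "asv9", "asv19", "asv18", "asv1")] <-
    c(0.14, 0.12, 0.10, 0.09, 0.09, 0.07, 0.06,
      0.05, 0.05, 0.04, 0.03, 0.02, 0.02, 0.03)
  diverse <- diverse / sum(diverse) * (1 - 0.045)
  diverse[diverse == 0] <- 0.045 / sum(diverse == 0)
  # dominated states: one species holds 0.85, the remainder is a companion
  # flora of other lactobacilli plus a few common co-residents; centroid
  # effective ASV number ~2
  companions <- zero
  companions[c("asv1", "asv2", "asv4", "asv5", "asv6", "asv8", "asv10",
               "asv13", "asv11", "asv15", "asv16")] <-
    c(0.18, 0.10, 0.08, 0.04, 0.10, 0.14, 0.12, 0.08, 0.05, 0.04, 0.03)
  companions[companions == 0] <- 0.04 / sum(companions == 0)
  dominated <- function(mass) {
    rest <- companions
    rest[names(mass)] <- 0
    out <- rest / sum(rest) * (1 - sum(mass))
    out[names(mass)] <- mass
    out
  }
  centroids <- rbind(
    "L. crispatus" = dominated(c(asv2 = 0.75, asv3 = 0.10)),
    "L. iners" = dominated(c(asv1 = 0.85)),
    "L. gasseri" = dominated(c(asv4 = 0.85)),
    "L. jensenii" = dominated(c(asv5 = 0.85)),
    "Bifidobacterium" = dominated(c(asv6 = 0.78, asv7 = 0.07)),
    "diverse" = diverse)
  list(taxonomy = tax, centroids = centroids)
}

#' Cohort configuration
#'
#' Defaults encode the study conditions: weekly gestational sampling from
#' about 10 weeks before term, monthly postpartum sampling over one year of
#' follow-up, library sizes around 156,000 reads, a delivery perturbation in
#' 80% of deliveries, per-taxon recovery hazards whose combined any-
#' Lactobacillus one-year incidence is about 0.49, an L. crispatus parity
#' odds ratio of 0.2, and cytokines coupled to the Shannon index on the
#' log10 scale.
#'
#' @param n_pregnancies Number of pregnancies.
#' @param fraction_prior_live_birth Probability a (first-enrolled) pregnancy
#'   has a history of prior live birth.
#' @param fraction_repeat_participants Fraction of additional pregnancies
#'   contributed as second enrollments of existing participants (their
#'   second pregnancy is necessarily parous).
#' @param state_probs_nulliparous Named probabilities over the six states for
#'   nulliparous pregnancies.
#' @param crispatus_parity_or True one-vs-rest odds ratio of the
#'   majority-L. crispatus state for prior live birth (parous probabilities
#'   are derived from the nulliparous ones by applying this OR to
#'   L. crispatus and renormalizing the remainder proportionally).
#' @param long_interval_or Odds multiplier on the L. crispatus state for
#'   parous pregnancies whose birth-to-conception interval exceeds 18 months
#'   (1 disables the interval effect).
#' @param fraction_long_interval Fraction of parous pregnancies with an
#'   interval > 18 months.
#' @param dirichlet_concentration Dirichlet precision around state centroids.
#' @param p_delivery_perturbation Probability the community switches to the
#'   diverse state at delivery.
#' @param recovery_hazards Named per-day cause-specific hazards of postpartum
#'   transition to dominance, keyed by state/taxon label.
#' @param covariate_effects Named hazard-ratio multipliers applied to all
#'   recovery hazards from the covariate's onset day
#'   (contraception/menses_resumption/lactation_end).
#' @param cytokine_slope log10(pg/mL) change per Shannon unit for
#'   delivery-responsive analytes (the remainder get slope 0).
#' @param cytokine_noise_sd Residual SD of log10 concentrations.
#' @param llod,ulod Detection limits (pg/mL), recycled across analytes.
#' @param gestational_interval,postpartum_interval,follow_up_days Sampling
#'   design, in days; first postpartum sample at `postpartum_interval`.
#' @param enrollment_day Earliest gestational sampling day (delivery = 0).
#' @param library_size_mean,library_size_sd,p_low_yield Sequencing depth
#'   model; low-yield samples draw uniformly from 1,000-39,999 reads.
#' @param panel ASV panel from [default_asv_panel()].
#' @return List of class `vag_config`.
#' @export
cohort_config <- function(
    n_pregnancies = 100,
    fraction_prior_live_birth = 0.5,
    fraction_repeat_participants = 0.15,
    state_probs_nulliparous = c("L. crispatus" = 0.40, "L. iners" = 0.22,
                                "L. gasseri" = 0.08, "L. jensenii" = 0.04,
                                "Bifidobacterium" = 0.06, "diverse" = 0.20),
    crispatus_parity_or = 0.2,
    long_interval_or = 2,
    fraction_long_interval = 0.5,
    dirichlet_concentration = 150,
    p_delivery_perturbation = 0.8,
    recovery_hazards = -log(1 - c("L. iners" = 0.35, "L. gasseri" = 0.15,
                                  "Bifidobacterium" = 0.25,
                                  "L. crispatus" = 0.05,
                                  "L. jensenii" = 0.03)) / 365,
    covariate_effects = c(contraception = 3, menses_resumption = 1,
                          lactation_end = 2),
    cytokine_slope = 0.3,
    cytokine_noise_sd = 0.3,
    llod = 2, ulod = 10000,
    gestational_interval = 7,
    postpartum_interval = 30,
    follow_up_days = 365,
    enrollment_day = -210,
    library_size_mean = 156041,
    library_size_sd = 42865,
    p_low_yield = 0.02,
    panel = default_asv_panel()) {
  stopifnot(abs(sum(state_probs_nulliparous) - 1) < 1e-8,
            all(state_probs_nulliparous > 0),
            all(recovery_hazards >= 0),
            dirichlet_concentration > 0,
            p_delivery_perturbation >= 0, p_delivery_perturbation <= 1,
            all(names(recovery_hazards) %in% rownames(panel$centroids)))
  if (any(abs(rowSums(panel$centroids) - 1) > 1e-8))
    stop("invalid composition: centroids must sum to 1")
  # delivery-responsive analytes carry the diversity coupling
  responsive <- c("IL-10", "IL-17", "IL-23", "IL-6", "MIP-1a", "MIP-1b",
                  "MIP-3a", "TNF-a", "IL-1a", "IP-10")
  slopes <- stats::setNames(rep(0, length(cytokine_panel)), cytokine_panel)
  slopes[responsive] <- cytokine_slope
  structure(list(
    n_pregnancies = n_pregnancies,
    fraction_prior_live_birth = fraction_prior_live_birth,
    fraction_repeat_participants = fraction_repeat_participants,
    state_probs_nulliparous = state_probs_nulliparous,
    crispatus_parity_or = crispatus_parity_or,
    long_interval_or = long_interval_or,
    fraction_long_interval = fraction_long_interval,
    dirichlet_concentration = dirichlet_concentration,
    p_delivery_perturbation = p_delivery_perturbation,
    recovery_hazards = recovery_hazards,
    covariate_effects = covariate_effects,
    cytokine_slopes = slopes,
    cytokine_noise_sd = cytokine_noise_sd,
    llod = stats::setNames(rep_len(llod, length(cytokine_panel)), cytokine_panel),
    ulod = stats::setNames(rep_len(ulod, length(cytokine_panel)), cytokine_panel),
    cytokine_intercepts = stats::setNames(
      seq(0.8, 1.6, length.out = length(cytokine_panel)), cytokine_panel),
    gestational_interval = gestational_interval,
    postpartum_interval = postpartum_interval,
    follow_up_days = follow_up_days,
    enrollment_day = enrollment_day,
    library_size_mean = library_size_mean,
    library_size_sd = library_size_sd,
    p_low_yield = p_low_yield,
    panel = panel), class = "vag_config")
}

# state probabilities for one pregnancy given parity and interval bin
.state_probs <- function(config, parous, long_interval = FALSE) {
  p0 <- config$state_probs_nulliparous
  if (!parous) return(p0)
  or <- config$crispatus_parity_or
  if (long_interval) or <- or * config$long_interval_or
  odds1 <- or * p0[["L. crispatus"]] / (1 - p0[["L. crispatus"]])
  p1c <- odds1 / (1 + odds1)
  p1 <- p0
  p1[["L. crispatus"]] <- p1c
  others <- setdiff(names(p0), "L. crispatus")
  p1[others] <- p0[others] / sum(p0[others]) * (1 - p1c)
  p1
}

#' Closed-form ground truth for a cohort configuration
#'
#' @param config A [cohort_config()].
#' @return List of class `vag_truth`:
#'   \describe{
#'     \item{state_or}{Exact marginal one-vs-rest odds ratio (parous vs
#'       nulliparous) of each community state.}
#'     \item{taxon_incidence_1yr}{Per-taxon 1 - exp(-365 * hazard), the
#'       incidence each cause-specific hazard would produce acting alone.}
#'     \item{taxon_incidence_competing}{Sub-distribution incidence under the
#'       competing hazards, (h_x / H) * (1 - exp(-365 * H)).}
#'     \item{observable_incidence}{The estimand induced by the monthly visit
#'       schedule: events can only be seen at visit days, and cases already
#'       transitioned at the first postpartum visit are not at risk.}
#'     \item{lactobacillus_incidence_1yr, lactobacillus_observable}{The same
#'       quantities for dominance by any Lactobacillus species.}
#'     \item{covariate_hr, cytokine_slopes}{Echoed from the configuration.}
#'   }
#' @export
truth_summary <- function(config) {
  p0 <- config$state_probs_nulliparous
  pL <- .state_probs(config, TRUE, TRUE)
  pS <- .state_probs(config, TRUE, FALSE)
  p1 <- config$fraction_long_interval * pL +
    (1 - config$fraction_long_interval) * pS
  state_or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  h <- config$recovery_hazards
  H <- sum(h)
  horizon <- config$follow_up_days
  sub_inc <- function(rate_subset, t) {
    if (H == 0) return(stats::setNames(rep(0, length(rate_subset)),
                                       names(rate_subset)))
    rate_subset / H * (1 - exp(-H * t))
  }
  v1 <- config$postpartum_interval
  last_visit <- floor(config$follow_up_days / config$postpartum_interval) *
    config$postpartum_interval
  observable <- if (H == 0) stats::setNames(rep(0, length(h)), names(h)) else {
    (sub_inc(h, last_visit) - sub_inc(h, v1)) / (1 - sub_inc(h, v1))
  }
  lacto <- grepl("^L\\. ", names(h))
  hl <- sum(h[lacto])
  lacto_inc <- if (H == 0) 0 else hl / H * (1 - exp(-H * horizon))
  lacto_obs <- if (H == 0) 0 else {
    unname((hl / H * (1 - exp(-H * last_visit)) - hl / H * (1 - exp(-H * v1))) /
             (1 - hl / H * (1 - exp(-H * v1))))
  }
  structure(list(
    state_or = state_or,
    taxon_incidence_1yr = 1 - exp(-horizon * h),
    taxon_incidence_competing = sub_inc(h, horizon),
    observable_incidence = observable,
    lactobacillus_incidence_1yr = lacto_inc,
    lactobacillus_observable = lacto_obs,
    covariate_hr = config$covariate_effects,
    cytokine_slopes = config$cytokine_slopes), class = "vag_truth")
}

# piecewise-exponential transition day for total hazard H with multiplier
# steps at `onsets` (named by covariate); returns Inf when H == 0
.transition_day <- function(H, onsets, effects) {
  if (H <= 0) return(Inf)
  onsets <- onsets[!is.na(onsets)]
  brk <- sort(unique(c(0, onsets)))
  mult <- vapply(brk, function(t0) {
    prod(effects[names(onsets)[onsets <= t0]])
  }, numeric(1))
  e <- stats::rexp(1)
  for (k in seq_along(brk)) {
    width <- if (k < length(brk)) brk[k + 1] - brk[k] else Inf
    rate <- H * mult[k]
    if (e < rate * width) return(brk[k] + e / rate)
    e <- e - rate * width
  }
  Inf
}

#' Simulate a longitudinal cohort
#'
#' @param config A [cohort_config()].
#' @param seed Mandatory RNG seed; identical seeds give identical cohorts.
#' @return List of class `vag_cohort`: `counts` (samples x ASVs), `taxonomy`,
#'   `sample_meta` (sample_id, pregnancy_id, participant_id,
#'   day_vs_delivery, library_size, phase, anchor), `pregnancy_meta`
#'   (covariates plus true_* ground-truth columns), `cytokines` (long
#'   data.frame with raw concentrations and per-analyte limits), `truth`
#'   ([truth_summary()] of the config), `config`.
#' @export
simulate_cohort <- function(config, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(config, "vag_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  npg <- config$n_pregnancies
  n_repeat <- round(config$fraction_repeat_participants * npg)
  n_participants <- npg - n_repeat
  participant <- c(seq_len(n_participants),
                   sample(n_participants, n_repeat, replace = FALSE))
  enrollment_order <- stats::ave(seq_len(npg), participant,
                                 FUN = seq_along)
  pid <- sprintf("p%03d", seq_len(npg))
  wid <- sprintf("w%03d", participant)

  parous <- stats::rbinom(npg, 1, config$fraction_prior_live_birth) == 1
  parous[enrollment_order == 2] <- TRUE
  long_int <- stats::rbinom(npg, 1, config$fraction_long_interval) == 1
  interval <- ifelse(parous,
                     ifelse(long_int, stats::runif(npg, 19, 60),
                            stats::runif(npg, 6, 18)), NA_real_)

  gest_state <- vapply(seq_len(npg), function(i) {
    sample(names(config$state_probs_nulliparous), 1,
           prob = .state_probs(config, parous[i], isTRUE(long_int[i])))
  }, character(1))

  perturbed <- stats::rbinom(npg, 1, config$p_delivery_perturbation) == 1
  # a diverse gestational community is already in the post-delivery state
  post_diverse <- perturbed | gest_state == "diverse"

  # behavioural covariates with onset days (days postpartum)
  contraception <- ifelse(stats::rbinom(npg, 1, 0.6) == 1,
                          round(stats::runif(npg, 10, 150)), NA_real_)
  menses <- ifelse(stats::rbinom(npg, 1, 0.7) == 1,
                   round(stats::runif(npg, 60, 300)), NA_real_)
  lactation <- ifelse(stats::rbinom(npg, 1, 0.65) == 1,
                      round(stats::runif(npg, 90, 330)), NA_real_)

  H <- sum(config$recovery_hazards)
  trans_day <- rep(Inf, npg)
  trans_taxon <- rep(NA_character_, npg)
  for (i in seq_len(npg)) {
    if (!post_diverse[i] || H == 0) next
    onsets <- c(contraception = contraception[i],
                menses_resumption = menses[i],
                lactation_end = lactation[i])
    onsets <- onsets[names(config$covariate_effects)]
    names(onsets) <- names(config$covariate_effects)
    trans_day[i] <- .transition_day(H, onsets, config$covariate_effects)
    if (is.finite(trans_day[i])) {
      trans_taxon[i] <- sample(names(config$recovery_hazards), 1,
                               prob = config$recovery_hazards)
    }
  }

  gest_days <- lapply(seq_len(npg), function(i) {
    start <- config$enrollment_day + sample.int(14, 1) - 1
    seq(start, -7, by = config$gestational_interval)
  })
  post_days <- seq(config$postpartum_interval,
                   config$follow_up_days,
                   by = config$postpartum_interval)

  # per-sample state
  sm <- do.call(rbind, lapply(seq_len(npg), function(i) {
    gd <- gest_days[[i]]
    pdays <- post_days
    gstate <- rep(gest_state[i], length(gd))
    pstate <- if (post_diverse[i]) {
      ifelse(pdays >= trans_day[i], trans_taxon[i], "diverse")
    } else rep(gest_state[i], length(pdays))
    data.frame(pregnancy_id = pid[i], participant_id = wid[i],
               day_vs_delivery = c(gd, pdays),
               state = c(gstate, pstate),
               phase = rep(c("gestation", "postpartum"),
                           c(length(gd), length(pdays))),
               stringsAsFactors = FALSE)
  }))
  ns <- nrow(sm)
  sm$sample_id <- sprintf("s%05d", seq_len(ns))

  low <- stats::rbinom(ns, 1, config$p_low_yield) == 1
  lib <- ifelse(low, round(stats::runif(ns, 1000, 39999)),
                pmax(1000, round(stats::rnorm(ns, config$library_size_mean,
                                              config$library_size_sd))))
  sm$library_size <- as.integer(lib)

  centroids <- config$panel$centroids
  alpha <- centroids[sm$state, , drop = FALSE] * config$dirichlet_concentration
  gam <- matrix(stats::rgamma(length(alpha), shape = alpha),
                nrow = ns, ncol = ncol(centroids))
  prob <- gam / rowSums(gam)
  counts <- t(vapply(seq_len(ns), function(j) {
    stats::rmultinom(1, lib[j], prob[j, ])[, 1]
  }, integer(ncol(centroids))))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sm$sample_id, colnames(centroids))

  # cytokines at the three anchor timepoints of each pregnancy
  sm$anchor <- NA_character_
  for (i in seq_len(npg)) {
    idx <- which(sm$pregnancy_id == pid[i])
    g <- idx[sm$phase[idx] == "gestation"]
    p <- idx[sm$phase[idx] == "postpartum"]
    sm$anchor[g[which.max(sm$day_vs_delivery[g])]] <- "lastGest"
    sm$anchor[p[which.min(sm$day_vs_delivery[p])]] <- "firstPost"
    late <- p[which.min(abs(sm$day_vs_delivery[p] - 285))]
    if (is.na(sm$anchor[late])) sm$anchor[late] <- "latePost"
  }
  anchors <- which(!is.na(sm$anchor))
  sdi <- vegan::diversity(counts[anchors, , drop = FALSE] /
                            rowSums(counts[anchors, , drop = FALSE]))
  cyto <- do.call(rbind, lapply(seq_along(anchors), function(k) {
    a <- anchors[k]
    lg <- config$cytokine_intercepts + config$cytokine_slopes * sdi[k] +
      stats::rnorm(length(cytokine_panel), 0, config$cytokine_noise_sd)
    data.frame(sample_id = sm$sample_id[a], analyte = cytokine_panel,
               concentration = 10^lg,
               llod = unname(config$llod), ulod = unname(config$ulod),
               stringsAsFactors = FALSE)
  }))

  pregnancy_meta <- data.frame(
    pregnancy_id = pid, participant_id = wid,
    prior_live_birth = parous,
    birth_to_conception_months = interval,
    maternal_age = round(stats::runif(npg, 22, 42)),
    delivery_mode = sample(c("vaginal", "cesarean"), npg, TRUE, c(0.7, 0.3)),
    labor_onset = sample(c("spontaneous", "induced"), npg, TRUE, c(0.6, 0.4)),
    membrane_rupture = sample(c("spontaneous", "artificial"), npg, TRUE),
    gbs_positive = stats::rbinom(npg, 1, 0.25) == 1,
    peripartum_antibiotics = stats::rbinom(npg, 1, 0.4) == 1,
    infant_sex = sample(c("F", "M"), npg, TRUE),
    contraception_start_day = contraception,
    menses_resumption_day = menses,
    lactation_end_day = lactation,
    true_state = gest_state,
    true_perturbed = perturbed,
    true_transition_day = trans_day,
    true_transition_taxon = trans_taxon,
    stringsAsFactors = FALSE)

  structure(list(
    counts = counts,
    taxonomy = config$panel$taxonomy,
    sample_meta = sm[, c("sample_id", "pregnancy_id", "participant_id",
                         "day_vs_delivery", "phase", "anchor",
                         "library_size")],
    pregnancy_meta = pregnancy_meta,
    cytokines = cyto,
    truth = truth_summary(config),
    config = config), class = "vag_cohort")
}

#' Write a cohort to the pipeline's file dialects
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed): counts.tsv, taxonomy.tsv,
#'   sample_metadata.csv, pregnancy_metadata.csv, cytokines.csv.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  utils::write.table(cohort$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$sample_meta, file.path(dir, "sample_metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$pregnancy_meta,
                   file.path(dir, "pregnancy_metadata.csv"), row.names = FALSE)
  utils::write.csv(cohort$cytokines, file.path(dir, "cytokines.csv"),
                   row.names = FALSE)
  invisible(dir)
}
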