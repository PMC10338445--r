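# Parity inference: one-vs-rest community-state outcomes, cluster-robust
# logistic regression under repeated subsampling, and the birth-to-conception
# interval analysis.

#' One-versus-rest binary outcomes for a focal community state
#'
#' @param states Character vector of per-sample state labels.
#' @param focal_state The state coded 1.
#' @return Integer 0/1 vector. Errors when the focal state is absent; a
#'   warning flags the degenerate all-focal case.
#' @export
one_vs_rest_outcomes <- function(states, focal_state) {
  y <- as.integer(states == focal_state)
  if (sum(y) == 0) stop("degenerate outcome: focal state '", focal_state,
                        "' absent from data")
  if (all(y == 1)) warning("degenerate outcome: all samples are the focal state")
  y
}

#' Cluster-robust logistic regression
#'
#' Maximum-likelihood logit fit of a binary outcome on a binary exposure; the
#' covariance is the cluster-aggregated sandwich estimator, so Wald CIs and p
#' values account for correlation among longitudinal samples from the same
#' cluster (gestation by default). Point estimates equal the unclustered ML
#' estimates; only the covariance differs.
#'
#' @param y Binary outcome per sample.
#' @param x Binary exposure per sample.
#' @param cluster Cluster id per sample.
#' @return List of class `vag_logit`: `odds_ratio`, `ci_95`, `p_value`,
#'   `log_or`, `log_or_se`, `n_clusters`, `n_samples`, `separation`.
#' @export
clustered_logistic <- function(y, x, cluster) {
  stopifnot(length(y) == length(x), length(y) == length(cluster))
  if (length(unique(y)) < 2) stop("degenerate outcome: y does not vary")
  if (length(unique(x)) < 2) stop("exposure does not vary")
  dat <- data.frame(y = y, x = x)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(), data = dat))
  b <- unname(stats::coef(fit)["x"])
  vc <- sandwich::vcovCL(fit, cluster = cluster)
  se <- sqrt(vc["x", "x"])
  separation <- !fit$converged || abs(b) > 15 || !is.finite(se)
  list(odds_ratio = exp(b),
       ci_95 = c(exp(b - 1.96 * se), exp(b + 1.96 * se)),
       p_value = 2 * stats::pnorm(-abs(b / se)),
       log_or = b, log_or_se = se,
       n_clusters = length(unique(cluster)), n_samples = length(y),
       separation = separation)
}

#' Parity association under repeated per-gestation subsampling
#'
#' Differences in sampling effort across gestations are addressed by drawing
#' `n_per_gestation` gestational samples per gestation without replacement
#' (all samples when fewer are available), fitting [clustered_logistic()] to
#' each draw, and averaging odds ratios, CI endpoints, and p values across
#' iterations. Iterations whose subsample has a degenerate outcome are
#' recorded as failed and excluded from the means.
#'
#' @param states Per-sample state labels (gestational samples only).
#' @param gestation Gestation (cluster) id per sample.
#' @param exposure Named logical/0-1 vector per gestation (names = gestation
#'   ids), e.g. history of prior live birth.
#' @param focal_state Focal state for the one-vs-rest outcome.
#' @param n_per_gestation Samples drawn per gestation (default 6).
#' @param n_iterations Number of draws (default 100).
#' @param seed Mandatory RNG seed; identical seeds give identical aggregates.
#' @return List of class `vag_parity`: `mean_or`, `mean_ci`, `mean_p`,
#'   `n_iterations`, `n_failed`, `per_iteration` (data.frame).
#' @export
subsample_aggregate <- function(states, gestation, exposure, focal_state,
                                n_per_gestation = 6, n_iterations = 100,
                                seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(states) == length(gestation))
  gest_ids <- sort(unique(as.character(gestation)))
  if (!all(gest_ids %in% names(exposure)))
    stop("exposure missing for some gestations")
  idx_by_gest <- split(seq_along(states), as.character(gestation))[gest_ids]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- lapply(seq_len(n_iterations), function(it) {
    take <- unlist(lapply(idx_by_gest, function(idx) {
      if (length(idx) <= n_per_gestation) idx
      else sample(idx, n_per_gestation)
    }), use.names = FALSE)
    res <- tryCatch({
      y <- one_vs_rest_outcomes(states[take], focal_state)
      g <- as.character(gestation)[take]
      clustered_logistic(y, as.numeric(exposure[g]), g)
    }, error = function(e) NULL)
    if (is.null(res)) {
      data.frame(iteration = it, or = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, failed = TRUE)
    } else {
      data.frame(iteration = it, or = res$odds_ratio, ci_low = res$ci_95[1],
                 ci_high = res$ci_95[2], p = res$p_value, failed = FALSE)
    }
  })
  per <- do.call(rbind, rows)
  ok <- !per$failed
  if (!any(ok)) stop("all iterations failed")
  structure(list(mean_or = mean(per$or[ok]),
                 mean_ci = c(mean(per$ci_low[ok]), mean(per$ci_high[ok])),
                 mean_p = mean(per$p[ok]),
                 n_iterations = n_iterations, n_failed = sum(!ok),
                 per_iteration = per),
            class = "vag_parity")
}

#' Birth-to-conception interval vs L. crispatus predominance
#'
#' Gestations with a prior live birth are binned by the interval between that
#' birth and conception of the current pregnancy (<= 18 or > 18 months) and
#' cross-tabulated against taxon predominance (average gestational frequency
#' > 0.5); the association is tested with a two-sided Fisher's exact test.
#' Gestations without a prior live birth carry no interval and are excluded.
#'
#' @param interval_months Numeric vector per gestation (NA = no prior live
#'   birth).
#' @param predominant Logical vector per gestation.
#' @param cutoff_months Bin boundary (default 18; an interval of exactly 18
#'   months falls in the short bin).
#' @return List with `table` (2x2: rows short/long interval, cols
#'   not-predominant/predominant) and `fisher_p`.
#' @export
birth_to_conception_analysis <- function(interval_months, predominant,
                                         cutoff_months = 18) {
  stopifnot(length(interval_months) == length(predominant))
  keep <- !is.na(interval_months)
  interval_months <- interval_months[keep]
  predominant <- predominant[keep]
  bin <- factor(ifelse(interval_months <= cutoff_months, "short", "long"),
                levels = c("short", "long"))
  pred <- factor(predominant, levels = c(FALSE, TRUE))
  tab <- table(interval = bin, predominant = pred)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in 2x2 table")
  list(table = tab, fisher_p = stats::fisher.test(tab)$p.value)
}
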