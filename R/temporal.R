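# Trend and turnover analyses anchored on delivery.

#' Linear mixed-effects trend of diversity over time
#'
#' Fits diversity ~ day with a random intercept and slope per pregnancy by
#' maximum likelihood. The fixed-effect slope is tested with a two-sided
#' t-test on `n_pregnancies - 2` degrees of freedom. Pregnancies with a
#' single timepoint are dropped with a warning.
#'
#' @param observations data.frame with columns `pregnancy_id`, `day`,
#'   `diversity`.
#' @return List of class `vag_trend`: `slope`, `slope_se`, `slope_p`,
#'   `intercept`, `n_pregnancies`, `n_samples`.
#' @export
fit_lme_trend <- function(observations) {
  stopifnot(all(c("pregnancy_id", "day", "diversity") %in% names(observations)))
  tab <- table(observations$pregnancy_id)
  singletons <- names(tab)[tab < 2]
  if (length(singletons) > 0) {
    warning(length(singletons), " pregnancies with a single timepoint dropped")
    observations <- observations[!observations$pregnancy_id %in% singletons, ]
  }
  n_preg <- length(unique(observations$pregnancy_id))
  if (n_preg < 2) stop("need at least 2 pregnancies with > 1 timepoint")
  fit <- tryCatch(
    nlme::lme(diversity ~ day, random = ~ day | pregnancy_id,
              data = observations, method = "ML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200, returnObject = TRUE)),
    error = function(e) stop("LME did not converge: ", conditionMessage(e)))
  fe <- nlme::fixef(fit)
  se <- sqrt(diag(fit$varFix))
  df <- n_preg - 2
  tval <- fe[["day"]] / se[["day"]]
  structure(list(slope = unname(fe[["day"]]), slope_se = unname(se[["day"]]),
                 slope_p = 2 * stats::pt(-abs(tval), df = df),
                 intercept = unname(fe[["(Intercept)"]]),
                 n_pregnancies = n_preg, n_samples = nrow(observations)),
            class = "vag_trend")
}

#' Monthly-binned compositional turnover within pregnancies
#'
#' All within-pregnancy sample pairs collected `min_gap_days` to
#' `max_gap_days` apart (3.5 to 9 weeks by default) are scored with
#' Bray-Curtis dissimilarity on fourth-root transformed counts and binned to
#' the start month (the earliest month in the pair, floor of the earlier day
#' over the month length). Pairs spanning delivery (one day < 0, one >= 0)
#' are placed at month 0. The per-(pregnancy, month) mean is returned.
#'
#' @param counts Count matrix for one pregnancy's samples (rows ordered is
#'   not required).
#' @param days day_vs_delivery per row of `counts`.
#' @param pregnancy_id Identifier copied into the output.
#' @param min_gap_days,max_gap_days Inclusive pair-gap window in days.
#' @param month_length_days Month length (default 365.25 / 12).
#' @return data.frame: pregnancy_id, month, mean_dissimilarity, n_pairs.
#'   Empty when no pair qualifies.
#' @export
turnover_by_month <- function(counts, days, pregnancy_id = "preg",
                              min_gap_days = 24.5, max_gap_days = 63,
                              month_length_days = 365.25 / 12) {
  stopifnot(nrow(counts) == length(days))
  n <- nrow(counts)
  if (n < 2) stop("need at least 2 samples")
  pairs <- utils::combn(n, 2)
  gaps <- abs(days[pairs[1, ]] - days[pairs[2, ]])
  keep <- gaps >= min_gap_days & gaps <= max_gap_days
  if (!any(keep)) {
    return(data.frame(pregnancy_id = character(0), month = integer(0),
                      mean_dissimilarity = numeric(0), n_pairs = integer(0)))
  }
  pairs <- pairs[, keep, drop = FALSE]
  d1 <- days[pairs[1, ]]
  d2 <- days[pairs[2, ]]
  early <- pmin(d1, d2)
  late <- pmax(d1, d2)
  month <- ifelse(early < 0 & late >= 0, 0L,
                  as.integer(floor(early / month_length_days)))
  diss <- vapply(seq_len(ncol(pairs)), function(k) {
    dissimilarity(counts[pairs[1, k], ], counts[pairs[2, k], ],
                  metric = "bray_curtis", transform = "fourth_root")
  }, numeric(1))
  agg <- stats::aggregate(diss, by = list(month = month),
                          FUN = function(x) c(mean(x), length(x)))
  data.frame(pregnancy_id = pregnancy_id, month = agg$month,
             mean_dissimilarity = agg$x[, 1], n_pairs = as.integer(agg$x[, 2]),
             stringsAsFactors = FALSE)
}

#' Turnover bins for a whole cohort
#'
#' @param counts Full count matrix (samples x ASVs).
#' @param meta Sample metadata with `sample_id`, `pregnancy_id`,
#'   `day_vs_delivery` (rows matched to `counts` by sample_id).
#' @inheritParams turnover_by_month
#' @return Row-bound per-pregnancy results of [turnover_by_month()].
#' @export
cohort_turnover <- function(counts, meta, min_gap_days = 24.5,
                            max_gap_days = 63,
                            month_length_days = 365.25 / 12) {
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  out <- lapply(split(seq_len(nrow(counts)), meta$pregnancy_id), function(idx) {
    if (length(idx) < 2) return(NULL)
    turnover_by_month(counts[idx, , drop = FALSE],
                      meta$day_vs_delivery[idx],
                      pregnancy_id = meta$pregnancy_id[idx[1]],
                      min_gap_days = min_gap_days, max_gap_days = max_gap_days,
                      month_length_days = month_length_days)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Spearman correlation between last-gestational and first-postpartum diversity
#'
#' Quantifies how strongly the postpartum state remembers the pre-delivery
#' state; values near 0 indicate that delivery decouples the time series.
#'
#' @param last_gest,first_post Paired diversity values (one pair per
#'   delivery).
#' @return List with `rho`, `p`, `n`, and `degenerate` (TRUE when either
#'   vector is constant, in which case rho is NA).
#' @export
decoupling_correlation <- function(last_gest, first_post) {
  stopifnot(length(last_gest) == length(first_post))
  if (length(last_gest) < 3) stop("need at least 3 pairs")
  if (stats::sd(last_gest) == 0 || stats::sd(first_post) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(last_gest),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(last_gest, first_post, method = "spearman",
                    exact = length(last_gest) <= 9))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(last_gest),
       degenerate = FALSE)
}
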