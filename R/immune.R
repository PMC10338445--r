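# Cytokine panel processing and taxa-cytokine integration: LOD censoring,
# phase-level ordination/PERMANOVA, repeated-measures correlation networks,
# and constrained correspondence analysis.

#' The 16-analyte cytokine/chemokine panel
#' @format Character vector of analyte names.
#' @export
cytokine_panel <- c("IFN-g", "IL-1a", "IL-1b", "IL-5", "IL-6", "IL-10",
                    "IL-17", "IL-21", "IL-23", "IP-10", "ITAC", "MIG",
                    "MIP-1a", "MIP-1b", "MIP-3a", "TNF-a")

#' Apply detection-limit censoring to raw cytokine concentrations
#'
#' Concentrations below the lower limit of detection are set to half the
#' analyte's minimum detectable concentration; those above the upper limit
#' are set to the upper limit. Flags record the applied rule.
#'
#' @param panel data.frame with columns `sample_id`, `analyte`,
#'   `concentration`, `llod`, `ulod` (limits in the same pg/mL units).
#' @return The input with `concentration` replaced by the censored value and
#'   two added columns: `raw_concentration` and `censor_flag`
#'   ("below"/"above"/"in_range").
#' @export
censor_lod <- function(panel) {
  stopifnot(all(c("sample_id", "analyte", "concentration", "llod", "ulod")
                %in% names(panel)))
  if (any(panel$concentration < 0)) stop("negative raw concentration")
  if (any(panel$llod <= 0) || any(panel$ulod <= 0)) stop("limits must be positive")
  flag <- ifelse(panel$concentration < panel$llod, "below",
                 ifelse(panel$concentration > panel$ulod, "above", "in_range"))
  value <- ifelse(flag == "below", panel$llod / 2,
                  ifelse(flag == "above", panel$ulod, panel$concentration))
  out <- panel
  out$raw_concentration <- panel$concentration
  out$concentration <- value
  out$censor_flag <- flag
  out
}

#' Reshape a long cytokine panel to a samples x analytes matrix
#' @param panel Long data.frame (`sample_id`, `analyte`, `concentration`).
#' @return Numeric matrix.
#' @export
cytokine_matrix <- function(panel) {
  wide <- stats::reshape(panel[, c("sample_id", "analyte", "concentration")],
                         idvar = "sample_id", timevar = "analyte",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  colnames(m) <- sub("^concentration\\.", "", colnames(m))
  m
}

#' PCA of log cytokine concentrations with a phase-effect test
#'
#' Concentrations are log10-transformed, column-centered and unit-variance
#' scaled before PCA. The effect of temporal phase (e.g. lateGest, earlyPost,
#' latePost) is tested by permutational MANOVA on Canberra distances of the
#' log concentrations.
#'
#' @param conc Samples x analytes concentration matrix (post LOD censoring,
#'   strictly positive).
#' @param phases Phase label per sample.
#' @param n_perm Number of permutations for the phase test.
#' @param seed RNG seed for the permutation stream.
#' @return List: `scores`, `sdev`, `loadings`, `dropped` (constant analytes),
#'   `pseudo_F`, `p`.
#' @export
pca_phases <- function(conc, phases, n_perm = 999, seed = 1) {
  stopifnot(nrow(conc) == length(phases))
  lg <- log10(conc)
  keep <- apply(lg, 2, stats::sd) > 0
  if (!all(keep)) warning("dropping constant analytes: ",
                          paste(colnames(lg)[!keep], collapse = ", "))
  lg <- lg[, keep, drop = FALSE]
  pc <- stats::prcomp(lg, center = TRUE, scale. = TRUE)
  if (any(lg < 0))
    stop("Canberra distances need non-negative data: concentrations below ",
         "1 pg/mL give negative log10 values")
  d <- vegan::vegdist(lg, method = "canberra")
  pt <- permanova(d, phases, n_perm = n_perm, seed = seed)
  list(scores = pc$x, sdev = pc$sdev, loadings = pc$rotation,
       dropped = colnames(conc)[!keep], pseudo_F = pt$pseudo_F, p = pt$p)
}

#' Permutational MANOVA on a distance matrix
#'
#' Pseudo-F from the Gower-centered between/within partition of squared
#' distances; the p value is (1 + number of permuted F >= observed) /
#' (n_perm + 1) under random relabeling.
#'
#' @param d A `dist` object or square symmetric matrix.
#' @param groups Group label per observation (>= 2 groups, none empty).
#' @param n_perm Number of label permutations (default 999; the smallest
#'   attainable p is 1 / (n_perm + 1)).
#' @param seed RNG seed for the permutation stream.
#' @return List with `pseudo_F` and `p`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  dat <- data.frame(g = groups)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- vegan::adonis2(d ~ g, data = dat, permutations = n_perm)
  list(pseudo_F = res$F[1], p = res$`Pr(>F)`[1])
}

#' Repeated-measures (common within-subject) correlation
#'
#' The analysis-of-covariance decomposition: y is modelled on subject
#' (intercepts) and x (common slope); r_rm takes its sign from the common
#' slope and its magnitude from sqrt(SS_x / (SS_x + SS_error)). The p value
#' is an F test on 1 and n_obs - n_subjects - 1 degrees of freedom. Subjects
#' with fewer than 2 observations are dropped with a warning.
#'
#' @param subject Subject id per observation.
#' @param x,y Paired observations.
#' @return List of class `vag_rmcorr`: `r_rm`, `df`, `p_value`,
#'   `n_subjects`, `n_observations`.
#' @export
rmcorr <- function(subject, x, y) {
  stopifnot(length(subject) == length(x), length(x) == length(y))
  subject <- as.character(subject)
  tab <- table(subject)
  drop <- names(tab)[tab < 2]
  if (length(drop) > 0) {
    warning(length(drop), " subjects with a single observation dropped")
    keep <- !subject %in% drop
    subject <- subject[keep]; x <- x[keep]; y <- y[keep]
  }
  n_sub <- length(unique(subject))
  if (n_sub < 2) stop("need at least 2 subjects with >= 2 observations")
  fit <- stats::lm(y ~ factor(subject) + x)
  an <- stats::anova(fit)
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- length(x) - n_sub - 1
  r <- sign(stats::coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_err))
  f <- (ss_x / 1) / (ss_err / df)
  p <- stats::pf(f, 1, df, lower.tail = FALSE)
  structure(list(r_rm = r, df = df, p_value = p, n_subjects = n_sub,
                 n_observations = length(x)),
            class = "vag_rmcorr")
}

#' Taxa-cytokine repeated-measures correlation network
#'
#' Computes [rmcorr()] for every variable pair, adjusts p values across all
#' pairs jointly by Benjamini-Hochberg, and keeps an edge when the adjusted p
#' falls below `p_thresh` and the correlation is positive and above
#' `r_thresh`. Isolated nodes (no passing edge) are absent from `nodes`.
#'
#' @param vars Samples x variables matrix (taxa frequencies, SDI, log10
#'   cytokines).
#' @param subject Subject (pregnancy) id per row.
#' @param var_type Named character vector tagging each variable "taxon" or
#'   "cytokine".
#' @param r_thresh Minimum (positive) r_rm for an edge (default 0.35).
#' @param p_thresh Maximum BH-adjusted p (default 0.001).
#' @return List: `edges` (node_a, node_b, r_rm, p, p_adj, edge_class),
#'   `nodes` (connected nodes), `all_pairs` (every pair with its statistics).
#' @export
build_network <- function(vars, subject, var_type, r_thresh = 0.35,
                          p_thresh = 0.001) {
  stopifnot(!is.null(colnames(vars)), nrow(vars) == length(subject))
  if (!all(colnames(vars) %in% names(var_type)))
    stop("var_type missing for some variables")
  pair_idx <- utils::combn(ncol(vars), 2)
  rows <- lapply(seq_len(ncol(pair_idx)), function(k) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    rc <- tryCatch(suppressWarnings(rmcorr(subject, vars[, i], vars[, j])),
                   error = function(e) NULL)
    data.frame(node_a = colnames(vars)[i], node_b = colnames(vars)[j],
               r_rm = if (is.null(rc)) NA_real_ else rc$r_rm,
               p = if (is.null(rc)) NA_real_ else rc$p_value,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  cls <- function(a, b) {
    ta <- var_type[[a]]; tb <- var_type[[b]]
    if (ta == tb) paste0(ta, "-", tb) else "mixed"
  }
  pairs$edge_class <- mapply(cls, pairs$node_a, pairs$node_b)
  keep <- !is.na(pairs$r_rm) & pairs$r_rm > r_thresh & pairs$p_adj < p_thresh
  edges <- pairs[keep, , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, nodes = sort(unique(c(edges$node_a, edges$node_b))),
       all_pairs = pairs)
}

#' Benjamini-Hochberg step-up adjustment
#' @param p Vector of p values in (0, 1\].
#' @return Adjusted p values (order-preserving, monotone).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Constrained correspondence analysis of taxa on cytokine constraints
#'
#' The chi-square standardized community matrix is projected (row-weighted
#' least squares) onto the constraint space and decomposed by singular
#' values. The constrained fraction is the constrained share of total
#' inertia; its significance is assessed with an ANOVA-like permutation test
#' for the joint effect of the constraints.
#'
#' @param community Samples x taxa non-negative matrix with positive row and
#'   column sums (taxon frequencies).
#' @param constraints Samples x variables numeric matrix/data.frame (log10
#'   cytokine concentrations). Rank-deficient constraint sets have aliased
#'   columns dropped with a warning.
#' @param n_perm Permutations for the joint test (default 999).
#' @param seed RNG seed for the permutation stream.
#' @return List of class `vag_cca`: `site_scores`, `species_scores`,
#'   `biplot_scores`, `constrained_inertia`, `total_inertia`,
#'   `constrained_fraction`, `permutation_p`, `dropped`, and the vegan model
#'   as `fit`.
#' @export
cca_constrained <- function(community, constraints, n_perm = 999, seed = 1) {
  community <- as.matrix(community)
  if (any(community < 0)) stop("community matrix must be non-negative")
  if (any(rowSums(community) == 0) || any(colSums(community) == 0))
    stop("community matrix needs positive row and column sums")
  constraints <- as.data.frame(constraints)
  mod <- vegan::cca(community ~ ., data = constraints)
  dropped <- character(0)
  if (!is.null(mod$CCA$alias)) {
    dropped <- mod$CCA$alias
    warning("rank-deficient constraints; dropped: ",
            paste(dropped, collapse = ", "))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  an <- stats::anova(mod, permutations = n_perm)
  structure(list(
    site_scores = vegan::scores(mod, display = "sites"),
    species_scores = vegan::scores(mod, display = "species"),
    biplot_scores = if (is.null(mod$CCA$biplot)) NULL else mod$CCA$biplot,
    constrained_inertia = mod$CCA$tot.chi,
    total_inertia = mod$tot.chi,
    constrained_fraction = mod$CCA$tot.chi / mod$tot.chi,
    permutation_p = an$`Pr(>F)`[1],
    dropped = dropped, fit = mod), class = "vag_cca")
}
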