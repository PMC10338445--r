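toy_panel <- function(conc, llod = 2, ulod = 10000) {
  data.frame(sample_id = "s1", analyte = paste0("A", seq_along(conc)),
             concentration = conc, llod = llod, ulod = ulod,
             stringsAsFactors = FALSE)
}

test_that("LOD censoring applies the half-minimum and upper-limit rules", {
  out <- censor_lod(toy_panel(c(0.5, 57.3, 20000)))
  expect_equal(out$concentration, c(1, 57.3, 10000))
  expect_equal(out$censor_flag, c("below", "in_range", "above"))
  expect_equal(out$raw_concentration, c(0.5, 57.3, 20000))
  # boundary: exactly at the limits is in range
  out2 <- censor_lod(toy_panel(c(2, 10000)))
  expect_equal(out2$censor_flag, c("in_range", "in_range"))
  expect_error(censor_lod(toy_panel(-1)), "negative")
})

test_that("PCA of log concentrations is deterministic, scaled, and rank-bounded", {
  set.seed(91)
  n <- 24
  conc <- matrix(10^rnorm(n * 5, 1.2, 0.4), n, 5,
                 dimnames = list(sprintf("s%02d", 1:n), paste0("A", 1:5)))
  conc[2, ] <- conc[1, ]
  phases <- rep(c("gest", "post"), each = n / 2)
  res <- pca_phases(conc, phases, n_perm = 99, seed = 4)
  expect_equal(res$scores[1, ], res$scores[2, ])
  cv <- stats::cov(res$scores)
  expect_equal(cv[upper.tri(cv)], rep(0, sum(upper.tri(cv))), tolerance = 1e-10)
  expect_true(all(diff(diag(cv)) <= 1e-10))
  expect_lte(qr(res$scores)$rank, min(n - 1, 5))
  # constant analyte dropped with a warning
  conc2 <- cbind(conc, A6 = 10)
  expect_warning(res2 <- pca_phases(conc2, phases, n_perm = 19, seed = 4),
                 "constant")
  expect_equal(res2$dropped, "A6")
})

test_that("PERMANOVA separates shifted groups and respects the p lower bound", {
  set.seed(92)
  x <- rbind(matrix(rnorm(30, 0), 10), matrix(rnorm(30, 3), 10))
  d <- stats::dist(x)
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(d, g, n_perm = 999, seed = 1)
  expect_equal(res$p, 1 / 1000)  # minimum attainable p
  expect_gt(res$pseudo_F, 1)
  # identical point multisets: F near its permutation mean, p large
  y <- rbind(diag(4), diag(4))
  res2 <- permanova(stats::dist(y), rep(c("a", "b"), each = 4),
                    n_perm = 199, seed = 2)
  expect_gt(res2$p, 0.5)
  expect_error(permanova(d, rep("a", 20)), "2 groups")
})

test_that("rmcorr equals the subject-centered Pearson construction", {
  set.seed(93)
  for (i in 1:25) {
    ns <- sample(4:8, 1)
    subject <- rep(seq_len(ns), each = 5)
    x <- rnorm(ns * 5) + rep(rnorm(ns, sd = 2), each = 5)
    y <- 0.4 * x + rnorm(ns * 5) + rep(rnorm(ns, sd = 2), each = 5)
    rc <- rmcorr(subject, x, y)
    expect_equal(rc$r_rm, rmcorr_centered_oracle(subject, x, y),
                 tolerance = 1e-10)
    expect_equal(rc$df, length(x) - ns - 1)
  }
})

test_that("rmcorr is exactly +-1 under perfect within-subject linearity", {
  subject <- rep(1:5, each = 4)
  x <- rnorm(20)
  offs <- rep(rnorm(5, sd = 3), each = 4)
  expect_equal(suppressWarnings(rmcorr(subject, x, x + offs)$r_rm), 1)
  expect_equal(suppressWarnings(rmcorr(subject, x, -x + offs)$r_rm), -1)
  # null: within-subject independence
  set.seed(94)
  zs <- replicate(30, {
    rc <- rmcorr(rep(1:10, each = 4), rnorm(40), rnorm(40))
    rc$r_rm * sqrt(rc$df) / sqrt(1 - rc$r_rm^2)
  })
  expect_gt(mean(abs(zs) < 3), 0.9)
  expect_warning(rmcorr(c(1, 1, 2, 2, 3), rnorm(5), rnorm(5)), "dropped")
})

test_that("network edges require positive, significant, threshold-passing rmcorr", {
  set.seed(95)
  n_sub <- 30
  subject <- rep(seq_len(n_sub), each = 3)
  n <- length(subject)
  base <- rnorm(n)
  vars <- cbind(t1 = base + rnorm(n, sd = 0.1),
                c1 = base + rnorm(n, sd = 0.1),
                t2 = rnorm(n), c2 = rnorm(n))
  vt <- c(t1 = "taxon", t2 = "taxon", c1 = "cytokine", c2 = "cytokine")
  net <- build_network(vars, subject, vt)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(c(net$edges$node_a, net$edges$node_b)), c("c1", "t1"))
  expect_equal(net$edges$edge_class, "mixed")
  expect_equal(net$nodes, c("c1", "t1"))  # isolated nodes removed
  # a strong negative pair must not become an edge
  vars2 <- cbind(t1 = base, c1 = -base + rnorm(n, sd = 0.1),
                 t2 = rnorm(n), c2 = rnorm(n))
  net2 <- build_network(vars2, subject, vt)
  expect_false(any(net2$edges$node_a == "t1" & net2$edges$node_b == "c1"))
  # monotone in thresholds; degenerate limits give the complete graph
  net_all <- build_network(vars, subject, vt, r_thresh = -1.01, p_thresh = 1.01)
  expect_equal(nrow(net_all$edges), 6)
  net_tight <- build_network(vars, subject, vt, r_thresh = 0.9)
  expect_lte(nrow(net_tight$edges), nrow(net$edges))
})

test_that("BH adjustment matches hand arithmetic and limits", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(96)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_oracle(p))
  # order-preserving
  expect_equal(order(bh_adjust(p)[order(p)]), seq_along(p))
})

test_that("CCA matches a direct eigendecomposition on a toy matrix", {
  Y <- matrix(c(10, 2, 1,
                8, 4, 2,
                2, 9, 5,
                1, 3, 12), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  X <- data.frame(c1 = c(0.2, 0.5, 1.4, 2.2))
  fit <- suppressWarnings(cca_constrained(Y, X, n_perm = 99, seed = 1))
  oracle <- cca_oracle(Y, X)
  expect_equal(fit$total_inertia, oracle$total_inertia, tolerance = 1e-10)
  expect_equal(fit$constrained_inertia, oracle$constrained_inertia,
               tolerance = 1e-10)
  expect_equal(fit$constrained_fraction,
               oracle$constrained_inertia / oracle$total_inertia,
               tolerance = 1e-10)
  expect_lte(fit$constrained_fraction, 1)
})

test_that("CCA reaches fraction 1 under saturated constraints and stays small under noise", {
  set.seed(97)
  Y <- matrix(rpois(8 * 6, 20), 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:6)))
  sat <- data.frame(stats::model.matrix(~ 0 + factor(1:8))[, 1:7])
  names(sat) <- paste0("x", 1:7)
  fit_sat <- suppressWarnings(cca_constrained(Y, sat, n_perm = 19, seed = 1))
  expect_equal(fit_sat$constrained_fraction, 1, tolerance = 1e-8)
  # pure-noise constraint explains little on a larger sample
  Y2 <- matrix(rpois(60 * 6, 20), 60, 6)
  rownames(Y2) <- paste0("s", 1:60); colnames(Y2) <- paste0("t", 1:6)
  xn <- rnorm(60)
  fit_noise <- cca_constrained(Y2, data.frame(x = xn), n_perm = 99, seed = 2)
  expect_lt(fit_noise$constrained_fraction, 0.2)
  # row permutation applied jointly leaves the partition unchanged
  perm <- sample(60)
  fit_perm <- cca_constrained(Y2[perm, ], data.frame(x = xn[perm]),
                              n_perm = 99, seed = 2)
  expect_equal(fit_perm$total_inertia, fit_noise$total_inertia,
               tolerance = 1e-10)
  expect_equal(fit_perm$constrained_fraction, fit_noise$constrained_fraction,
               tolerance = 1e-10)
})
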