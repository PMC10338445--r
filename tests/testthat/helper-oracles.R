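# Independent oracles used by the tests. Each re-derives its quantity from
# first principles (direct summation, enumeration, closed forms) without
# calling the implementation path it checks.

shannon_oracle <- function(f) {
  f <- f[f > 0]
  -sum(f * log(f))
}

bray_curtis_oracle <- function(x, y) {
  sum(abs(x - y)) / sum(x + y)
}

canberra_oracle <- function(x, y) {
  nz <- x + y > 0
  mean(abs(x[nz] - y[nz]) / (x[nz] + y[nz]))
}

# product-limit estimator by hand: ordered event times, S = prod(1 - d/n)
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# two-sided Fisher p by hypergeometric enumeration on a 2x2 table
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Cox partial log-likelihood for one binary covariate, Breslow risk sets,
# no ties assumed; counting-process (start, stop] intervals
cox_loglik_oracle <- function(intervals, beta) {
  ev <- which(intervals$event_at_stop)
  ll <- 0
  for (i in ev) {
    t <- intervals$stop_day[i]
    at_risk <- intervals$start_day < t & intervals$stop_day >= t
    ll <- ll + beta * intervals$covariate[i] -
      log(sum(exp(beta * intervals$covariate[at_risk])))
  }
  ll
}

# subject-mean-centered Pearson construction of the repeated-measures
# correlation
rmcorr_centered_oracle <- function(subject, x, y) {
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  stats::cor(xc, yc)
}

# chi-square standardization + row-weighted projection + SVD, from scratch
cca_oracle <- function(Y, X) {
  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  Q <- (P - E) / sqrt(E)
  total <- sum(Q^2)
  Xc <- sweep(as.matrix(X), 2, colSums(as.matrix(X) * r), "-")
  Xw <- Xc * sqrt(r)
  fitted <- Xw %*% solve(crossprod(Xw), crossprod(Xw, Q))
  sv <- svd(fitted)
  list(total_inertia = total,
       constrained_inertia = sum(fitted^2),
       eig = sv$d[sv$d > 1e-12]^2)
}

# BH step-up by hand
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
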