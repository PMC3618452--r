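# Independent oracles, deliberately written against the definitions
# rather than the package's code paths.

# NIPALS PLS1 (regression mode), the classical algorithm with X and y
# deflation; used as the reference for the OPLS prediction-equivalence
# property and the brute-force Q2 loop.
pls1_fit <- function(X, y, ncomp) {
  W <- P <- matrix(0, ncol(X), ncomp)
  cc <- numeric(ncomp)
  Xi <- X
  yi <- y
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xi, yi))
    w <- w / sqrt(sum(w^2))
    t_ <- drop(Xi %*% w)
    p_ <- drop(crossprod(Xi, t_)) / sum(t_^2)
    c_ <- sum(yi * t_) / sum(t_^2)
    Xi <- Xi - tcrossprod(t_, p_)
    yi <- yi - t_ * c_
    W[, a] <- w
    P[, a] <- p_
    cc[a] <- c_
  }
  list(W = W, P = P, c = cc)
}

pls1_predict <- function(fit, X) {
  yhat <- numeric(nrow(X))
  Xi <- X
  for (a in seq_along(fit$c)) {
    t_ <- drop(Xi %*% fit$W[, a])
    yhat <- yhat + t_ * fit$c[a]
    Xi <- Xi - tcrossprod(t_, fit$P[, a])
  }
  yhat
}

# Brute-force hold-out Q2: same fold convention (seeded shuffle +
# round-robin), per-fold scaling done with base R, per-fold model via
# the independent PLS1 with n_orth + 1 components.
brute_force_q2 <- function(raw, y_coded, n_orth, k, seed) {
  n <- nrow(raw)
  set.seed(seed)
  perm <- sample.int(n)
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(k), n)
  press <- 0
  for (f in seq_len(k)) {
    te <- folds == f
    Xtr <- raw[!te, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, sd)
    keep <- sdv > 0
    Xs <- scale(Xtr[, keep, drop = FALSE], mu[keep], sdv[keep])
    Xte <- scale(raw[te, keep, drop = FALSE], mu[keep], sdv[keep])
    ybar <- mean(y_coded[!te])
    fit <- pls1_fit(Xs, y_coded[!te] - ybar, n_orth + 1)
    press <- press + sum((y_coded[te] - (pls1_predict(fit, Xte) + ybar))^2)
  }
  1 - press / sum((y_coded - mean(y_coded))^2)
}

# Exhaustive right-tail hypergeometric probability by summing point
# masses P(X = k) = C(K,k) C(N-K, n-k) / C(N, n) for k >= h.
enum_hyper_tail <- function(h, K, N, n) {
  ks <- seq(h, min(K, n))
  ks <- ks[ks >= max(0, n - (N - K))]
  if (!length(ks)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Step-up q-value oracle straight from the definition:
# q_(i) = min_{j >= i} pi0 * m * p_(j) / j, capped at 1.
stepup_qvalues <- function(p, pi0) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(pi0 * m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exhaustive point-by-point bucket assignment: loop every grid point
# over every bucket interval (epsilon-shifted half-open membership),
# returning per-bucket sums over the full (unexcluded) tiling.
brute_force_binning <- function(ppm, intensity, lo, width, n_buckets) {
  vals <- numeric(n_buckets)
  counts <- integer(length(ppm))
  for (i in seq_along(ppm)) {
    x <- ppm[i] + 1e-9 * width
    for (b in seq_len(n_buckets)) {
      b_lo <- lo + (b - 1) * width
      if (x >= b_lo && x < b_lo + width) {
        vals[b] <- vals[b] + intensity[i]
        counts[i] <- counts[i] + 1L
      }
    }
  }
  list(values = vals, assignments_per_point = counts)
}

# Scale new data with a training uv_scaled object's parameters via base
# R, used when feeding the PLS1 oracle.
apply_scaling_oracle <- function(sc, newdata) {
  cols <- colnames(sc$values)
  scale(newdata[, cols, drop = FALSE], sc$center[cols], sc$scale[cols])
}
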