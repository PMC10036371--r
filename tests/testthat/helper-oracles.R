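# Independent oracles, coded from first principles and kept free of the
# package's own computational paths.

# Exhaustive paired sign-flip Tmax p-values.  D: pairs x samples difference
# matrix; tail "negative" or "positive".  Returns per-sample exact p over
# all 2^n sign patterns (identity included), with extremes taken over
# `test_idx`.
oracle_paired_tmax <- function(D, tail, test_idx = seq_len(ncol(D))) {
  n <- nrow(D)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tmat <- apply(signs, 1, function(s) {
    d <- s * D
    m <- colMeans(d)
    se <- apply(d, 2, stats::sd) / sqrt(n)
    m / se
  })                                    # samples x 2^n
  t_obs <- tmat[, nrow(signs)]          # last row of expand.grid is all +1
  stopifnot(all(signs[nrow(signs), ] == 1))
  if (tail == "negative") {
    extr <- apply(tmat[test_idx, , drop = FALSE], 2, min)
    vapply(t_obs, function(t0) mean(extr <= t0), numeric(1))
  } else {
    extr <- apply(tmat[test_idx, , drop = FALSE], 2, max)
    vapply(t_obs, function(t0) mean(extr >= t0), numeric(1))
  }
}

# Exhaustive independent-group relabeling Tmax p-values (Welch t), over all
# choose(n, na) assignments of rows of X to group a.
oracle_independent_tmax <- function(a, b, tail, test_idx = NULL) {
  X <- rbind(a, b)
  na <- nrow(a); n <- nrow(X)
  test_idx <- test_idx %||% seq_len(ncol(X))
  combos <- utils::combn(n, na)
  welch <- function(ia) {
    xa <- X[ia, , drop = FALSE]; xb <- X[-ia, , drop = FALSE]
    (colMeans(xa) - colMeans(xb)) /
      sqrt(apply(xa, 2, stats::var) / nrow(xa) +
             apply(xb, 2, stats::var) / nrow(xb))
  }
  t_obs <- welch(seq_len(na))
  tmat <- apply(combos, 2, welch)       # samples x n_combos
  if (tail == "negative") {
    extr <- apply(tmat[test_idx, , drop = FALSE], 2, min)
    vapply(t_obs, function(t0) mean(extr <= t0), numeric(1))
  } else {
    extr <- apply(tmat[test_idx, , drop = FALSE], 2, max)
    vapply(t_obs, function(t0) mean(extr >= t0), numeric(1))
  }
}

# Brute-force two-way within-subject ANOVA from orthonormal contrasts:
# direct sums of squares on the contrast-transformed cell matrix.
# Y: subjects x (kd*kb) cell matrix, columns ordered factor A slow, B fast.
oracle_rm_anova <- function(Y, ka, kb) {
  n <- nrow(Y)
  orth <- function(k) {
    C <- stats::contr.helmert(k)
    sweep(C, 2, sqrt(colSums(C^2)), "/")
  }
  Ca <- orth(ka); Cb <- orth(kb)
  aj <- rep(seq_len(ka), each = kb); bj <- rep(seq_len(kb), ka)
  one_effect <- function(M) {
    Z <- Y %*% M
    q <- ncol(M)
    zb <- colMeans(Z)
    ss_eff <- n * sum(zb^2)
    E <- crossprod(sweep(Z, 2, zb))     # error SSCP
    ss_err <- sum(diag(E))
    Fv <- (ss_eff / q) / (ss_err / (q * (n - 1)))
    eps <- sum(diag(E))^2 / (q * sum(E * E))
    list(F = Fv, df1 = q, df2 = q * (n - 1), eps = eps,
         eta_p = ss_eff / (ss_eff + ss_err), ss_eff = ss_eff,
         ss_err = ss_err)
  }
  Ma <- Ca[aj, , drop = FALSE] / kb
  Mb <- Cb[bj, , drop = FALSE] / ka
  Mab <- Ca[aj, rep(seq_len(ka - 1), kb - 1), drop = FALSE] *
    Cb[bj, rep(seq_len(kb - 1), each = ka - 1), drop = FALSE]
  list(A = one_effect(Ma), B = one_effect(Mb), AB = one_effect(Mab))
}

# Mean of a Gaussian pulse A*exp(-(t-mu)^2/(2*sd^2)) over [w1, w2],
# computed by the closed-form integral.
oracle_gaussian_window_mean <- function(A, mu, sd, w1, w2) {
  A * sd * sqrt(2 * pi) *
    (stats::pnorm((w2 - mu) / sd) - stats::pnorm((w1 - mu) / sd)) / (w2 - w1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
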