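# Independent brute-force oracles used across the suite.

# net force on cell i by direct summation over all pairs and anchors,
# written without the package's spatial index or C++ path
oracle_net_force <- function(i, pos, types, anchors, fp) {
  f <- c(0, 0, 0)
  for (j in seq_len(nrow(pos))) {
    if (j == i) next
    dvec <- pos[j, ] - pos[i, ]
    d <- sqrt(sum(dvec^2))
    if (d == 0) next
    u <- dvec / d
    as_ij <- fp$AS[types[i], types[j]]
    att <- as_ij * fp$A * 0.01^(d / fp$tau_a)
    rep_ <- fp$R * 0.01^(d / fp$tau_r)
    f <- f + (att - rep_) * u
  }
  if (!is.null(anchors) && nrow(anchors) > 0) {
    for (m in seq_len(nrow(anchors))) {
      dvec <- c(anchors[m, 1], anchors[m, 2], 0) - pos[i, ]
      d <- sqrt(sum(dvec^2))
      if (d == 0) next
      f <- f + fp$S * 0.01^(d / fp$tau_s) * dvec / d
    }
  }
  f
}

# sign-change scan of the pairwise net force over a fine distance grid
oracle_equilibrium_scan <- function(A_eff, tau_a, R, tau_r, step = 0.01,
                                    upper = 500) {
  d <- seq(0, upper, by = step)
  net <- A_eff * 0.01^(d / tau_a) - R * 0.01^(d / tau_r)
  sgn <- sign(net)
  flip <- which(diff(sgn) != 0)
  if (length(flip) == 0) {
    if (abs(net[1]) < 1e-12) return(0)
    return(NA_real_)
  }
  d[flip[1]]
}

# literal shift-multiply-sum cross-correlation
oracle_xcorr2d <- function(X, Y) {
  M <- nrow(X); N <- ncol(X)
  C <- matrix(0, 2 * M - 1, 2 * N - 1)
  for (k in -(M - 1):(M - 1)) {
    for (l in -(N - 1):(N - 1)) {
      acc <- 0
      for (m in 1:M) for (n in 1:N) {
        mi <- m - k; ni <- n - l
        if (mi >= 1 && mi <= M && ni >= 1 && ni <= N)
          acc <- acc + X[m, n] * Y[mi, ni]
      }
      C[k + M, l + N] <- acc
    }
  }
  C
}

# total within-z-bin pair count by direct enumeration
oracle_zbin_pairs <- function(pos, z_bin = 10) {
  zb <- floor(pos[, 3] / z_bin)
  sum(vapply(unique(zb), function(b) {
    n <- sum(zb == b)
    n * (n - 1) / 2
  }, numeric(1)))
}

small_slit_config <- function(...) {
  simulation_config(
    confinement(kind = "slit", length = 600, width = 150, height = 100),
    ...)
}
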