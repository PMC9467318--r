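# Independent oracles, written as naive per-sample / dense-matrix code so
# they share no implementation path with the package internals.

# Brute-force threshold scanner: labels every sample of every valid segment
# saccadic or not with explicit loops, then walks the labels to build event
# boundaries with the same tiling convention as the detector.
brute_force_scanner <- function(samples, params = detection_params(),
                                geom = screen_geometry()) {
  ok <- samples$valid & is.finite(samples$x_px) & is.finite(samples$y_px)
  n <- nrow(samples)
  # segment boundaries: split at runs of >= 2 invalid samples
  seg_id <- integer(n)
  cur <- 1L
  i <- 1L
  while (i <= n) {
    if (!ok[i]) {
      j <- i
      while (j < n && !ok[j + 1L]) j <- j + 1L
      if (j - i + 1L >= 2L) cur <- cur + 1L
      seg_id[i:j] <- NA_integer_
      i <- j + 1L
    } else {
      seg_id[i] <- cur
      i <- i + 1L
    }
  }
  fix <- list()
  sac <- list()
  for (s in unique(stats::na.omit(seg_id))) {
    idx <- which(!is.na(seg_id) & seg_id == s)
    if (length(idx) < 2) next
    t <- samples$t_ms[idx]
    pos <- px_to_deg(cbind(samples$x_px[idx], samples$y_px[idx]), geom)
    m <- length(t)
    h <- (params$smooth_window - 1L) %/% 2L
    speed <- numeric(m)
    for (k in seq_len(m)) {
      lo <- max(k - h, 1L)
      hi <- min(k + h, m)
      speed[k] <- sqrt(sum((pos[hi, ] - pos[lo, ])^2)) /
        ((t[hi] - t[lo]) / 1000)
    }
    lab <- logical(m)
    for (k in seq_len(m)) {
      lo <- max(k - 1L, 1L)
      hi <- min(k + 1L, m)
      acc <- (speed[hi] - speed[lo]) / ((t[hi] - t[lo]) / 1000)
      lab[k] <- speed[k] > params$vel_thresh ||
        abs(acc) > params$acc_thresh
    }
    k <- 1L
    while (k <= m) {
      j <- k
      while (j < m && lab[j + 1L] == lab[k]) j <- j + 1L
      off <- if (j < m) t[j + 1L] else t[j]
      if (lab[k]) {
        sac[[length(sac) + 1L]] <- c(onset = t[k], offset = off)
      } else if (j > k) {
        fix[[length(fix) + 1L]] <- c(onset = t[k], offset = off)
      }
      k <- j + 1L
    }
  }
  list(fixations = do.call(rbind, fix), saccades = do.call(rbind, sac))
}

# Dense-matrix REML deviance (up to the same constant as the package):
# builds V = I + lambda Z Z' explicitly.
dense_reml_deviance <- function(y, X, group, lambda) {
  Z <- stats::model.matrix(~ factor(group) - 1)
  V <- diag(length(y)) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  drop(determinant(V)$modulus) + drop(determinant(XtVX)$modulus) +
    (length(y) - ncol(X)) * log(quad)
}

# Two-stage dense grid search for the profiled variance ratio: coarse grid
# over log-lambda, then step-1e-4 refinement around the coarse minimum.
grid_lambda_oracle <- function(y, X, group, coarse_lo = -8, coarse_hi = 8) {
  u <- seq(coarse_lo, coarse_hi, by = 0.01)
  dev <- vapply(u, function(uu) dense_reml_deviance(y, X, group, exp(uu)),
                numeric(1))
  u0 <- u[which.min(dev)]
  uf <- seq(u0 - 0.02, u0 + 0.02, by = 1e-4)
  devf <- vapply(uf, function(uu) dense_reml_deviance(y, X, group, exp(uu)),
                 numeric(1))
  uf[which.min(devf)]
}

# Brute-force JZS Bayes factor: dense-matrix marginal likelihood ratio in
# the original flat-intercept formulation, integrated over g by trapezoid
# on a dense log grid.
brute_jzs_log_bf <- function(y, W, rscale, nodes = 1e5,
                             g_lo = 1e-6, g_hi = 1e6) {
  n <- length(y)
  one <- rep(1, n)
  S0 <- sum((y - mean(y))^2)
  u <- seq(log(g_lo), log(g_hi), length.out = nodes)
  lp <- vapply(u, function(uu) {
    g <- exp(uu)
    M <- diag(n) + g * tcrossprod(W)
    Mi <- solve(M)
    omo <- drop(t(one) %*% Mi %*% one)
    omy <- drop(t(one) %*% Mi %*% y)
    S <- drop(t(y) %*% Mi %*% y) - omy^2 / omo
    logR <- -0.5 * drop(determinant(M)$modulus) -
      0.5 * (log(omo) - log(n)) - (n - 1) / 2 * (log(S) - log(S0))
    logR + 0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * uu -
      rscale^2 / (2 * g) + uu
  }, numeric(1))
  du <- u[2] - u[1]
  m <- max(lp)
  m + log((sum(exp(lp - m)) - 0.5 * (exp(lp[1] - m) +
                                       exp(lp[nodes] - m))) * du)
}

# Sum-to-zero projected design for a factor column, independent of the
# package's eigen-based construction (uses Helmert-style contrasts,
# orthonormalized).
oracle_fixed_design <- function(f) {
  f <- factor(f)
  a <- nlevels(f)
  C <- stats::contr.helmert(a)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  stats::model.matrix(~ f - 1) %*% C
}

# Analytic gaze traces -------------------------------------------------

# Constant-position trace in degrees, rendered to pixels.
constant_trace <- function(dur_ms = 300, pos_deg = c(0, 0), rate = 1000,
                           geom = screen_geometry()) {
  t <- seq(0, dur_ms, by = 1000 / rate)
  px <- deg_to_px(matrix(pos_deg, length(t), 2, byrow = TRUE), geom)
  data.frame(t_ms = t, x_px = px[, 1], y_px = px[, 2], valid = TRUE)
}

# Two steady segments joined by a linear ramp of given amplitude/duration.
step_trace <- function(hold_ms = 200, ramp_ms = 20, amp_deg = 6,
                       rate = 1000, geom = screen_geometry()) {
  t <- seq(0, 2 * hold_ms + ramp_ms, by = 1000 / rate)
  x <- ifelse(t < hold_ms, 0,
              ifelse(t <= hold_ms + ramp_ms,
                     amp_deg * (t - hold_ms) / ramp_ms, amp_deg))
  px <- deg_to_px(cbind(x - amp_deg / 2, 0 * x), geom)
  data.frame(t_ms = t, x_px = px[, 1], y_px = px[, 2], valid = TRUE)
}

# Multi-fixation trace: holds at a sequence of x positions (deg) joined by
# constant-velocity ramps.
multi_step_trace <- function(xs_deg, hold_ms = 150, vel = 300, rate = 1000,
                             geom = screen_geometry()) {
  dt <- 1000 / rate
  t <- 0
  tt <- numeric(0)
  xx <- numeric(0)
  for (i in seq_along(xs_deg)) {
    th <- seq(t, t + hold_ms, by = dt)
    tt <- c(tt, th)
    xx <- c(xx, rep(xs_deg[i], length(th)))
    t <- t + hold_ms + dt
    if (i < length(xs_deg)) {
      ramp_ms <- abs(xs_deg[i + 1] - xs_deg[i]) / vel * 1000
      tr <- seq(t, t + ramp_ms, by = dt)
      frac <- (tr - t) / ramp_ms
      tt <- c(tt, tr)
      xx <- c(xx, xs_deg[i] + frac * (xs_deg[i + 1] - xs_deg[i]))
      t <- tr[length(tr)] + dt
    }
  }
  px <- deg_to_px(cbind(xx, 0 * xx), geom)
  data.frame(t_ms = tt, x_px = px[, 1], y_px = px[, 2], valid = TRUE)
}

# Small hand-built trial: targets on a horizontal line, one fixation/click
# schedule supplied by the caller.
toy_layout <- function(xs_deg = c(-6, 0, 6), geom = screen_geometry()) {
  centers <- deg_to_px(cbind(xs_deg, rep(0, length(xs_deg))), geom)
  target_layout("A", centers, labels = as.character(seq_along(xs_deg)),
                geom = geom)
}
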