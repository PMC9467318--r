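#' Specification of a random-intercept mixed model
#'
#' Fixed effects are dummy-coded with reference levels TMT-A (test type)
#' and accuracy (instruction); the grouping factor is always the subject.
#'
#' @param response Name of the response column (one of the eight test
#'   scores, or any numeric column of the table).
#' @param fixed Character subset of
#'   `c("test_type", "instruction", "interaction")`; the interaction
#'   requires both main effects.
#' @param log_transform Natural-log transform the response before fitting?
#' @param reml Use REML (default) rather than ML.
#' @return An object of class `lmm_spec`.
#' @export
model_spec <- function(response,
                       fixed = c("test_type", "instruction", "interaction"),
                       log_transform = FALSE, reml = TRUE) {
  fixed <- match.arg(fixed, several.ok = TRUE)
  if ("interaction" %in% fixed &&
      !all(c("test_type", "instruction") %in% fixed)) {
    stop("the interaction requires both main effects")
  }
  structure(
    list(response = response, fixed = fixed,
         log_transform = isTRUE(log_transform), reml = isTRUE(reml)),
    class = "lmm_spec"
  )
}

# Dummy-coded design matrix with fixed reference levels A / accuracy.
.lmm_design <- function(table, spec) {
  n <- nrow(table)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if ("test_type" %in% spec$fixed) {
    if (!all(table$test_type %in% c("A", "B"))) {
      stop("test_type must be 'A' or 'B'")
    }
    X <- cbind(X, test_typeB = as.numeric(table$test_type == "B"))
  }
  if ("instruction" %in% spec$fixed) {
    if (!all(table$instruction %in% c("accuracy", "speed"))) {
      stop("instruction must be 'accuracy' or 'speed'")
    }
    X <- cbind(X, instructionspeed = as.numeric(table$instruction == "speed"))
  }
  if ("interaction" %in% spec$fixed) {
    X <- cbind(X, "test_typeB:instructionspeed" =
                 X[, "test_typeB"] * X[, "instructionspeed"])
  }
  X
}

#' Fit a random-intercept linear mixed model by profiled (RE)ML
#'
#' Estimation maximizes the (RE)ML profile deviance over the variance ratio
#' `lambda = sd_intercept^2 / sd_resid^2` by one-dimensional bounded
#' optimization on the log scale (with the `lambda = 0` boundary checked
#' explicitly), solving generalized least squares for the fixed effects at
#' each candidate `lambda`. The random-intercept structure makes every
#' evaluation closed-form: `V = I + lambda Z Z'` is block-diagonal by
#' subject, so `V^{-1}` and `log|V|` follow from per-group Woodbury
#' identities. Standard errors come from the GLS covariance at the optimum,
#' `t = b / SE`, and 95% intervals are Wald, `b +/- 1.96 SE`.
#'
#' Rows with a missing response are dropped (complete-case per response);
#' `n_obs` and `n_groups` report what was actually fitted.
#'
#' @param table Long-format score table with columns `subject`,
#'   `test_type`, `instruction` and the response.
#' @param spec A [model_spec()].
#' @return An object of class `lmm_fit` with elements `coefficients`
#'   (term, estimate, se, t, ci_lo, ci_hi), `sd_intercept`, `sd_resid`,
#'   `lambda`, `loglik`, `n_obs`, `n_groups`, `fitted` (fixed-effect
#'   predictions), `ranef` (subject BLUPs), `vcov`, `data` and `spec`.
#' @examples
#' tab <- simulate_scores(score_sim_config(), seed = 1)
#' fit <- fit_lmm(tab, model_spec("value"))
#' fit$coefficients
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "lmm_spec"))
  need <- c("subject", intersect(c("test_type", "instruction"), spec$fixed),
            spec$response)
  if (!all(need %in% names(table))) {
    stop("table is missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  }
  keep <- stats::complete.cases(table[, need, drop = FALSE]) &
    is.finite(table[[spec$response]])
  table <- table[keep, , drop = FALSE]

  y <- table[[spec$response]]
  if (spec$log_transform) {
    if (any(y <= 0)) stop("log transform requires a positive response")
    y <- log(y)
  }
  X <- .lmm_design(table, spec)
  g <- match(table$subject, unique(table$subject))
  n <- length(y)
  p <- ncol(X)
  J <- if (n) max(g) else 0L
  if (J < 2 || n - J < 2) {
    stop("need at least 2 subjects with at least 2 observations")
  }
  if (qr(X)$rank < p) {
    stop("rank error: design is singular (a coefficient is inestimable; ",
         "check for empty design cells)")
  }

  prof <- .lmm_profile(y, X, g, reml = spec$reml)
  obj <- function(u) prof(exp(u))$dev
  opt <- stats::optimize(obj, interval = c(-15, 15), tol = 1e-10)
  cand <- list(boundary = prof(0), interior = prof(exp(opt$minimum)))
  lambda <- if (cand$boundary$dev <= cand$interior$dev) 0 else exp(opt$minimum)
  sol <- prof(lambda)

  dof <- if (spec$reml) n - p else n
  sigma2 <- sol$quad / dof
  vcov_beta <- sigma2 * solve(sol$XtVX)
  se <- sqrt(diag(vcov_beta))
  beta <- drop(sol$beta)
  loglik <- -0.5 * (sol$logdetV + dof * (log(2 * pi * sigma2) + 1) +
                      if (spec$reml) sol$logdetXtVX else 0)

  fitted <- drop(X %*% beta)
  # Subject BLUPs: shrunk group means of the marginal residuals.
  r <- y - fitted
  nj <- tabulate(g, J)
  ranef <- (lambda * nj / (1 + lambda * nj)) *
    (rowsum(r, g)[, 1] / nj)

  coefs <- data.frame(
    term = colnames(X), estimate = beta, se = se, t = beta / se,
    ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
    row.names = NULL
  )
  structure(
    list(coefficients = coefs, sd_intercept = sqrt(sigma2 * lambda),
         sd_resid = sqrt(sigma2), lambda = lambda, loglik = loglik,
         n_obs = n, n_groups = J, fitted = fitted,
         ranef = stats::setNames(ranef, unique(table$subject)),
         vcov = vcov_beta, y = y, X = X, group = g,
         data = table, spec = spec),
    class = "lmm_fit"
  )
}

# Profile (RE)ML machinery. Returns a function of lambda evaluating the
# deviance (up to a constant) plus the GLS solution, using per-group
# Woodbury identities:
#   V_j^{-1} = I - (lambda / (1 + lambda n_j)) J_nj,
#   log|V_j| = log(1 + lambda n_j).
.lmm_profile <- function(y, X, g, reml = TRUE) {
  n <- length(y)
  p <- ncol(X)
  J <- max(g)
  nj <- tabulate(g, J)
  Sx <- rowsum(X, g)
  Sy <- rowsum(y, g)[, 1]
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  function(lambda) {
    w <- lambda / (1 + lambda * nj)
    XtVX <- XtX - crossprod(Sx * sqrt(w))
    XtVy <- Xty - crossprod(Sx, w * Sy)
    ytVy <- yty - sum(w * Sy^2)
    R <- tryCatch(chol(XtVX), error = function(e) {
      stop("rank error: generalized least squares system is singular")
    })
    beta <- backsolve(R, forwardsolve(t(R), XtVy))
    quad <- max(ytVy - sum(XtVy * beta), .Machine$double.eps)
    logdetV <- sum(log1p(lambda * nj))
    logdetXtVX <- 2 * sum(log(diag(R)))
    dev <- if (reml) {
      logdetV + logdetXtVX + (n - p) * log(quad)
    } else {
      logdetV + n * log(quad)
    }
    list(dev = dev, beta = beta, quad = quad, XtVX = XtVX,
         logdetV = logdetV, logdetXtVX = logdetXtVX)
  }
}

#' @export
print.lmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Random-intercept LMM (%s), response: %s%s\n",
              if (x$spec$reml) "REML" else "ML", x$spec$response,
              if (x$spec$log_transform) " (log)" else ""))
  cat(sprintf("  %d observations, %d subjects\n", x$n_obs, x$n_groups))
  cf <- x$coefficients
  cf[, -1] <- round(cf[, -1], digits)
  print(cf, row.names = FALSE)
  cat(sprintf("  SD_Intercept = %.*f, SD_Residual = %.*f, logLik = %.2f\n",
              digits, x$sd_intercept, digits, x$sd_resid, x$loglik))
  invisible(x)
}

#' Wald p-values for a fitted mixed model
#'
#' Two-sided p-values from the t statistics `b / SE`. With
#' `df_method = "residual"` the degrees of freedom are
#' `n_obs - p - (n_groups - 1)`, the classical within-subject residual df
#' for a random-intercept model; `"satterthwaite"` computes per-coefficient
#' df from the variance-component covariance (numerical REML Hessian).
#' P-values in mixed models are approximations either way; confidence
#' intervals are the primary inferential output.
#'
#' @param fit An [fit_lmm()] result.
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @return Data frame with `term`, `t`, `df`, `p` and the method used.
#' @export
wald_pvalues <- function(fit, df_method = c("residual", "satterthwaite")) {
  stopifnot(inherits(fit, "lmm_fit"))
  df_method <- match.arg(df_method)
  tval <- fit$coefficients$t
  if (df_method == "residual") {
    df <- rep(max(fit$n_obs - nrow(fit$coefficients) -
                    (fit$n_groups - 1), 1), length(tval))
  } else {
    df <- vapply(seq_along(tval), function(i) .satterthwaite_df(fit, i),
                 numeric(1))
  }
  data.frame(term = fit$coefficients$term, t = tval, df = df,
             p = 2 * stats::pt(-abs(tval), df), method = df_method,
             row.names = NULL)
}

# Satterthwaite df for coefficient i:
#   df = 2 f(theta)^2 / (grad' Vtheta grad),
# with f(theta) = [X' Sigma^{-1} X]^{-1}_{ii}, theta = (sd_u^2, sd_e^2),
# and Vtheta the inverse numerical Hessian of the REML deviance in theta.
.satterthwaite_df <- function(fit, i) {
  y <- fit$y; X <- fit$X; g <- fit$group
  n <- length(y); p <- ncol(X)
  prof <- .lmm_profile(y, X, g)
  f <- function(th) {
    s2u <- max(th[1], 0); s2e <- max(th[2], .Machine$double.eps)
    sol <- prof(s2u / s2e)
    (s2e * solve(sol$XtVX))[i, i]
  }
  dev <- function(th) {
    s2u <- max(th[1], 0); s2e <- max(th[2], .Machine$double.eps)
    sol <- prof(s2u / s2e)
    # full REML -2 loglik in theta (quad is on the unit-V scale)
    sol$logdetV + (n - p) * log(2 * pi * s2e) + sol$logdetXtVX +
      sol$quad / s2e
  }
  th <- c(fit$sd_intercept^2, fit$sd_resid^2)
  h <- pmax(1e-4 * pmax(abs(th), 1e-6), 1e-8)
  grad_f <- .fd_grad(f, th, h)
  H <- .fd_hessian(dev, th, h) / 2        # Hessian of -loglik
  Vth <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Vth)) return(n - p)
  denom <- drop(t(grad_f) %*% Vth %*% grad_f)
  if (!is.finite(denom) || denom <= 0) return(n - p)
  max(2 * f(th)^2 / denom, 1)
}

.fd_grad <- function(f, x, h) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h[k]
    (f(x + e) - f(pmax(x - e, 0))) / (x[k] + h[k] - pmax(x[k] - h[k], 0))
  }, numeric(1))
}

.fd_hessian <- function(f, x, h) {
  m <- length(x)
  H <- matrix(0, m, m)
  f0 <- f(x)
  for (a in seq_len(m)) {
    for (b in a:m) {
      ea <- numeric(m); ea[a] <- h[a]
      eb <- numeric(m); eb[b] <- h[b]
      H[a, b] <- H[b, a] <-
        (f(x + ea + eb) - f(x + ea) - f(x + eb) + f0) / (h[a] * h[b])
    }
  }
  H
}

#' Default model specifications for the eight test scores
#'
#' Full dummy-coded test_type x instruction models with the standard
#' log-transform set: `n_fixations`, `n_searching`, `mean_eye_hand_span`
#' and `scanpath_length` are fitted on the natural-log scale.
#'
#' @param reml Use REML (default).
#' @return Named list of [model_spec()] objects.
#' @export
tmt_model_specs <- function(reml = TRUE) {
  logged <- c("n_fixations", "n_searching", "mean_eye_hand_span",
              "scanpath_length")
  measures <- .score_measures()
  stats::setNames(lapply(measures, function(m) {
    model_spec(m, log_transform = m %in% logged, reml = reml)
  }), measures)
}

#' Fit all test-score models and summarize them in one table
#'
#' One random-intercept model per score, reported long: a row per
#' score x coefficient with estimate, Wald interval, SE, t and p
#' (residual-df method), plus the per-model group count, observation count
#' and variance components.
#'
#' @param scores Aggregated score table (one row per subject x cell), e.g.
#'   from [aggregate_scores()] or [simulate_score_table()].
#' @param specs Named list of [model_spec()]s; default [tmt_model_specs()].
#' @return Data frame summary; the fitted `lmm_fit` objects are attached as
#'   attribute `"fits"`.
#' @export
lmm_report <- function(scores, specs = tmt_model_specs()) {
  rows <- list()
  fits <- list()
  for (dv in names(specs)) {
    fit <- fit_lmm(scores, specs[[dv]])
    pv <- wald_pvalues(fit)
    cf <- fit$coefficients
    rows[[dv]] <- data.frame(
      dv = dv, term = cf$term, estimate = cf$estimate, se = cf$se,
      t = cf$t, p = pv$p, ci_lo = cf$ci_lo, ci_hi = cf$ci_hi,
      n_groups = fit$n_groups, n_obs = fit$n_obs,
      sd_intercept = fit$sd_intercept, sd_resid = fit$sd_resid,
      log_transform = specs[[dv]]$log_transform, row.names = NULL
    )
    fits[[dv]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
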