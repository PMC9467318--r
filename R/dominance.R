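#' Prior specification for JZS Bayes factors
#'
#' Zellner-Siow mixture-of-g priors on standardized effects: a Cauchy scale
#' of 0.5 on fixed (experimental) effect blocks and 1.0 on random (subject)
#' effect blocks, the conventional "medium" / "nuisance" defaults for
#' ANOVA-type designs. The common g per block carries a scaled
#' inverse-chi-square(1) prior, equivalent to the Cauchy scale on the
#' effects, and is integrated out by deterministic adaptive quadrature on
#' the log-g scale.
#'
#' @param rscale_fixed Cauchy scale for fixed-effect blocks.
#' @param rscale_random Cauchy scale for random-factor blocks.
#' @param rel_tol Relative tolerance of the quadrature.
#' @return An object of class `bf_prior_spec`.
#' @export
bf_prior_spec <- function(rscale_fixed = 0.5, rscale_random = 1,
                          rel_tol = 1e-6) {
  if (rscale_fixed <= 0 || rscale_random <= 0) {
    stop("prior scales must be strictly positive")
  }
  structure(list(rscale_fixed = rscale_fixed,
                 rscale_random = rscale_random, rel_tol = rel_tol),
            class = "bf_prior_spec")
}

# Sum-to-zero projection for a fixed factor with a levels: Q is a x (a-1)
# with Q'Q = I and QQ' = I - J/a, so effects theta ~ N(0, g sigma^2 I) on
# the projected columns imply the exchangeable sum-to-zero prior
# N(0, g sigma^2 (I - J/a)) on the a cell effects.
.fixed_projection <- function(a) {
  e <- eigen(diag(a) - 1 / a, symmetric = TRUE)
  e$vectors[, e$values > 0.5, drop = FALSE]
}

# log marginal likelihood ratio m(g)/m(null) for y = mu 1 + W theta + e,
# theta | g ~ N(0, g sigma^2 I_k), flat priors on (mu, log sigma).
# Integrating mu exactly reduces the problem to the orthogonal complement
# of the intercept: with centered response y~ and the centered Gram matrix
# W'(I - 11'/n)W (eigenvalues d, response loadings a),
#   log m(g)/m(0) = -1/2 sum log(1 + g d_i)
#                   - (n-1)/2 [log S(g) - log S(0)],
#   S(g) = ||y~||^2 - sum a_i^2 g/(1 + g d_i),
# which is numerically stable for arbitrarily large g. Each evaluation
# costs O(k).
.jzs_ratio_fn <- function(y, W) {
  n <- length(y)
  yc <- y - mean(y)
  S0 <- sum(yc^2)
  cs <- colSums(W)
  G <- crossprod(W) - tcrossprod(cs) / n
  ed <- eigen(G, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  a <- drop(crossprod(ed$vectors, crossprod(W, yc)))
  # null directions of the centered design carry no signal
  a[d < max(d) * 1e-12] <- 0
  function(g) {
    S <- S0 - sum(a^2 * g / (1 + g * d))
    if (S <= 0) S <- S0 * 1e-300
    out <- -0.5 * sum(log1p(g * d)) - (n - 1) / 2 * (log(S) - log(S0))
    if (!is.finite(out)) -Inf else out
  }
}

# log InverseGamma(1/2, r^2/2) density of g (the Zellner-Siow mixing prior).
.log_g_prior <- function(g, rscale) {
  0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    rscale^2 / (2 * g)
}

.jzs_log_bf <- function(y, W, rscale, rel_tol = 1e-6) {
  if (is.null(W) || ncol(W) == 0) return(0)
  ratio <- .jzs_ratio_fn(y, W)
  logpost <- function(u) {
    v <- ratio(exp(u)) + .log_g_prior(exp(u), rscale) + u
    if (is.finite(v)) v else -Inf
  }
  mode <- stats::optimize(logpost, interval = c(-40, 40),
                          maximum = TRUE, tol = 1e-8)
  m <- mode$objective
  val <- stats::integrate(function(u) exp(vapply(u, logpost, numeric(1)) - m),
                          lower = mode$maximum - 50,
                          upper = mode$maximum + 50,
                          rel.tol = min(rel_tol, 1e-6),
                          subdivisions = 5000L)
  m + log(val$value)
}

#' JZS Bayes factor of a fixed- or random-effects-only model
#'
#' Compares, against the intercept-only model, either the model holding
#' only the experimental instruction effect (fixed-effects-only) or the
#' model holding only the subject factor (random-effects-only), within one
#' test half. The marginal likelihood integrates the common effect-scale g
#' under the Zellner-Siow prior; the result is deterministic given the
#' quadrature tolerance and invariant to the location and scale of the
#' response.
#'
#' @param table Data frame for one test half with columns `subject`,
#'   `instruction` and the response.
#' @param model `"fixed"` (instruction only) or `"random"` (subject only).
#' @param response Name of the response column (default `"value"`).
#' @param priors A [bf_prior_spec()].
#' @return An object of class `jzs_bf`: list with `bf` (BF10), `log_bf`,
#'   `model`, `rscale`, `n`.
#' @export
jzs_bf <- function(table, model = c("fixed", "random"), response = "value",
                   priors = bf_prior_spec()) {
  model <- match.arg(model)
  stopifnot(inherits(priors, "bf_prior_spec"))
  fac_col <- if (model == "fixed") "instruction" else "subject"
  need <- c(fac_col, response)
  if (!all(need %in% names(table))) {
    stop("table is missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  }
  keep <- stats::complete.cases(table[, need, drop = FALSE])
  table <- table[keep, , drop = FALSE]
  y <- table[[response]]
  if (length(y) < 3) stop("need at least 3 observations")
  if (stats::var(y) == 0) {
    stop("degenerate response: zero variance, Bayes factor undefined")
  }
  f <- factor(table[[fac_col]])
  if (nlevels(f) < 2) stop("factor must have at least 2 levels")
  ind <- stats::model.matrix(~ f - 1)
  if (model == "fixed") {
    W <- ind %*% .fixed_projection(nlevels(f))
    rscale <- priors$rscale_fixed
  } else {
    W <- ind
    rscale <- priors$rscale_random
  }
  log_bf <- .jzs_log_bf(y, W, rscale, priors$rel_tol)
  structure(list(bf = exp(log_bf), log_bf = log_bf, model = model,
                 rscale = rscale, n = length(y)),
            class = "jzs_bf")
}

#' @export
print.jzs_bf <- function(x, ...) {
  cat(sprintf("<jzs_bf> %s-effects-only vs intercept-only: BF10 = %.4g (n = %d, rscale = %g)\n",
              x$model, x$bf, x$n, x$rscale))
  invisible(x)
}

#' Dominance quotient of two Bayes factors
#'
#' The quotient BF(fixed-only) / BF(random-only). A quotient above 1 means
#' the experimental manipulation dominates the score
#' (`"fixed-dominated"`); below 1, interindividual variability dominates
#' (`"random-dominated"`).
#'
#' @param bf_fixed,bf_random Positive numbers or [jzs_bf()] objects.
#' @return List with `quotient` and `verdict`.
#' @export
dominance_quotient <- function(bf_fixed, bf_random) {
  bf <- function(x) if (inherits(x, "jzs_bf")) x$bf else as.numeric(x)
  bf_fixed <- bf(bf_fixed)
  bf_random <- bf(bf_random)
  if (is.na(bf_fixed) || is.na(bf_random) || bf_fixed <= 0 ||
      bf_random <= 0) {
    stop("Bayes factors must be strictly positive")
  }
  q <- bf_fixed / bf_random
  verdict <- if (q > 1) {
    "fixed-dominated"
  } else if (q < 1) {
    "random-dominated"
  } else {
    "undetermined"
  }
  list(quotient = q, verdict = verdict)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance decomposition for a random-intercept model: with `s2_f` the
#' population variance of the fixed-effect predictions, `s2_u` the
#' subject-intercept variance and `s2_e` the residual variance,
#' `R2_marginal = s2_f / (s2_f + s2_u + s2_e)` and
#' `R2_conditional = (s2_f + s2_u) / (s2_f + s2_u + s2_e)`.
#'
#' @param fit An [fit_lmm()] result.
#' @return List with `r2_marginal` and `r2_conditional`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  s2_f <- mean((fit$fitted - mean(fit$fitted))^2)
  s2_u <- fit$sd_intercept^2
  s2_e <- fit$sd_resid^2
  tot <- s2_f + s2_u + s2_e
  if (tot <= 0) stop("zero total variance: R-squared undefined")
  list(r2_marginal = s2_f / tot, r2_conditional = (s2_f + s2_u) / tot)
}

#' Cluster-bootstrap confidence intervals for mixed-model R-squared
#'
#' Resamples subjects with replacement (preserving within-subject
#' dependence), refits the model on each replicate and returns percentile
#' 95% intervals for the marginal and conditional R-squared. Replicates
#' whose refit fails are dropped and counted.
#'
#' @param table Long-format score table.
#' @param spec A [model_spec()].
#' @param B Number of bootstrap replicates.
#' @param seed Optional seed (reproducible resampling).
#' @return List with `ci_r2m`, `ci_r2c` (length-2 vectors), `B`,
#'   `n_failed`, and the replicate values `r2m`, `r2c`.
#' @export
bootstrap_r2_ci <- function(table, spec, B = 1000, seed = NULL) {
  stopifnot(inherits(spec, "lmm_spec"))
  subjects <- unique(table$subject)
  if (length(subjects) < 5) stop("need at least 5 subjects to bootstrap")
  rows_by_subj <- split(seq_len(nrow(table)), table$subject)
  .with_seed(seed, {
    r2m <- r2c <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      pick <- sample(subjects, length(subjects), replace = TRUE)
      idx <- unlist(rows_by_subj[pick], use.names = FALSE)
      boot <- table[idx, , drop = FALSE]
      # Relabel so a subject drawn twice counts as two clusters.
      boot$subject <- rep(seq_along(pick),
                          lengths(rows_by_subj[pick]))
      r2 <- tryCatch(r2_nakagawa(fit_lmm(boot, spec)),
                     error = function(e) NULL)
      if (!is.null(r2)) {
        r2m[b] <- r2$r2_marginal
        r2c[b] <- r2$r2_conditional
      }
    }
    ok <- !is.na(r2m)
    if (!any(ok)) stop("all bootstrap refits failed")
    list(ci_r2m = unname(stats::quantile(r2m[ok], c(0.025, 0.975))),
         ci_r2c = unname(stats::quantile(r2c[ok], c(0.025, 0.975))),
         B = B, n_failed = sum(!ok), r2m = r2m[ok], r2c = r2c[ok])
  })
}

#' Dominance analysis of one test score in one test half
#'
#' The two-step procedure that classifies a score as driven by the
#' speed/accuracy manipulation or by interindividual variability: within a
#' test half, (1) the JZS Bayes factor of the instruction-only model and of
#' the subject-only model, each against the intercept-only model, and their
#' quotient; (2) marginal and conditional R-squared of the random-intercept
#' model `response ~ instruction + (1 | subject)` with cluster-bootstrap
#' 95% intervals.
#'
#' @param table Data frame for one test half: columns `subject`,
#'   `instruction`, response.
#' @param response Response column name.
#' @param log_transform Analyze the natural-log response?
#' @param priors A [bf_prior_spec()].
#' @param B Bootstrap replicates.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `dominance_result`: list with `bf_fixed`,
#'   `bf_random`, `quotient`, `verdict`, `r2_marginal`, `r2_conditional`,
#'   `ci_r2m`, `ci_r2c`, `n_boot_failed`, `n_obs`, `n_groups`, `priors`.
#' @export
dominance <- function(table, response, log_transform = FALSE,
                      priors = bf_prior_spec(), B = 1000, seed = NULL) {
  keep <- stats::complete.cases(table[, c("subject", "instruction",
                                          response), drop = FALSE])
  table <- table[keep, , drop = FALSE]
  if (log_transform) {
    if (any(table[[response]] <= 0)) {
      stop("log transform requires a positive response")
    }
    table[[response]] <- log(table[[response]])
  }
  bf_f <- jzs_bf(table, "fixed", response, priors)
  bf_r <- jzs_bf(table, "random", response, priors)
  q <- dominance_quotient(bf_f, bf_r)
  spec <- model_spec(response, fixed = "instruction")
  fit <- fit_lmm(table, spec)
  r2 <- r2_nakagawa(fit)
  ci <- bootstrap_r2_ci(table, spec, B = B, seed = seed)
  structure(
    list(bf_fixed = bf_f$bf, bf_random = bf_r$bf, quotient = q$quotient,
         verdict = q$verdict, r2_marginal = r2$r2_marginal,
         r2_conditional = r2$r2_conditional, ci_r2m = ci$ci_r2m,
         ci_r2c = ci$ci_r2c, n_boot_failed = ci$n_failed,
         n_obs = fit$n_obs, n_groups = fit$n_groups, priors = priors),
    class = "dominance_result"
  )
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("<dominance_result> BF_fixed = %.4g, BF_random = %.4g\n",
              x$bf_fixed, x$bf_random))
  cat(sprintf("  quotient = %.4g -> %s\n", x$quotient, x$verdict))
  cat(sprintf("  R2m = %.3f [%.3f, %.3f], R2c = %.3f [%.3f, %.3f]\n",
              x$r2_marginal, x$ci_r2m[1], x$ci_r2m[2],
              x$r2_conditional, x$ci_r2c[1], x$ci_r2c[2]))
  invisible(x)
}

#' Dominance analysis for every test score and test half
#'
#' @param scores Aggregated score table (subject x test_type x instruction
#'   rows) holding the eight score columns.
#' @param dvs Score columns to analyze; defaults to all eight.
#' @param priors A [bf_prior_spec()].
#' @param B Bootstrap replicates per score and half.
#' @param seed Master seed; each score x half gets a split sub-seed.
#' @return Data frame, one row per score x test half: `bf_fixed`,
#'   `bf_random`, `quotient`, `r2m`, `r2m_lo`, `r2m_hi`, `r2c`, `r2c_lo`,
#'   `r2c_hi`, `verdict`.
#' @export
dominance_report <- function(scores, dvs = .score_measures(),
                             priors = bf_prior_spec(), B = 1000,
                             seed = 1) {
  logged <- vapply(tmt_model_specs()[intersect(dvs, .score_measures())],
                   `[[`, logical(1), "log_transform")
  rows <- list()
  k <- 0L
  for (dv in dvs) {
    for (half in c("A", "B")) {
      k <- k + 1L
      tab <- scores[scores$test_type == half, , drop = FALSE]
      res <- dominance(tab, dv,
                       log_transform = isTRUE(logged[dv]),
                       priors = priors, B = B,
                       seed = .split_seed(seed, k))
      rows[[k]] <- data.frame(
        dv = dv, test_type = half, bf_fixed = res$bf_fixed,
        bf_random = res$bf_random, quotient = res$quotient,
        r2m = res$r2_marginal, r2m_lo = res$ci_r2m[1],
        r2m_hi = res$ci_r2m[2], r2c = res$r2_conditional,
        r2c_lo = res$ci_r2c[1], r2c_hi = res$ci_r2c[2],
        verdict = res$verdict, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
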