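toy_half <- function(seed, betas = c(20, 0, -3, 0), sd_subject = 2,
                     sd_resid = 2, n_subjects = 6) {
  tab <- simulate_scores(score_sim_config(betas = betas,
                                          sd_subject = sd_subject,
                                          sd_resid = sd_resid,
                                          n_subjects = n_subjects),
                         seed = seed)
  tab[tab$test_type == "A", ]
}

test_that("JZS Bayes factors match brute-force g-integration on small tables", {
  tabs <- list(toy_half(1, n_subjects = 6),                   # 12 rows
               toy_half(2, n_subjects = 8, sd_subject = 4))   # 16 rows
  for (tab in tabs) {
    for (model in c("fixed", "random")) {
      mine <- jzs_bf(tab, model)
      if (model == "fixed") {
        W <- oracle_fixed_design(tab$instruction)
        r <- 0.5
      } else {
        W <- stats::model.matrix(~ factor(tab$subject) - 1)
        r <- 1
      }
      oracle <- exp(brute_jzs_log_bf(tab$value, W, r))
      expect_lt(abs(mine$bf / oracle - 1), 0.01)
    }
  }
})

test_that("the intercept-only model against itself has Bayes factor 1", {
  tab <- toy_half(3)
  expect_equal(trailgaze:::.jzs_log_bf(tab$value,
                                       matrix(0, nrow(tab), 0), 0.5), 0)
})

test_that("pure-noise data favor the simpler model", {
  bfs <- vapply(1:200, function(i) {
    tab <- simulate_scores(score_sim_config(betas = c(50, 0, 0, 0),
                                            sd_subject = 0, sd_resid = 10),
                           seed = 40000 + i)
    jzs_bf(tab[tab$test_type == "A", ], "fixed")$bf
  }, numeric(1))
  expect_lt(median(bfs), 1)
})

test_that("Bayes factors are invariant to the location and scale of the response", {
  tab <- toy_half(5)
  for (model in c("fixed", "random")) {
    base <- jzs_bf(tab, model)$log_bf
    tab2 <- tab
    tab2$value <- tab$value * 250 - 1000
    expect_equal(jzs_bf(tab2, model)$log_bf, base, tolerance = 1e-6)
  }
})

test_that("degenerate or malformed BF inputs are rejected", {
  tab <- toy_half(6)
  tab$value <- 7
  expect_error(jzs_bf(tab, "fixed"), "degenerate")
  expect_error(jzs_bf(toy_half(6)[, c("subject", "value")], "fixed"),
               "missing columns")
})

test_that("the dominance quotient and verdict follow the decision rule", {
  q <- dominance_quotient(4, 2)
  expect_equal(q$quotient, 2)
  expect_equal(q$verdict, "fixed-dominated")
  expect_equal(dominance_quotient(0.5, 0.5)$quotient, 1)
  expect_equal(dominance_quotient(0.5, 0.5)$verdict, "undetermined")
  expect_equal(dominance_quotient(0.2, 0.8)$verdict, "random-dominated")
  expect_error(dominance_quotient(-1, 2), "positive")
  # verdict agrees with bf_fixed > bf_random for jzs_bf objects
  tab <- toy_half(7, betas = c(20, 0, -8, 0), sd_subject = 0.5)
  bf_f <- jzs_bf(tab, "fixed")
  bf_r <- jzs_bf(tab, "random")
  expect_equal(dominance_quotient(bf_f, bf_r)$quotient > 1,
               bf_f$bf > bf_r$bf)
})

test_that("R-squared decomposition follows the variance arithmetic", {
  fake <- structure(list(fitted = c(-1, 1, -1, 1) * sqrt(4 / 3),
                         sd_intercept = 1, sd_resid = sqrt(2)),
                    class = "lmm_fit")
  # population variance of fitted = 4/3 ... adjust to exactly 1
  fake$fitted <- c(-1, 1, -1, 1)        # population variance 1
  r2 <- r2_nakagawa(fake)
  expect_equal(r2$r2_marginal, 0.25)
  expect_equal(r2$r2_conditional, 0.50)
  # constant fixed predictions give marginal 0
  fake$fitted <- rep(5, 4)
  expect_equal(r2_nakagawa(fake)$r2_marginal, 0)
  # noise-free limit: everything explained by the fixed effects
  tab <- simulate_scores(score_sim_config(betas = c(10, 0, -4, 0),
                                          sd_subject = 0, sd_resid = 0),
                         seed = 8)
  fit <- fit_lmm(tab[tab$test_type == "A", ],
                 model_spec("value", fixed = "instruction"))
  r2nf <- r2_nakagawa(fit)
  expect_equal(r2nf$r2_marginal, 1, tolerance = 1e-6)
  expect_equal(r2nf$r2_conditional, 1, tolerance = 1e-6)
  # degenerate: no variance at all
  fake$fitted <- rep(0, 4)
  fake$sd_intercept <- 0
  fake$sd_resid <- 0
  expect_error(r2_nakagawa(fake), "zero total variance")
})

test_that("R-squared invariants hold across random fits", {
  for (s in 1:10) {
    tab <- simulate_scores(score_sim_config(
      betas = c(50, stats::rnorm(1, 0, 10), stats::rnorm(1, 0, 10), 0),
      sd_subject = stats::runif(1, 0, 20),
      sd_resid = stats::runif(1, 1, 20), n_subjects = 12), seed = 500 + s)
    fit <- fit_lmm(tab, model_spec("value"))
    r2 <- r2_nakagawa(fit)
    expect_gte(r2$r2_marginal, 0)
    expect_lte(r2$r2_marginal, r2$r2_conditional)
    expect_lte(r2$r2_conditional, 1)
  }
})

test_that("bootstrap intervals behave in the degenerate limits", {
  half <- toy_half(9, n_subjects = 8)
  spec <- model_spec("value", fixed = "instruction")
  one <- bootstrap_r2_ci(half, spec, B = 1, seed = 2)
  expect_equal(one$ci_r2m[1], one$ci_r2m[2])
  expect_equal(one$ci_r2m[1], one$r2m)
  # identical noise-free subjects: every resample gives the same R2
  ident <- expand.grid(subject = sprintf("s%d", 1:8),
                       instruction = c("accuracy", "speed"),
                       stringsAsFactors = FALSE)
  ident$value <- ifelse(ident$instruction == "speed", 8, 12)
  ci <- bootstrap_r2_ci(ident, spec, B = 20, seed = 3)
  expect_equal(diff(ci$ci_r2m), 0, tolerance = 1e-9)
  expect_equal(diff(ci$ci_r2c), 0, tolerance = 1e-9)
  expect_error(bootstrap_r2_ci(half[half$subject %in%
                                      sprintf("s%02d", 1:3), ],
                               spec, B = 5), "at least 5")
  # reproducible under seed
  a <- bootstrap_r2_ci(half, spec, B = 30, seed = 11)
  b <- bootstrap_r2_ci(half, spec, B = 30, seed = 11)
  expect_identical(a$ci_r2m, b$ci_r2m)
})

test_that("dominance verdicts track the generating regime (Monte Carlo)", {
  n_rep <- 20
  q_fixed <- q_random <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    fx <- simulate_scores(score_sim_config(betas = c(72.55, 0, -28.18, 0)),
                          seed = 52000 + i)
    rx <- simulate_scores(score_sim_config(betas = c(72.55, 0, 0, 0)),
                          seed = 53000 + i)
    df <- dominance(fx[fx$test_type == "A", ], "value", B = 10,
                    seed = i)
    dr <- dominance(rx[rx$test_type == "A", ], "value", B = 10,
                    seed = i)
    q_fixed[i] <- df$quotient
    q_random[i] <- dr$quotient
  }
  expect_gte(mean(q_fixed > 1), 0.9)
  expect_gte(mean(q_random < 1), 0.9)
})

test_that("the dominance report covers every score and half with coherent columns", {
  tab <- simulate_score_table(n_subjects = 10, seed = 6)
  rep <- dominance_report(tab, dvs = c("trial_duration",
                                       "mean_fixation_duration"),
                          B = 20, seed = 4)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$quotient == rep$bf_fixed / rep$bf_random))
  expect_true(all(rep$r2m_lo <= rep$r2m_hi))
  expect_true(all((rep$quotient > 1) == (rep$verdict == "fixed-dominated")))
  # determinism of the full report under a fixed seed
  rep2 <- dominance_report(tab, dvs = c("trial_duration",
                                        "mean_fixation_duration"),
                           B = 20, seed = 4)
  expect_identical(rep, rep2)
})
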