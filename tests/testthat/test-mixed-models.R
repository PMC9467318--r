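test_that("noise-free balanced data recovers the cell means exactly", {
  tab <- simulate_scores(score_sim_config(betas = c(10, 4, 2, 0),
                                          sd_subject = 0, sd_resid = 0,
                                          n_subjects = 6), seed = 1)
  fit <- fit_lmm(tab, model_spec("value"))
  expect_equal(fit$coefficients$estimate, c(10, 4, 2, 0), tolerance = 1e-7)
  expect_lt(fit$sd_resid, 1e-4)
})

test_that("with no subject variance the fit collapses to the OLS oracle", {
  tab <- simulate_scores(score_sim_config(sd_subject = 0), seed = 4)
  fit <- fit_lmm(tab, model_spec("value"))
  X <- cbind(1, tab$test_type == "B", tab$instruction == "speed",
             (tab$test_type == "B") * (tab$instruction == "speed"))
  beta_ols <- solve(crossprod(X), crossprod(X, tab$value))
  s2 <- sum((tab$value - X %*% beta_ols)^2) / (nrow(X) - ncol(X))
  se_ols <- sqrt(diag(s2 * solve(crossprod(X))))
  expect_lt(max(abs(fit$coefficients$estimate - beta_ols)), 1e-8)
  expect_lt(max(abs(fit$coefficients$se - se_ols)), 1e-8)
})

test_that("the profiled optimizer matches a dense grid search on small instances", {
  for (s in 1:3) {
    tab <- simulate_scores(score_sim_config(sd_subject = 15, sd_resid = 10,
                                            n_subjects = 6 + s),
                           seed = 40 + s)
    fit <- fit_lmm(tab, model_spec("value"))
    spec <- model_spec("value")
    X <- trailgaze:::.lmm_design(tab, spec)
    u_star <- grid_lambda_oracle(tab$value, X,
                                 match(tab$subject, unique(tab$subject)))
    expect_gt(fit$lambda, 0)
    expect_lte(abs(log(fit$lambda) - u_star), 1e-4 + 1e-8)
  }
})

test_that("the fit agrees with lme4 on betas, SEs and variance components", {
  tab <- simulate_scores(score_sim_config(), seed = 8)
  fit <- fit_lmm(tab, model_spec("value"))
  m <- lme4::lmer(value ~ test_type * instruction + (1 | subject),
                  data = tab, REML = TRUE)
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(m)),
               tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(coef(summary(m))[, "Std. Error"]), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$sd_intercept, vc$sdcor[1], tolerance = 1e-5)
  expect_equal(fit$sd_resid, vc$sdcor[2], tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  # ML variant
  fit_ml <- fit_lmm(tab, model_spec("value", reml = FALSE))
  m_ml <- lme4::lmer(value ~ test_type * instruction + (1 | subject),
                     data = tab, REML = FALSE)
  expect_equal(fit_ml$loglik, as.numeric(stats::logLik(m_ml)),
               tolerance = 1e-6)
})

test_that("in a balanced design the instruction coefficient is the mean within-subject contrast", {
  tab <- simulate_scores(score_sim_config(), seed = 12)
  fit <- fit_lmm(tab, model_spec("value"))
  a <- tab[tab$test_type == "A", ]
  # speed minus accuracy per subject in TMT-A
  spd <- a$value[a$instruction == "speed"][order(a$subject[a$instruction == "speed"])]
  acc <- a$value[a$instruction == "accuracy"][order(a$subject[a$instruction == "accuracy"])]
  contrast <- mean(spd - acc)
  b_ins <- fit$coefficients$estimate[fit$coefficients$term ==
                                       "instructionspeed"]
  expect_equal(b_ins, contrast, tolerance = 1e-9)
})

test_that("REML variance estimates are unbiased over repeated simulation", {
  n_sim <- 1000
  s2 <- su2 <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    tab <- simulate_scores(score_sim_config(), seed = 70000 + i)
    fit <- fit_lmm(tab, model_spec("value"))
    s2[i] <- fit$sd_resid^2
    su2[i] <- fit$sd_intercept^2
  }
  expect_lt(abs(mean(s2) / 20.9^2 - 1), 0.02)
  expect_lt(abs(mean(su2) / 17.22^2 - 1), 0.05)
})

test_that("the log-transform flag fits on the natural-log scale", {
  cfg <- score_sim_config(betas = c(5.54, 0.25, -0.33, 0.30),
                          sd_subject = 0.26, sd_resid = 0.206,
                          log_response = TRUE)
  tab <- simulate_scores(cfg, seed = 21)
  fit <- fit_lmm(tab, model_spec("value", log_transform = TRUE))
  manual <- tab
  manual$value <- log(manual$value)
  fit_manual <- fit_lmm(manual, model_spec("value"))
  expect_equal(fit$coefficients, fit_manual$coefficients)
  # and the standard spec set flags exactly the four log-scale scores
  specs <- tmt_model_specs()
  expect_equal(names(which(vapply(specs, `[[`, logical(1),
                                  "log_transform"))),
               c("n_fixations", "n_searching", "mean_eye_hand_span",
                 "scanpath_length"))
})

test_that("missing responses are dropped case-wise and reported", {
  tab <- simulate_scores(score_sim_config(), seed = 30)
  tab$value[c(3, 10, 40)] <- NA
  fit <- fit_lmm(tab, model_spec("value"))
  expect_equal(fit$n_obs, nrow(tab) - 3)
  expect_equal(fit$n_groups, 58)
})

test_that("singular designs raise an explicit rank error", {
  tab <- simulate_scores(score_sim_config(n_subjects = 6), seed = 31)
  tab <- tab[!(tab$test_type == "B" & tab$instruction == "speed"), ]
  expect_error(fit_lmm(tab, model_spec("value")), "rank|singular")
  expect_error(fit_lmm(tab[0, ], model_spec("value")), "at least 2")
})

test_that("Wald p-values behave at the reference points", {
  tab <- simulate_scores(score_sim_config(), seed = 33)
  fit <- fit_lmm(tab, model_spec("value"))
  pv <- wald_pvalues(fit)
  expect_equal(pv$df[1], 232 - 4 - 57)
  # t = 0 -> p = 1 ; |t| = 1.96 at large df -> ~0.05
  fake <- fit
  fake$coefficients$t <- c(0, 1.96, -1.96, 5.921)
  pv2 <- wald_pvalues(fake)
  expect_equal(pv2$p[1], 1)
  expect_lt(abs(pv2$p[2] - 0.05), 0.005)
  expect_lt(pv2$p[4], 0.001)
  # Satterthwaite df agrees with lmerTest within a few percent
  m <- lmerTest::lmer(value ~ test_type * instruction + (1 | subject),
                      data = tab, REML = TRUE)
  df_ref <- coef(summary(m))[, "df"]
  pv_sat <- wald_pvalues(fit, "satterthwaite")
  expect_equal(pv_sat$df, unname(df_ref), tolerance = 0.05)
})

test_that("the report covers every score with Table-style columns", {
  tab <- simulate_score_table(n_subjects = 12, seed = 2)
  rep <- lmm_report(tab)
  expect_equal(sort(unique(rep$dv)), sort(names(tmt_model_specs())))
  expect_equal(nrow(rep), 8 * 4)
  expect_true(all(rep$ci_lo < rep$estimate & rep$estimate < rep$ci_hi))
  expect_true(all(rep$n_groups == 12))
  fits <- attr(rep, "fits")
  expect_s3_class(fits$trial_duration, "lmm_fit")
})
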