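test_that("embedded chain estimation is the transition-count ratio", {
  tr <- dplyr::bind_rows(
    single_edge_traj(rep(1, 30)),
    dplyr::mutate(single_edge_traj(rep(1, 70)), stroke_state = 7L,
                  patient_id = sprintf("q%04d", 1:70))
  )
  emb <- estimate_embedded(tr)
  expect_equal(emb$p[emb$from == 1 & emb$to == 6], 0.3)
  expect_equal(emb$p[emb$from == 1 & emb$to == 7], 0.7)
  expect_equal(sum(emb$n), 100)

  single <- single_edge_traj(rep(1, 5))
  emb1 <- estimate_embedded(single)
  expect_equal(emb1$p[emb1$from == 1 & emb1$to == 6], 1)
  expect_error(estimate_embedded(single[0, ]), "no observed")
})

test_that("embedded estimates recover simulated probabilities within 3 binomial SE", {
  cfg <- scenario_config(seed = 41, n_patients = 5000)
  tr <- simulate_trajectories(cfg)
  emb <- estimate_embedded(tr)
  truth <- default_true_model()$edges
  for (k in seq_len(nrow(truth))) {
    row <- emb[emb$from == truth$from[k] & emb$to == truth$to[k], ]
    n_out <- sum(emb$n[emb$from == truth$from[k]])
    se <- sqrt(truth$p[k] * (1 - truth$p[k]) / n_out)
    expect_lt(abs(row$p - truth$p[k]), 3 * se + 1e-12)
  }
})

test_that("single-edge Weibull fit matches the AFT oracle (survreg)", {
  skip_if_not_installed("survival")
  withr::with_seed(13, {
    n <- 800
    z <- rbinom(n, 1, 0.5)
    d <- rweibull(n, shape = 1.4, scale = 2.5 * exp(-0.6 * z / 1.4))
    cens <- runif(n, 0, 6)
    time <- pmin(d, cens)
    status <- d <= cens
  })
  tr <- single_edge_traj(time, status, covariates = tibble::tibble(x = z))
  fit <- fit_smp(tr, covariate_map = tibble::tibble(from = 1L, to = 6L,
                                                    covariate = "x"))
  sr <- survival::survreg(survival::Surv(time, status) ~ z, dist = "weibull")
  shape <- 1 / sr$scale
  expect_equal(fit$params$v[1], shape, tolerance = 1e-3)
  expect_equal(fit$params$sigma[1], exp(unname(coef(sr)[1])), tolerance = 1e-3)
  expect_equal(fit$coef$estimate[1], -unname(coef(sr)[2]) * shape,
               tolerance = 1e-3)
  # Wald p agrees with the score-free normal approximation route
  expect_equal(fit$coef$p_value[1],
               wald_test(fit$coef$estimate[1], fit$coef$std_error[1])$p_value)
})

test_that("exponential data recover the closed-form MLE and rate ratio", {
  withr::with_seed(17, {
    n <- 5000
    d0 <- rexp(n / 2, rate = 0.5)   # z = 0, mean 2
    d1 <- rexp(n / 2, rate = 1.0)   # z = 1, mean 1
  })
  tr <- single_edge_traj(c(d0, d1),
                         covariates = tibble::tibble(x = rep(c(0, 1),
                                                             each = n / 2)))
  fit <- fit_smp(tr, covariate_map = tibble::tibble(from = 1L, to = 6L,
                                                    covariate = "x"))
  # sigma-hat close to the exponential MLE (mean duration of the base group)
  expect_equal(fit$params$sigma[1], mean(d0), tolerance = 0.05)
  expect_lt(abs(fit$params$v[1] - 1), 3 * fit$params$v_se[1])
  # beta-hat close to the closed-form log rate ratio
  rr_oracle <- log((length(d1) / sum(d1)) / (length(d0) / sum(d0)))
  expect_lt(abs(fit$coef$estimate[1] - rr_oracle),
            3 * fit$coef$std_error[1])
})

test_that("MLE on eight listed durations agrees with a brute-force grid search", {
  d <- c(0.5, 1.2, 2.3, 0.8, 1.7, 3.1, 0.4, 2.0)
  fit <- fit_smp(single_edge_traj(d))
  nll <- function(sigma, v) {
    -sum(log(sojourn_density(d, sigma, v)))
  }
  # two-stage grid: coarse, then 1e-3 resolution around the coarse optimum
  coarse <- expand.grid(sigma = seq(0.5, 4, by = 0.05),
                        v = seq(0.3, 4, by = 0.05))
  coarse$nll <- mapply(nll, coarse$sigma, coarse$v)
  c0 <- coarse[which.min(coarse$nll), ]
  fine <- expand.grid(sigma = seq(c0$sigma - 0.06, c0$sigma + 0.06, by = 1e-3),
                      v = seq(c0$v - 0.06, c0$v + 0.06, by = 1e-3))
  fine$nll <- mapply(nll, fine$sigma, fine$v)
  f0 <- fine[which.min(fine$nll), ]
  expect_equal(fit$params$sigma[1], f0$sigma, tolerance = 1e-3)
  expect_equal(fit$params$v[1], f0$v, tolerance = 1e-3)
})

test_that("Wald test follows the chi-square(1) tail", {
  expect_equal(wald_test(0, 1)$p_value, 1)
  expect_equal(wald_test(1.96, 1)$p_value, 0.05, tolerance = 1e-3)
  wt <- wald_test(0.5, 0.1)
  expect_equal(wt$statistic, 25)
  expect_equal(wt$p_value, 2 * pnorm(5, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(wald_test(1, 0), "positive")
})

test_that("the score vanishes at the reported optimum", {
  cfg <- scenario_config(seed = 43, n_patients = 1500)
  tr <- simulate_trajectories(cfg)
  fit <- fit_smp(tr, covariate_map = c("gender", "temperature"))
  expect_lt(fit$max_grad, 1e-4)
  expect_true(fit$converged)
})

test_that("estimates are invariant to row order and patient relabeling", {
  cfg <- scenario_config(seed = 44, n_patients = 600)
  tr <- simulate_trajectories(cfg)
  fit1 <- fit_smp(tr, covariate_map = "gender")
  tr2 <- withr::with_seed(9, tr[sample(nrow(tr)), ])
  tr2$patient_id <- paste0("relabel_", seq_len(nrow(tr2)))
  fit2 <- fit_smp(tr2, covariate_map = "gender")
  expect_identical(fit1$params$sigma, fit2$params$sigma)
  expect_identical(fit1$params$v, fit2$params$v)
  expect_identical(fit1$coef$estimate, fit2$coef$estimate)
  expect_identical(fit1$loglik, fit2$loglik)
})

test_that("administrative censoring does not bias the scale estimates", {
  # same generating model, follow-up shortened to raise censoring to ~30%
  # in the stroke layer; scale estimates must stay within 3 SE of truth
  cfg <- scenario_config(seed = 45, n_patients = 4000,
                         model = null_true_model(),
                         entry_start = as.Date("2002-01-01"),
                         entry_end = as.Date("2008-12-31"))
  tr <- simulate_trajectories(cfg)
  expect_gt(mean(tr$censored), 0.25)
  fit <- fit_smp(tr)
  truth <- null_true_model()$edges
  cmp <- dplyr::inner_join(fit$params, truth, by = c("from", "to"),
                           suffix = c("", "_t"))
  expect_true(all(abs(cmp$sigma - cmp$sigma_t) < 3 * cmp$sigma_se))
})
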