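test_that("exponential limit (v = 1) matches closed forms to machine precision", {
  sigma <- 2.3
  t <- c(0.1, 0.5, 1, 2.7, 10)
  expect_equal(sojourn_hazard(t, sigma, 1), rep(1 / sigma, 5), tolerance = 1e-12)
  expect_equal(sojourn_survival(t, sigma, 1), exp(-t / sigma), tolerance = 1e-12)
  expect_equal(sojourn_density(t, sigma, 1), exp(-t / sigma) / sigma,
               tolerance = 1e-12)
  mom <- sojourn_moments(sigma, 1)
  expect_equal(mom$mean, sigma, tolerance = 1e-12)
  expect_equal(mom$sd, sigma, tolerance = 1e-12)
})

test_that("hazard matches simple closed-form cases and boundary conventions", {
  expect_equal(sojourn_hazard(5, sigma = 2, v = 1), 0.5)
  expect_equal(sojourn_hazard(1, sigma = 1, v = 2), 2.0)
  # t = 0 conventions by shape
  expect_equal(sojourn_hazard(0, 2, 2), 0)
  expect_equal(sojourn_hazard(0, 2, 1), 0.5)
  expect_identical(sojourn_hazard(0, 2, 0.7), Inf)
  expect_error(sojourn_hazard(-1, 2, 1), "nonnegative")
  expect_error(sojourn_hazard(1, -2, 1), "positive")
})

test_that("hazard agrees with the finite-difference of -log S", {
  for (par in list(c(2.5, 1.7, 0.8), c(1.2, 0.9, 1.5), c(4, 2.2, 3))) {
    sigma <- par[1]; v <- par[2]; t <- par[3]
    h <- 1e-6
    oracle <- -(log(sojourn_survival(t + h, sigma, v)) -
                  log(sojourn_survival(t - h, sigma, v))) / (2 * h)
    expect_equal(sojourn_hazard(t, sigma, v), oracle, tolerance = 1e-7)
  }
})

test_that("survival agrees with one minus the quadrature of the density", {
  for (par in list(c(3, 0.8, 2), c(2, 1.5, 1.3), c(1, 2.5, 0.6))) {
    sigma <- par[1]; v <- par[2]; t <- par[3]
    q <- stats::integrate(function(u) sojourn_density(u, sigma, v), 0, t,
                          rel.tol = 1e-10)
    expect_equal(sojourn_survival(t, sigma, v), 1 - q$value, tolerance = 1e-7)
    expect_equal(sojourn_survival(0, sigma, v), 1)
  }
})

test_that("density is hazard times survival, matches dF/dt and normalizes", {
  sigma <- 2; v <- 1.5; t <- 1.3
  h <- 1e-5
  cdf <- function(u) 1 - sojourn_survival(u, sigma, v)
  expect_equal(sojourn_density(t, sigma, v), (cdf(t + h) - cdf(t - h)) / (2 * h),
               tolerance = 1e-7)
  for (par in list(c(1, 1), c(2, 1.5), c(3, 0.8), c(0.5, 2.5))) {
    q <- stats::integrate(function(u) sojourn_density(u, par[1], par[2]),
                          0, 200 * par[1], rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
})

test_that("moments match analytics and Monte-Carlo oracles", {
  mom <- sojourn_moments(1, 2)
  expect_equal(mom$mean, sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(mom$sd, sqrt(1 - pi / 4), tolerance = 1e-12)
  withr::with_seed(99, {
    for (par in list(c(1, 2), c(3, 0.7))) {
      draws <- stats::rweibull(1e6, shape = par[2], scale = par[1])
      mom <- sojourn_moments(par[1], par[2])
      se_mean <- stats::sd(draws) / sqrt(length(draws))
      expect_lt(abs(mom$mean - mean(draws)), 3 * se_mean)
      expect_lt(abs(mom$sd - stats::sd(draws)) / mom$sd, 0.01)
    }
  })
})

test_that("covariate hazard is proportional and reduces to baseline at z = 0", {
  expect_equal(covariate_hazard(1.4, 2, 1.3, beta = c(0.5, -0.2), z = c(0, 0)),
               sojourn_hazard(1.4, 2, 1.3))
  # hazard ratio between two covariate vectors is constant over t
  tg <- seq(0.2, 8, length.out = 40)
  r <- vapply(tg, function(t) {
    covariate_hazard(t, 2, 1.3, beta = 0.7, z = 1) /
      covariate_hazard(t, 2, 1.3, beta = 0.7, z = 0)
  }, numeric(1))
  expect_equal(r, rep(exp(0.7), 40), tolerance = 1e-10)
  # reported effect sizes: multiplier exp(beta) at every t
  expect_equal(round(covariate_hazard(2, 3, 1, beta = 0.214, z = 1) /
                       sojourn_hazard(2, 3, 1), 2), 1.24)
  expect_equal(round(covariate_hazard(2, 3, 1, beta = -2.538, z = 1) /
                       sojourn_hazard(2, 3, 1), 2), 0.08)
  expect_error(covariate_hazard(1, 2, 1, beta = c(1, 2), z = 1), "length")
})

test_that("relative risk is exp(beta) and round-trips through log", {
  expect_equal(round(relative_risk(1.364), 2), 3.91)
  expect_equal(round(relative_risk(-0.822), 2), 0.44)
  expect_equal(relative_risk(0), 1)
  x <- c(0.01, 0.5, 1, 2.7, 40)
  expect_equal(relative_risk(log(x)), x, tolerance = 1e-12)
})

test_that("transition cdf and kernel honour boundary and limit behaviour", {
  m <- toy_model(p16 = 0.4, sigma16 = 2, v16 = 1)
  at0 <- transition_cdf(m, 1, 6, 0)
  expect_equal(at0$cdf, 0)
  expect_equal(at0$q, 0)
  far <- transition_cdf(m, 1, 6, 1e4)
  expect_equal(far$cdf, 1, tolerance = 1e-9)
  expect_equal(far$q, 0.4, tolerance = 1e-9)
  # exponential closed form: Q(2) = 0.4 * (1 - exp(-1))
  expect_equal(transition_cdf(m, 1, 6, 2)$q, 0.4 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_error(transition_cdf(m, 1, 8, 1), "not in the model")
})

test_that("kernels of a state sum to one in the limit", {
  m <- toy_model()
  for (i in 1:7) {
    qs <- sum(vapply(which(m$edges$from == i), function(k) {
      transition_cdf(m, i, m$edges$to[k], 1e4)$q
    }, numeric(1)))
    expect_equal(qs, 1, tolerance = 1e-6)
  }
})

test_that("state waiting survival mixes edge survivals over the chain", {
  m <- toy_model()
  expect_equal(state_waiting_survival(m, 3, 0), 1)
  # two edges with p = (0.3, 0.7), both unit exponentials, collapse
  e <- smp_edges()
  e$p <- rep(c(0.3, 0.7, 0.3, 0.7, 0.3, 0.7, 0.3, 0.7, 0.3, 0.7, 0.5, 0.5, 0.5, 0.5))
  e$sigma <- 1; e$v <- 1
  m2 <- smp_model(e)
  expect_equal(state_waiting_survival(m2, 1, 1), exp(-1), tolerance = 1e-12)
  # absorbing convention
  expect_equal(state_waiting_survival(m2, 8, c(0, 5, 50)), rep(1, 3))
  expect_error(state_waiting_survival(m2, 99, 1), "unknown")
})

test_that("semi-Markov hazard composes Eqs for kernel, density and waiting survival", {
  # single-edge, exponential: constant 1/sigma
  m <- toy_model(p16 = 1, sigma16 = 3, v16 = 1)
  # make state 1 single-edge by zeroing 1->7
  expect_equal(smp_hazard(m, 1, 6, c(0.5, 2, 7)),
               rep(1 / 3, 3) *
                 sojourn_survival(c(0.5, 2, 7), 3, 1) /
                 state_waiting_survival(m, 1, c(0.5, 2, 7)) * 1,
               tolerance = 1e-12)
  # direct composition oracle on a mixed state
  e <- smp_edges()
  e$p <- 0.5; e$p[e$from == 1 & e$to == 6] <- 0.4
  e$p[e$from == 1 & e$to == 7] <- 0.6
  e$sigma <- 2; e$v <- 1
  e$sigma[e$from == 1 & e$to == 6] <- 1
  m3 <- smp_model(e)
  t <- 1
  s1 <- 0.4 * exp(-1) + 0.6 * exp(-0.5)
  oracle <- 0.4 * exp(-1) * 1 / s1
  expect_equal(smp_hazard(m3, 1, 6, t), oracle, tolerance = 1e-12)
  # off-structure pair has zero hazard
  expect_equal(smp_hazard(m3, 1, 8, t), 0)
  expect_error(smp_hazard(m3, 8, 9, 1), "absorbing")
})

test_that("hazard matrix rows sum to zero by the diagonal convention", {
  m <- toy_model()
  lam <- smp_hazard_matrix(m, 1.7)
  expect_equal(unname(rowSums(lam)), rep(0, 9), tolerance = 1e-12)
  expect_true(all(lam[8:9, ] == 0))
})

test_that("waiting-survival underflow raises an explicit evaluation error", {
  m <- toy_model()
  expect_error(smp_hazard(m, 1, 6, 1e6), "support")
})
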