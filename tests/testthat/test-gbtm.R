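# Brute-force mixture log-likelihood: explicit loops over participants,
# groups and observations; independent of the package's vectorised path.
brute_loglik <- function(pi, beta, sigma, series) {
  ids <- unique(series$participant_id)
  total <- 0
  for (id in ids) {
    rows <- series[series$participant_id == id, ]
    contrib <- 0
    for (j in seq_along(pi)) {
      prod_j <- pi[j]
      for (r in seq_len(nrow(rows))) {
        mu <- sum(beta[, j] * rows$t[r]^(seq_len(nrow(beta)) - 1))
        prod_j <- prod_j * dnorm(rows$speed[r], mu, sigma)
      }
      contrib <- contrib + prod_j
    }
    total <- total + log(contrib)
  }
  total
}

test_that("log-likelihood matches closed forms and a brute-force oracle", {
  # single standard-normal observation at the group mean: log phi(0)
  m <- manual_gbtm(pi = 1, beta = matrix(2), sigma = 1, t_max = 0)
  ser <- make_series(A = list(t = 0, speed = 2))
  expect_equal(gbtm_loglik(m, ser), -0.5 * log(2 * pi), tolerance = 1e-12)

  # a degenerate mixture weight reduces to the single-group likelihood
  set.seed(31)
  ser2 <- make_series(
    A = list(t = 0:8, speed = rnorm(9, 2, 0.5)),
    B = list(t = c(0, 3, 7), speed = rnorm(3, 2, 0.5))
  )
  m1 <- manual_gbtm(pi = 1, beta = matrix(2), sigma = 0.5)
  m2 <- manual_gbtm(pi = c(1, 0), beta = matrix(c(2, 99), 1, 2), sigma = 0.5)
  m2$pi <- c(1 - 1e-300, 1e-300) # log(0) guard: numerically degenerate
  expect_equal(gbtm_loglik(m2, ser2), gbtm_loglik(m1, ser2), tolerance = 1e-9)

  # random small instances against the loop-based oracle
  for (seed in 1:5) {
    set.seed(seed)
    beta <- matrix(rnorm(4, 3, 1), 2, 2) # order-1 polynomials, 2 groups
    piv <- c(0.3, 0.7)
    sigma <- 0.8
    ser3 <- make_series(
      A = list(t = 0:3, speed = rnorm(4, 3, 1)),
      B = list(t = c(1, 4), speed = rnorm(2, 3, 1)),
      C = list(t = 7, speed = rnorm(1, 3, 1))
    )
    m3 <- manual_gbtm(pi = piv, beta = beta, sigma = sigma)
    expect_equal(gbtm_loglik(m3, ser3),
                 brute_loglik(piv, beta, sigma, ser3), tolerance = 1e-9)
  }

  expect_error(gbtm_loglik(manual_gbtm(1, matrix(2), sigma = 0), ser),
               class = "trajsat_config_error")
})

test_that("K = 1 EM equals ordinary polynomial least squares", {
  set.seed(32)
  d <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:40), t = 0:8) |>
    dplyr::mutate(speed = 3 + 0.2 * t - 0.01 * t^2 + rnorm(dplyr::n(), 0, 0.4))
  fit <- gbtm_fit(d, k = 1, order = 2, n_starts = 1)
  ls <- unname(coef(lm(speed ~ t + I(t^2), data = d)))
  expect_equal(unname(fit$beta[, 1]), ls, tolerance = 1e-6)
  expect_identical(fit$pi, 1)
  # and the shared sigma is the ML (1/N) residual SD
  expect_equal(fit$sigma,
               sqrt(mean(residuals(lm(speed ~ t + I(t^2), data = d))^2)),
               tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing and recovers planted groups", {
  cfg <- synth_config(
    n_participants = 200, true_pi = c(0.5, 0.5), true_beta = list(2, 6),
    sigma = 0.3, visit_missing_rate = 0, seed = 33
  )
  ser <- build_series(compute_speed(clean_visits(generate_cohort(cfg)$visits)))
  fit <- gbtm_fit(ser, k = 2, order = 0, n_starts = 2)
  expect_true(all(diff(fit$loglik_history) >= -1e-9))
  expect_true(fit$converged)
  expect_lt(max(abs(unname(fit$beta[1, ]) - c(2, 6))), 0.1)
  expect_lt(max(abs(fit$pi - 0.5)), 0.05)
  # groups come out in canonical ascending-intercept order
  expect_true(fit$beta[1, 1] < fit$beta[1, 2])
  # likelihood is invariant to relabelling: swapped parameters score the same
  swapped <- fit
  swapped$pi <- rev(fit$pi)
  swapped$beta <- fit$beta[, 2:1, drop = FALSE]
  expect_equal(gbtm_loglik(swapped, ser), gbtm_loglik(fit, ser),
               tolerance = 1e-9)
  expect_error(gbtm_fit(ser, k = 500), class = "trajsat_config_error")
})

test_that("BIC follows the trajectory-modelling convention", {
  m <- manual_gbtm(pi = 1, beta = matrix(2), sigma = 1)
  m$loglik <- -1000
  m$n_params <- 10L
  m$n_participants <- 2138L
  m$n_obs <- 12787L
  expect_equal(gbtm_bic(m), -1000 - 5 * log(2138), tolerance = 1e-12)
  expect_equal(round(gbtm_bic(m), 2), -1038.34)
  # observation-count alternative sits behind the flag
  expect_equal(gbtm_bic(m, "observations"), -1000 - 5 * log(12787),
               tolerance = 1e-12)
  # penalty-free limit
  m$n_params <- 0L
  expect_identical(gbtm_bic(m), m$loglik)
  m$n_participants <- 1L
  expect_error(gbtm_bic(m), class = "trajsat_config_error")
})

test_that("model selection picks the larger BIC and a single candidate is returned as-is", {
  cfg <- synth_config(
    n_participants = 150, true_pi = c(0.5, 0.5), true_beta = list(2, 6),
    sigma = 0.3, visit_missing_rate = 0, seed = 35
  )
  ser <- build_series(compute_speed(clean_visits(generate_cohort(cfg)$visits)))
  sel <- gbtm_select(ser, k_range = 1:3, order = 0, n_starts = 2, tol = 1e-7)
  expect_identical(sel$best$K, sel$table$K[which.max(sel$table$bic)])
  expect_identical(sel$best$K, 2L)

  only1 <- gbtm_select(ser, k_range = 1, order = 0, n_starts = 1)
  expect_identical(only1$best$K, 1L)
  expect_identical(nrow(only1$table), 1L)
})

test_that("posterior assignment obeys Bayes' rule symmetries", {
  # K = 1: certainty
  ser <- make_series(A = list(t = 0:2, speed = c(2, 2.2, 1.9)),
                     B = list(t = 0:2, speed = c(2.1, 2, 2)))
  m1 <- manual_gbtm(1, matrix(2), 0.5, t_max = 2)
  p1 <- gbtm_posteriors(m1, ser)
  expect_identical(p1$posterior$prob_group1, c(1, 1))

  # equidistant point between symmetric groups: exactly (0.5, 0.5)
  m2 <- manual_gbtm(c(0.5, 0.5), matrix(c(1, 3), 1, 2), 1, t_max = 0)
  pmid <- gbtm_posteriors(m2, make_series(A = list(t = 0, speed = 2)))
  expect_equal(unname(unlist(pmid$posterior[1, c("prob_group1", "prob_group2")])),
               c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(pmid$posterior$group, 1L) # tie broken to the lowest index

  # rows always sum to one
  set.seed(36)
  ser3 <- make_series(
    A = list(t = 0:8, speed = rnorm(9, 3, 1)),
    B = list(t = c(0, 4, 8), speed = rnorm(3, 5, 1)),
    C = list(t = 2, speed = rnorm(1, 4, 1))
  )
  m3 <- manual_gbtm(c(0.4, 0.6), matrix(c(2, 0.1, 5, -0.1), 2, 2), 0.7)
  p3 <- gbtm_posteriors(m3, ser3)
  sums <- p3$posterior$prob_group1 + p3$posterior$prob_group2
  expect_equal(sums, rep(1, 3), tolerance = 1e-10)
  expect_identical(p3$posterior$group,
                   max.col(as.matrix(p3$posterior[c("prob_group1", "prob_group2")]),
                           ties.method = "first"))
})
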