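# Build a small labelled cohort end to end for panel tests.
panel_fixture <- function(n = 60, seed = 51, missing = 0) {
  cfg <- synth_config(n_participants = n, visit_missing_rate = missing,
                      seed = seed)
  coh <- generate_cohort(cfg)
  cl <- clean_visits(coh$visits)
  labels <- dplyr::transmute(coh$truth, participant_id,
                             satisficer = true_satisficer)
  list(cohort = coh, clean = cl, labels = labels)
}

test_that("the panel is long-format with fixed reference codings", {
  fx <- panel_fixture(n = 2, missing = 0)
  panel <- build_panel(fx$labels, fx$clean, fx$cohort$participants)
  expect_identical(nrow(panel), 18L) # 2 participants x 9 visits
  # outcome constant within participant
  per <- dplyr::summarise(dplyr::group_by(panel, participant_id),
                          k = dplyr::n_distinct(satisficer))
  expect_true(all(per$k == 1))
  expect_identical(levels(panel$race), c("white", "black", "other"))
  expect_identical(levels(panel$education), c("college", "lt_college", "gt_college"))
  expect_identical(levels(panel$hiv), c("neg", "pos"))
  expect_identical(levels(panel$sexual_activity), c("none", "one", "multiple"))
  # age is centred and scaled per 10 years
  p <- fx$cohort$participants
  expect_equal(panel$baseline_age_per10,
               (p$baseline_age[match(panel$participant_id, p$participant_id)] -
                  mean(p$baseline_age)) / 10,
               tolerance = 1e-12)

  # dummy coding against a hand-built design matrix on a 3-row fixture
  mini <- tibble::tibble(
    satisficer = c(0L, 1L, 1L),
    race = factor(c("white", "black", "other"),
                  levels = c("white", "black", "other"))
  )
  mm <- model.matrix(~race, mini)
  hand <- cbind(`(Intercept)` = c(1, 1, 1), raceblack = c(0, 1, 0),
                raceother = c(0, 0, 1))
  expect_equal(unname(mm), unname(hand), ignore_attr = TRUE)

  # a labelled participant with no visits is an error
  orphan <- dplyr::bind_rows(fx$labels,
                             tibble::tibble(participant_id = "GHOST",
                                            satisficer = TRUE))
  expect_error(build_panel(orphan, fx$clean, fx$cohort$participants),
               "GHOST", class = "trajsat_data_error")
})

test_that("with one visit per cluster the GEE equals ordinary logistic regression", {
  set.seed(52)
  n <- 400
  d <- tibble::tibble(
    participant_id = sprintf("P%04d", 1:n),
    x = rbinom(n, 1, 0.5)
  )
  d$satisficer <- rbinom(n, 1, plogis(-0.5 + 0.9 * d$x))
  fit <- gee_logistic(satisficer ~ x, d)
  ml <- glm(satisficer ~ x, binomial, d)
  expect_equal(unname(fit$coefficients), unname(coef(ml)), tolerance = 1e-6)

  # ... and its OR equals the crude 2x2 OR
  a <- sum(d$x == 1 & d$satisficer == 1); b <- sum(d$x == 0 & d$satisficer == 1)
  cc <- sum(d$x == 1 & d$satisficer == 0); dd <- sum(d$x == 0 & d$satisficer == 0)
  crude <- or_from_2x2(a, b, cc, dd)
  expect_equal(exp(unname(fit$coefficients["x"])), crude$or, tolerance = 1e-4)

  # robust SEs agree with the reference sandwich estimator (HC0, clustered)
  skip_if_not_installed("sandwich")
  vc <- sandwich::vcovCL(ml, cluster = d$participant_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(sqrt(diag(fit$robust_vcov))), unname(sqrt(diag(vc))),
               tolerance = 1e-6)
})

test_that("a covariate independent of the outcome estimates a null log-OR", {
  set.seed(53)
  n <- 5000
  d <- tibble::tibble(
    participant_id = sprintf("P%05d", 1:n),
    x = rbinom(n, 1, 0.5),
    satisficer = rbinom(n, 1, 0.3)
  )
  fit <- gee_logistic(satisficer ~ x, d)
  lor <- unname(fit$coefficients["x"])
  se <- sqrt(fit$robust_vcov["x", "x"])
  expect_lt(abs(lor), 0.1)
  expect_true(lor - 1.96 * se < 0 && lor + 1.96 * se > 0) # CI covers OR = 1
})

test_that("repeated-measures fits recover a planted cluster-level effect", {
  set.seed(54)
  n <- 800
  ids <- sprintf("P%04d", 1:n)
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  panel <- tidyr::expand_grid(i = 1:n, t = 0:8) |>
    dplyr::mutate(participant_id = ids[i], x = x[i], satisficer = y[i])
  fit <- gee_logistic(satisficer ~ x, panel)
  expect_equal(unname(fit$coefficients["x"]), 0.8, tolerance = 0.25)
  expect_gt(fit$alpha, 0.9) # outcome constant within cluster
})

test_that("odds-ratio tables carry references, CIs and diagnostics", {
  fx <- panel_fixture(n = 250, seed = 55)
  panel <- build_panel(fx$labels, fx$clean, fx$cohort$participants)
  ors <- fit_repeated_logistic(panel, mode = "both")
  expect_s3_class(ors, "or_table")
  expect_setequal(unique(ors$model), c("univariate", "multivariate"))
  refs <- dplyr::filter(ors, reference)
  expect_true(all(refs$or == 1))
  est <- dplyr::filter(ors, !reference)
  expect_true(all(est$conf.low <= est$or & est$or <= est$conf.high))
  diag <- glance(ors)
  expect_true(all(diag$converged))
  # univariate age model appears in both modes with identical estimates
  uni <- dplyr::filter(ors, model == "univariate",
                       variable == "baseline_age_per10")
  expect_identical(nrow(uni), 1L)
  expect_error(
    fit_repeated_logistic(panel[panel$race != "other", ]),
    "empty level", class = "trajsat_data_error"
  )
})

test_that("crude 2x2 odds ratios follow the Woolf formulas", {
  sym <- or_from_2x2(1, 1, 1, 1)
  expect_identical(sym$or, 1)
  # cohort-table race counts: satisficer black/white vs nonsatisficer
  crude <- or_from_2x2(194, 268, 339, 1073)
  expect_equal(crude$or, (194 * 1073) / (268 * 339), tolerance = 1e-12)
  expect_equal(round(crude$or, 2), 2.29)
  expect_equal(crude$se, sqrt(1 / 194 + 1 / 268 + 1 / 339 + 1 / 1073),
               tolerance = 1e-12)
  # doubling every cell preserves the OR and shrinks the CI
  doubled <- or_from_2x2(388, 536, 678, 2146)
  expect_equal(doubled$or, crude$or, tolerance = 1e-12)
  expect_lt(doubled$conf.high - doubled$conf.low,
            crude$conf.high - crude$conf.low)
  # zero cells get the 0.5 continuity correction rather than Inf
  zc <- or_from_2x2(0, 5, 5, 5)
  expect_equal(zc$or, (0.5 * 5.5) / (5.5 * 5.5), tolerance = 1e-12)
  expect_error(or_from_2x2(-1, 1, 1, 1), class = "trajsat_data_error")
})

test_that("the descriptive table reports counts, column percents and age IQR", {
  # build a cohort whose education margins match a known report layout
  participants <- tibble::tibble(
    participant_id = sprintf("P%04d", 1:2138),
    baseline_age = rep(51, 2138),
    race = factor("white", levels = c("white", "black", "other")),
    education = factor(
      c(rep(c("lt_college", "college", "gt_college"), c(145, 240, 158)),
        rep(c("lt_college", "college", "gt_college"), c(238, 756, 601))),
      levels = c("lt_college", "college", "gt_college")
    ),
    hiv = factor("neg", levels = c("neg", "pos"))
  )
  labels <- tibble::tibble(
    participant_id = participants$participant_id,
    satisficer = rep(c(TRUE, FALSE), c(543, 1595))
  )
  t1 <- table1_summary(labels, participants)
  edu <- dplyr::filter(t1$categorical, variable == "education")
  sat_college_up <- sum(edu$n[edu$status == "satisficer" &
                                edu$level %in% c("college", "gt_college")])
  non_college_up <- sum(edu$n[edu$status == "nonsatisficer" &
                                edu$level %in% c("college", "gt_college")])
  expect_identical(sat_college_up, 398L)
  expect_identical(non_college_up, 1357L)
  expect_identical(round_half_up(100 * sat_college_up / 543, 2), 73.30)
  expect_identical(round_half_up(100 * non_college_up / 1595, 2), 85.08)
  # column percents sum to 100 within each status
  tot <- edu |>
    dplyr::group_by(status) |>
    dplyr::summarise(p = sum(percent))
  expect_true(all(abs(tot$p - 100) < 0.05))
  # one-participant cohort: 100% in its own categories
  t1b <- table1_summary(labels[1, ], participants[1, ])
  expect_true(all(t1b$categorical$percent == 100))
  expect_identical(t1$age$median[t1$age$status == "total"], 51)
})
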