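#' Build the long-format panel for association models
#'
#' Joins satisficer labels to cleaned visit records and baseline covariates,
#' producing one row per retained participant-visit. Categorical codings use
#' fixed reference levels: race = white, education = college, HIV = negative,
#' sexual activity = none, drug use = none. Baseline age enters as
#' `(age - cohort mean) / 10` so its coefficient is per 10-year increase
#' (centering does not affect the age OR). Rows with a missing covariate are
#' dropped listwise with a message.
#'
#' @param labels A `satisficing_result` or a tibble with `participant_id` and
#'   logical `satisficer`.
#' @param visits Cleaned visit records (a `clean_result` or its `kept`
#'   tibble) carrying `sexual_activity` and `drug_use`.
#' @param participants Baseline covariates (`participant_id`, `baseline_age`,
#'   `race`, `education`, `hiv`).
#' @param visit_zero Visit number coded as time 0 (default 50).
#' @return Tibble of class `satisficing_panel` with columns
#'   `participant_id`, `t`, `satisficer` (0/1), `baseline_age_per10`, `race`,
#'   `education`, `hiv`, `sexual_activity`, `drug_use`.
#' @export
build_panel <- function(labels, visits, participants, visit_zero = 50) {
  if (inherits(labels, "satisficing_result")) labels <- labels$labels
  if (inherits(visits, "clean_result")) visits <- visits$kept
  lab <- tibble::as_tibble(labels)[c("participant_id", "satisficer")]
  orphans <- setdiff(lab$participant_id, visits$participant_id)
  if (length(orphans)) {
    stop_data(paste0("Labelled participants with no visit records: ",
                     paste(utils::head(orphans, 5), collapse = ", ")))
  }
  p <- tibble::as_tibble(participants)
  panel <- visits |>
    dplyr::select("participant_id", "visit",
                  dplyr::any_of(c("sexual_activity", "drug_use"))) |>
    dplyr::inner_join(lab, by = "participant_id") |>
    dplyr::inner_join(p, by = "participant_id") |>
    dplyr::mutate(
      t = as.integer(.data$visit - visit_zero),
      satisficer = as.integer(.data$satisficer),
      baseline_age_per10 = (.data$baseline_age - mean(p$baseline_age)) / 10,
      race = factor(.data$race, levels = c("white", "black", "other")),
      education = factor(.data$education,
                         levels = c("college", "lt_college", "gt_college")),
      hiv = factor(.data$hiv, levels = c("neg", "pos")),
      sexual_activity = factor(.data$sexual_activity,
                               levels = c("none", "one", "multiple")),
      drug_use = factor(.data$drug_use, levels = c("none", "one", "multiple"))
    ) |>
    dplyr::select("participant_id", "t", "satisficer", "baseline_age_per10",
                  "race", "education", "hiv", "sexual_activity", "drug_use") |>
    dplyr::arrange(.data$participant_id, .data$t)
  cc <- complete.cases(panel)
  if (any(!cc)) {
    inform(paste0("Dropping ", sum(!cc), " rows with missing covariates."))
    panel <- panel[cc, , drop = FALSE]
  }
  class(panel) <- c("satisficing_panel", class(panel))
  panel
}

#' GEE logistic regression with exchangeable working correlation
#'
#' Marginal logistic model for a binary outcome observed repeatedly within
#' participants, estimated by generalized estimating equations with an
#' exchangeable working correlation and robust (sandwich) standard errors
#' clustered by participant. The working correlation parameter is the usual
#' moment estimator from Pearson residuals, capped at 0.95 for stability
#' (outcomes constant within participant push it to 1; the cap leaves the
#' coefficient estimates consistent and the sandwich variance valid).
#'
#' @param formula Model formula, e.g. `satisficer ~ race`.
#' @param data Data frame containing the variables and `id`.
#' @param id Column name of the cluster identifier (default
#'   `"participant_id"`).
#' @param maxit,tol Fisher-scoring iteration cap and convergence tolerance on
#'   the coefficients.
#' @return List of class `trajsat_gee`: `coefficients`, `robust_vcov`,
#'   `alpha` (working correlation), `phi` (dispersion), `iterations`,
#'   `converged`, `n_clusters`, `n_obs`, `xlevels`, `formula`.
#' @export
gee_logistic <- function(formula, data, id = "participant_id",
                         maxit = 50, tol = 1e-10) {
  d2 <- as.data.frame(data)[unique(c(all.vars(formula), id))]
  d2 <- d2[complete.cases(d2), , drop = FALSE]
  mf <- stats::model.frame(formula, data = d2)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2) {
    stop_data("Outcome must have both classes.")
  }
  X <- model.matrix(attr(mf, "terms"), mf)
  cl <- factor(d2[[id]])
  cid <- as.integer(cl)
  n_clus <- nlevels(cl)
  sizes <- tabulate(cid, n_clus)
  p <- ncol(X)

  beta <- logistic_start(X, y)
  alpha <- 0
  phi <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-10)
    e <- (y - mu) / sqrt(v) # Pearson residuals
    N <- length(y)
    phi <- sum(e^2) / (N - p)
    s <- as.numeric(rowsum(e, cid))
    q <- as.numeric(rowsum(e^2, cid))
    denom <- sum(sizes * (sizes - 1)) / 2 - p
    alpha <- if (denom > 0) sum(s^2 - q) / 2 / (phi * denom) else 0
    alpha <- min(max(alpha, 0), 0.95)

    # exchangeable inverse applied in closed form, vectorised over clusters
    Z <- X * sqrt(v)
    u <- (y - mu) / sqrt(v)
    cfac <- alpha / (1 + (sizes - 1) * alpha) # per cluster
    S <- rowsum(Z, cid)                       # per-cluster column sums of Z
    usum <- as.numeric(rowsum(u, cid))
    M <- (crossprod(Z) - crossprod(S, cfac * S)) / (1 - alpha)
    score <- (crossprod(Z, u) - crossprod(S, cfac * usum)) / (1 - alpha)
    step <- solve(M, score)
    beta_new <- beta + drop(step)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  # sandwich variance at the solution
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  v <- pmax(mu * (1 - mu), 1e-10)
  Z <- X * sqrt(v)
  u <- (y - mu) / sqrt(v)
  cfac <- alpha / (1 + (sizes - 1) * alpha)
  S <- rowsum(Z, cid)
  usum <- as.numeric(rowsum(u, cid))
  M <- (crossprod(Z) - crossprod(S, cfac * S)) / (1 - alpha)
  G <- (rowsum(Z * u, cid) - (cfac * usum) * S) / (1 - alpha)
  Minv <- solve(M)
  vcov <- Minv %*% crossprod(G) %*% Minv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  if (!converged || max(abs(beta)) > 15) {
    warn("GEE fit did not converge cleanly (possible separation); inspect diagnostics.")
  }
  structure(
    list(coefficients = setNames(drop(beta), colnames(X)),
         robust_vcov = vcov, alpha = alpha, phi = phi, iterations = iter,
         converged = converged, n_clusters = n_clus, n_obs = length(y),
         formula = formula,
         xlevels = stats::.getXlevels(attr(mf, "terms"), mf)),
    class = "trajsat_gee"
  )
}

# IRLS logistic start values without the glm() formula overhead.
logistic_start <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
  b <- fit$coefficients
  b[is.na(b)] <- 0
  b
}

#' Odds-ratio tables from repeated-measures logistic models
#'
#' Fits GEE logistic models of satisficing on the panel covariates:
#' univariate (one covariate at a time), multivariate (all jointly), or both.
#' ORs are exponentiated coefficients; 95% CIs are Wald intervals on the
#' robust SE, `exp(b +/- 1.96 se)`; p-values are two-sided Wald. Reference
#' levels are included with OR 1 by construction.
#'
#' @param panel Output of [build_panel()].
#' @param covariates Covariate column names (default the full
#'   socio-demographic set).
#' @param mode `"both"` (default), `"univariate"` or `"multivariate"`.
#' @return A tibble of class `or_table`: `model`, `variable`, `level`,
#'   `reference` (logical), `estimate` (log OR), `std.error`, `or`,
#'   `conf.low`, `conf.high`, `p.value`; fit diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
fit_repeated_logistic <- function(panel,
                                  covariates = c("baseline_age_per10", "race",
                                                 "education", "hiv",
                                                 "sexual_activity", "drug_use"),
                                  mode = c("both", "univariate", "multivariate")) {
  mode <- match.arg(mode)
  for (cv in covariates) {
    if (is.factor(panel[[cv]])) {
      empty <- setdiff(levels(panel[[cv]]), unique(as.character(panel[[cv]])))
      if (length(empty)) {
        stop_data(paste0("Covariate `", cv, "` has empty level(s): ",
                         paste(empty, collapse = ", ")))
      }
    }
  }
  specs <- list()
  if (mode %in% c("univariate", "both")) {
    for (cv in covariates) specs[[paste0("univariate:", cv)]] <- cv
  }
  if (mode %in% c("multivariate", "both")) {
    specs[["multivariate"]] <- covariates
  }
  diags <- list()
  rows <- purrr::imap(specs, function(cvs, nm) {
    tag <- if (startsWith(nm, "univariate")) "univariate" else "multivariate"
    f <- as.formula(paste("satisficer ~", paste(cvs, collapse = " + ")))
    fit <- gee_logistic(f, panel)
    diags[[nm]] <<- tibble::tibble(
      model = nm, alpha = fit$alpha, iterations = fit$iterations,
      converged = fit$converged, n_clusters = fit$n_clusters,
      n_obs = fit$n_obs
    )
    or_rows(fit, panel, cvs, tag)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "diagnostics") <- dplyr::bind_rows(diags)
  class(out) <- c("or_table", class(out))
  out
}

or_rows <- function(fit, panel, covariates, tag) {
  b <- fit$coefficients
  se <- sqrt(diag(fit$robust_vcov))
  purrr::map_dfr(covariates, function(cv) {
    if (is.factor(panel[[cv]])) {
      levs <- levels(panel[[cv]])
      terms <- paste0(cv, levs[-1])
      est <- b[terms]
      s <- se[terms]
      tibble::tibble(
        model = tag, variable = cv, level = levs,
        reference = c(TRUE, rep(FALSE, length(levs) - 1)),
        estimate = c(0, unname(est)), std.error = c(NA, unname(s)),
        or = exp(c(0, unname(est))),
        conf.low = c(NA, exp(unname(est) - 1.96 * unname(s))),
        conf.high = c(NA, exp(unname(est) + 1.96 * unname(s))),
        p.value = c(NA, 2 * pnorm(-abs(unname(est) / unname(s))))
      )
    } else {
      tibble::tibble(
        model = tag, variable = cv, level = cv, reference = FALSE,
        estimate = unname(b[cv]), std.error = unname(se[cv]),
        or = exp(unname(b[cv])),
        conf.low = exp(unname(b[cv]) - 1.96 * unname(se[cv])),
        conf.high = exp(unname(b[cv]) + 1.96 * unname(se[cv])),
        p.value = 2 * pnorm(-abs(unname(b[cv]) / unname(se[cv])))
      )
    }
  })
}

#' @rdname fit_repeated_logistic
#' @param x An `or_table`.
#' @export
tidy.or_table <- function(x, ...) tibble::as_tibble(x)

#' @rdname fit_repeated_logistic
#' @export
glance.or_table <- function(x, ...) attr(x, "diagnostics")

#' Crude odds ratio from a 2x2 table
#'
#' `OR = (a d)/(b c)` with the Woolf (log-scale Wald) 95% confidence
#' interval `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell
#' is zero, the Haldane-Anscombe continuity correction adds 0.5 to every
#' cell. Intended as the unadjusted oracle against which repeated-measures
#' estimates are compared.
#'
#' @param a,b,c,d Cell counts: `a`/`b` exposed/unexposed among cases,
#'   `c`/`d` among controls (any layout with OR = ad/bc).
#' @return Tibble with `or`, `conf.low`, `conf.high`, `log_or`, `se`.
#' @examples
#' or_from_2x2(194, 268, 339, 1073) # crude race OR ~ 2.29
#' @export
or_from_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop_data("2x2 cells must be nonnegative.")
  if (any(cells == 0)) cells <- cells + 0.5
  lor <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  tibble::tibble(
    or = exp(lor),
    conf.low = exp(lor - 1.96 * se),
    conf.high = exp(lor + 1.96 * se),
    log_or = lor, se = se
  )
}

#' Descriptive cohort table by satisficing status
#'
#' Counts and column percentages of each baseline category by satisficing
#' status plus the total column, and median/IQR of baseline age, in the
#' layout conventional for cohort characteristic tables.
#'
#' @param labels A `satisficing_result` or tibble with `participant_id`,
#'   `satisficer`.
#' @param participants Baseline covariate tibble.
#' @return List of class `table1`: `categorical` (tibble `variable`, `level`,
#'   `status`, `n`, `percent` with status in
#'   nonsatisficer/satisficer/total) and `age` (tibble `status`, `median`,
#'   `q1`, `q3`).
#' @export
table1_summary <- function(labels, participants) {
  if (inherits(labels, "satisficing_result")) labels <- labels$labels
  d <- dplyr::inner_join(
    tibble::as_tibble(labels)[c("participant_id", "satisficer")],
    tibble::as_tibble(participants), by = "participant_id"
  ) |>
    dplyr::mutate(status = ifelse(.data$satisficer, "satisficer", "nonsatisficer"))
  d_tot <- dplyr::mutate(d, status = "total")
  dd <- dplyr::bind_rows(d, d_tot)
  cat_vars <- intersect(c("race", "education", "hiv"), names(d))
  categorical <- purrr::map_dfr(cat_vars, function(v) {
    dd |>
      dplyr::count(.data$status, level = as.character(.data[[v]])) |>
      dplyr::group_by(.data$status) |>
      dplyr::mutate(percent = round_half_up(100 * .data$n / sum(.data$n), 2)) |>
      dplyr::ungroup() |>
      dplyr::mutate(variable = v, .before = 1)
  })
  age <- dd |>
    dplyr::group_by(.data$status) |>
    dplyr::summarise(
      median = median(.data$baseline_age),
      q1 = unname(quantile(.data$baseline_age, 0.25, type = 2)),
      q3 = unname(quantile(.data$baseline_age, 0.75, type = 2)),
      .groups = "drop"
    )
  structure(list(categorical = categorical, age = age), class = "table1")
}

#' @export
print.table1 <- function(x, ...) {
  cat("<table1> baseline characteristics by satisficing status\n")
  print(x$age)
  print(x$categorical, n = Inf)
  invisible(x)
}
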