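#' Group-based trajectory model: finite mixture of polynomial trajectories
#'
#' Fits a K-group mixture in which each latent group j has mean speed
#' \eqn{\mu_j(t) = \sum_m \beta_{jm} t^m} over coded time and observations are
#' normal around the group mean with a shared (default) or per-group residual
#' SD. Estimation is by EM on the per-participant likelihood — a participant
#' contributes the mixture over groups of the product of normal densities
#' across their observed visits — so unbalanced panels are handled naturally.
#' Multiple restarts are used: the first initialisation splits participants
#' into K blocks by mean speed (deterministic), later ones perturb that
#' ranking with seeded noise. Groups are relabelled by ascending intercept so
#' reported labels are deterministic.
#'
#' @param data A tibble with columns `participant_id`, `t` (coded time) and
#'   `speed`, e.g. from [build_series()].
#' @param k Number of groups (>= 1).
#' @param order Polynomial degree of the group trajectories, 0-3 (default 3,
#'   the conventional cubic).
#' @param shared_sigma Single residual SD across groups (default TRUE).
#' @param n_starts Number of EM initialisations (default 5).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param seed Seed for the perturbed restarts.
#' @param pi_floor Lower bound on mixing proportions to prevent degenerate
#'   collapse (default 1e-6); a floored component is reported via
#'   `collapsed`.
#' @return An object of class `gbtm`: list with `pi` (mixing proportions),
#'   `beta` ((order+1) x K coefficient matrix), `sigma`, `loglik`,
#'   `n_params`, `bic`, `converged`, `n_participants`, `n_obs`, `t_max`,
#'   `loglik_history` (winning start), `collapsed`.
#' @examples
#' cfg <- synth_config(n_participants = 60, true_pi = c(0.5, 0.5),
#'                     true_beta = list(2, 6), sigma = 0.3,
#'                     visit_missing_rate = 0, seed = 3)
#' coh <- generate_cohort(cfg)
#' ser <- clean_visits(coh$visits) |> compute_speed() |> build_series()
#' fit <- gbtm_fit(ser, k = 2, order = 0, n_starts = 2)
#' glance(fit)
#' @export
gbtm_fit <- function(data, k, order = 3, shared_sigma = TRUE, n_starts = 5,
                     max_iter = 500, tol = 1e-8, seed = 1L,
                     pi_floor = 1e-6) {
  if (k < 1) stop_config("`k` must be at least 1.")
  if (order < 0 || order > 3) stop_config("`order` must be between 0 and 3.")
  if (n_starts < 1) stop_config("`n_starts` must be at least 1.")
  if (tol <= 0) stop_config("`tol` must be positive.")

  d <- prepare_panel(data)
  n <- d$n
  if (k > n) stop_config("`k` exceeds the number of distinct participants.")
  X <- outer(d$t, 0:order, `^`)
  y <- d$y

  # deterministic first start: quantile blocks of participant mean speed
  mean_speed <- as.numeric(rowsum(y, d$pid) / tabulate(d$pid, n))
  best <- NULL
  for (s in seq_len(n_starts)) {
    if (s == 1) {
      score <- mean_speed
    } else {
      set.seed(derive_seed(seed, s))
      score <- mean_speed + rnorm(n, 0, max(sd(mean_speed), 1e-8))
    }
    block <- if (k == 1) rep(1L, n) else {
      as.integer(cut(rank(score, ties.method = "first"),
                     breaks = k, labels = FALSE))
    }
    W0 <- matrix(0, n, k)
    W0[cbind(seq_len(n), block)] <- 1
    fit <- gbtm_em(X, y, d$pid, n, k, W0, shared_sigma, max_iter, tol, pi_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$beta[1, ])
  beta <- best$beta[, ord, drop = FALSE]
  pi <- best$pi[ord]
  sigma <- if (shared_sigma) best$sigma else best$sigma[ord]
  rownames(beta) <- paste0("t^", 0:order)
  colnames(beta) <- paste0("group", seq_len(k))

  n_params <- k * (order + 1) + (k - 1) + if (shared_sigma) 1L else k
  structure(
    list(
      pi = pi, beta = beta, sigma = sigma, shared_sigma = shared_sigma,
      K = as.integer(k), order = as.integer(order),
      loglik = best$loglik, n_params = as.integer(n_params),
      bic = gbtm_bic_value(best$loglik, n_params, n),
      converged = best$converged, n_participants = n, n_obs = length(y),
      t_max = max(d$t), loglik_history = best$history,
      collapsed = best$collapsed, participants = d$levels
    ),
    class = "gbtm"
  )
}

prepare_panel <- function(data) {
  if (!all(c("participant_id", "t", "speed") %in% names(data))) {
    stop_data("Data must have columns participant_id, t, speed.")
  }
  data <- dplyr::arrange(tibble::as_tibble(data), .data$participant_id, .data$t)
  levels <- unique(data$participant_id)
  list(
    pid = match(data$participant_id, levels),
    t = as.numeric(data$t),
    y = as.numeric(data$speed),
    n = length(levels),
    levels = levels
  )
}

# Per-participant log-likelihood matrix (n x K) given parameters.
gbtm_logdens <- function(X, y, pid, n, beta, sigma, shared_sigma) {
  mu <- X %*% beta
  K <- ncol(beta)
  if (shared_sigma) {
    ld <- dnorm(y - mu, sd = sigma, log = TRUE)
  } else {
    ld <- vapply(seq_len(K),
                 function(j) dnorm(y - mu[, j], sd = sigma[j], log = TRUE),
                 numeric(length(y)))
  }
  rowsum(ld, pid)
}

gbtm_em <- function(X, y, pid, n, K, W, shared_sigma, max_iter, tol, pi_floor) {
  n_obs <- length(y)
  history <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  collapsed <- FALSE
  pi <- beta <- sigma <- NULL
  for (iter in seq_len(max_iter)) {
    # M-step from current responsibilities
    pi <- colMeans(W)
    if (any(pi < pi_floor)) {
      collapsed <- TRUE
      pi <- pmax(pi, pi_floor)
      pi <- pi / sum(pi)
    }
    Wobs <- W[pid, , drop = FALSE]
    beta <- vapply(seq_len(K), function(j) {
      lm.wfit(X, y, pmax(Wobs[, j], 1e-12))$coefficients
    }, numeric(ncol(X)))
    beta <- matrix(beta, ncol = K)
    beta[is.na(beta)] <- 0
    resid2 <- (y - X %*% beta)^2
    if (shared_sigma) {
      sigma <- max(sqrt(sum(Wobs * resid2) / n_obs), 1e-8)
    } else {
      sigma <- pmax(sqrt(colSums(Wobs * resid2) / colSums(Wobs)), 1e-8)
    }
    # E-step
    L <- gbtm_logdens(X, y, pid, n, beta, sigma, shared_sigma)
    M <- sweep(L, 2, log(pi), `+`)
    lse <- row_log_sum_exp(M)
    ll <- sum(lse)
    W <- exp(M - lse)
    history <- c(history, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(pi = pi, beta = beta, sigma = sigma, loglik = ll,
       converged = converged, history = history, collapsed = collapsed)
}

gbtm_bic_value <- function(loglik, n_params, n) {
  if (n < 2) stop_config("BIC requires at least 2 participants.")
  loglik - 0.5 * n_params * log(n)
}

#' Mixture log-likelihood of a fitted trajectory model
#'
#' \eqn{\sum_i \log \sum_j \pi_j \prod_t \phi((y_{it}-\mu_j(t_{it}))/\sigma)/\sigma},
#' computed with log-sum-exp stabilisation.
#'
#' @param model A `gbtm` fit.
#' @param data Speed panel (`participant_id`, `t`, `speed`).
#' @return The log-likelihood (scalar).
#' @export
gbtm_loglik <- function(model, data) {
  if (any(model$sigma <= 0)) stop_config("`sigma` must be positive.")
  d <- prepare_panel(data)
  X <- outer(d$t, 0:model$order, `^`)
  L <- gbtm_logdens(X, d$y, d$pid, d$n, model$beta, model$sigma,
                    model$shared_sigma)
  M <- sweep(L, 2, log(model$pi), `+`)
  sum(row_log_sum_exp(M))
}

#' Bayesian information criterion of a trajectory model
#'
#' Uses the trajectory-modelling convention
#' `BIC = loglik - 0.5 * n_params * log(n)`, under which the best model has
#' the largest (least negative) BIC. `n` is the number of participants by
#' default; the per-observation alternative is available since the criterion
#' is stated ambiguously in this literature.
#'
#' @param model A `gbtm` fit.
#' @param n_for_bic `"participants"` (default) or `"observations"`.
#' @return The BIC (scalar; larger is better).
#' @export
gbtm_bic <- function(model, n_for_bic = c("participants", "observations")) {
  n_for_bic <- match.arg(n_for_bic)
  n <- if (n_for_bic == "participants") model$n_participants else model$n_obs
  gbtm_bic_value(model$loglik, model$n_params, n)
}

#' Fit trajectory models over a range of K and select by BIC
#'
#' Fits each candidate number of groups with its own seeded restarts and
#' returns the model with the largest BIC (ties go to the smaller K). A
#' candidate K whose fit fails is recorded in the table and skipped.
#'
#' @inheritParams gbtm_fit
#' @param k_range Integer vector of candidate group counts.
#' @param ... Passed to [gbtm_fit()] (`order`, `n_starts`, `tol`, ...).
#' @return An object of class `gbtm_selection`: list with `best` (the
#'   selected `gbtm`), `table` (tibble of K, loglik, n_params, bic,
#'   converged, error) and `models` (all fits, named by K).
#' @export
gbtm_select <- function(data, k_range = 1:5, ..., seed = 1L) {
  if (!length(k_range)) stop_config("`k_range` must be nonempty.")
  k_range <- sort(unique(as.integer(k_range)))
  models <- list()
  rows <- purrr::map(k_range, function(k) {
    fit <- tryCatch(
      gbtm_fit(data, k = k, ..., seed = derive_seed(seed, k)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(tibble::tibble(K = k, loglik = NA_real_, n_params = NA_integer_,
                            bic = NA_real_, converged = NA,
                            error = conditionMessage(fit)))
    }
    models[[as.character(k)]] <<- fit
    tibble::tibble(K = k, loglik = fit$loglik, n_params = fit$n_params,
                   bic = fit$bic, converged = fit$converged,
                   error = NA_character_)
  })
  table <- dplyr::bind_rows(rows)
  ok <- which(!is.na(table$bic))
  if (!length(ok)) stop_data("Every candidate K failed to fit.")
  best_k <- table$K[ok[which.max(table$bic[ok])]]
  structure(
    list(best = models[[as.character(best_k)]], table = table,
         models = models),
    class = "gbtm_selection"
  )
}

#' @export
print.gbtm_selection <- function(x, ...) {
  cat("<gbtm_selection> best K =", x$best$K, "\n")
  print(x$table)
  invisible(x)
}

#' Posterior group membership of each participant
#'
#' Bayes-rule responsibilities given the fitted mixture, hard labels by
#' maximum posterior (ties to the lowest group index), and the per-group
#' average of the winners' posteriors (the usual classification-quality
#' diagnostic).
#'
#' @param model A `gbtm` fit.
#' @param data Speed panel the model was fitted to.
#' @return List of class `gbtm_posterior`: `posterior` (tibble with
#'   `participant_id`, one `prob_group<j>` column per group, `group`),
#'   `avg_posterior` (tibble `group`, `avg_max_posterior`, `n`).
#' @export
gbtm_posteriors <- function(model, data) {
  d <- prepare_panel(data)
  X <- outer(d$t, 0:model$order, `^`)
  L <- gbtm_logdens(X, d$y, d$pid, d$n, model$beta, model$sigma,
                    model$shared_sigma)
  M <- sweep(L, 2, log(model$pi), `+`)
  W <- exp(M - row_log_sum_exp(M))
  hard <- max.col(W, ties.method = "first")
  post <- tibble::as_tibble(W, .name_repair = ~ paste0("prob_group", seq_len(model$K)))
  post <- dplyr::bind_cols(
    tibble::tibble(participant_id = d$levels), post,
    tibble::tibble(group = hard)
  )
  avg <- post |>
    dplyr::mutate(max_post = W[cbind(dplyr::row_number(), hard)]) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(avg_max_posterior = mean(.data$max_post),
                     n = dplyr::n(), .groups = "drop")
  structure(list(posterior = post, avg_posterior = avg),
            class = "gbtm_posterior")
}

#' @export
print.gbtm <- function(x, ...) {
  cat("<gbtm> K =", x$K, " order =", x$order,
      " loglik =", format(x$loglik, digits = 6),
      " BIC =", format(x$bic, digits = 6),
      if (!x$converged) " (NOT converged)", "\n")
  cat("pi:", paste(format(x$pi, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' @rdname gbtm_fit
#' @param x A `gbtm` object.
#' @export
tidy.gbtm <- function(x, ...) {
  tibble::tibble(
    group = rep(seq_len(x$K), each = x$order + 1),
    term = rep(rownames(x$beta), x$K),
    estimate = as.numeric(x$beta)
  )
}

#' @rdname gbtm_fit
#' @export
glance.gbtm <- function(x, ...) {
  tibble::tibble(
    K = x$K, order = x$order, loglik = x$loglik, n_params = x$n_params,
    bic = x$bic, sigma = if (x$shared_sigma) x$sigma else mean(x$sigma),
    converged = x$converged, n_participants = x$n_participants,
    n_obs = x$n_obs
  )
}

#' Fitted group-mean trajectories on a coded-time grid
#'
#' @param model A `gbtm` fit.
#' @param t_grid Coded times at which to evaluate (default the observed
#'   integer range).
#' @return Tibble with `group`, `t`, `mu` and the group's mixing proportion.
#' @export
gbtm_trajectories <- function(model, t_grid = 0:model$t_max) {
  X <- outer(as.numeric(t_grid), 0:model$order, `^`)
  mu <- X %*% model$beta
  tidyr::expand_grid(group = seq_len(model$K), t = as.numeric(t_grid)) |>
    dplyr::arrange(.data$group, .data$t) |>
    dplyr::mutate(mu = as.numeric(mu[cbind(match(.data$t, t_grid), .data$group)]),
                  pi = model$pi[.data$group])
}
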