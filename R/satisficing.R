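#' Configuration for the two-step satisficer classifier
#'
#' Controls how fitted trajectories are read for the "recent speed increase"
#' signature and how the two trajectory-model stages are fitted. The recency
#' criterion is operationalised as: the fitted trajectory's derivative at the
#' final visit is positive AND its value at the final visit exceeds its
#' minimum over the trailing `window + 1` visits by more than
#' `margin * sigma_hat` words/second.
#'
#' @param window Trailing number of visits defining "recent" (default 2, i.e.
#'   the last three visits enter the rise computation).
#' @param margin Minimum fitted rise as a multiple of the model's residual SD
#'   (default 0.1).
#' @param k_range Candidate group counts for the cohort-level fit
#'   (default 1:5).
#' @param k_range_step2 Candidate subgroup counts for the within-group refit
#'   (default = `k_range`).
#' @param order,n_starts,max_iter,tol Passed to [gbtm_fit()] at both steps.
#' @param min_group_mult A candidate group smaller than
#'   `min_group_mult * max(k_range_step2)` participants skips the refit and is
#'   labelled satisficer wholesale, with a warning (mixture fits on tiny
#'   groups are unstable).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(window = 2, margin = 0.1, k_range = 1:5,
                              k_range_step2 = k_range, order = 3,
                              n_starts = 3, max_iter = 500, tol = 1e-8,
                              min_group_mult = 10, seed = 1L) {
  if (window < 1) stop_config("`window` must be at least 1.")
  if (margin < 0) stop_config("`margin` must be nonnegative.")
  structure(
    list(window = as.integer(window), margin = as.numeric(margin),
         k_range = as.integer(k_range),
         k_range_step2 = as.integer(k_range_step2),
         order = as.integer(order), n_starts = as.integer(n_starts),
         max_iter = as.integer(max_iter), tol = as.numeric(tol),
         min_group_mult = as.numeric(min_group_mult),
         seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Trajectory-shape flags for each fitted group
#'
#' Evaluates each group's fitted polynomial on the integer coded-time grid
#' and derives the quantities the classification reads: the derivative at the
#' final visit, the rise over the trailing window, and the overall change
#' from first to last visit. `recent_increase` requires a positive end
#' derivative and a trailing rise above the margin; `overall_decreasing`
#' marks groups whose net change is below minus the margin and that are not
#' recent risers (an early rise followed by decline is therefore not a
#' satisficing candidate).
#'
#' @param model A `gbtm` fit.
#' @param config A [classifier_config()].
#' @return Tibble with one row per group: `group`, `pi`, `end_derivative`,
#'   `recent_rise`, `overall_change`, `recent_increase`,
#'   `overall_decreasing`, and the fitted means as a list-column `fitted`.
#' @export
shape_flags <- function(model, config = classifier_config()) {
  t_max <- model$t_max
  if (t_max < config$window) {
    stop_config("`window` must be smaller than the observed time span.")
  }
  delta <- config$margin * mean(model$sigma)
  grid <- 0:t_max
  X <- outer(as.numeric(grid), 0:model$order, `^`)
  mu <- X %*% model$beta
  dcoef <- seq_len(model$order) # derivative: sum m * beta_m t^(m-1)
  purrr::map_dfr(seq_len(model$K), function(j) {
    muj <- mu[, j]
    endd <- if (model$order == 0) 0 else {
      sum(dcoef * model$beta[-1, j] * t_max^(dcoef - 1))
    }
    recent <- muj[t_max + 1] - min(muj[(t_max - config$window):t_max + 1])
    overall <- muj[t_max + 1] - muj[1]
    ri <- endd > 0 && recent > delta
    tibble::tibble(
      group = j, pi = model$pi[j],
      end_derivative = endd, recent_rise = recent, overall_change = overall,
      recent_increase = ri,
      overall_decreasing = (overall < -delta) && !ri,
      fitted = list(tibble::tibble(t = grid, mu = muj))
    )
  })
}

#' Groups whose fitted speed rises over recent visits
#'
#' @param shapes Output of [shape_flags()].
#' @return Integer vector of candidate group indices (possibly empty).
#' @export
select_candidate_groups <- function(shapes) {
  shapes$group[shapes$recent_increase]
}

#' Two-step trajectory-based satisficer classification
#'
#' Step 1 fits trajectory models over `k_range` to the whole cohort, selects
#' by BIC, hard-assigns participants by maximum posterior and flags groups
#' whose fitted speed rises over recent visits. Step 2 refits, within each
#' flagged group, a second trajectory-model selection over `k_range_step2`,
#' flags the rising subgroups the same way, and labels their members
#' satisficers; everyone else is a nonsatisficer. Full provenance (both
#' selections, shape tables, candidate sets) is retained.
#'
#' @param data Speed panel (`participant_id`, `t`, `speed`), e.g. from
#'   [build_series()].
#' @param config A [classifier_config()].
#' @return An object of class `satisficing_result`: list with `labels`
#'   (tibble `participant_id`, `step1_group`, `step2_subgroup`,
#'   `satisficer`), `n`, `n_satisficers`, `prop_satisficers`, and
#'   `provenance` (step-1 selection and shapes, candidates, per-candidate
#'   step-2 selections and shapes, the config).
#' @examples
#' cfg <- synth_config(n_participants = 120, seed = 11)
#' coh <- generate_cohort(cfg)
#' ser <- clean_visits(coh$visits) |> compute_speed() |> build_series()
#' res <- classify_satisficers(ser, classifier_config(k_range = 1:3,
#'                                                    n_starts = 2))
#' glance(res)
#' @export
classify_satisficers <- function(data, config = classifier_config()) {
  d <- prepare_panel(data)
  if (d$n < 2) stop_config("Classification needs at least 2 participants.")
  step1 <- with_stage("step1 trajectory selection", gbtm_select(
    data, k_range = config$k_range, order = config$order,
    n_starts = config$n_starts, max_iter = config$max_iter,
    tol = config$tol, seed = derive_seed(config$seed, 101)
  ))
  post1 <- gbtm_posteriors(step1$best, data)
  shapes1 <- shape_flags(step1$best, config)
  candidates <- select_candidate_groups(shapes1)

  labels <- post1$posterior |>
    dplyr::select("participant_id", step1_group = "group") |>
    dplyr::mutate(step2_subgroup = NA_integer_, satisficer = FALSE)

  step2 <- list()
  min_size <- config$min_group_mult * max(config$k_range_step2)
  for (g in candidates) {
    members <- labels$participant_id[labels$step1_group == g]
    if (length(members) < min_size) {
      warn(paste0("Candidate group ", g, " has only ", length(members),
                  " members; labelled satisficer wholesale without a refit."))
      labels$satisficer[labels$step1_group == g] <- TRUE
      step2[[as.character(g)]] <- list(selection = NULL, shapes = NULL,
                                       flagged = NA, wholesale = TRUE)
      next
    }
    sub <- data[data$participant_id %in% members, , drop = FALSE]
    sel <- with_stage(paste0("step2 refit of group ", g), gbtm_select(
      sub, k_range = config$k_range_step2, order = config$order,
      n_starts = config$n_starts, max_iter = config$max_iter,
      tol = config$tol, seed = derive_seed(config$seed, 200 + g)
    ))
    post2 <- gbtm_posteriors(sel$best, sub)
    shapes2 <- shape_flags(sel$best, config)
    flagged <- select_candidate_groups(shapes2)
    idx <- match(post2$posterior$participant_id, labels$participant_id)
    labels$step2_subgroup[idx] <- post2$posterior$group
    labels$satisficer[idx[post2$posterior$group %in% flagged]] <- TRUE
    step2[[as.character(g)]] <- list(selection = sel, shapes = shapes2,
                                     flagged = flagged, wholesale = FALSE)
  }

  new_satisficing_result(labels, step1, shapes1, candidates, step2, config)
}

new_satisficing_result <- function(labels, step1, shapes1, candidates, step2,
                                   config) {
  n <- nrow(labels)
  ns <- sum(labels$satisficer)
  structure(
    list(
      labels = labels, n = n, n_satisficers = ns,
      prop_satisficers = ns / n,
      provenance = list(step1 = step1, shapes1 = shapes1,
                        candidates = candidates, step2 = step2,
                        config = config)
    ),
    class = "satisficing_result"
  )
}

#' Re-derive satisficer labels from stored fits under a new margin/window
#'
#' Reapplies [shape_flags()] and the labelling rule to the trajectory models
#' already stored in a [classify_satisficers()] result, without refitting.
#' Useful for sensitivity analyses in the margin `delta` (raising the margin
#' can only shrink the satisficer set).
#'
#' @param result A `satisficing_result`.
#' @param config A [classifier_config()]; only `window` and `margin` matter.
#' @return A new `satisficing_result` sharing the stored fits.
#' @export
reclassify <- function(result, config) {
  prov <- result$provenance
  shapes1 <- shape_flags(prov$step1$best, config)
  candidates <- select_candidate_groups(shapes1)
  labels <- result$labels |>
    dplyr::mutate(satisficer = FALSE)
  step2 <- list()
  for (g in candidates) {
    st2 <- prov$step2[[as.character(g)]]
    if (is.null(st2) || isTRUE(st2$wholesale) || is.null(st2$selection)) {
      labels$satisficer[labels$step1_group == g] <- TRUE
      step2[[as.character(g)]] <- list(selection = NULL, shapes = NULL,
                                       flagged = NA, wholesale = TRUE)
      next
    }
    shapes2 <- shape_flags(st2$selection$best, config)
    flagged <- select_candidate_groups(shapes2)
    in_g <- labels$step1_group == g & !is.na(labels$step2_subgroup)
    labels$satisficer[in_g & labels$step2_subgroup %in% flagged] <- TRUE
    step2[[as.character(g)]] <- list(selection = st2$selection,
                                     shapes = shapes2, flagged = flagged,
                                     wholesale = FALSE)
  }
  new_satisficing_result(labels, prov$step1, shapes1, candidates, step2, config)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Stage [", stage, "] failed: ", conditionMessage(e)),
          class = "trajsat_stage_error", parent = e)
  })
}

#' @export
print.satisficing_result <- function(x, ...) {
  cat("<satisficing_result> ", x$n_satisficers, "/", x$n, " satisficers (",
      format(round_half_up(100 * x$prop_satisficers, 2), nsmall = 2),
      "%)\n", sep = "")
  invisible(x)
}

#' @rdname classify_satisficers
#' @param x A `satisficing_result`.
#' @export
tidy.satisficing_result <- function(x, ...) x$labels

#' @rdname classify_satisficers
#' @export
glance.satisficing_result <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_satisficers = x$n_satisficers,
    n_nonsatisficers = x$n - x$n_satisficers,
    pct_satisficers = round_half_up(100 * x$prop_satisficers, 2),
    k_step1 = x$provenance$step1$best$K,
    n_candidate_groups = length(x$provenance$candidates)
  )
}

#' Reporting-style proportion summary of a classification
#'
#' Counts and percentages (rounded half away from zero to two decimals, the
#' convention used in cohort reports) for the step-1 groups as shares of the
#' cohort, the step-2 subgroups as shares of their parent group, and the
#' satisficer/nonsatisficer split.
#'
#' @param object A `satisficing_result`.
#' @param ... Unused.
#' @return Tibble with `level`, `category`, `numerator`, `denominator`,
#'   `percent`.
#' @export
summary.satisficing_result <- function(object, ...) {
  lab <- object$labels
  g <- lab |>
    dplyr::count(.data$step1_group) |>
    dplyr::transmute(level = "step1_group",
                     category = paste0("group", .data$step1_group),
                     numerator = .data$n, denominator = object$n)
  sg <- lab |>
    dplyr::filter(!is.na(.data$step2_subgroup)) |>
    dplyr::count(.data$step1_group, .data$step2_subgroup) |>
    dplyr::group_by(.data$step1_group) |>
    dplyr::mutate(denominator = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::transmute(level = "step2_subgroup",
                     category = paste0("group", .data$step1_group,
                                       "/subgroup", .data$step2_subgroup),
                     numerator = .data$n, denominator = .data$denominator)
  s <- tibble::tibble(
    level = "satisficing",
    category = c("satisficer", "nonsatisficer"),
    numerator = c(object$n_satisficers, object$n - object$n_satisficers),
    denominator = object$n
  )
  dplyr::bind_rows(g, sg, s) |>
    dplyr::mutate(percent = round_half_up(100 * .data$numerator / .data$denominator, 2))
}
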