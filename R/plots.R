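#' Plot fitted trajectory groups
#'
#' Fitted mean response speed per group over coded time, labelled with each
#' group's mixing proportion — the standard way trajectory-group solutions
#' are displayed.
#'
#' @param object A `gbtm` fit.
#' @param data Optional speed panel; when supplied, per-visit observed group
#'   means (by posterior hard label) are overlaid as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gbtm <- function(object, data = NULL, ...) {
  traj <- gbtm_trajectories(object) |>
    dplyr::mutate(group_label = sprintf("group %d (%.1f%%)", .data$group,
                                        100 * .data$pi))
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$t, y = .data$mu,
                                          colour = .data$group_label)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Coded visit time", y = "Response speed (words/s)",
                  colour = NULL,
                  title = sprintf("Fitted trajectory groups (K = %d)", object$K)) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    post <- gbtm_posteriors(object, data)
    obs <- data |>
      dplyr::inner_join(
        dplyr::select(post$posterior, "participant_id", "group"),
        by = "participant_id"
      ) |>
      dplyr::group_by(.data$group, .data$t) |>
      dplyr::summarise(speed = mean(.data$speed), .groups = "drop") |>
      dplyr::mutate(group_label = sprintf("group %d (%.1f%%)", .data$group,
                                          100 * object$pi[.data$group]))
    p <- p + ggplot2::geom_point(
      data = obs, ggplot2::aes(y = .data$speed), shape = 1
    )
  }
  p
}

#' Plot both classification steps
#'
#' Step-1 cohort trajectories and, for each candidate group refitted in step
#' 2, the subgroup trajectories, faceted side by side.
#'
#' @param object A `satisficing_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.satisficing_result <- function(object, ...) {
  prov <- object$provenance
  traj1 <- gbtm_trajectories(prov$step1$best) |>
    dplyr::mutate(panel = "Step 1: cohort",
                  curve = sprintf("group %d (%.1f%%)", .data$group,
                                  100 * .data$pi))
  traj2 <- purrr::imap_dfr(prov$step2, function(s, g) {
    if (isTRUE(s$wholesale) || is.null(s$selection)) return(NULL)
    gbtm_trajectories(s$selection$best) |>
      dplyr::mutate(panel = sprintf("Step 2: within group %s", g),
                    curve = sprintf("subgroup %d (%.1f%%)", .data$group,
                                    100 * .data$pi))
  })
  ggplot2::ggplot(dplyr::bind_rows(traj1, traj2),
                  ggplot2::aes(x = .data$t, y = .data$mu, colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "Coded visit time", y = "Response speed (words/s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of an odds-ratio table
#'
#' @param object An `or_table` from [fit_repeated_logistic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.or_table <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(!.data$reference) |>
    dplyr::mutate(label = paste(.data$variable, .data$level, sep = ": "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
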