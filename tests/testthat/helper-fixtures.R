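# Small builders shared across tests. Everything is generated in code; no
# stored fixtures.

# A speed panel from explicit per-participant (t, speed) vectors.
make_series <- function(...) {
  parts <- list(...)
  purrr::imap_dfr(parts, function(m, nm) {
    tibble::tibble(participant_id = nm, t = m$t, speed = m$speed)
  }) |>
    build_series()
}

# A hand-assembled gbtm model object (for posterior / shape tests that need
# exact parameters rather than a fitted approximation).
manual_gbtm <- function(pi, beta, sigma, t_max = 8, shared_sigma = TRUE) {
  beta <- as.matrix(beta)
  structure(
    list(pi = pi, beta = beta, sigma = sigma, shared_sigma = shared_sigma,
         K = length(pi), order = nrow(beta) - 1,
         loglik = NA_real_, n_params = NA_integer_, bic = NA_real_,
         converged = TRUE, n_participants = NA_integer_, n_obs = NA_integer_,
         t_max = t_max, loglik_history = numeric(0), collapsed = FALSE),
    class = "gbtm"
  )
}

# Fast classifier settings used where the test targets logic, not accuracy.
quick_classifier <- function(...) {
  classifier_config(n_starts = 2, tol = 1e-7, max_iter = 200, ...)
}

# Visit tibble with coherent ISO 8601 timestamps for given durations (secs).
make_visits <- function(participant_id, visit, duration, word_count,
                        day = "2008-10-01", start_clock = "09:00:00") {
  start <- as.POSIXct(paste(day, start_clock), tz = "UTC")
  tibble::tibble(
    participant_id = participant_id,
    visit = as.integer(visit),
    start_time = format(start, "%Y-%m-%dT%H:%M:%S"),
    end_time = format(start + duration, "%Y-%m-%dT%H:%M:%S"),
    word_count = as.integer(word_count)
  )
}
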