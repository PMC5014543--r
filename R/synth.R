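#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the full parameter set for [generate_cohort()]. The
#' defaults emulate a semiannual behavioural-survey cohort observed over nine
#' visits (coded 50..58): three latent response-speed trajectory groups with
#' mean speeds near 2, 4 and 6 words/second, group shares matching a cohort of
#' roughly 2100 men, about a quarter of visits unattended, and a questionnaire
#' that loses about 30 questions from the seventh coded visit onward.
#'
#' @param n_participants Number of participants (default 2138).
#' @param n_visits Number of scheduled visits (default 9); visit numbers run
#'   `visit_zero .. visit_zero + n_visits - 1` and coded time is
#'   `visit - visit_zero`.
#' @param visit_zero First visit number (default 50).
#' @param true_pi Probabilities of the latent trajectory groups; nonnegative,
#'   summing to 1.
#' @param true_beta List of per-group polynomial coefficient vectors
#'   (words/second over coded time; element m is the coefficient of t^(m-1)).
#' @param sigma Residual SD of speed around the group mean (words/second,
#'   >= 0; 0 gives noise-free trajectories).
#' @param satisficer_groups Indices of groups whose members are the planted
#'   satisficers (default 1, the slow group with a late rise).
#' @param visit_missing_rate Probability a scheduled visit is unattended;
#'   every participant keeps at least one visit.
#' @param corrupt_rates Named triple `c(missing_start=, missing_end=,
#'   illogical=)` of record-corruption rates applied by
#'   [inject_timestamp_errors()].
#' @param covariate_model List controlling baseline and visit-level
#'   covariates; see Details.
#' @param base_word_count Mean responded word count per visit before the
#'   questionnaire shortening.
#' @param word_drop Mean word-count reduction from `word_drop_time` onward.
#' @param word_drop_time Coded time at which the shorter questionnaire starts
#'   (default 6, i.e. visit 56).
#' @param start_date Date of the first visit window.
#' @param visit_spacing_days Days between consecutive visit windows
#'   (default 182, semiannual).
#' @param seed Integer seed; the same config and seed reproduce the cohort
#'   byte for byte.
#'
#' @details
#' `covariate_model` has entries `age_mean`, `age_sd` (baseline age, years),
#' `race_probs` (white/black/other), `education_probs`
#' (lt_college/college/gt_college), `hiv_prob` (probability seropositive),
#' `sexual_activity_probs` and `drug_use_probs` (none/one/multiple; these are
#' visit-level categories drawn around a participant-level latent category
#' with `stability` probability of repeating it at each visit), and
#' `group_logodds`, a named numeric vector of log-odds tilts on membership in
#' the satisficer group(s): recognised names are `age_per10`, `race_black`,
#' `race_other`, `edu_lt_college`, `edu_gt_college`, `hiv_pos`, `sex_one`,
#' `sex_multiple`, `drug_one`, `drug_multiple`. With a single satisficer
#' group the marginal model for membership is exactly logistic in these
#' covariates, so planted effects are recoverable on the log-OR scale.
#'
#' @return A list of class `synth_config`.
#' @seealso [generate_cohort()], [inject_timestamp_errors()]
#' @export
synth_config <- function(n_participants = 2138,
                         n_visits = 9,
                         visit_zero = 50,
                         true_pi = c(809, 1048, 281) / 2138,
                         true_beta = list(
                           c(2.0, 0, 0, 0.002),
                           c(4.5, -0.25, 0.022, -0.0006),
                           c(6.2, 0.3, -0.06, 0.002)
                         ),
                         sigma = 0.5,
                         satisficer_groups = 1L,
                         visit_missing_rate = 0.23,
                         corrupt_rates = c(
                           missing_start = 14 / 14722,
                           missing_end = 1887 / 14722,
                           illogical = 34 / 14722
                         ),
                         covariate_model = list(),
                         base_word_count = 1500,
                         word_drop = 225,
                         word_drop_time = 6,
                         start_date = as.Date("2008-10-01"),
                         visit_spacing_days = 182,
                         seed = 1L) {
  cov_default <- list(
    age_mean = 51.5, age_sd = 9,
    race_probs = c(white = 0.6272, black = 0.2493, other = 0.1235),
    education_probs = c(lt_college = 0.1791, college = 0.4659, gt_college = 0.3550),
    hiv_prob = 0.5,
    sexual_activity_probs = c(none = 0.35, one = 0.35, multiple = 0.30),
    drug_use_probs = c(none = 0.60, one = 0.25, multiple = 0.15),
    stability = 0.8,
    group_logodds = c()
  )
  covariate_model <- utils::modifyList(cov_default, covariate_model)
  cfg <- structure(
    list(
      n_participants = as.integer(n_participants),
      n_visits = as.integer(n_visits),
      visit_zero = as.integer(visit_zero),
      true_pi = as.numeric(true_pi),
      true_beta = lapply(true_beta, as.numeric),
      sigma = as.numeric(sigma),
      satisficer_groups = as.integer(satisficer_groups),
      visit_missing_rate = as.numeric(visit_missing_rate),
      corrupt_rates = corrupt_rates,
      covariate_model = covariate_model,
      base_word_count = as.numeric(base_word_count),
      word_drop = as.numeric(word_drop),
      word_drop_time = as.numeric(word_drop_time),
      start_date = as.Date(start_date),
      visit_spacing_days = as.numeric(visit_spacing_days),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_participants < 1) stop_config("`n_participants` must be a positive integer.")
  if (cfg$n_visits < 2) stop_config("`n_visits` must be at least 2.")
  if (any(cfg$true_pi < 0) || abs(sum(cfg$true_pi) - 1) > 1e-12) {
    stop_config("`true_pi` must be nonnegative and sum to 1.")
  }
  if (length(cfg$true_beta) != length(cfg$true_pi)) {
    stop_config("`true_beta` must have one coefficient vector per entry of `true_pi`.")
  }
  if (cfg$sigma < 0) stop_config("`sigma` must be nonnegative.")
  if (cfg$visit_missing_rate < 0 || cfg$visit_missing_rate > 1) {
    stop_config("`visit_missing_rate` must lie in [0, 1].")
  }
  if (any(cfg$corrupt_rates < 0) || any(cfg$corrupt_rates > 1)) {
    stop_config("`corrupt_rates` entries must lie in [0, 1].")
  }
  if (sum(cfg$corrupt_rates) > 1) stop_config("`corrupt_rates` must sum to at most 1.")
  if (any(cfg$satisficer_groups < 1) ||
      any(cfg$satisficer_groups > length(cfg$true_pi))) {
    stop_config("`satisficer_groups` must index entries of `true_pi`.")
  }
  if (cfg$base_word_count <= 0) stop_config("`base_word_count` must be positive.")
  invisible(cfg)
}

poly_eval <- function(beta, t) {
  drop(outer(t, seq_along(beta) - 1, `^`) %*% beta)
}

sample_cat <- function(n, probs) {
  factor(names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)],
         levels = names(probs))
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates participants with latent trajectory-group membership (optionally
#' tilted by covariates on a multinomial-logit scale), per-visit responded
#' word counts, and survey durations consistent with the group's mean speed
#' plus Gaussian noise, so that word count divided by duration recovers the
#' planted speed. Visits are dropped independently at `visit_missing_rate`
#' (each participant keeps at least one). Timestamps are emitted as coherent
#' start/end pairs; corruption is applied separately by
#' [inject_timestamp_errors()].
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_cohort`: a list with tibbles
#'   * `visits`: `participant_id`, `visit`, `start_time`, `end_time`
#'     (POSIXct), `word_count`, `sexual_activity`, `drug_use`;
#'   * `participants`: `participant_id`, `baseline_age`, `race`,
#'     `education`, `hiv`;
#'   * `truth`: `participant_id`, `true_group`, `true_satisficer`.
#' @examples
#' cfg <- synth_config(n_participants = 50, seed = 7)
#' coh <- generate_cohort(cfg)
#' dplyr::count(coh$truth, true_group)
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  cm <- config$covariate_model
  n <- config$n_participants
  K <- length(config$true_pi)

  pid <- sprintf("P%05d", seq_len(n))
  age <- pmin(pmax(round(rnorm(n, cm$age_mean, cm$age_sd)), 20), 90)
  race <- sample_cat(n, cm$race_probs)
  education <- sample_cat(n, cm$education_probs)
  hiv <- factor(ifelse(runif(n) < cm$hiv_prob, "pos", "neg"),
                levels = c("neg", "pos"))
  sex_latent <- sample_cat(n, cm$sexual_activity_probs)
  drug_latent <- sample_cat(n, cm$drug_use_probs)

  # Group membership: multinomial logit with baseline log(true_pi) and a
  # covariate tilt applied to the satisficer group(s) only.
  lo <- cm$group_logodds
  tilt <- rep(0, n)
  if (length(lo)) {
    g <- function(nm) if (nm %in% names(lo)) lo[[nm]] else 0
    tilt <- g("age_per10") * (age - cm$age_mean) / 10 +
      g("race_black") * (race == "black") +
      g("race_other") * (race == "other") +
      g("edu_lt_college") * (education == "lt_college") +
      g("edu_gt_college") * (education == "gt_college") +
      g("hiv_pos") * (hiv == "pos") +
      g("sex_one") * (sex_latent == "one") +
      g("sex_multiple") * (sex_latent == "multiple") +
      g("drug_one") * (drug_latent == "one") +
      g("drug_multiple") * (drug_latent == "multiple")
  }
  eta <- matrix(log(pmax(config$true_pi, 1e-300)), n, K, byrow = TRUE)
  eta[, config$satisficer_groups] <- eta[, config$satisficer_groups] + tilt
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  u <- runif(n)
  cum <- pr %*% upper.tri(diag(K), diag = TRUE) # row-wise cumulative sums
  cum[, K] <- 1
  true_group <- max.col(u < cum, ties.method = "first")
  true_satisficer <- true_group %in% config$satisficer_groups

  # Visit attendance: Bernoulli per scheduled visit, at least one kept.
  tcode <- 0:(config$n_visits - 1)
  attend <- matrix(runif(n * config$n_visits) >= config$visit_missing_rate,
                   n, config$n_visits)
  none <- which(rowSums(attend) == 0)
  if (length(none)) {
    attend[cbind(none, sample.int(config$n_visits, length(none), replace = TRUE))] <- TRUE
  }

  idx <- which(attend, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[, 1]
  t <- tcode[idx[, 2]]
  m <- length(i)

  mu <- vapply(seq_len(m), function(r) {
    poly_eval(config$true_beta[[true_group[i[r]]]], t[r])
  }, numeric(1))
  speed <- mu + rnorm(m, 0, config$sigma)
  bad <- which(speed <= 0.05)
  while (length(bad)) { # resample rare non-positive speeds
    speed[bad] <- mu[bad] + rnorm(length(bad), 0, config$sigma)
    bad <- bad[speed[bad] <= 0.05]
  }

  wc_mean <- config$base_word_count -
    config$word_drop * (t >= config$word_drop_time)
  word_count <- pmax(rpois(m, wc_mean), 1L)
  duration <- word_count / speed

  # Visit-level behavioural categories around the participant latent one.
  redraw_sex <- runif(m) >= cm$stability
  sex_visit <- as.character(sex_latent[i])
  sex_visit[redraw_sex] <- as.character(sample_cat(sum(redraw_sex), cm$sexual_activity_probs))
  redraw_drug <- runif(m) >= cm$stability
  drug_visit <- as.character(drug_latent[i])
  drug_visit[redraw_drug] <- as.character(sample_cat(sum(redraw_drug), cm$drug_use_probs))

  day <- as.POSIXct(config$start_date, tz = "UTC") +
    t * config$visit_spacing_days * 86400 +
    floor(runif(m, 0, 120)) * 86400
  start_time <- day + 8 * 3600 + floor(runif(m, 0, 10 * 3600))
  end_time <- start_time + duration

  visits <- tibble::tibble(
    participant_id = pid[i],
    visit = config$visit_zero + t,
    start_time = start_time,
    end_time = end_time,
    word_count = as.integer(word_count),
    sexual_activity = factor(sex_visit, levels = names(cm$sexual_activity_probs)),
    drug_use = factor(drug_visit, levels = names(cm$drug_use_probs))
  )
  participants <- tibble::tibble(
    participant_id = pid,
    baseline_age = as.numeric(age),
    race = race,
    education = education,
    hiv = hiv
  )
  truth <- tibble::tibble(
    participant_id = pid,
    true_group = as.integer(true_group),
    true_satisficer = true_satisficer
  )
  structure(
    list(visits = visits, participants = participants, truth = truth,
         config = config),
    class = "synth_cohort"
  )
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", nrow(x$participants), " participants, ",
      nrow(x$visits), " visit records\n", sep = "")
  invisible(x)
}

#' Corrupt timestamp fields by exact quota sampling
#'
#' Applies the three corruption modes seen in real interview paradata —
#' missing start time, missing end time, and an end time recorded before the
#' start — to a cohort's visit records. Quotas are `round(rate * n_records)`
#' drawn without replacement, so configured rates reproduce exact corruption
#' counts; a record receives at most one corruption, with priority
#' missing_start > missing_end > illogical.
#'
#' @param cohort A `synth_cohort` or a visits tibble.
#' @param corrupt_rates Named triple `c(missing_start=, missing_end=,
#'   illogical=)`; must sum to at most 1.
#' @param seed Integer seed for the quota draw.
#' @return The cohort (or tibble) with corrupted records and a `corruption`
#'   bookkeeping tibble (`participant_id`, `visit`, `type`) attached as the
#'   `corruption` element (attribute for plain tibbles).
#' @examples
#' coh <- generate_cohort(synth_config(n_participants = 40, seed = 2))
#' coh2 <- inject_timestamp_errors(coh, c(missing_start = 0.01,
#'                                        missing_end = 0.1,
#'                                        illogical = 0.005), seed = 3)
#' dplyr::count(coh2$corruption, type)
#' @export
inject_timestamp_errors <- function(cohort,
                                    corrupt_rates = c(missing_start = 14 / 14722,
                                                      missing_end = 1887 / 14722,
                                                      illogical = 34 / 14722),
                                    seed = 1L) {
  is_cohort <- inherits(cohort, "synth_cohort")
  visits <- if (is_cohort) cohort$visits else cohort
  rates <- corrupt_rates[c("missing_start", "missing_end", "illogical")]
  if (anyNA(rates)) {
    stop_config("`corrupt_rates` needs entries missing_start, missing_end, illogical.")
  }
  if (any(rates < 0) || sum(rates) > 1) {
    stop_config("`corrupt_rates` must be nonnegative and sum to at most 1.")
  }
  n <- nrow(visits)
  quota <- round(rates * n)
  set.seed(seed)
  picked <- sample.int(n, sum(quota))
  type <- rep(c("missing_start", "missing_end", "illogical"), quota)

  out <- visits
  ms <- picked[type == "missing_start"]
  me <- picked[type == "missing_end"]
  il <- picked[type == "illogical"]
  out$start_time[ms] <- as.POSIXct(NA)
  out$end_time[me] <- as.POSIXct(NA)
  if (length(il)) {
    # end moved before start on the same day (e.g. 21:00 start, 10:00 end)
    out$end_time[il] <- out$start_time[il] - runif(length(il), 3600, 6 * 3600)
  }
  bookkeeping <- tibble::tibble(
    participant_id = visits$participant_id[picked],
    visit = visits$visit[picked],
    type = type
  )
  if (is_cohort) {
    cohort$visits <- out
    cohort$corruption <- bookkeeping
    cohort
  } else {
    attr(out, "corruption") <- bookkeeping
    out
  }
}

#' Write a cohort to delimited text files
#'
#' Writes `visits.csv` (timestamps as ISO 8601, empty when missing),
#' `participants.csv` and, when present, `truth.csv` under `dir`.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- cohort$visits
  v$start_time <- ifelse(is.na(v$start_time),
                         "", format(v$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  v$end_time <- ifelse(is.na(v$end_time),
                       "", format(v$end_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  paths <- c(
    visits = file.path(dir, "visits.csv"),
    participants = file.path(dir, "participants.csv")
  )
  readr::write_csv(v, paths[["visits"]])
  readr::write_csv(cohort$participants, paths[["participants"]])
  if (!is.null(cohort$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    readr::write_csv(cohort$truth, paths[["truth"]])
  }
  invisible(paths)
}

#' Read visit records written by [write_cohort()]
#'
#' Also accepts real exports with the same header. Timestamps are parsed as
#' ISO 8601 (empty fields become missing) by [clean_visits()]; this reader
#' keeps them as character so that malformed values can be reported rather
#' than silently dropped.
#'
#' @param path Path to a visits CSV.
#' @return A tibble of visit records.
#' @export
read_visits <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      visit = readr::col_integer(),
      start_time = readr::col_character(),
      end_time = readr::col_character(),
      word_count = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Read participant-level covariates written by [write_cohort()]
#' @param path Path to a participants CSV.
#' @return A tibble with factor-coded covariates.
#' @export
read_participants <- function(path) {
  p <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      baseline_age = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  p$race <- factor(p$race, levels = c("white", "black", "other"))
  p$education <- factor(p$education, levels = c("lt_college", "college", "gt_college"))
  p$hiv <- factor(p$hiv, levels = c("neg", "pos"))
  p
}
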