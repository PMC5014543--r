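#' Configuration for the end-to-end pipeline
#'
#' One master seed governs every stochastic stage; stage seeds are derived
#' from it deterministically, so two runs with the same config are byte
#' identical.
#'
#' @param out_dir Directory for all artifacts (created if needed).
#' @param synth A [synth_config()], used when `simulate = TRUE`. Its seed and
#'   the corruption seed are overridden by the derived stage seeds.
#' @param classifier A [classifier_config()]; its seed is likewise derived.
#' @param simulate Generate the cohort (default TRUE) or read it from
#'   `visits_file`/`participants_file`.
#' @param visits_file,participants_file Input CSVs when `simulate = FALSE`.
#' @param association_mode Passed to [fit_repeated_logistic()].
#' @param visit_zero Visit number coded as time 0.
#' @param max_duration Cleaning duration cap in seconds.
#' @param corrupt Apply [inject_timestamp_errors()] after simulation
#'   (default TRUE).
#' @param make_plots Write trajectory plots as PNG (default FALSE; all other
#'   artifacts are plain text).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            synth = synth_config(),
                            classifier = classifier_config(),
                            simulate = TRUE,
                            visits_file = NULL,
                            participants_file = NULL,
                            association_mode = "both",
                            visit_zero = 50,
                            max_duration = 24 * 3600,
                            corrupt = TRUE,
                            make_plots = FALSE,
                            seed = 1L) {
  if (!simulate && (is.null(visits_file) || is.null(participants_file))) {
    stop_config("With `simulate = FALSE`, both input files must be given.")
  }
  structure(
    list(out_dir = out_dir, synth = synth, classifier = classifier,
         simulate = simulate, visits_file = visits_file,
         participants_file = participants_file,
         association_mode = association_mode, visit_zero = visit_zero,
         max_duration = max_duration, corrupt = corrupt,
         make_plots = make_plots, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full satisficing pipeline
#'
#' Executes simulate (or load) -> clean -> speed -> classify -> associate,
#' writing every intermediate artifact under `config$out_dir` (cohort CSVs,
#' cleaning report JSON, speed panel CSV, label CSV, model provenance JSON,
#' OR tables and descriptive summary CSVs, a Markdown report, and a run
#' manifest with the config hash, seed, per-stage row counts and timings).
#' Any stage failure aborts with the stage name; artifacts written before the
#' failure are left in place for debugging.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `manifest`, the fitted
#'   `satisficing_result`, the `or_table`, the `table1` summary and the
#'   cleaning report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("trajsat")),
    stages = list()
  )
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- with_stage(name, expr)
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }
  art <- function(...) file.path(config$out_dir, ...)

  # -- simulate / load --------------------------------------------------
  if (config$simulate) {
    cohort <- t_stage("simulate", {
      sc <- config$synth
      sc$seed <- derive_seed(config$seed, 1)
      coh <- generate_cohort(sc)
      if (config$corrupt) {
        coh <- inject_timestamp_errors(coh, sc$corrupt_rates,
                                       seed = derive_seed(config$seed, 2))
      }
      write_cohort(coh, art("cohort"))
      coh
    })
    visits <- cohort$visits
    participants <- cohort$participants
    manifest$stages$simulate$n_visits <- nrow(visits)
    manifest$stages$simulate$n_participants <- nrow(participants)
  } else {
    cohort <- NULL
    visits <- NULL
    participants <- NULL
  }

  # -- clean ------------------------------------------------------------
  cleaned <- t_stage("clean", {
    if (!config$simulate) {
      if (!file.exists(config$visits_file)) {
        stop_data(paste0("Visits file not found: ", config$visits_file))
      }
      if (!file.exists(config$participants_file)) {
        stop_data(paste0("Participants file not found: ", config$participants_file))
      }
      visits <- read_visits(config$visits_file)
      participants <- read_participants(config$participants_file)
    }
    cl <- clean_visits(visits, max_duration = config$max_duration)
    jsonlite::write_json(as.list(cl$report), art("clean_report.json"),
                         auto_unbox = TRUE)
    list(cl = cl, visits = visits, participants = participants)
  })
  visits <- cleaned$visits
  participants <- cleaned$participants
  cleaned <- cleaned$cl
  manifest$stages$clean <- c(manifest$stages$clean, as.list(cleaned$report))

  # -- speed ------------------------------------------------------------
  series <- t_stage("speed", {
    sp <- compute_speed(cleaned, visit_zero = config$visit_zero)
    ser <- build_series(sp)
    readr::write_csv(ser[c("participant_id", "t", "speed")], art("speeds.csv"))
    ser
  })
  manifest$stages$speed$n_obs <- nrow(series)
  manifest$stages$speed$n_participants <- dplyr::n_distinct(series$participant_id)

  # -- classify ---------------------------------------------------------
  result <- t_stage("classify", {
    cc <- config$classifier
    cc$seed <- derive_seed(config$seed, 3)
    res <- classify_satisficers(series, cc)
    readr::write_csv(res$labels, art("labels.csv"))
    jsonlite::write_json(provenance_json(res), art("classification.json"),
                         auto_unbox = TRUE, digits = NA)
    if (config$make_plots) {
      ggplot2::ggsave(art("step1_trajectories.png"),
                      autoplot(res$provenance$step1$best),
                      width = 7, height = 5, dpi = 150)
    }
    res
  })
  manifest$stages$classify$n_satisficers <- result$n_satisficers
  manifest$stages$classify$k_step1 <- result$provenance$step1$best$K

  # -- associate --------------------------------------------------------
  assoc <- t_stage("associate", {
    panel <- build_panel(result, cleaned, participants,
                         visit_zero = config$visit_zero)
    ors <- fit_repeated_logistic(panel, mode = config$association_mode)
    readr::write_csv(tidy(ors), art("odds_ratios.csv"))
    t1 <- table1_summary(result, participants)
    readr::write_csv(t1$categorical, art("table1_categorical.csv"))
    readr::write_csv(t1$age, art("table1_age.csv"))
    list(panel = panel, ors = ors, table1 = t1)
  })
  manifest$stages$associate$n_rows <- nrow(assoc$panel)

  write_report(config, cleaned$report, result, assoc, art("report.md"))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest, result = result, or_table = assoc$ors,
                 table1 = assoc$table1, clean_report = cleaned$report))
}

provenance_json <- function(res) {
  model_json <- function(m) {
    list(K = m$K, order = m$order, pi = m$pi, beta = as.list(as.data.frame(m$beta)),
         sigma = m$sigma, loglik = m$loglik, bic = m$bic,
         converged = m$converged, n_participants = m$n_participants)
  }
  prov <- res$provenance
  list(
    n = res$n, n_satisficers = res$n_satisficers,
    pct_satisficers = round_half_up(100 * res$prop_satisficers, 2),
    candidates = prov$candidates,
    step1 = list(model = model_json(prov$step1$best),
                 bic_table = prov$step1$table,
                 shapes = dplyr::select(prov$shapes1, -"fitted")),
    step2 = purrr::map(prov$step2, function(s) {
      if (isTRUE(s$wholesale)) return(list(wholesale = TRUE))
      list(model = model_json(s$selection$best),
           bic_table = s$selection$table,
           shapes = dplyr::select(s$shapes, -"fitted"),
           flagged = s$flagged)
    }),
    config = unclass(prov$config)
  )
}

write_report <- function(config, report, result, assoc, path) {
  s <- summary(result)
  lines <- c(
    "# Satisficing pipeline report",
    "",
    sprintf("- Seed: %d; config hash: %s", config$seed,
            rlang::hash(unclass(config))),
    "",
    "## Record cleaning",
    sprintf("- %d input records; excluded %d missing start, %d missing end, %d illogical; %d kept.",
            report$n_input, report$n_missing_start, report$n_missing_end,
            report$n_illogical, report$n_kept),
    "",
    "## Trajectory classification",
    sprintf("- Step-1 model: K = %d (BIC-selected).",
            result$provenance$step1$best$K),
    sprintf("- Candidate rising groups: %s.",
            paste(result$provenance$candidates, collapse = ", ")),
    sprintf("- Satisficers: %d / %d (%.2f%%).", result$n_satisficers,
            result$n, round_half_up(100 * result$prop_satisficers, 2)),
    "",
    "### Proportions",
    knit_table(s),
    "",
    "## Associations (odds ratios)",
    knit_table(dplyr::select(
      tibble::as_tibble(assoc$ors), "model", "variable", "level", "or",
      "conf.low", "conf.high", "p.value"
    ))
  )
  writeLines(lines, path)
}

# minimal Markdown table writer (keeps the report dependency-free)
knit_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", formatC(x, digits = 4, format = "g"))
    else ifelse(is.na(x), "", as.character(x))
  }
  cells <- purrr::map(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- purrr::pmap_chr(cells, function(...) {
    paste0("| ", paste(c(...), collapse = " | "), " |")
  })
  c(header, sep, body)
}
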