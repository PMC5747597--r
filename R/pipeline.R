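## End-to-end pipeline: simulate or load, then validation, reliability
## and agreement stages, with JSON-first reports mirroring the three
## standard result tables of a validation paper and CSV point files for
## Bland-Altman plotting.

#' Pipeline configuration
#'
#' Exactly one of `input` (a readings CSV) or `scenario` (a packaged
#' scenario name or YAML path for the synthetic generator) must be set.
#'
#' @param input path to a long-format readings CSV
#' @param scenario scenario name/path for [esh_scenario()]
#' @param variables variables to analyse
#' @param sessions sessions to analyse
#' @param icc_model ICC model passed to [icc_estimate()]
#' @param t_mode between-device t-test mode for [device_mean_comparison()]
#' @param n_base ESH base design size (33)
#' @param out_dir output directory for reports
#' @param seed RNG seed (simulation and Monte-Carlo p-values)
#' @param log_level `"info"` or `"quiet"`
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input = NULL, scenario = NULL,
                            variables = ESH_VARIABLES,
                            sessions = c(1L, 2L),
                            icc_model = "two_way_random_absolute",
                            t_mode = "independent",
                            n_base = 33L, out_dir = "eshval-report",
                            seed = 1L, log_level = "info") {
  if (is.null(input) == is.null(scenario)) {
    stop("exactly one of `input` or `scenario` must be given", call. = FALSE)
  }
  structure(list(input = input, scenario = scenario,
                 variables = variables, sessions = as.integer(sessions),
                 icc_model = icc_model, t_mode = t_mode,
                 n_base = as.integer(n_base), out_dir = out_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Loads or simulates a study, then runs the ESH validation, the
#' test-device reliability analysis (intrasession and intersession ICC,
#' SEM, paired session-change t-tests) and the between-device agreement
#' analysis (means, t-test, Pearson r, Bland-Altman), writing
#' `table_reliability.json`, `table_validation.json`,
#' `table_agreement.json`, per-scope Bland-Altman point CSVs, a
#' plain-text `summary.txt` with the overall verdict, and a
#' `manifest.json` recording inputs, seed and package version.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the dataset and all stage results
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_info <- function(...) {
    if (identical(config$log_level, "info")) message("[eshval] ", ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dataset <- stage("load", {
    if (!is.null(config$input)) {
      log_info("reading study from ", config$input)
      read_study(config$input)
    } else {
      log_info("simulating scenario ", config$scenario,
               " (seed ", config$seed, ")")
      generate_study(esh_scenario(config$scenario), seed = config$seed)
    }
  })

  verdict <- stage("validation",
                   validate_device(dataset, config$variables,
                                   config$sessions, config$n_base))
  reliability <- stage("reliability",
                       reliability_report(dataset, config$variables,
                                          model = config$icc_model))
  agreement <- stage("agreement", {
    scopes <- c("session1", "session2", "intersession")[
      c(1L %in% config$sessions, 2L %in% config$sessions,
        all(c(1L, 2L) %in% config$sessions))]
    lapply(stats::setNames(scopes, scopes), function(sc) {
      mns <- suppressWarnings(
        participant_means(dataset, sc, config$variables))
      list(means = mns,
           comparison = device_mean_comparison(mns, config$t_mode),
           correlation = device_correlation(mns),
           bland_altman = bland_altman(mns))
    })
  })

  stage("report", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    jsonlite::write_json(reliability_json(reliability),
                         out("table_reliability.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(verdict_json(verdict), out("table_validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(agreement_json(agreement),
                         out("table_agreement.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (sc in names(agreement)) {
      pts <- do.call(rbind, lapply(agreement[[sc]]$bland_altman,
                                   function(s) s$points))
      write.csv(pts, out(paste0("ba_points_", sc, ".csv")),
                row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(
      list(package = "eshval",
           version = as.character(utils::packageVersion("eshval")),
           input = config$input, scenario = config$scenario,
           seed = config$seed, variables = config$variables,
           sessions = config$sessions, icc_model = config$icc_model,
           t_mode = config$t_mode,
           decisions = c("inclusive band boundaries",
                         "requirement scaling k = round(n/33)",
                         "signed mean differences",
                         "independent-samples device t-test by default")),
      out("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      sprintf("ESH validation verdict: %s (n=%d completers)",
              toupper(verdict$overall), verdict$n_subjects),
      vapply(verdict$components, function(comp) {
        sprintf("  %s%d: %s (bands %s; good %d, bad %d; mean diff %.2f +/- %.2f)",
                comp$variable, comp$session,
                if (comp$pass) "pass" else "FAIL",
                paste(comp$band_counts[1:3], collapse = "/"),
                comp$phase2$counts[["good"]], comp$phase2$counts[["bad"]],
                comp$mean_difference, comp$sd_difference)
      }, character(1))), out("summary.txt"))
    log_info("reports written to ", config$out_dir)
  })

  invisible(list(dataset = dataset, verdict = verdict,
                 reliability = reliability, agreement = agreement))
}

#' Test-device reliability report (intrasession and intersession)
#'
#' For each variable: per-session ICC/SEM over the three test-device
#' readings (k = 3), the intersession ICC over the two session means
#' (k = 2), and the paired t-test for systematic change between
#' sessions. Mirrors the reliability table of a validation paper.
#'
#' @param dataset a [study_dataset]
#' @param variables variables to analyse
#' @param model ICC model, see [icc_estimate()]
#' @return nested list keyed by variable, each with `session1`,
#'   `session2`, `intersession` reliability estimates and
#'   `session_change` (the paired t)
#' @export
reliability_report <- function(dataset, variables = ESH_VARIABLES,
                               model = "two_way_random_absolute") {
  ids <- complete_participants(dataset, variables, c(1L, 2L))
  lapply(stats::setNames(variables, variables), function(v) {
    m1 <- series_matrix(dataset, 1L, v, ids)[, TEST_POSITIONS, drop = FALSE]
    m2 <- series_matrix(dataset, 2L, v, ids)[, TEST_POSITIONS, drop = FALSE]
    sm <- cbind(rowMeans(m1), rowMeans(m2))
    list(session1 = icc_estimate(m1, model),
         session2 = icc_estimate(m2, model),
         intersession = icc_estimate(sm, model),
         session_change = intersession_change_test(sm[, 1L], sm[, 2L]))
  })
}

## ---- JSON shaping helpers (full precision; table mirrors round to 2) ----

reliability_json <- function(rel) {
  lapply(rel, function(r) {
    shape <- function(e) list(
      mean = e$mean, sd = e$sd, range = e$range, icc = e$icc,
      ci = c(e$ci_low, e$ci_high), sem = e$sem,
      interpretation = e$interpretation, n = e$n, k = e$k,
      degenerate = e$degenerate)
    list(session1 = shape(r$session1), session2 = shape(r$session2),
         intersession = shape(r$intersession),
         session_change = r$session_change)
  })
}

verdict_json <- function(v) {
  list(n_subjects = v$n_subjects,
       requirements = unclass(v$requirements),
       overall = v$overall,
       components = lapply(v$components, function(comp) {
         list(variable = comp$variable, session = comp$session,
              bands = comp$bands,
              band_counts = as.list(comp$band_counts),
              phase1 = list(verdict = comp$phase1$verdict,
                            two_of = comp$phase1$criteria_met$two_of,
                            all_of = comp$phase1$criteria_met$all_of),
              phase2 = list(verdict = comp$phase2$verdict,
                            good = comp$phase2$counts[["good"]],
                            bad = comp$phase2$counts[["bad"]]),
              mean_difference = comp$mean_difference,
              sd_difference = comp$sd_difference,
              pass = comp$pass)
       }))
}

agreement_json <- function(agr) {
  lapply(agr, function(a) {
    list(comparison = a$comparison, correlation = a$correlation,
         bland_altman = lapply(a$bland_altman, function(s)
           s[c("variable", "n", "bias", "sd_diff", "loa_low", "loa_high")]))
  })
}
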