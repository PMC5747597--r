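## Between-device agreement at the participant level: per-device means,
## t-tests, Pearson correlation, Bland-Altman limits of agreement.

#' Per-participant device means
#'
#' For each participant and variable, the arithmetic mean of the
#' criterion readings (4 per session, positions 1/3/5/7) and of the
#' test readings (3 per session, positions 2/4/6). The `intersession`
#' scope averages the two session means, so each device contributes
#' equally per session.
#'
#' @param dataset a [study_dataset]
#' @param scope `"session1"`, `"session2"` or `"intersession"`
#' @param variables variables to include
#' @return data.frame with columns `participant_id`, `variable`,
#'   `scope`, `criterion_mean`, `test_mean`; participants lacking a
#'   complete series for the scope are excluded with a warning
#' @export
participant_means <- function(dataset,
                              scope = c("session1", "session2",
                                        "intersession"),
                              variables = ESH_VARIABLES) {
  stopifnot(inherits(dataset, "study_dataset"))
  scope <- match.arg(scope)
  sessions <- switch(scope, session1 = 1L, session2 = 2L,
                     intersession = c(1L, 2L))
  all_ids <- unique(dataset$readings$participant_id)
  out <- list()
  for (v in variables) {
    ids <- complete_participants(dataset, v, sessions)
    if (length(ids) < length(all_ids)) {
      warning(length(all_ids) - length(ids), " participant(s) excluded for ",
              v, " (", scope, "): incomplete series", call. = FALSE)
    }
    if (length(ids) == 0L) next
    crit <- test <- matrix(NA_real_, length(ids), length(sessions))
    for (j in seq_along(sessions)) {
      m <- series_matrix(dataset, sessions[j], v, ids)
      crit[, j] <- rowMeans(m[, CRITERION_POSITIONS, drop = FALSE])
      test[, j] <- rowMeans(m[, TEST_POSITIONS, drop = FALSE])
    }
    out[[v]] <- data.frame(participant_id = ids, variable = v,
                           scope = scope,
                           criterion_mean = rowMeans(crit),
                           test_mean = rowMeans(test),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Between-device comparison of participant means
#'
#' Compares test-device and criterion-device participant means per
#' variable. The default is an independent-samples t-test (the
#' conventional, conservative choice for device validation reports);
#' a paired test on the within-participant differences is available.
#'
#' @param means a [participant_means()] data.frame
#' @param mode `"independent"` (default) or `"paired"`
#' @return data.frame, one row per variable, with per-device mean and
#'   SD, `t`, `df`, `p`, `mode` and a `degenerate` flag (zero variance)
#' @export
device_mean_comparison <- function(means,
                                   mode = c("independent", "paired")) {
  mode <- match.arg(mode)
  rows <- lapply(split(means, means$variable), function(g) {
    x <- g$criterion_mean; y <- g$test_mean
    if (length(x) < 2L) stop("need n >= 2 per device", call. = FALSE)
    base <- data.frame(variable = g$variable[1L],
                       criterion_mean = mean(x), criterion_sd = sd(x),
                       test_mean = mean(y), test_sd = sd(y),
                       mode = mode, stringsAsFactors = FALSE)
    degenerate <- (mode == "independent" && sd(x) == 0 && sd(y) == 0) ||
      (mode == "paired" && sd(y - x) == 0)
    if (degenerate) {
      identical_means <- isTRUE(all.equal(mean(x), mean(y)))
      cbind(base, t = if (identical_means) 0 else NA_real_,
            df = NA_real_, p = if (identical_means) 1 else NA_real_,
            degenerate = !identical_means)
    } else {
      tt <- if (mode == "paired") t.test(y, x, paired = TRUE)
            else t.test(y, x, var.equal = FALSE)
      cbind(base, t = unname(tt$statistic), df = unname(tt$parameter),
            p = tt$p.value, degenerate = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pearson correlation between device means
#'
#' Product-moment correlation of the per-participant (criterion mean,
#' test mean) pairs, per variable, with a two-sided p-value from the
#' t transform.
#'
#' @param means a [participant_means()] data.frame
#' @return data.frame, one row per variable, with `n`, `r`, `p` and a
#'   `degenerate` flag (zero variance on either axis)
#' @export
device_correlation <- function(means) {
  rows <- lapply(split(means, means$variable), function(g) {
    x <- g$criterion_mean; y <- g$test_mean
    if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
    if (sd(x) == 0 || sd(y) == 0) {
      return(data.frame(variable = g$variable[1L], n = length(x),
                        r = NA_real_, p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(x, y)
    data.frame(variable = g$variable[1L], n = length(x),
               r = unname(ct$estimate), p = ct$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Bland-Altman agreement summary
#'
#' Per variable: bias (mean of test - criterion participant means), SD
#' of the differences, 1.96-SD limits of agreement, and the
#' per-participant (average, difference) point set for plotting.
#'
#' @param means a [participant_means()] data.frame
#' @return named list (one element per variable) of class
#'   `bland_altman`; each element holds `bias`, `sd_diff`, `loa_low`,
#'   `loa_high` and a `points` data.frame
#'   (`participant_id`, `variable`, `avg`, `diff`)
#' @export
bland_altman <- function(means) {
  out <- lapply(split(means, means$variable), function(g) {
    if (nrow(g) < 3L) stop("need n >= 3", call. = FALSE)
    d <- g$test_mean - g$criterion_mean
    a <- (g$test_mean + g$criterion_mean) / 2
    bias <- mean(d); sdd <- sd(d)
    list(variable = g$variable[1L], n = nrow(g),
         bias = bias, sd_diff = sdd,
         loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
         points = data.frame(participant_id = g$participant_id,
                             variable = g$variable[1L],
                             avg = a, diff = d,
                             stringsAsFactors = FALSE))
  })
  structure(out, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (test - criterion)\n")
  for (s in x) {
    cat(sprintf("  %-4s n=%d  bias %.2f  SD %.2f  LoA [%.2f, %.2f]\n",
                s$variable, s$n, s$bias, s$sd_diff, s$loa_low, s$loa_high))
  }
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, variable = NULL, ...) {
  s <- if (is.null(variable)) x[[1L]] else x[[variable]]
  unit <- if (s$variable == "HR") "bpm" else "mm Hg"
  plot(s$points$avg, s$points$diff,
       xlab = paste0("Mean of devices (", unit, ")"),
       ylab = paste0("Test - criterion (", unit, ")"),
       main = paste("Bland-Altman:", s$variable), ...)
  abline(h = c(s$bias, s$loa_low, s$loa_high),
         lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}
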