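## Test-retest reliability: two-way ANOVA intraclass correlation with
## F-based confidence intervals, standard error of measurement, paired
## t-tests across sessions, Monte-Carlo Lilliefors normality check.

#' Intraclass correlation for a subjects x measurements matrix
#'
#' Single-measures ICC from the two-way ANOVA decomposition of an
#' n x k repeated-measures matrix (participants in rows, repeated
#' readings in columns). The default model is two-way random effects
#' with absolute agreement — readings of an automatic device are
#' interchangeable "raters" and device validation cares about absolute
#' agreement, not mere consistency. 95% confidence bounds use the
#' F-distribution method; SEM is the pooled SD times sqrt(1 - ICC).
#'
#' @param m numeric matrix, n >= 2 rows (participants), k >= 2 columns
#'   (repeated measurements), no missing cells
#' @param model `"two_way_random_absolute"` (default) or
#'   `"two_way_mixed_consistency"`
#' @param conf_level confidence level for the interval (0.95)
#' @return an object of class `reliability_estimate` with elements
#'   `icc`, `ci_low`, `ci_high`, `sem`, `mean`, `sd`, `range`,
#'   `interpretation` (Landis-Koch label), `degenerate`, and the ANOVA
#'   mean squares
#' @export
icc_estimate <- function(m, model = c("two_way_random_absolute",
                                      "two_way_mixed_consistency"),
                         conf_level = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 rows and 2 columns", call. = FALSE)

  gm <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  pooled_sd <- sd(as.numeric(m))
  alpha <- 1 - conf_level

  if (sst < .Machine$double.eps * max(1, abs(gm)) || msr <= 0) {
    ## no variance anywhere: ICC undefined, flag rather than throw
    out <- list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                sem = NA_real_, mean = gm, sd = pooled_sd,
                range = range(m), n = n, k = k, model = model,
                ms = c(rows = msr, cols = msc, error = mse),
                interpretation = NA_character_, degenerate = TRUE)
    return(structure(out, class = "reliability_estimate"))
  }

  if (model == "two_way_random_absolute") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    ## F-based interval (two-way random, absolute agreement, single
    ## measures) with Satterthwaite degrees of freedom
    if (mse <= 0) {
      ci <- c(icc, icc)
    } else {
      fj <- msc / mse
      a <- k * icc * fj + n * (1 + (k - 1) * icc) - k * icc
      vn <- (k - 1) * (n - 1) * a^2
      vd <- (n - 1) * k^2 * icc^2 * fj^2 +
        (n * (1 + (k - 1) * icc) - k * icc)^2
      v <- vn / vd
      fu <- qf(1 - alpha / 2, n - 1, v)
      fl <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - fu * mse) /
        (fu * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fl * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fl * msr)
      ci <- c(lo, hi)
    }
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) {
      ci <- c(icc, icc)
    } else {
      f <- msr / mse
      df2 <- (n - 1) * (k - 1)
      fl <- f / qf(1 - alpha / 2, n - 1, df2)
      fu <- f * qf(1 - alpha / 2, df2, n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  }
  ci[1] <- min(ci[1], icc)
  ci[2] <- max(ci[2], icc)

  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 sem = sem_from_summary(pooled_sd, min(icc, 1)),
                 mean = gm, sd = pooled_sd, range = range(m),
                 n = n, k = k, model = model,
                 ms = c(rows = msr, cols = msc, error = mse),
                 interpretation = landis_koch(icc), degenerate = FALSE),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat("ICC undefined (no variance); degenerate result\n")
    return(invisible(x))
  }
  cat(sprintf("ICC (%s, single measures): %.3f (95%% CI %.3f-%.3f), %s\n",
              x$model, x$icc, x$ci_low, x$ci_high, x$interpretation))
  cat(sprintf("  mean %.2f (SD %.2f), range %.1f-%.1f, SEM %.2f  [n=%d, k=%d]\n",
              x$mean, x$sd, x$range[1], x$range[2], x$sem, x$n, x$k))
  invisible(x)
}

#' Landis-Koch agreement label for an ICC
#'
#' Slight (at most 0.20), fair (0.21-0.40), moderate (0.41-0.60),
#' substantial (0.61-0.80), almost perfect (0.81 and above). Values in
#' the open gap (0.80, 0.81) are labelled substantial.
#'
#' @param icc numeric ICC value
#' @return character label
#' @export
landis_koch <- function(icc) {
  vapply(icc, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x >= 0.81) "almost perfect"
    else if (x > 0.60) "substantial"
    else if (x > 0.40) "moderate"
    else if (x > 0.20) "fair"
    else "slight"
  }, character(1))
}

#' Standard error of measurement from summary statistics
#'
#' SEM = SD * sqrt(1 - ICC), in the variable's units.
#'
#' @param sd pooled standard deviation (non-negative)
#' @param icc intraclass correlation (at most 1)
#' @return the SEM
#' @export
sem_from_summary <- function(sd, icc) {
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  if (any(icc > 1)) stop("icc cannot exceed 1", call. = FALSE)
  sd * sqrt(1 - icc)
}

#' Paired t-test for systematic change between sessions
#'
#' Classical paired t on the within-participant differences of the two
#' session means. Identical sessions return t = 0, p = 1 by convention;
#' a constant non-zero shift (zero variance of differences) is reported
#' as a degenerate infinite-t result with p = 0.
#'
#' @param session1_means,session2_means paired numeric vectors
#' @return list with `t`, `df`, `p`, `mean_change` (session 2 - session
#'   1), `sd_change`, `degenerate`
#' @export
intersession_change_test <- function(session1_means, session2_means) {
  x <- as.numeric(session1_means); y <- as.numeric(session2_means)
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need equal-length paired vectors with n >= 2", call. = FALSE)
  }
  d <- y - x
  md <- mean(d); sdd <- sd(d); n <- length(d)
  if (sdd == 0) {
    if (md == 0) {
      return(list(t = 0, df = n - 1L, p = 1, mean_change = 0,
                  sd_change = 0, degenerate = FALSE))
    }
    return(list(t = sign(md) * Inf, df = n - 1L, p = 0, mean_change = md,
                sd_change = 0, degenerate = TRUE))
  }
  tt <- t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_change = md, sd_change = sdd,
       degenerate = FALSE)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' KS distance between the empirical distribution and a normal with the
#' sample's estimated mean and SD. Because the parameters are estimated,
#' the usual KS null distribution does not apply; the p-value is
#' computed by Monte Carlo, re-estimating the parameters in each normal
#' resample (the Lilliefors correction).
#'
#' @param values numeric vector, n >= 5
#' @param n_rep number of Monte-Carlo resamples (default 9999)
#' @param seed RNG seed for the resamples
#' @return list with `statistic` (the KS distance), `p`, `n_rep`,
#'   `degenerate`
#' @export
normality_check <- function(values, n_rep = 9999L, seed = 20101L) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 5L) stop("need at least 5 observations", call. = FALSE)
  if (sd(x) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, n_rep = 0L,
                degenerate = TRUE))
  }
  d_obs <- lilliefors_stat(x)
  d_null <- with_seed(seed, {
    vapply(seq_len(n_rep), function(i) lilliefors_stat(rnorm(n)),
           numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (n_rep + 1)
  list(statistic = d_obs, p = p, n_rep = as.integer(n_rep),
       degenerate = FALSE)
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

## evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
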