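## Synthetic validation-study generator. The generative model mirrors
## the alternating seven-reading protocol: subject true value (truncated
## normal), a subject x session shift, an independent serial fluctuation
## per position (readings are 2-3 minutes apart), device-specific noise,
## and an optional constant/proportional test-device bias. Each position
## has its own latent value: the flanking criterion readings bracket the
## test reading rather than sharing its instant.

## per-variable generative defaults: population scale per the baseline
## characteristics of a healthy adult validation cohort, eligibility
## truncation ranges, serial and device noise in the variable's units
default_variable_params <- function() {
  list(
    SBP = list(mean = 127, sd = 16, range = c(90, 180),
               within_subject_sd = 3.0, session_effect_sd = 2.0,
               criterion_noise_sd = 1.5, test_noise_sd = 1.5,
               test_bias = 0, test_proportional_bias = 0),
    DBP = list(mean = 74, sd = 10, range = c(40, 130),
               within_subject_sd = 3.0, session_effect_sd = 2.0,
               criterion_noise_sd = 1.5, test_noise_sd = 1.5,
               test_bias = 0, test_proportional_bias = 0),
    HR  = list(mean = 71, sd = 10, range = c(40, 180),
               within_subject_sd = 2.5, session_effect_sd = 2.0,
               criterion_noise_sd = 1.5, test_noise_sd = 1.5,
               test_bias = 0, test_proportional_bias = 0)
  )
}

#' Configuration of a synthetic validation study
#'
#' @param n_subjects number of recruited subjects (default 100)
#' @param seed default RNG seed used by [generate_study()] when none is
#'   passed explicitly
#' @param variables named list of per-variable parameter lists; entries
#'   given here override the defaults per field. Fields per variable:
#'   `mean`, `sd` (population distribution of the subject's true value),
#'   `range` (eligibility truncation of the true value),
#'   `within_subject_sd` (serial reading-to-reading fluctuation),
#'   `session_effect_sd` (subject x session shift),
#'   `criterion_noise_sd`, `test_noise_sd` (device error),
#'   `test_bias` (constant additive device bias),
#'   `test_proportional_bias` (slope on the centred true value).
#' @param dropout fraction completing only session 1 (default 0.2)
#' @param integer_rounding round readings to integers as real devices
#'   display them (default TRUE)
#' @param position_drift systematic linear change per position (units
#'   per step, default 0); blood pressure typically drifts down over a
#'   resting session
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(n_subjects = 100L, seed = 1L,
                              variables = list(), dropout = 0.2,
                              integer_rounding = TRUE,
                              position_drift = 0) {
  stopifnot(n_subjects >= 1, dropout >= 0, dropout < 1)
  vp <- default_variable_params()
  for (v in names(variables)) {
    v_name <- match.arg(v, ESH_VARIABLES)
    for (field in names(variables[[v]])) {
      stopifnot(field %in% names(vp[[v_name]]))
      vp[[v_name]][[field]] <- variables[[v]][[field]]
    }
  }
  for (v in names(vp)) {
    p <- vp[[v]]
    stopifnot(p$sd >= 0, p$within_subject_sd >= 0,
              p$session_effect_sd >= 0, p$criterion_noise_sd >= 0,
              p$test_noise_sd >= 0, p$range[1] < p$range[2])
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), variables = vp,
                 dropout = dropout,
                 integer_rounding = isTRUE(integer_rounding),
                 position_drift = position_drift),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation config: %d subjects, dropout %.0f%%, %s\n",
              x$n_subjects, 100 * x$dropout,
              if (x$integer_rounding) "integer readings" else "decimal readings"))
  for (v in names(x$variables)) {
    p <- x$variables[[v]]
    cat(sprintf("  %-4s true %s(%.0f, %.1f) in [%g,%g]; serial SD %.2f, session SD %.2f, device SD %.2f/%.2f, bias %.2f\n",
                v, "N", p$mean, p$sd, p$range[1], p$range[2],
                p$within_subject_sd, p$session_effect_sd,
                p$criterion_noise_sd, p$test_noise_sd, p$test_bias))
  }
  invisible(x)
}

## truncated-normal sampling via the inverse CDF
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and SD of N(mean, sd^2) truncated to
#' \[lower, upper\]; used to predict what the generator's subject-level
#' distribution (and hence the ICC) should look like.
#'
#' @param mean,sd parent normal parameters
#' @param lower,upper truncation bounds
#' @return list with `mean` and `sd` of the truncated distribution
#' @export
truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd; b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- dnorm(b)
  m <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

#' Generate a complete synthetic validation study
#'
#' Draws, per subject and variable, a true value from the truncated
#' population normal; per session a subject x session shift; per
#' position an independent serial fluctuation; then adds device noise
#' (and the configured test-device bias) to form the seven alternating
#' readings per session. A fixed fraction of subjects (chosen at
#' random) completes only session 1. Fully reproducible from the seed.
#'
#' @param config a [simulation_config()]
#' @param seed RNG seed; defaults to the config's own
#' @return a [study_dataset] with synthetic profiles and metadata
#'   recording the seed
#' @export
generate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  ids <- sprintf("P%03d", seq_len(n))
  with_seed(seed, {
    n_drop <- round(n * config$dropout)
    dropped <- if (n_drop > 0) sample(ids, n_drop) else character(0)

    frames <- vector("list", length(ESH_VARIABLES))
    names(frames) <- ESH_VARIABLES
    for (v in ESH_VARIABLES) {
      p <- config$variables[[v]]
      truth <- rtruncnorm(n, p$mean, p$sd, p$range[1], p$range[2])
      rows <- vector("list", 2L)
      for (s in 1:2) {
        shift <- rnorm(n, 0, p$session_effect_sd)
        latent <- truth + shift +
          matrix(rnorm(n * 7L, 0, p$within_subject_sd), n, 7L)
        if (config$position_drift != 0) {
          latent <- latent + config$position_drift *
            matrix(0:6, n, 7L, byrow = TRUE)
        }
        value <- latent
        value[, CRITERION_POSITIONS] <- value[, CRITERION_POSITIONS] +
          matrix(rnorm(n * 4L, 0, p$criterion_noise_sd), n, 4L)
        value[, TEST_POSITIONS] <- value[, TEST_POSITIONS] +
          p$test_bias + p$test_proportional_bias * (truth - p$mean) +
          matrix(rnorm(n * 3L, 0, p$test_noise_sd), n, 3L)
        if (config$integer_rounding) value <- round(value)
        rows[[s]] <- data.frame(
          participant_id = rep(ids, 7L),
          session = s,
          position = rep(1:7, each = n),
          device = rep(device_for_position(1:7), each = n),
          variable = v,
          value = as.numeric(value),
          stringsAsFactors = FALSE)
      }
      frames[[v]] <- rbind(rows[[1L]], rows[[2L]])
    }
    readings <- do.call(rbind, frames)
    readings <- readings[!(readings$participant_id %in% dropped &
                             readings$session == 2L), , drop = FALSE]
    row.names(readings) <- NULL

    profiles <- synthetic_profiles(ids)
    suppressWarnings(
      ds <- study_dataset(readings, profiles = profiles,
                          metadata = list(generator = "eshval synthetic",
                                          seed = seed,
                                          dropped = dropped))
    )
    ds
  })
}

## synthetic cohort demographics on the scale of a healthy adult
## validation sample (about one third male; ages 25+)
synthetic_profiles <- function(ids) {
  n <- length(ids)
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(0.37, 0.63))
  height <- rnorm(n, ifelse(sex == "male", 172, 164.5), 7.3)
  weight <- rnorm(n, ifelse(sex == "male", 84.6, 71.3), 13.2)
  data.frame(participant_id = ids, sex = sex,
             age = round(rtruncnorm(n, 52, 19, 25, 90)),
             weight_kg = round(weight, 1),
             height_cm = round(height, 1),
             arm_circ_mm = round(rtruncnorm(n, 295, 35, 220, 320)),
             stringsAsFactors = FALSE)
}

#' Load a packaged simulation scenario
#'
#' Scenario files are YAML descriptions of a [simulation_config()].
#' Three are shipped: `paper_like` (a zero-bias, low-noise device whose
#' difference distribution is calibrated to a published passing study),
#' `biased_device` (constant +20 mm Hg / +10 bpm test bias) and
#' `noisy_device` (6 mm Hg constant bias with 4 mm Hg device noise).
#'
#' @param name scenario name or a path to a YAML scenario file
#' @return a [simulation_config()]
#' @export
esh_scenario <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "eshval")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown scenario: ", name, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  simulation_config(
    n_subjects = y$n_subjects %||% 100L,
    seed = y$seed %||% 1L,
    variables = y$variables %||% list(),
    dropout = y$dropout %||% 0.2,
    integer_rounding = y$integer_rounding %||% TRUE,
    position_drift = y$position_drift %||% 0)
}

#' Pass probability of the ESH decision under a scenario
#'
#' Monte-Carlo operating characteristic of the validation rule: runs
#' [generate_study()] and [validate_device()] on `n_replicates`
#' independently seeded studies and reports the fraction passing with
#' an exact (Clopper-Pearson) 95% confidence interval.
#'
#' @param config a [simulation_config()]
#' @param n_replicates number of replicate studies (>= 1)
#' @param seed master seed from which per-replicate seeds are derived
#' @return list with `pass_fraction`, `n_pass`, `n_replicates`,
#'   `ci_low`, `ci_high`
#' @export
pass_probability <- function(config, n_replicates, seed = config$seed) {
  stopifnot(n_replicates >= 1)
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max, n_replicates))
  passes <- vapply(seeds, function(s) {
    ds <- generate_study(config, seed = s)
    v <- validate_device(ds)
    v$overall == "pass"
  }, logical(1))
  x <- sum(passes)
  list(pass_fraction = x / n_replicates, n_pass = x,
       n_replicates = as.integer(n_replicates),
       ci_low = if (x == 0) 0 else qbeta(0.025, x, n_replicates - x + 1),
       ci_high = if (x == n_replicates) 1 else
         qbeta(0.975, x + 1, n_replicates - x))
}
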