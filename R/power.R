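## Paired-design sample size with attrition inflation, and its inverse.

#' Sample size for detecting a mean paired difference
#'
#' Normal-approximation sample size for a two-sided paired t design:
#' n = ceiling(((z_{1-alpha/2} + z_{power}) * sigma / delta)^2),
#' inflated for anticipated loss to follow-up by dividing by
#' (1 - attrition) and ceiling. With delta 0.9 mm Hg, sigma 3.2 mm Hg,
#' alpha 0.05, power 0.80 and 20% attrition this gives 100 completers
#' and 125 recruits. A noncentral-t iteration is available via
#' `method = "t"`; it typically asks for one or two more subjects.
#'
#' @param delta minimum detectable mean difference (> 0), in the
#'   variable's units
#' @param sigma SD of the paired differences (> 0)
#' @param alpha two-sided type-I error rate
#' @param power target power (1 - beta)
#' @param attrition anticipated loss-to-follow-up fraction in [0, 1)
#' @param method `"normal"` (default) or `"t"` (noncentral-t iteration)
#' @return list with `n_effective` (completers) and `n_recruit`
#' @export
paired_sample_size <- function(delta, sigma, alpha = 0.05, power = 0.80,
                               attrition = 0, method = c("normal", "t")) {
  method <- match.arg(method)
  if (delta <= 0) stop("delta must be positive (delta = 0 needs infinite n)",
                       call. = FALSE)
  stopifnot(sigma > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            attrition >= 0, attrition < 1)
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  n_eff <- ceiling((z * sigma / delta)^2)
  if (method == "t") {
    ## smallest n whose noncentral-t power reaches the target
    n <- max(2, n_eff - 2)
    repeat {
      ncp <- delta / (sigma / sqrt(n))
      crit <- qt(1 - alpha / 2, n - 1)
      pw <- 1 - pt(crit, n - 1, ncp) + pt(-crit, n - 1, ncp)
      if (pw >= power) break
      n <- n + 1
    }
    n_eff <- n
  }
  list(n_effective = as.integer(n_eff),
       n_recruit = as.integer(ceiling(n_eff / (1 - attrition))))
}

#' Power achieved by a paired design of size n
#'
#' Normal-approximation inverse of [paired_sample_size()]:
#' power = Phi(delta / (sigma / sqrt(n)) - z_{1-alpha/2}).
#'
#' @param n number of completers (>= 2)
#' @param delta true mean difference
#' @param sigma SD of the paired differences
#' @param alpha two-sided type-I error rate
#' @return power estimate in (0, 1)
#' @export
achieved_power <- function(n, delta, sigma, alpha = 0.05) {
  stopifnot(n >= 2, sigma > 0, alpha > 0, alpha < 1)
  pnorm(abs(delta) / (sigma / sqrt(n)) - qnorm(1 - alpha / 2))
}
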