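#' Poisson conversion of a per-CNV gene-count odds ratio to SD units
#'
#' Converts a multiplicative case effect on a Poisson-distributed count
#' (e.g. genes affected per rare CNV, control mean 2.2, case ratio 1.21)
#' into a standardized mean difference using the control-group SD
#' (`sqrt` of the control mean): `control_mean * (ratio - 1) /
#' sqrt(control_mean)`. With the schizophrenia-burden inputs (2.2, 1.21)
#' this gives ~0.3 SD units.
#'
#' @param control_mean mean count in controls (> 0).
#' @param ratio multiplicative case effect (> 0); 1 = null.
#' @return standardized difference in SD units.
#' @examples
#' poissonEffectSd(2.2, 1.21)  # ~0.31
#' @export
poissonEffectSd <- function(control_mean, ratio) {
  if (!is.numeric(control_mean) || any(control_mean <= 0))
    stop("control_mean must be positive")
  if (!is.numeric(ratio) || any(ratio <= 0))
    stop("ratio must be positive")
  control_mean * (ratio - 1) / sqrt(control_mean)
}

#' Two-sample normal-approximation power for a standardized difference
#'
#' Power of the two-sample z-test for a standardized mean difference
#' `effect_sd` between groups of `n1` and `n2`:
#' `Phi(effect_sd / sqrt(1/n1 + 1/n2) - z_alpha)`, with `z_alpha` the
#' one- or two-sided critical value. One-sided is the default since
#' burden hypotheses are directional. At the null (`effect_sd = 0`) the
#' power equals `alpha` (one-sided).
#'
#' @param n1,n2 group sizes.
#' @param effect_sd standardized difference (>= 0).
#' @param alpha significance level.
#' @param sided `"one"` or `"two"`.
#' @return power in `[0, 1]`.
#' @examples
#' twoSamplePower(7414, 5044, 0.3)    # ~1
#' twoSamplePower(7414, 5044, 0.05)   # > 0.80
#' @export
twoSamplePower <- function(n1, n2, effect_sd, alpha = 0.05,
                           sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(alpha > 0, alpha < 1, effect_sd >= 0, n1 > 0, n2 > 0)
  z <- qnorm(1 - alpha / ifelse(sided == "one", 1, 2))
  pnorm(effect_sd / sqrt(1 / n1 + 1 / n2) - z)
}

#' Monte-Carlo check of the two-sample power approximation
#'
#' Simulates `nsim` two-sample z statistics (group means drawn from
#' their exact normal sampling distributions under unit within-group SD)
#' and returns the rejection fraction, for cross-checking
#' [twoSamplePower()].
#'
#' @inheritParams twoSamplePower
#' @param nsim number of simulated statistics.
#' @return empirical power.
#' @export
mcTwoSamplePower <- function(n1, n2, effect_sd, alpha = 0.05,
                             sided = c("one", "two"), nsim = 1e5) {
  sided <- match.arg(sided)
  se <- sqrt(1 / n1 + 1 / n2)
  z <- (effect_sd + rnorm(nsim, 0, sqrt(1 / n1)) -
          rnorm(nsim, 0, sqrt(1 / n2))) / se
  if (sided == "one") mean(z > qnorm(1 - alpha))
  else mean(abs(z) > qnorm(1 - alpha / 2))
}

#' Burden power table over a grid of effect sizes
#'
#' @inheritParams twoSamplePower
#' @param effects vector of standardized differences.
#' @return `data.frame` with one row per effect size.
#' @export
powerTable <- function(n1, n2, effects = c(0.05, 0.1, 0.2, 0.3),
                       alpha = 0.05, sided = "one") {
  data.frame(n_cases = n1, n_controls = n2, effect_sd = effects,
             alpha = alpha, sided = sided,
             power = vapply(effects, function(e)
               twoSamplePower(n1, n2, e, alpha, sided), 0))
}
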