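# Synthetic recurrent-GBM patient cohort: RAD18 expression correlated with
# proliferation at a target Pearson r, hypermutation drawn from a logistic
# model on proliferation-adjusted RAD18 and MGMT status, Signature-11
# mutation counts consistent with the strict >500 hypermutation rule.

#' Cohort design
#'
#' @param n_samples Cohort size (default 72, the scale at which a Pearson
#'   correlation of 0.75 reaches p ~ 1e-14).
#' @param rho Target RAD18-proliferation correlation, |rho| < 1 (default
#'   0.75).
#' @param beta0,beta_rad18,beta_mgmt Logistic coefficients on the logit
#'   scale for intercept, proliferation-adjusted RAD18 expression, and the
#'   MGMT-low indicator (defaults -2, -1.5, +2: hypermutation is enriched
#'   at low adjusted RAD18 and low MGMT).
#' @param mgmt_low_fraction Proportion of MGMT-low samples in `[0, 1]`
#'   (default 0.5).
#' @param pole_fraction Proportion of POLE-mutant samples (default 0; such
#'   samples are excluded before modelling when present).
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_samples = 72, rho = 0.75, beta0 = -2,
                          beta_rad18 = -1.5, beta_mgmt = 2,
                          mgmt_low_fraction = 0.5, pole_fraction = 0) {
  stopifnot(n_samples >= 3, abs(rho) < 1,
            mgmt_low_fraction >= 0, mgmt_low_fraction <= 1,
            pole_fraction >= 0, pole_fraction <= 1)
  structure(
    list(n_samples = as.integer(n_samples), rho = rho, beta0 = beta0,
         beta_rad18 = beta_rad18, beta_mgmt = beta_mgmt,
         mgmt_low_fraction = mgmt_low_fraction,
         pole_fraction = pole_fraction),
    class = "cohort_design"
  )
}

#' Simulate a patient cohort with known hypermutation model
#'
#' Proliferation scores are standard normal; RAD18 expression is
#' `rho * proliferation + sqrt(1 - rho^2) * noise`, so the population
#' correlation is exactly `rho`. Hypermutation is Bernoulli with logit
#' `beta0 + beta_rad18 * adj + beta_mgmt * mgmt_low`, where `adj` is the
#' true proliferation-independent RAD18 component. Signature-11 counts are
#' drawn above 500 for hypermutant samples and at or below 500 otherwise,
#' consistent with the strict classification rule.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @return List with `cohort` (tibble: `sample`, `rad18`, `proliferation`,
#'   `mgmt` low/high factor, `mgmt_low`, `pole_mutant`, `sig11_count`,
#'   `hypermutant`) and `truth` (the generating coefficients).
#' @export
sim_cohort <- function(design = cohort_design(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  run <- function() {
    n <- design$n_samples
    prolif <- rnorm(n)
    adj_true <- sqrt(1 - design$rho^2) * rnorm(n)
    rad18 <- design$rho * prolif + adj_true
    mgmt_low <- as.integer(runif(n) < design$mgmt_low_fraction)
    pole <- runif(n) < design$pole_fraction
    eta <- design$beta0 + design$beta_rad18 * adj_true +
      design$beta_mgmt * mgmt_low
    hyper <- runif(n) < plogis(eta)
    sig11 <- integer(n)
    sig11[hyper] <- 501L + rnbinom(sum(hyper), size = 5, mu = 400)
    sig11[!hyper] <- pmin(500L, rnbinom(sum(!hyper), size = 5, mu = 150))
    list(
      cohort = tibble(
        sample = sprintf("pt%03d", seq_len(n)),
        rad18 = rad18, proliferation = prolif,
        mgmt = factor(ifelse(mgmt_low == 1, "low", "high"),
                      levels = c("high", "low")),
        mgmt_low = mgmt_low, pole_mutant = pole,
        sig11_count = sig11, hypermutant = hyper
      ),
      truth = tibble(
        beta0 = design$beta0, beta_rad18 = design$beta_rad18,
        beta_mgmt = design$beta_mgmt, rho = design$rho
      )
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
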