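#' Prior / variability distribution specification
#'
#' Three families are used throughout: lognormal specified by geometric
#' mean and geometric SD, uniform by min and max, and halfnormal (mean
#' zero) by its SD.  Internally the lognormal is stored as
#' (log-median, log-SD = log geometric SD).
#'
#' @param family one of `"lognormal"`, `"uniform"`, `"halfnormal"`.
#' @param gm,gsd geometric mean (> 0) and geometric SD (> 1), lognormal.
#' @param min,max support bounds, uniform (`max > min`).
#' @param sd scale (> 0), halfnormal.
#' @return object of class `prior_spec`.
#' @examples
#' sp <- prior_spec("lognormal", gm = 1.33e-7, gsd = 1.2)
#' median(sample_prior(sp, 1e4, seed = 1))
#' @export
prior_spec <- function(family = c("lognormal", "uniform", "halfnormal"),
                       gm = NULL, gsd = NULL, min = NULL, max = NULL,
                       sd = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    lognormal = {
      stopifnot(gm > 0, gsd > 1)
      list(family = family, meanlog = log(gm), sdlog = log(gsd))
    },
    uniform = {
      stopifnot(max > min)
      list(family = family, min = min, max = max)
    },
    halfnormal = {
      stopifnot(sd > 0)
      list(family = family, sd = sd)
    })
  structure(spec, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(switch(x$family,
    lognormal = sprintf("LN(gm = %g, gsd = %g)", exp(x$meanlog), exp(x$sdlog)),
    uniform = sprintf("U(%g, %g)", x$min, x$max),
    halfnormal = sprintf("HN(sd = %g)", x$sd)), "\n")
  invisible(x)
}

#' Log prior density
#'
#' @param spec a [prior_spec()].
#' @param x values.
#' @return log density (`-Inf` outside the support).
#' @export
dprior <- function(spec, x) {
  stopifnot(inherits(spec, "prior_spec"))
  switch(spec$family,
    lognormal = dlnorm(x, spec$meanlog, spec$sdlog, log = TRUE),
    uniform = dunif(x, spec$min, spec$max, log = TRUE),
    halfnormal = ifelse(x < 0, -Inf,
                        log(2) + dnorm(x, 0, spec$sd, log = TRUE)))
}

#' Draw from a prior / variability distribution
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @param seed optional integer; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return numeric vector of length `n`.
#' @export
sample_prior <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), n >= 1)
  .with_seed(seed, switch(spec$family,
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    uniform = runif(n, spec$min, spec$max),
    halfnormal = abs(rnorm(n, 0, spec$sd))))
}

#' Prior quantiles
#' @param spec a [prior_spec()].
#' @param p probabilities.
#' @return quantiles of the prior.
#' @export
qprior <- function(spec, p) {
  switch(spec$family,
    lognormal = stats::qlnorm(p, spec$meanlog, spec$sdlog),
    uniform = stats::qunif(p, spec$min, spec$max),
    halfnormal = stats::qnorm((1 + p) / 2, 0, spec$sd))
}

#' Priors of the calibrated in vitro model
#'
#' The ten kinetic/regulatory parameters (two FSH slope factors, four
#' Vmax, four Km), the inter-study hyperparameters (`mu0`, `Sigma1`) and
#' the two measurement-error scales (`Sigma2` for mRNA/protein
#' endpoints, `Sigma3` for hormone endpoints).  `Sigma1`–`Sigma3` are
#' log-scale standard deviations.
#'
#' @param n_studies number of studies in the calibration collection
#'   (one random effect `sigma_L` each).
#' @return list with `top` (named list of [prior_spec()]) and
#'   `n_studies`.
#' @export
calibration_priors <- function(n_studies = 10) {
  stopifnot(n_studies >= 1)
  list(top = list(
    kappa_Cyp19       = prior_spec("uniform", min = 0, max = 1e7),
    kappa_Hsd17b1     = prior_spec("uniform", min = 0, max = 1e6),
    lambda_Cyp19_A    = prior_spec("lognormal", gm = 1.33e-7, gsd = 1.2),
    lambda_Cyp19_T    = prior_spec("lognormal", gm = 1.33e-7, gsd = 2.0),
    lambda_Hsd17b1_A  = prior_spec("lognormal", gm = 7.59e-8, gsd = 2.0),
    lambda_Hsd17b1_E1 = prior_spec("lognormal", gm = 1.03e-5, gsd = 2.0),
    xi_Cyp19_A        = prior_spec("lognormal", gm = 8.10e-9, gsd = 1.2),
    xi_Cyp19_T        = prior_spec("lognormal", gm = 3.24e-8, gsd = 2.0),
    xi_Hsd17b1_A      = prior_spec("lognormal", gm = 4.32e-5, gsd = 2.0),
    xi_Hsd17b1_E1     = prior_spec("lognormal", gm = 5.29e-6, gsd = 2.0),
    mu0               = prior_spec("lognormal", gm = 1, gsd = 2.0),
    Sigma1            = prior_spec("halfnormal", sd = 0.5),
    Sigma2            = prior_spec("halfnormal", sd = 0.2),
    Sigma3            = prior_spec("halfnormal", sd = 0.2)),
    n_studies = n_studies)
}

# canonical parameter-vector names for a calibration with n studies
.sampled_names <- function(n_studies) {
  c("kappa_Cyp19", "kappa_Hsd17b1",
    "lambda_Cyp19_A", "lambda_Cyp19_T", "lambda_Hsd17b1_A",
    "lambda_Hsd17b1_E1", "xi_Cyp19_A", "xi_Cyp19_T", "xi_Hsd17b1_A",
    "xi_Hsd17b1_E1", "mu0", "Sigma1",
    paste0("sigma_L", seq_len(n_studies)), "Sigma2", "Sigma3")
}

.theta_names <- function() .sampled_names(0)[1:10]

#' Posterior maximum a posteriori estimates of the calibrated model
#'
#' The full 24-component sampled vector (10 studies) at its posterior
#' mode, as shipped: useful as a ground truth for synthetic-data
#' generation and as the deterministic parameter choice for flux
#' analyses.
#'
#' @return named numeric vector (length 24).
#' @export
map_estimates <- function() {
  c(kappa_Cyp19 = 2.08e6, kappa_Hsd17b1 = 6.04e5,
    lambda_Cyp19_A = 1.07e-7, lambda_Cyp19_T = 2.67e-7,
    lambda_Hsd17b1_A = 5.65e-8, lambda_Hsd17b1_E1 = 1.78e-5,
    xi_Cyp19_A = 8.25e-9, xi_Cyp19_T = 1.24e-8,
    xi_Hsd17b1_A = 4.84e-5, xi_Hsd17b1_E1 = 1.30e-6,
    mu0 = 1.46, Sigma1 = 0.265,
    sigma_L1 = 0.117, sigma_L2 = 1.99, sigma_L3 = 0.0293,
    sigma_L4 = 0.0193, sigma_L5 = 2.86, sigma_L6 = 0.0213,
    sigma_L7 = 0.153, sigma_L8 = 0.612, sigma_L9 = 0.114,
    sigma_L10 = 0.685,
    Sigma2 = 0.626, Sigma3 = 0.501)
}

#' In vivo variability distributions
#'
#' Parameters that are not calibrated from in vitro data but vary
#' between animals; used by the Monte-Carlo layer of the in vivo
#' simulations.  All lognormal (geometric mean, geometric SD).
#'
#' @return named list of [prior_spec()] objects.
#' @export
invivo_variability_priors <- function() {
  ln <- function(gm, gsd) prior_spec("lognormal", gm = gm, gsd = gsd)
  list(
    Q_base_FSH  = ln(330, 1.2),  Q_scale_FSH = ln(1450, 1.2),
    Q_base_A    = ln(1.2, 1.2),  Q_scale_A   = ln(18, 1.2),
    Q_base_T    = ln(3, 1.2),    Q_scale_T   = ln(13, 1.2),
    F_ov        = ln(0.2654, 1.1),
    K_out_A     = ln(1e-8, 2.0), R_oi_A      = ln(0.0124, 1.2),
    K_out_T     = ln(1e-8, 2.0), R_oi_T      = ln(0.0130, 1.2),
    K_out_E1    = ln(1e-8, 2.0), R_oi_E1     = ln(0.0084, 1.2),
    K_out_E2    = ln(1e-8, 2.0), R_oi_E2     = ln(0.0108, 1.2),
    delta_mRNA  = ln(0.006, 1.2), delta_prot = ln(0.003, 1.2),
    nu_mRNA_Cyp19   = ln(3e-10, 1.2),
    nu_mRNA_Hsd17b1 = ln(6e-10, 1.2),
    nu_mRNA_Hsd17b2 = ln(4.2e-11, 1.2),
    nu_prot_Cyp19   = ln(6000, 1.2),
    nu_prot_Hsd17b1 = ln(6300, 1.2),
    nu_prot_Hsd17b2 = ln(6000, 1.2),
    lambda_Hsd17b2_T  = ln(6.65e-8, 2.0),
    lambda_Hsd17b2_E2 = ln(7.91e-6, 2.0),
    xi_Hsd17b2_T      = ln(5.67e-8, 2.0),
    xi_Hsd17b2_E2     = ln(5.40e-6, 2.0))
}
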