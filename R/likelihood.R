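#' Log prior density of a sampled parameter vector
#'
#' Sum of the top-level prior log densities (ten kinetic/regulatory
#' parameters, hyperparameters `mu0` and `Sigma1`, error scales
#' `Sigma2`, `Sigma3`) plus the hierarchical terms of the per-study
#' transcription factors, `log sigma_L ~ N(log mu0, Sigma1^2)`.
#' Returns `-Inf` outside the joint support.
#'
#' @param v named sampled vector (see [map_estimates()] for the layout).
#' @param priors a [calibration_priors()] list.
#' @return scalar log density.
#' @export
log_prior <- function(v, priors) {
  top <- priors$top
  lp <- 0
  for (nm in names(top)) lp <- lp + dprior(top[[nm]], v[[nm]])
  sl <- v[grep("^sigma_L", names(v))]
  if (length(sl)) {
    if (v[["Sigma1"]] <= 0 || v[["mu0"]] <= 0) return(-Inf)
    lp <- lp + sum(dlnorm(sl, log(v[["mu0"]]), v[["Sigma1"]], log = TRUE))
  }
  if (!is.finite(lp)) return(-Inf)
  lp
}

#' Log likelihood of calibration data
#'
#' Observations are lognormal around the model predictions:
#' `log(obs) ~ N(log(pred), Sigma^2)` with `Sigma = Sigma2` for
#' mRNA/protein endpoints and `Sigma3` for hormone endpoints.
#' Predictions for study `i` are computed under that study's
#' `sigma_L<i>`; one model solve is shared by all observations of a
#' condition.
#'
#' @param v named sampled vector (kinetics, hyperparameters, per-study
#'   `sigma_L<i>`, `Sigma2`, `Sigma3`).
#' @param data a [calibration_data()] table.
#' @param params base [gc_parameters()].
#' @param rtol,atol reduced-model error control.
#' @return scalar log likelihood; `-Inf` (with a `diagnostic`
#'   attribute) if any prediction is non-positive.
#' @export
log_likelihood <- function(v, data, params = gc_parameters(),
                           rtol = 3e-4, atol = 1e-11) {
  data <- calibration_data(data)
  if (v[["Sigma2"]] <= 0 || v[["Sigma3"]] <= 0) return(-Inf)
  studies <- unique(data$study)
  ll <- 0
  for (i in seq_along(studies)) {
    rows <- data[data$study == studies[i], ]
    sl <- v[[paste0("sigma_L", i)]]
    pred <- predict_endpoints(v[.theta_names()], sl, rows, params,
                              rtol, atol)
    if (any(!is.finite(pred) | pred <= 0)) {
      out <- -Inf
      attr(out, "diagnostic") <- paste("non-positive prediction in study",
                                       studies[i])
      return(out)
    }
    sdlog <- ifelse(rows$endpoint_class == "hormone",
                    v[["Sigma3"]], v[["Sigma2"]])
    ll <- ll + sum(dnorm(log(rows$value), log(pred), sdlog, log = TRUE))
  }
  ll
}
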