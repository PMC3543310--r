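#' Endocrine-disruptor exposure scenario
#'
#' A scenario carries the in vitro measured perturbations of one
#' chemical: transcription fold-changes for the two FSH-inducible
#' enzymes and the direct aromatase activity fold (converted to the Km
#' fold `f_M` via [km_fold_change()]).  In vivo, the folds switch on at
#' a cycle-anchored exposure time (default 8 h after the start of the
#' second modelled diestrus) and the readout is taken 6 h later,
#' matching the sacrifice time of the exposure experiments.
#'
#' @param name chemical name.
#' @param f_cyp19,f_hsd17b1 mRNA-synthesis fold-changes (unmeasured
#'   entries default to 1).
#' @param activity_fold direct aromatase activity fold-change.
#' @param start_delay exposure start, minutes after diestrus onset.
#' @param readout_delay readout, minutes after exposure start.
#' @return object of class `edc_scenario`.
#' @export
edc_scenario <- function(name, f_cyp19 = 1, f_hsd17b1 = 1,
                         activity_fold = 1, start_delay = 480,
                         readout_delay = 360) {
  structure(list(name = name,
                 fc = fold_changes(f_cyp19, f_hsd17b1,
                                   km_fold_change(activity_fold)),
                 activity_fold = activity_fold,
                 start_delay = start_delay,
                 readout_delay = readout_delay),
            class = "edc_scenario")
}

#' @export
print.edc_scenario <- function(x, ...) {
  cat(sprintf("<edc_scenario> %s: f_Cyp19 = %g, f_Hsd17b1 = %g, f_M = %g\n",
              x$name, x$fc[["cyp19"]], x$fc[["hsd17b1"]], x$fc[["km"]]))
  invisible(x)
}

#' Bundled exposure scenarios
#'
#' The five reference chemicals with their measured granulosa-cell
#' fold-changes (mRNA levels at 4 h, direct aromatase activity on
#' microsomes).  By default all measured values are applied;
#' `significant_only = TRUE` resets the folds that were not
#' statistically distinguishable from control to 1.  The aromatase
#' inhibitor letrozole has no mRNA measurements: only its activity fold
#' (0.29, i.e. `f_M` = 3.45) is applied.
#'
#' @param significant_only apply only statistically significant folds.
#' @return named list of [edc_scenario()] objects: `atrazine`,
#'   `bisphenol_a`, `hpte`, `vinclozolin_m2`, `letrozole`.
#' @export
edc_scenarios <- function(significant_only = FALSE) {
  # (activity fold, Cyp19 mRNA fold, Hsd17b1 mRNA fold, significance)
  tab <- list(
    atrazine       = list(0.99, 1.94, 3.04, c(FALSE, TRUE,  TRUE)),
    bisphenol_a    = list(0.94, 1.61, 1.41, c(FALSE, TRUE,  FALSE)),
    hpte           = list(0.89, 1.06, 1.32, c(TRUE,  FALSE, FALSE)),
    vinclozolin_m2 = list(0.98, 3.13, 1.61, c(FALSE, TRUE,  TRUE)),
    letrozole      = list(0.29, 1,    1,    c(TRUE,  FALSE, FALSE)))
  out <- lapply(names(tab), function(nm) {
    e <- tab[[nm]]
    act <- e[[1]]; fc <- e[[2]]; fh <- e[[3]]
    if (significant_only) {
      if (!e[[4]][1]) act <- 1
      if (!e[[4]][2]) fc <- 1
      if (!e[[4]][3]) fh <- 1
    }
    edc_scenario(nm, fc, fh, act)
  })
  setNames(out, names(tab))
}

#' Ovarian estradiol at the exposure readout
#'
#' Convenience extractor: whole-ovary E2 concentration at the readout
#' time of an exposure simulation (or at the equivalent time of an
#' unexposed control).
#'
#' @param traj a `gc_invivo_trajectory` from [simulate_cycle()].
#' @param readout_time readout time (min); default the trajectory's
#'   recorded readout.
#' @return E2 concentration (pmoles/ml ovary).
#' @export
e2_at_readout <- function(traj, readout_time = NULL) {
  if (is.null(readout_time)) {
    et <- attr(traj, "edc_times")
    if (is.null(et)) stop("trajectory has no exposure times; give ",
                          "readout_time explicitly")
    readout_time <- et[["readout"]]
  }
  unname(ovarian_concentrations(traj, readout_time)[["E2"]])
}

#' Monte-Carlo distribution of ovarian estradiol under exposure
#'
#' For each draw, one posterior kinetic/regulatory vector is combined
#' with one draw from each in vivo variability distribution; the ovary
#' is simulated with and without the exposure scenario using the same
#' draw, and the whole-ovary E2 concentration at the readout time is
#' recorded for both.  The paired control makes direction-of-effect
#' comparisons free of Monte-Carlo coupling noise.
#'
#' @param scenario an [edc_scenario()].
#' @param posterior_samples matrix of sampled vectors (or `NULL` to fix
#'   the kinetics at `params`).
#' @param invivo_priors named list of [prior_spec()]; `list()` disables
#'   variability.
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @param params base [gc_parameters()].
#' @param template a [cycle_template()].
#' @param n_cycles cycles simulated (exposure in the second).
#' @return list of class `edc_prediction`: `treated` and `control` E2
#'   samples (pmoles/ml), `quartiles` of both, and the scenario.
#' @export
predict_edc_distribution <- function(scenario, posterior_samples = NULL,
                                     invivo_priors =
                                       invivo_variability_priors(),
                                     n = 100, seed = 1,
                                     params = gc_parameters(),
                                     template = cycle_template(),
                                     n_cycles = 2) {
  stopifnot(inherits(scenario, "edc_scenario"), n >= 1)
  treated <- control <- numeric(n)
  .with_seed(seed, {
    for (i in seq_len(n)) {
      p_i <- params
      if (!is.null(posterior_samples)) {
        row <- posterior_samples[sample.int(nrow(posterior_samples), 1), ]
        p_i <- .apply_theta(p_i, row)
      }
      var_draw <- lapply(invivo_priors, sample_prior, n = 1)
      ap <- .apply_variability(p_i, template, var_draw)
      tr1 <- suppressWarnings(simulate_cycle(ap$params, ap$template,
                                             n_cycles = n_cycles,
                                             edc = scenario))
      rt <- attr(tr1, "edc_times")[["readout"]]
      tr0 <- suppressWarnings(simulate_cycle(ap$params, ap$template,
                                             n_cycles = n_cycles))
      treated[i] <- e2_at_readout(tr1)
      control[i] <- e2_at_readout(tr0, rt)
    }
  })
  structure(list(
    scenario = scenario, treated = treated, control = control,
    quartiles = rbind(treated = quantile(treated, c(0.25, 0.5, 0.75)),
                      control = quantile(control, c(0.25, 0.5, 0.75)))),
    class = "edc_prediction")
}

#' @export
print.edc_prediction <- function(x, ...) {
  cat("<edc_prediction>", x$scenario$name, "(n =", length(x$treated), ")\n")
  print(signif(x$quartiles, 4))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares predicted and observed distributions: the statistic is the
#' supremum distance between the empirical CDFs; the p-value is exact
#' for small samples without ties and asymptotic otherwise (the
#' standard two-sample procedure of `stats::ks.test`).
#'
#' @param x,y numeric samples (non-empty).
#' @return named vector `c(D = statistic, p = p.value)`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  kt <- suppressWarnings(ks.test(x, y))
  c(D = unname(kt$statistic), p = unname(kt$p.value))
}
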