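#' Cyclic hormone input into the ovary
#'
#' Blood-borne input rate of FSH or androgens, modelled as a constant
#' baseline plus a scaled periodic template:
#' `Q_input(t) = Q_base + Q_scale * Q_shape(t mod period)`.
#'
#' @param Q_base baseline input rate (pg/min for FSH, pmoles/min for
#'   steroids).
#' @param Q_scale unitless magnitude of the cyclic part.
#' @param shape either a function of cycle time (min) or a two-column
#'   matrix/data.frame of sampled `(time, value)` pairs interpolated
#'   periodically; conventionally unit peak.
#' @param period cycle length (min); default the 4-day rat estrous
#'   cycle.
#' @return object of class `cyclic_input`.
#' @export
cyclic_input <- function(Q_base, Q_scale, shape = function(t) 0,
                         period = 5760) {
  stopifnot(Q_base >= 0, Q_scale >= 0, period > 0)
  if (is.data.frame(shape) || is.matrix(shape)) {
    tab <- as.matrix(shape)
    f <- approxfun(tab[, 1], tab[, 2], rule = 2)
    shape_fun <- function(t) f(t %% period)
  } else {
    stopifnot(is.function(shape))
    shape_fun <- function(t) shape(t %% period)
  }
  structure(list(Q_base = Q_base, Q_scale = Q_scale, shape = shape_fun,
                 period = period), class = "cyclic_input")
}

#' Evaluate a cyclic input rate
#'
#' @param t time (min); vectorized.
#' @param input a [cyclic_input()].
#' @return input rate at `t`; negative template excursions are clamped
#'   to zero with a warning.
#' @export
hormone_input_rate <- function(t, input) {
  stopifnot(inherits(input, "cyclic_input"))
  q <- input$Q_base + input$Q_scale * vapply(t, input$shape, 0)
  if (any(q < 0)) {
    warning("negative input rate clamped to zero")
    q[q < 0] <- 0
  }
  q
}

# smooth periodic template: unit-peak bump centred at `peak`, optionally
# minus a secondary negative lobe (post-peak decline below baseline)
.cycle_bump <- function(peak, width, period = 5760,
                        dip_peak = NULL, dip_width = NULL, dip_depth = 0) {
  gauss <- function(tc, p0, w) {
    d <- (tc - p0) %% period
    d <- pmin(d, period - d)
    exp(-0.5 * (d / w)^2)
  }
  function(tc) {
    v <- gauss(tc, peak, width)
    if (dip_depth > 0) v <- v - dip_depth * gauss(tc, dip_peak, dip_width)
    v
  }
}

#' Estrous-cycle template: forcing shapes, geometry and stage times
#'
#' The source observations constrain only the resulting ovarian hormone
#' profiles, not the input waveforms themselves, so the package ships an
#' editable template: smooth unit-peak bumps for FSH and androgen input
#' centred near proestrus, constant compartment geometry
#' (`V_ext = V_others = V_ov/3`, cell numbers filling the granulosa
#' third of the ovary), and the cycle times at which the four stages are
#' sampled.  The bundled `"calibrated"` template was tuned so that the
#' baseline in vivo flux analysis reproduces the reference A->E1 rates
#' at diestrus/proestrus/estrus.
#'
#' @param name template name (only `"calibrated"` is bundled) or the
#'   path of a template YAML file.
#' @return list with components `period`, `inputs` (list of
#'   [cyclic_input()] for `FSH`, `A`, `T`), `geometry` (constants
#'   `N_GCs`, `N_others`, `V_ext`, `V_others`), `stage_times` (named
#'   cycle times, min).
#' @export
cycle_template <- function(name = "calibrated") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("cycle_template_", name, ".yaml"),
                package = "gcsteroid", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  period <- as.numeric(cfg$period_min)
  mk <- function(sh, base, scale)
    cyclic_input(base, scale,
                 .cycle_bump(as.numeric(sh$peak_min),
                             as.numeric(sh$width_min), period,
                             dip_peak = as.numeric(sh$dip_peak_min %||% 0),
                             dip_width = as.numeric(sh$dip_width_min %||% 1),
                             dip_depth = as.numeric(sh$dip_depth %||% 0)),
                 period)
  list(
    period = period,
    inputs = list(
      FSH = mk(cfg$shapes$FSH, as.numeric(cfg$Q_base$FSH),
               as.numeric(cfg$Q_scale$FSH)),
      A = mk(cfg$shapes$A, as.numeric(cfg$Q_base$A),
             as.numeric(cfg$Q_scale$A)),
      T = mk(cfg$shapes$T, as.numeric(cfg$Q_base$T),
             as.numeric(cfg$Q_scale$T))),
    geometry = lapply(cfg$geometry, as.numeric),
    stage_times = unlist(lapply(cfg$stage_times, as.numeric)))
}

#' Estrous stage onsets within the modelled cycle
#'
#' The 4-day cycle is partitioned metestrus, diestrus, proestrus,
#' estrus (one day each); cycle time 0 is the onset of metestrus.
#'
#' @param period cycle length (min).
#' @return named vector of stage onset times (min).
#' @export
estrous_stage_onsets <- function(period = 5760) {
  setNames(period * (0:3) / 4,
           c("metestrus", "diestrus", "proestrus", "estrus"))
}

# apply named in vivo variability draws to a parameter set and template
.apply_variability <- function(params, template, draw) {
  if (is.null(draw) || !length(draw)) return(list(params = params,
                                                  template = template))
  p <- unclass(params)
  for (nm in names(draw)) {
    v <- draw[[nm]]
    if (nm %in% c("delta_mRNA", "delta_prot", "F_ov")) p[[nm]] <- v
    else if (grepl("^K_out_", nm)) p$K_out[[sub("^K_out_", "", nm)]] <- v
    else if (grepl("^R_oi_", nm)) p$R_oi[[sub("^R_oi_", "", nm)]] <- v
    else if (grepl("^nu_mRNA_", nm)) p$nu_mRNA[[sub("^nu_mRNA_", "", nm)]] <- v
    else if (grepl("^nu_prot_", nm)) p$nu_prot[[sub("^nu_prot_", "", nm)]] <- v
    else if (grepl("^lambda_", nm)) p$lambda[[sub("^lambda_", "", nm)]] <- v
    else if (grepl("^xi_", nm)) p$xi[[sub("^xi_", "", nm)]] <- v
    else if (grepl("^(Q_base|Q_scale)_", nm)) {
      horm <- sub("^Q_(base|scale)_", "", nm)
      slot <- if (grepl("^Q_base_", nm)) "Q_base" else "Q_scale"
      template$inputs[[horm]][[slot]] <- v
    } else if (nm %in% .theta_names()) {
      # calibrated kinetic/regulatory parameter
      if (grepl("^kappa_", nm)) p$kappa[[sub("^kappa_", "", nm)]] <- v
      else if (grepl("^lambda_", nm)) p$lambda[[sub("^lambda_", "", nm)]] <- v
      else p$xi[[sub("^xi_", "", nm)]] <- v
    } else stop("unknown variability component: ", nm)
  }
  list(params = structure(p, class = "gc_parameters"), template = template)
}

# apply a sampled 10-component kinetic vector to a parameter set
.apply_theta <- function(params, theta) {
  p <- unclass(params)
  for (nm in intersect(names(theta), .theta_names())) {
    if (grepl("^kappa_", nm)) p$kappa[[sub("^kappa_", "", nm)]] <- theta[[nm]]
    else if (grepl("^lambda_", nm))
      p$lambda[[sub("^lambda_", "", nm)]] <- theta[[nm]]
    else p$xi[[sub("^xi_", "", nm)]] <- theta[[nm]]
  }
  structure(p, class = "gc_parameters")
}

#' Simulate the ovary over repeated estrous cycles
#'
#' Three-compartment whole-ovary model (granulosa cells, metabolically
#' inert "other cells", extracellular space) driven by cyclic FSH and
#' androgen input and cleared by ovarian blood flow.  The first cycle is
#' burn-in; convergence to a periodic orbit is checked from the
#' cycle-to-cycle change of the ovarian steroid concentrations.
#'
#' @param params a [gc_parameters()] object.
#' @param template a [cycle_template()].
#' @param n_cycles number of cycles simulated (>= 2; the first is
#'   burn-in).
#' @param sigma_L transcription factor of the in vivo cell (default 1:
#'   no culture pre-treatment effect).
#' @param edc optional [edc_scenario()] applied during the simulation
#'   (fold changes step on 8 h after the start of the second modelled
#'   diestrus and persist).
#' @param dt_out output resolution (min).
#' @param rtol,atol solver tolerances.
#' @return object of class `gc_invivo_trajectory`: deSolve matrix with
#'   the 22 states and fluxes, plus attributes `template`, `params`,
#'   `ovarian` (function: time -> named ovarian concentrations,
#'   pmoles/ml or pg/ml), `stage_table` (per-stage concentrations over
#'   the last cycle), `cycle_drift` (max relative cycle-to-cycle
#'   change), `edc_times` (exposure start/readout, if any).
#' @export
simulate_cycle <- function(params, template = cycle_template(),
                           n_cycles = 3, sigma_L = 1, edc = NULL,
                           dt_out = 30, rtol = 1e-7, atol = 1e-13) {
  stopifnot(n_cycles >= 2)
  period <- template$period
  tend <- n_cycles * period
  times <- seq(0, tend, by = dt_out)
  geom <- template$geometry

  # forcing tables (linear interpolation inside the solver; 5-min
  # sampling keeps the interpolation error of the surge bumps below
  # the solver tolerance scale)
  ft <- seq(0, tend, by = 5)
  f_of <- function(inp) cbind(ft, hormone_input_rate(ft, inp))
  const <- function(v) cbind(c(0, tend), c(v, v))
  fc_tab <- function(f0, f1, t0)
    cbind(c(0, t0 - 1e-3, t0, tend), c(f0, f0, f1, f1))
  edc_t0 <- NA_real_
  if (!is.null(edc)) {
    stopifnot(inherits(edc, "edc_scenario"))
    # exposure anchored to the onset of the second modelled diestrus
    edc_t0 <- period + estrous_stage_onsets(period)[["diestrus"]] +
      edc$start_delay
    if (edc_t0 >= tend)
      stop("exposure start lies outside the simulated span; increase ",
           "n_cycles")
    forc_fc <- list(fc_tab(1, edc$fc[["cyp19"]], edc_t0),
                    fc_tab(1, edc$fc[["hsd17b1"]], edc_t0),
                    fc_tab(1, edc$fc[["km"]], edc_t0))
  } else {
    forc_fc <- list(const(1), const(1), const(1))
  }
  forcings <- c(list(f_of(template$inputs$FSH),
                     f_of(template$inputs$A),
                     f_of(template$inputs$T),
                     const(geom$N_GCs), const(geom$N_others),
                     const(geom$V_ext), const(geom$V_others)),
                forc_fc)

  m0 <- sigma_L * params$nu_mRNA / params$delta_mRNA
  p0 <- params$nu_prot * m0 / params$delta_prot
  y0 <- c(m0, p0, rep(0, 16))
  names(y0) <- c(paste0("mRNA_", .enzymes), paste0("prot_", .enzymes),
                 "A_GC", "T_GC", "E1_GC", "E2_GC", "FSH_GC",
                 "A_oth", "T_oth", "E1_oth", "E2_oth", "FSH_oth",
                 "A_ext", "T_ext", "E1_ext", "E2_ext", "FSH_ext", "T2O")
  pv <- .pack_params(params, fold_changes(), sigma_L)
  out <- deSolve::ode(y = y0, times = times, parms = pv,
                      func = "gc_derivs_invivo",
                      initfunc = "gc_initmod_invivo",
                      initforc = "gc_initforc_invivo",
                      forcings = forcings,
                      fcontrol = list(method = "linear", rule = 2),
                      dllname = "gcsteroid", nout = 6,
                      outnames = paste0("alpha", 1:6),
                      rtol = rtol, atol = atol, method = "lsoda")
  if (attr(out, "istate")[1] < 0)
    stop("in vivo solver failed to converge")

  V_ov <- params$V_ov_diestrus
  ovarian <- function(t) {
    idx <- vapply(c("A", "T", "E1", "E2", "FSH"), function(h) {
      gcq <- approx(out[, "time"], out[, paste0(h, "_GC")], t)$y
      otq <- approx(out[, "time"], out[, paste0(h, "_oth")], t)$y
      exq <- approx(out[, "time"], out[, paste0(h, "_ext")], t)$y
      (geom$N_GCs * gcq + geom$N_others * otq + exq) / V_ov
    }, numeric(length(t)))
    if (length(t) == 1) setNames(as.numeric(idx),
                                 c("A", "T", "E1", "E2", "FSH"))
    else `colnames<-`(idx, c("A", "T", "E1", "E2", "FSH"))
  }

  # cycle-to-cycle drift of ovarian concentrations (last two cycles,
  # both after the burn-in cycle, so at least three cycles are needed)
  drift <- NA_real_
  if (n_cycles >= 3) {
    tprobe <- seq(0, period - dt_out, by = max(dt_out, period / 96))
    c1 <- ovarian(tprobe + (n_cycles - 2) * period)
    c2 <- ovarian(tprobe + (n_cycles - 1) * period)
    mx <- max(abs(c2))
    drift <- if (mx == 0) 0 else
      max(abs(c2 - c1) / pmax(abs(c2), mx * 1e-6))
    if (drift > 1e-3 && is.null(edc))
      warning(sprintf(
        "trajectory not periodic after %d cycles (drift %.2g)",
        n_cycles, drift))
  }

  stages <- template$stage_times
  st <- (n_cycles - 1) * period + stages
  st[st > tend] <- st[st > tend] - period
  stage_table <- data.frame(stage = names(stages),
                            cycle_time = unname(stages),
                            t(vapply(st, ovarian, numeric(5))))

  structure(out, class = c("gc_invivo_trajectory", class(out)),
            params = params, template = template, sigma_L = sigma_L,
            ovarian = ovarian, stage_table = stage_table,
            cycle_drift = drift,
            edc_times = if (!is.null(edc))
              c(start = edc_t0, readout = edc_t0 + edc$readout_delay))
}

#' Whole-ovary concentrations along a simulated cycle
#' @param traj a `gc_invivo_trajectory`.
#' @param t times (min).
#' @return matrix (or named vector) of ovarian concentrations.
#' @export
ovarian_concentrations <- function(traj, t) attr(traj, "ovarian")(t)

#' Per-stage ovarian concentration table of the final cycle
#' @param traj a `gc_invivo_trajectory`.
#' @return data.frame with stage, cycle time, and concentrations.
#' @export
stage_concentrations <- function(traj) attr(traj, "stage_table")

#' Monte-Carlo prediction of ovarian hormone concentrations
#'
#' Propagates posterior parameter uncertainty and in vivo variability:
#' each draw combines one sampled kinetic/regulatory vector with one
#' draw from each in vivo variability distribution, simulates the
#' cyclic ovary, and records the ovarian concentrations of the final
#' cycle; summaries are the pointwise mean and central 95% band.
#'
#' @param posterior_samples matrix of sampled parameter vectors (rows;
#'   columns named as in [map_estimates()]), e.g. pooled MCMC samples;
#'   or `NULL` to keep the parameter set fixed.
#' @param invivo_priors named list of [prior_spec()], default
#'   [invivo_variability_priors()]; use `list()` to disable variability.
#' @param n number of Monte-Carlo draws.
#' @param seed integer seed (required for reproducibility).
#' @param params base [gc_parameters()].
#' @param template a [cycle_template()].
#' @param t_grid cycle times (min, within one period) at which to
#'   summarize; default every 2 h.
#' @param n_cycles cycles per simulation (first is burn-in).
#' @param edc optional [edc_scenario()] passed to every simulation.
#' @return list with `times`, `mean`, `lower`, `upper` (matrices: time x
#'   hormone), and `draws` (array n x time x hormone).
#' @export
monte_carlo_predict <- function(posterior_samples = NULL,
                                invivo_priors = invivo_variability_priors(),
                                n = 100, seed = 1,
                                params = gc_parameters(),
                                template = cycle_template(),
                                t_grid = NULL, n_cycles = 3, edc = NULL) {
  stopifnot(n >= 1)
  period <- template$period
  if (is.null(t_grid)) t_grid <- seq(0, period, by = 120)
  horm <- c("A", "T", "E1", "E2", "FSH")
  draws <- array(NA_real_, c(n, length(t_grid), length(horm)),
                 dimnames = list(NULL, NULL, horm))
  .with_seed(seed, {
    for (i in seq_len(n)) {
      p_i <- params
      if (!is.null(posterior_samples)) {
        row <- posterior_samples[sample.int(nrow(posterior_samples), 1), ]
        p_i <- .apply_theta(p_i, row)
      }
      var_draw <- lapply(invivo_priors, sample_prior, n = 1)
      ap <- .apply_variability(p_i, template, var_draw)
      tr <- suppressWarnings(simulate_cycle(ap$params, ap$template,
                                            n_cycles = n_cycles, edc = edc))
      draws[i, , ] <- ovarian_concentrations(
        tr, (n_cycles - 1) * period + t_grid)[, horm]
    }
  })
  list(times = t_grid,
       mean = apply(draws, c(2, 3), mean),
       lower = apply(draws, c(2, 3), quantile, 0.025),
       upper = apply(draws, c(2, 3), quantile, 0.975),
       draws = draws)
}
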