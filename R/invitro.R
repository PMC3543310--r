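#' Describe an in vitro granulosa-cell culture experiment
#'
#' Two-compartment system: a representative cell and its share of the
#' culture medium.  Medium concentrations are declared in assay units
#' (nM for steroids, ng/ml for FSH) and converted once to per-cell
#' quantities (`1 nM = 1 pmol/ml`; per-cell share = concentration /
#' cells_per_ml).
#'
#' @param cells_per_ml plated cell density (cells/ml).
#' @param volume_ml total culture volume (ml).
#' @param medium_nM named vector of initial medium steroid
#'   concentrations (nM); names among `A`, `T`, `E1`, `E2`.
#' @param fsh_ng_ml FSH concentration in the medium (ng/ml).
#' @param fc a [fold_changes()] vector (disruptor treatment).
#' @param sigma_L inter-study transcription factor.
#' @param duration_min treatment duration (minutes; time 0 is treatment
#'   start).
#' @return object of class `invitro_system`.
#' @export
invitro_system <- function(cells_per_ml = 3e5, volume_ml = 2,
                           medium_nM = c(A = 0), fsh_ng_ml = 0,
                           fc = fold_changes(), sigma_L = 1,
                           duration_min = 2880) {
  stopifnot(cells_per_ml > 0, volume_ml > 0, fsh_ng_ml >= 0,
            all(medium_nM >= 0), sigma_L > 0, duration_min > 0)
  conc <- c(A = 0, T = 0, E1 = 0, E2 = 0)
  conc[names(medium_nM)] <- medium_nM
  n_cells <- cells_per_ml * volume_ml
  structure(list(
    cells_per_ml = cells_per_ml, volume_ml = volume_ml,
    n_cells = n_cells,
    V_med = volume_ml / n_cells,
    med0 = conc / cells_per_ml,              # pmoles per cell
    fsh0 = fsh_ng_ml * 1000 / cells_per_ml,  # pg per cell
    fc = fc, sigma_L = sigma_L, duration_min = duration_min),
    class = "invitro_system")
}

# initial 17-state vector; gene expression starts at the study's own
# equilibrium (sigma_L-scaled baseline), so that an untreated control is
# flat in time for any sigma_L
.invitro_init <- function(system, params) {
  sL <- system$sigma_L
  m0 <- sL * params$nu_mRNA / params$delta_mRNA
  p0 <- params$nu_prot * m0 / params$delta_prot
  c(mRNA_Cyp19 = m0[["Cyp19"]], mRNA_Hsd17b1 = m0[["Hsd17b1"]],
    mRNA_Hsd17b2 = m0[["Hsd17b2"]],
    prot_Cyp19 = p0[["Cyp19"]], prot_Hsd17b1 = p0[["Hsd17b1"]],
    prot_Hsd17b2 = p0[["Hsd17b2"]],
    A_GC = 0, T_GC = 0, E1_GC = 0, E2_GC = 0, FSH_GC = 0,
    A_med = system$med0[["A"]], T_med = system$med0[["T"]],
    E1_med = system$med0[["E1"]], E2_med = system$med0[["E2"]],
    FSH_med = system$fsh0, T2O = 0)
}

#' In vitro right-hand side (reference R implementation)
#'
#' Time derivatives of the 17-dimensional in vitro state (cell +
#' medium).  [simulate_invitro()] integrates the identical equations in
#' compiled code; this R version is the readable reference and is
#' asserted equal by the test suite.
#'
#' @param t time (min; unused, the system is autonomous).
#' @param state named 17-vector: [cell_state()] components plus
#'   `A_med`, `T_med`, `E1_med`, `E2_med` (pmoles/cell) and `FSH_med`
#'   (pg/cell).
#' @param params a [gc_parameters()] object.
#' @param system an [invitro_system()] (for the per-cell medium volume,
#'   fold changes and `sigma_L`).
#' @return list whose first element is the derivative vector (deSolve
#'   convention).
#' @export
invitro_rhs <- function(t, state, params, system) {
  kin <- k_in(params); kout <- params$K_out
  Vgc <- params$V_GC; Vmed <- system$V_med
  a <- reaction_fluxes(state, params, system$fc)
  S <- c(A = a[["alpha3"]] - a[["alpha1"]] - a[["alpha2"]],
         T = a[["alpha2"]] - a[["alpha3"]] - a[["alpha4"]],
         E1 = a[["alpha1"]] + a[["alpha6"]] - a[["alpha5"]],
         E2 = a[["alpha4"]] + a[["alpha5"]] - a[["alpha6"]])
  ge <- gene_expression_rhs(state, params, system$fc, system$sigma_L)
  med <- state[c("A_med", "T_med", "E1_med", "E2_med", "FSH_med")]
  gc <- state[c("A_GC", "T_GC", "E1_GC", "E2_GC", "FSH_GC")]
  tr <- kin * med / Vmed - kout * gc / Vgc
  d <- c(ge,
         tr[1:4] + S, FSH_GC = unname(tr[5]),
         -tr, T2O = unname(a[["alpha1"]]))
  names(d) <- names(state)
  list(d, alpha = a)
}

#' Simulate an in vitro culture experiment
#'
#' Integrates the two-compartment model (stiff-capable `lsoda`,
#' compiled right-hand side).  Gene expression starts at the
#' `sigma_L`-scaled baseline equilibrium; steroids start in the medium
#' as declared by the system.
#'
#' @param system an [invitro_system()].
#' @param params a [gc_parameters()] object.
#' @param t_grid output times (min), increasing from 0; default every
#'   15 min over the system duration.
#' @param rtol,atol solver tolerances (states span ~10 orders of
#'   magnitude, so the absolute tolerance is small).
#' @return object of class `gc_trajectory`: the deSolve output matrix
#'   (states plus the six fluxes `alpha1`..`alpha6`) with the system and
#'   parameters attached as attributes.
#' @examples
#' sys <- invitro_system(medium_nM = c(A = 200), duration_min = 2880)
#' tr <- simulate_invitro(sys, gc_parameters())
#' tail(as.data.frame(tr)[, c("time", "E2_med", "alpha1")], 2)
#' @export
simulate_invitro <- function(system, params, t_grid = NULL,
                             rtol = 1e-8, atol = 1e-14) {
  stopifnot(inherits(system, "invitro_system"),
            inherits(params, "gc_parameters"))
  .validate_parameters(params)
  if (system$V_med <= params$V_GC)
    stop("per-cell medium volume must exceed the cell volume")
  if (is.null(t_grid))
    t_grid <- unique(c(seq(0, system$duration_min, by = 15),
                       system$duration_min))
  stopifnot(t_grid[1] == 0, !is.unsorted(t_grid, strictly = TRUE))
  pv <- .pack_params(params, system$fc, system$sigma_L, system$V_med)
  y0 <- .invitro_init(system, params)
  out <- deSolve::ode(y = y0, times = t_grid, parms = pv,
                      func = "gc_derivs_invitro",
                      initfunc = "gc_initmod_invitro",
                      dllname = "gcsteroid",
                      nout = 6,
                      outnames = paste0("alpha", 1:6),
                      rtol = rtol, atol = atol, method = "lsoda")
  if (attr(out, "istate")[1] < 0)
    stop("in vitro solver failed to converge (istate = ",
         attr(out, "istate")[1], "); state/parameter scales may be ",
         "inconsistent")
  structure(out, class = c("gc_trajectory", class(out)),
            system = system, params = params)
}

#' @export
print.gc_trajectory <- function(x, ...) {
  cat("<gc_trajectory>", nrow(x), "time points over",
      max(x[, "time"]), "min\n")
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' @param traj a `gc_trajectory`.
#' @return data.frame with columns `time`, `species`, `quantity`.
#' @export
trajectory_table <- function(traj) {
  df <- as.data.frame(unclass(traj))
  species <- setdiff(names(df), "time")
  out <- data.frame(
    time = rep(df$time, length(species)),
    species = rep(species, each = nrow(df)),
    quantity = unlist(df[species], use.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Tritiated-water assay readout
#'
#' Cumulative tritiated water released by aromatization of labelled
#' androstenedione: the time integral of the A->E1 flux, reported per
#' cell.
#'
#' @param traj a trajectory from [simulate_invitro()].
#' @return data.frame with columns `time` (min) and `T2O` (pmoles/cell),
#'   non-decreasing in time.
#' @export
tritiated_water_assay <- function(traj) {
  data.frame(time = traj[, "time"], T2O = traj[, "T2O"])
}

# --- quasi-steady-state fast path -------------------------------------

# run the reduced in vitro model (see src/qssa.c); med0/fsh0 in per-cell
# quantities.  Returns a matrix with named columns.
.qssa_raw <- function(pv, med0, fsh0, m0, p0, tout,
                      rtol = 1e-4, atol = 1e-12) {
  .solve_counter$n <- .solve_counter$n + 1L
  .Call(C_qssa_run, as.double(pv),
        as.double(c(med0, 0, fsh0, m0, p0)), as.double(tout),
        c(rtol, atol))
}

.qssa_run <- function(pv, med0, fsh0, m0, p0, tout,
                      rtol = 1e-4, atol = 1e-12) {
  m <- .qssa_raw(pv, med0, fsh0, m0, p0, tout, rtol, atol)
  colnames(m) <- c("time", "A_tot", "T_tot", "E1_tot", "E2_tot", "T2O",
                   "A_GC", "T_GC", "E1_GC", "E2_GC",
                   paste0("alpha", 1:6),
                   "prot_Cyp19", "prot_Hsd17b1", "prot_Hsd17b2")
  m
}

#' Fast reduced simulation of an in vitro experiment
#'
#' Quasi-steady-state companion of [simulate_invitro()]: intracellular
#' steroid and FSH pools are slaved to their transport/metabolism
#' balance (they relax within seconds), gene expression is integrated in
#' closed form, and only the slowly varying total steroid pools are
#' integrated numerically.  This is the model evaluation used inside the
#' calibration likelihood, where it is called hundreds of thousands of
#' times; its agreement with the full solver is part of the test suite.
#'
#' @inheritParams simulate_invitro
#' @param t_grid output times (min).
#' @param rtol,atol error control of the reduced integrator.
#' @return matrix with columns `time`, total pools (`A_tot`..`E2_tot`),
#'   `T2O`, intracellular pools, fluxes `alpha1..6`, and the three
#'   enzyme proteins.  Medium quantities are `*_tot - *_GC`.
#' @export
simulate_invitro_qss <- function(system, params, t_grid = NULL,
                                 rtol = 1e-6, atol = 1e-13) {
  stopifnot(inherits(system, "invitro_system"))
  if (is.null(t_grid))
    t_grid <- unique(c(seq(0, system$duration_min, by = 15),
                       system$duration_min))
  pv <- .pack_params(params, system$fc, system$sigma_L, system$V_med)
  sL <- system$sigma_L
  m0 <- sL * params$nu_mRNA / params$delta_mRNA
  p0 <- params$nu_prot * m0 / params$delta_prot
  .qssa_run(pv, unname(system$med0), system$fsh0, unname(m0), unname(p0),
            t_grid, rtol, atol)
}
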