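#' Instantaneous flux report at a trajectory time point
#'
#' Evaluates the six interconversion rates at the (linearly
#' interpolated) state of a simulated trajectory and reports them both
#' absolutely (pmoles/min/cell) and relative to the reference A->E1
#' aromatization (`alpha1`).  Interpolation on the dense solver output
#' is used rather than re-stepping; with the default 15-min output grid
#' the interpolation error is far below solver error for these smooth
#' states.
#'
#' @param traj a `gc_trajectory` from [simulate_invitro()] (or a state
#'   matrix with the same columns).
#' @param t snapshot time (min), within the trajectory span.
#' @param params the [gc_parameters()] used for the simulation (default:
#'   taken from the trajectory attributes).
#' @param fc fold changes in force at `t` (default: from the system).
#' @param condition optional label for reports.
#' @return data.frame of class `flux_report` with columns `reaction`,
#'   `flux`, `relative`; `relative` is `NA` when `alpha1 = 0`.
#' @export
flux_snapshot <- function(traj, t, params = attr(traj, "params"),
                          fc = NULL, condition = "") {
  tt <- traj[, "time"]
  if (t < min(tt) || t > max(tt))
    stop("snapshot time outside the trajectory span")
  if (is.null(fc)) {
    sys <- attr(traj, "system")
    fc <- if (!is.null(sys)) sys$fc else fold_changes()
  }
  cols <- c(paste0("mRNA_", .enzymes), paste0("prot_", .enzymes),
            "A_GC", "T_GC", "E1_GC", "E2_GC", "FSH_GC")
  state <- vapply(cols, function(cn)
    approx(tt, traj[, cn], xout = t)$y, 0)
  state <- c(state, T2O = 0)
  a <- reaction_fluxes(state, params, fc)
  rel <- if (a[["alpha1"]] > 0) unname(a / a[["alpha1"]]) else
    rep(NA_real_, 6)
  structure(
    data.frame(reaction = names(.reactions),
               conversion = unname(.reactions),
               flux = unname(a), relative = rel,
               condition = condition),
    class = c("flux_report", "data.frame"), time = t)
}

#' Rank reactions by absolute flux
#'
#' Orders the six interconversion reactions by decreasing absolute
#' rate; ties keep the reaction index order.  The top of the ranking
#' identifies the preferential estradiol synthesis route.
#'
#' @param report a `flux_report` from [flux_snapshot()].
#' @return the report rows reordered, with a `rank` column.
#' @export
dominant_pathway <- function(report) {
  stopifnot(inherits(report, "flux_report"))
  ord <- order(-report$flux, seq_len(nrow(report)))
  out <- report[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @importFrom stats approx
NULL
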