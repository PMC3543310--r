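#' Steady-state synthesis rates from degradation rates and initial pools
#'
#' Granulosa cells at baseline (no FSH, no disruptor, unit inter-study
#' factor) are assumed to be at gene-expression equilibrium, so the
#' synthesis rates follow from the measured pools and the degradation
#' rate constants: `nu_mRNA = delta_mRNA * mRNA0` and, assuming one mRNA
#' is translated into one protein, `nu_prot = delta_prot * prot0 / mRNA0`.
#'
#' @param delta_mRNA mRNA degradation rate constant (/min).
#' @param delta_prot protein degradation rate constant (/min).
#' @param mRNA0 baseline mRNA quantity (pg/cell).
#' @param prot0 baseline protein quantity (pg/cell).
#' @return named numeric vector with components `nu_mRNA` (pg/min) and
#'   `nu_prot` (/min).  An empty cell (`mRNA0 = 0`, `prot0 = 0`) returns
#'   `c(0, 0)` by convention.
#' @examples
#' derive_steady_state_rates(6e-3, 3e-3, 7e-9, 0.014)
#' @export
derive_steady_state_rates <- function(delta_mRNA, delta_prot, mRNA0, prot0) {
  stopifnot(delta_mRNA > 0, delta_prot > 0, mRNA0 >= 0, prot0 >= 0)
  if (mRNA0 == 0) {
    if (prot0 > 0)
      stop("mRNA0 = 0 with prot0 > 0: protein synthesis rate is undefined")
    return(c(nu_mRNA = 0, nu_prot = 0))
  }
  c(nu_mRNA = delta_mRNA * mRNA0, nu_prot = delta_prot * prot0 / mRNA0)
}

#' Absolute initial enzyme pools from aromatase-relative measurements
#'
#' Experimental mRNA and protein levels of the two dehydrogenases are
#' measured relative to aromatase; absolute values follow by scaling the
#' aromatase initial quantities.
#'
#' @param aromatase_mRNA0,aromatase_prot0 absolute aromatase initial
#'   quantities (pg/cell).
#' @param mRNA_ratios,prot_ratios named numeric vectors of
#'   enzyme-to-aromatase ratios (must include `Cyp19 = 1` implicitly;
#'   any names are accepted).
#' @return list with components `mRNA0` and `prot0`, named per enzyme.
#' @export
scale_relative_initials <- function(aromatase_mRNA0, aromatase_prot0,
                                    mRNA_ratios, prot_ratios) {
  stopifnot(aromatase_mRNA0 > 0, aromatase_prot0 > 0,
            all(mRNA_ratios > 0), all(prot_ratios > 0))
  list(mRNA0 = aromatase_mRNA0 * mRNA_ratios,
       prot0 = aromatase_prot0 * prot_ratios)
}

.default_point_values <- function() {
  mRNA0 <- c(Cyp19 = 4.96e-8, Hsd17b1 = 1.03e-7, Hsd17b2 = 7.00e-9)
  prot0 <- c(Cyp19 = 0.1,     Hsd17b1 = 0.21,    Hsd17b2 = 0.014)
  list(
    delta_mRNA = 6.00e-3,
    delta_prot = 3.00e-3,
    # printed point values (computed by the source from rounded pools;
    # derive_steady_state_rates() gives the exact counterparts)
    nu_mRNA = c(Cyp19 = 3.00e-10, Hsd17b1 = 6.00e-10, Hsd17b2 = 4.20e-11),
    nu_prot = c(Cyp19 = 6000,     Hsd17b1 = 6300,     Hsd17b2 = 6000),
    mRNA0 = mRNA0,
    prot0 = prot0,
    lambda = c(Cyp19_A = 1.07e-7, Hsd17b1_A = 5.65e-8, Hsd17b2_T = 6.65e-8,
               Cyp19_T = 2.67e-7, Hsd17b1_E1 = 1.78e-5, Hsd17b2_E2 = 7.91e-8),
    xi     = c(Cyp19_A = 8.25e-9, Hsd17b1_A = 4.84e-5, Hsd17b2_T = 5.67e-6,
               Cyp19_T = 1.24e-8, Hsd17b1_E1 = 1.30e-6, Hsd17b2_E2 = 5.40e-6),
    kappa  = c(Cyp19 = 2.08e6, Hsd17b1 = 6.04e5),
    R_oi   = c(A = 0.0124, T = 0.013, E1 = 0.0084, E2 = 0.0108, FSH = 1),
    K_out  = c(A = 1e-8, T = 1e-8, E1 = 1e-8, E2 = 1e-8, FSH = 1e-8),
    V_GC = 0.27e-9,
    F_ov = 0.2654,
    V_ov_diestrus = 0.05
  )
}

#' Construct a granulosa-cell parameter set
#'
#' All kinetic, regulatory and transport constants for one granulosa
#' cell.  Quantities are per cell: pg for mRNA, protein and FSH, pmoles
#' for steroids, ml for volumes, minutes for time.  Defaults are the
#' literature/measured point values with the calibrated kinetic and
#' regulatory parameters at their posterior maximum (the values used for
#' the flux analyses); see [gc_preset()] for alternatives.
#'
#' The six interconversion reactions are labelled `Cyp19_A` (A->E1),
#' `Hsd17b1_A` (A->T), `Hsd17b2_T` (T->A), `Cyp19_T` (T->E2),
#' `Hsd17b1_E1` (E1->E2) and `Hsd17b2_E2` (E2->E1).
#'
#' Two published value sets disagree for the Hsd17b2 constants
#' (`lambda_Hsd17b2_E2` 7.91e-8 vs 7.91e-6 and `xi_Hsd17b2_T` 5.67e-6 vs
#' 5.67e-8); the deterministic default keeps the point-value table and
#' `hsd17b2 = "variability-set"` selects the alternative (with a
#' message, since the discrepancy is unresolved in the sources).
#'
#' @param ... replacement values for any of the list components (see
#'   [derive_steady_state_rates()] for `nu_mRNA`/`nu_prot` consistency).
#' @param hsd17b2 which of the two published Hsd17b2 constant sets to
#'   use, `"default"` or `"variability-set"`.
#' @return object of class `gc_parameters`.
#' @export
gc_parameters <- function(..., hsd17b2 = c("default", "variability-set")) {
  hsd17b2 <- match.arg(hsd17b2)
  p <- .default_point_values()
  if (hsd17b2 == "variability-set") {
    message("using the in-vivo variability-table Hsd17b2 constants ",
            "(lambda_E2 = 7.91e-6, xi_T = 5.67e-8), which disagree with ",
            "the deterministic point-value table")
    p$lambda[["Hsd17b2_E2"]] <- 7.91e-6
    p$xi[["Hsd17b2_T"]] <- 5.67e-8
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter component(s): ",
                          paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (length(dots[[nm]]) == length(p[[nm]]) || length(dots[[nm]]) == 1) {
        if (is.null(names(dots[[nm]])) || length(dots[[nm]]) == 1)
          p[[nm]][] <- dots[[nm]]
        else p[[nm]][names(dots[[nm]])] <- dots[[nm]]
      } else if (!is.null(names(dots[[nm]]))) {
        p[[nm]][names(dots[[nm]])] <- dots[[nm]]
      } else stop("component ", nm, " has wrong length")
    }
  }
  .validate_parameters(structure(p, class = "gc_parameters"))
}

#' @export
print.gc_parameters <- function(x, ...) {
  cat("<gc_parameters> (per-cell units: pg, pmoles, ml, min)\n")
  cat("  Vmax (pmoles/min/pg):",
      paste0(names(x$lambda), "=", signif(x$lambda, 3), collapse = " "), "\n")
  cat("  Km (pmoles):        ",
      paste0(names(x$xi), "=", signif(x$xi, 3), collapse = " "), "\n")
  cat("  FSH slopes (/pg):   ",
      paste0(names(x$kappa), "=", signif(x$kappa, 3), collapse = " "), "\n")
  cat("  turnover: delta_mRNA =", x$delta_mRNA,
      " delta_prot =", x$delta_prot, "\n")
  invisible(x)
}

.validate_parameters <- function(p) {
  num <- unlist(p[c("delta_mRNA", "delta_prot", "nu_prot", "lambda", "xi",
                    "R_oi", "K_out", "V_GC", "F_ov", "V_ov_diestrus")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all kinetic/transport parameters must be finite and positive")
  if (any(p$kappa < 0) || any(p$nu_mRNA < 0) ||
      any(p$mRNA0 < 0) || any(p$prot0 < 0))
    stop("negative value in kappa/nu_mRNA/initial pools")
  invisible(p)
}

#' Cellular uptake rate constants
#'
#' `K_in = K_out / R_oi`, so that at passive-transport equilibrium the
#' extra- over intra-cellular concentration ratio equals the partition
#' coefficient `R_oi`.
#'
#' @param params a [gc_parameters()] object.
#' @return named vector of uptake rate constants (ml/min) for
#'   A, T, E1, E2 and FSH.
#' @export
k_in <- function(params) params$K_out / params$R_oi

#' Bundled parameter presets
#'
#' * `"map"` (the default of [gc_parameters()]): measured/literature
#'   point values plus the calibrated parameters at their maximum a
#'   posteriori estimates — the set used for flux analyses.
#' * `"measured"`: only directly measured or literature values; the
#'   calibrated kinetic/regulatory parameters are set to their prior
#'   geometric means (uniform priors: midpoint).  Pre-calibration
#'   baseline.
#'
#' @param name preset name.
#' @param ... passed on to [gc_parameters()].
#' @return a `gc_parameters` object.
#' @export
gc_preset <- function(name = c("map", "measured"), ...) {
  name <- match.arg(name)
  switch(name,
    map = gc_parameters(...),
    measured = gc_parameters(
      kappa = c(Cyp19 = 5e6, Hsd17b1 = 5e5),
      lambda = c(Cyp19_A = 1.33e-7, Cyp19_T = 1.33e-7,
                 Hsd17b1_A = 7.59e-8, Hsd17b1_E1 = 1.03e-5),
      xi = c(Cyp19_A = 8.10e-9, Cyp19_T = 3.24e-8,
             Hsd17b1_A = 4.32e-5, Hsd17b1_E1 = 5.29e-6),
      ...)
  )
}

# shortest decimal that round-trips bit-identically
.fmt_full <- function(x) {
  if (!is.numeric(x)) return(as.character(x))
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

#' Write / read a parameter set as a YAML config
#'
#' Values are serialized in full decimal precision so that a round trip
#' through the file reproduces the in-memory numbers bit for bit.
#'
#' @param params a `gc_parameters` object.
#' @param path file path.
#' @return `read_parameters` returns a `gc_parameters` object;
#'   `write_parameters` returns `path` invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "gc_parameters"))
  ser <- lapply(unclass(params), function(v) {
    out <- as.list(.fmt_full(v))
    if (!is.null(names(v))) names(out) <- names(v)
    if (length(out) == 1 && is.null(names(v))) out <- out[[1]]
    out
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- lapply(raw, function(v) {
    if (is.list(v)) setNames(vapply(v, as.numeric, 0), names(v))
    else as.numeric(v)
  })
  .validate_parameters(structure(p, class = "gc_parameters"))
}
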