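#' Single-cell state vector
#'
#' Canonical named state of one granulosa cell: mRNA and protein
#' quantities of the three enzymes (pg), intracellular steroid
#' quantities (pmoles), intracellular FSH (pg) and the cumulative
#' tritiated-water readout (pmoles).
#'
#' @param mRNA,protein named length-3 vectors (`Cyp19`, `Hsd17b1`,
#'   `Hsd17b2`).
#' @param A,T,E1,E2 intracellular steroid quantities (pmoles).
#' @param FSH intracellular FSH (pg).
#' @param T2O cumulative tritiated water (pmoles).
#' @return named numeric vector of length 12.
#' @export
cell_state <- function(mRNA = c(Cyp19 = 4.96e-8, Hsd17b1 = 1.03e-7,
                                Hsd17b2 = 7.00e-9),
                       protein = c(Cyp19 = 0.1, Hsd17b1 = 0.21,
                                   Hsd17b2 = 0.014),
                       A = 0, T = 0, E1 = 0, E2 = 0, FSH = 0, T2O = 0) {
  s <- c(mRNA_Cyp19 = unname(mRNA[["Cyp19"]]),
         mRNA_Hsd17b1 = unname(mRNA[["Hsd17b1"]]),
         mRNA_Hsd17b2 = unname(mRNA[["Hsd17b2"]]),
         prot_Cyp19 = unname(protein[["Cyp19"]]),
         prot_Hsd17b1 = unname(protein[["Hsd17b1"]]),
         prot_Hsd17b2 = unname(protein[["Hsd17b2"]]),
         A_GC = A, T_GC = T, E1_GC = E1, E2_GC = E2,
         FSH_GC = FSH, T2O = T2O)
  if (any(s < 0)) stop("cell state quantities must be non-negative")
  s
}

#' Endocrine-disruptor fold changes
#'
#' Multiplicative perturbations applied while a chemical is present:
#' `cyp19` and `hsd17b1` act on the mRNA synthesis rates of the two
#' FSH-inducible enzymes, `km` (the Km fold-change f_M) inflates both
#' aromatase Michaelis constants.  The identity element is all ones.
#'
#' @param cyp19,hsd17b1 transcription fold-changes (> 0).
#' @param km aromatase Km fold-change f_M (> 0); see [km_fold_change()].
#' @return named numeric vector of class `gc_fold_changes`.
#' @export
fold_changes <- function(cyp19 = 1, hsd17b1 = 1, km = 1) {
  stopifnot(cyp19 > 0, hsd17b1 > 0, km > 0)
  structure(c(cyp19 = cyp19, hsd17b1 = hsd17b1, km = km),
            class = "gc_fold_changes")
}

#' Aromatase Km fold-change from an activity fold-change
#'
#' A direct competitive inhibitor scales measured aromatase activity by
#' `activity_fold`; since activity is inversely proportional to the
#' apparent Km, the Km fold-change is the reciprocal:
#' `f_M = 1 / activity_fold`.
#'
#' @param activity_fold treated/control aromatase activity ratio (> 0).
#' @return the Km fold-change f_M.
#' @examples
#' km_fold_change(0.29)  # a strong aromatase inhibitor
#' @export
km_fold_change <- function(activity_fold) {
  if (any(activity_fold <= 0)) stop("activity fold-change must be positive")
  1 / activity_fold
}

#' Transcription fold-change from equilibrium mRNA levels
#'
#' Inverse map of applying a transcription fold at gene-expression
#' equilibrium: the ratio of treated to control mRNA.
#'
#' @param treated,control mRNA quantities (pg/cell), `control > 0`.
#' @return the fold-change f_X.
#' @export
mrna_fold_change <- function(treated, control) {
  if (any(control <= 0)) stop("control mRNA level must be positive")
  treated / control
}

# pack a gc_parameters object (+ modifiers) into the C parameter layout
.pack_params <- function(params, fc = fold_changes(), sigma_L = 1,
                         V_med = 2 / 6e5) {
  p <- params
  c(p$kappa[["Cyp19"]], p$kappa[["Hsd17b1"]],
    p$lambda[["Cyp19_A"]], p$lambda[["Cyp19_T"]],
    p$lambda[["Hsd17b1_A"]], p$lambda[["Hsd17b1_E1"]],
    p$xi[["Cyp19_A"]], p$xi[["Cyp19_T"]],
    p$xi[["Hsd17b1_A"]], p$xi[["Hsd17b1_E1"]],
    p$lambda[["Hsd17b2_T"]], p$lambda[["Hsd17b2_E2"]],
    p$xi[["Hsd17b2_T"]], p$xi[["Hsd17b2_E2"]],
    p$delta_mRNA, p$delta_prot,
    p$nu_mRNA[["Cyp19"]], p$nu_mRNA[["Hsd17b1"]], p$nu_mRNA[["Hsd17b2"]],
    p$nu_prot[["Cyp19"]], p$nu_prot[["Hsd17b1"]], p$nu_prot[["Hsd17b2"]],
    p$R_oi[["A"]], p$R_oi[["T"]], p$R_oi[["E1"]], p$R_oi[["E2"]],
    p$R_oi[["FSH"]],
    p$K_out[["A"]], p$K_out[["T"]], p$K_out[["E1"]], p$K_out[["E2"]],
    p$K_out[["FSH"]],
    p$V_GC, V_med,
    fc[["km"]], fc[["cyp19"]], fc[["hsd17b1"]], sigma_L,
    p$F_ov, p$V_ov_diestrus)
}

#' Competitive Michaelis-Menten interconversion fluxes
#'
#' The six steroid biotransformation rates of one granulosa cell.  Each
#' reaction converts substrate Z with maximal rate `lambda * enzyme`
#' and apparent Km inflated competitively by the other substrate of the
#' same enzyme (the competitor's own Km acting as its inhibition
#' constant):
#' `alpha = lambda * E * Z / (Km * (1 + C/Km_C) + Z)`.
#' For the two aromatase reactions both Km values carry the
#' endocrine-disruptor fold `f_M`.
#'
#' @param state a [cell_state()] vector.
#' @param params a [gc_parameters()] object.
#' @param fc a [fold_changes()] vector.
#' @return named vector `alpha1`..`alpha6` (pmoles/min/cell), with the
#'   reaction labels as attribute `reaction`:
#'   alpha1 A->E1 (Cyp19), alpha2 A->T (Hsd17b1), alpha3 T->A (Hsd17b2),
#'   alpha4 T->E2 (Cyp19), alpha5 E1->E2 (Hsd17b1),
#'   alpha6 E2->E1 (Hsd17b2).
#' @export
reaction_fluxes <- function(state, params, fc = fold_changes()) {
  A <- max(state[["A_GC"]], 0); T <- max(state[["T_GC"]], 0)
  E1 <- max(state[["E1_GC"]], 0); E2 <- max(state[["E2_GC"]], 0)
  PC <- state[["prot_Cyp19"]]; PH1 <- state[["prot_Hsd17b1"]]
  PH2 <- state[["prot_Hsd17b2"]]
  lam <- params$lambda; xi <- params$xi; fM <- fc[["km"]]
  mm <- function(V, Z, K, KC, C) {
    den <- K * (1 + C / KC) + Z
    if (den <= 0 || Z <= 0) 0 else V * Z / den
  }
  a <- c(
    alpha1 = mm(lam[["Cyp19_A"]] * PC, A, xi[["Cyp19_A"]] * fM,
                xi[["Cyp19_T"]] * fM, T),
    alpha2 = mm(lam[["Hsd17b1_A"]] * PH1, A, xi[["Hsd17b1_A"]],
                xi[["Hsd17b1_E1"]], E1),
    alpha3 = mm(lam[["Hsd17b2_T"]] * PH2, T, xi[["Hsd17b2_T"]],
                xi[["Hsd17b2_E2"]], E2),
    alpha4 = mm(lam[["Cyp19_T"]] * PC, T, xi[["Cyp19_T"]] * fM,
                xi[["Cyp19_A"]] * fM, A),
    alpha5 = mm(lam[["Hsd17b1_E1"]] * PH1, E1, xi[["Hsd17b1_E1"]],
                xi[["Hsd17b1_A"]], A),
    alpha6 = mm(lam[["Hsd17b2_E2"]] * PH2, E2, xi[["Hsd17b2_E2"]],
                xi[["Hsd17b2_T"]], T))
  attr(a, "reaction") <- unname(.reactions)
  a
}

#' Gene-expression time derivatives
#'
#' mRNA synthesis of the two FSH-inducible enzymes is the baseline rate
#' times the inter-study factor `sigma_L`, the disruptor fold `f_X` and
#' the multiplicative FSH induction `(1 + kappa * FSH_GC)`; the
#' inactivating enzyme Hsd17b2 is neither FSH- nor disruptor-controlled.
#' Proteins follow first-order translation/degradation.  With
#' `sigma_L = 1`, unit folds and no FSH, the baseline pools are an
#' equilibrium by construction (see [derive_steady_state_rates()]).
#'
#' @inheritParams reaction_fluxes
#' @param sigma_L inter-study transcription variability factor (> 0).
#' @return named vector of time derivatives of the three mRNAs and
#'   three proteins (pg/min).
#' @export
gene_expression_rhs <- function(state, params, fc = fold_changes(),
                                sigma_L = 1) {
  stopifnot(sigma_L > 0)
  FSH <- state[["FSH_GC"]]
  m <- state[c("mRNA_Cyp19", "mRNA_Hsd17b1", "mRNA_Hsd17b2")]
  pr <- state[c("prot_Cyp19", "prot_Hsd17b1", "prot_Hsd17b2")]
  syn <- c(sigma_L * fc[["cyp19"]] * params$nu_mRNA[["Cyp19"]] *
             (1 + params$kappa[["Cyp19"]] * FSH),
           sigma_L * fc[["hsd17b1"]] * params$nu_mRNA[["Hsd17b1"]] *
             (1 + params$kappa[["Hsd17b1"]] * FSH),
           sigma_L * params$nu_mRNA[["Hsd17b2"]])
  dm <- syn - params$delta_mRNA * m
  dp <- params$nu_prot * m - params$delta_prot * pr
  setNames(c(dm, dp),
           c(paste0("mRNA_", .enzymes), paste0("prot_", .enzymes)))
}

#' Tritiated-water formation rate
#'
#' The aromatase activity assay counts one labelled water molecule per
#' aromatization of labelled androstenedione, so the readout rate is the
#' A->E1 flux alone.
#'
#' @param fluxes a vector from [reaction_fluxes()].
#' @return formation rate of tritiated water (pmoles/min/cell).
#' @export
t2o_rate <- function(fluxes) unname(fluxes[["alpha1"]])
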