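#' Calibration data format
#'
#' Calibration datasets are flat tables with one measured endpoint per
#' row.  Required columns:
#'
#' * `study` — study identifier (integer or character);
#' * `endpoint_class` — `"mRNA_protein"` or `"hormone"` (selects the
#'   measurement-error scale, `Sigma2` or `Sigma3`);
#' * `endpoint` — what was measured: medium hormone quantities per cell
#'   (`A_med`, `T_med`, `E1_med`, `E2_med`, pmoles), cumulative
#'   tritiated water (`T2O`), absolute per-cell mRNA/protein quantities
#'   (`mRNA_Cyp19`, ..., `prot_Hsd17b2`, pg), or FSH-response
#'   fold-changes (`fold_mRNA_Cyp19`, `fold_mRNA_Hsd17b1`);
#' * condition columns — `time_min`, `fsh_ng_ml`, `a0_nM`, `t0_nM`,
#'   `e10_nM`, `e20_nM`, `fc_cyp19`, `fc_hsd17b1`, `activity_fold`,
#'   `cells_per_ml`, `volume_ml`;
#' * `value` — the observed value (> 0, lognormal support);
#' * `replicate` — replicate number.
#'
#' @param data a data.frame to validate.
#' @return the validated data.frame (invisibly for the checker).
#' @seealso [generate_collection()] for synthetic data in this format,
#'   [read_calibration_data()] to load a CSV.
#' @export
calibration_data <- function(data) {
  need <- c("study", "endpoint_class", "endpoint", "time_min",
            "fsh_ng_ml", "a0_nM", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("calibration data lacks column(s): ", paste(miss, collapse = ", "))
  defaults <- list(t0_nM = 0, e10_nM = 0, e20_nM = 0, fc_cyp19 = 1,
                   fc_hsd17b1 = 1, activity_fold = 1,
                   cells_per_ml = 3e5, volume_ml = 2, replicate = 1L)
  for (nm in names(defaults))
    if (is.null(data[[nm]])) data[[nm]] <- rep(defaults[[nm]], nrow(data))
  if (any(!data$endpoint_class %in% c("mRNA_protein", "hormone")))
    stop("endpoint_class must be 'mRNA_protein' or 'hormone'")
  if (any(!is.na(data$value) & data$value <= 0))
    stop("observed values must be positive (lognormal error model)")
  data
}

#' @rdname calibration_data
#' @param path CSV file path.
#' @export
read_calibration_data <- function(path) {
  calibration_data(read.csv(path, comment.char = "#"))
}

#' @rdname calibration_data
#' @param data validated calibration data.
#' @export
write_calibration_data <- function(data, path) {
  write.csv(calibration_data(data), path, row.names = FALSE)
  invisible(path)
}

# condition signature used to share one model solve between observations
.condition_key <- function(d) {
  paste(d$time_min, d$fsh_ng_ml, d$a0_nM, d$t0_nM, d$e10_nM, d$e20_nM,
        d$fc_cyp19, d$fc_hsd17b1, d$activity_fold, d$cells_per_ml,
        d$volume_ml, sep = "|")
}

.expression_endpoints <- function() {
  c(paste0("mRNA_", .enzymes), paste0("prot_", .enzymes),
    "fold_mRNA_Cyp19", "fold_mRNA_Hsd17b1")
}
.hormone_endpoints <- function() {
  c("A_med", "T_med", "E1_med", "E2_med", "T2O")
}

# closed-form gene expression under constant intracellular FSH
# returns list(m = 3 x nt, P = 3 x nt) for one condition
.gene_closed_form <- function(params, sigma_L, fc_vec, Fgc, t) {
  dm <- params$delta_mRNA; dp <- params$delta_prot
  ind <- c(fc_vec[["cyp19"]] * (1 + params$kappa[["Cyp19"]] * Fgc),
           fc_vec[["hsd17b1"]] * (1 + params$kappa[["Hsd17b1"]] * Fgc),
           1)
  m0 <- sigma_L * params$nu_mRNA / dm
  minf <- sigma_L * ind * params$nu_mRNA / dm
  m <- outer(minf, rep(1, length(t))) +
    outer(m0 - minf, exp(-dm * t))
  P0 <- params$nu_prot * m0 / dp
  Pinf <- params$nu_prot * minf / dp
  C2 <- params$nu_prot * (m0 - minf) / (dp - dm)
  C1 <- P0 - Pinf - C2
  P <- outer(Pinf, rep(1, length(t))) + outer(C1, exp(-dp * t)) +
    outer(C2, exp(-dm * t))
  list(m = m, P = P, m0 = m0)
}

#' Model predictions for calibration endpoints
#'
#' Computes the model's expected value for each row of a calibration
#' table, given a sampled kinetic/regulatory vector and a study's
#' transcription factor.  Expression endpoints use the closed-form
#' gene-expression solution (intracellular FSH at partition
#' equilibrium); hormone endpoints use the reduced in vitro model
#' ([simulate_invitro_qss()]), one solve per distinct experimental
#' condition.
#'
#' @param theta named vector with the 10 calibrated parameters (subset
#'   of [map_estimates()] names); missing entries fall back to `params`.
#' @param sigma_L the study's transcription variability factor.
#' @param conditions calibration rows (see [calibration_data()]).
#' @param params base [gc_parameters()].
#' @param rtol,atol reduced-model error control.
#' @return numeric vector of predictions, parallel to the rows.
#' @export
predict_endpoints <- function(theta, sigma_L, conditions,
                              params = gc_parameters(),
                              rtol = 1e-4, atol = 1e-12) {
  p <- .apply_theta(params, theta)
  d <- calibration_data(conditions)
  out <- numeric(nrow(d))
  Vgc <- p$V_GC
  is_expr <- d$endpoint %in% .expression_endpoints()
  is_horm <- d$endpoint %in% .hormone_endpoints()
  if (any(!(is_expr | is_horm)))
    stop("unknown endpoint(s): ",
         paste(unique(d$endpoint[!(is_expr | is_horm)]), collapse = ", "))

  key <- .condition_key(d)
  for (k in unique(key)) {
    rows <- which(key == k)
    r1 <- d[rows[1], ]
    V_med <- 1 / r1$cells_per_ml
    fsh0 <- r1$fsh_ng_ml * 1000 / r1$cells_per_ml
    vr <- Vgc / p$R_oi[["FSH"]]
    Fgc <- fsh0 * vr / (V_med + vr)
    fc_vec <- fold_changes(r1$fc_cyp19, r1$fc_hsd17b1,
                           km_fold_change(r1$activity_fold))
    e_rows <- rows[is_expr[rows]]
    if (length(e_rows)) {
      gcf <- .gene_closed_form(p, sigma_L, fc_vec, Fgc, r1$time_min)
      species <- sub("^(fold_)?(mRNA|prot)_", "\\2_", d$endpoint[e_rows])
      for (i in seq_along(e_rows)) {
        ep <- d$endpoint[e_rows[i]]
        enz <- sub(".*_(Cyp19|Hsd17b1|Hsd17b2)$", "\\1", ep)
        j <- match(enz, .enzymes)
        out[e_rows[i]] <-
          if (grepl("^fold_mRNA", ep)) gcf$m[j, 1] / gcf$m0[j]
          else if (grepl("^mRNA", ep)) gcf$m[j, 1]
          else gcf$P[j, 1]
      }
    }
    h_rows <- rows[is_horm[rows]]
    if (length(h_rows)) {
      med0 <- c(r1$a0_nM, r1$t0_nM, r1$e10_nM, r1$e20_nM) / r1$cells_per_ml
      pv <- .pack_params(p, fc_vec, sigma_L, V_med)
      m0 <- sigma_L * p$nu_mRNA / p$delta_mRNA
      p0 <- p$nu_prot * m0 / p$delta_prot
      sim <- .qssa_run(pv, med0, fsh0, unname(m0), unname(p0),
                       r1$time_min, rtol, atol)
      for (i in seq_along(h_rows)) {
        ep <- d$endpoint[h_rows[i]]
        out[h_rows[i]] <- if (ep == "T2O") sim[1, "T2O"] else {
          h <- sub("_med$", "", ep)
          sim[1, paste0(h, "_tot")] - sim[1, paste0(h, "_GC")]
        }
      }
    }
  }
  out
}
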