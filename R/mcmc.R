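# ---- internal calibration context ------------------------------------
# Precomputes everything the sampler reuses: per-study condition tables,
# observation vectors on the log scale, packed parameter templates, and
# the mapping from conditions to observation slots.

.calib_context <- function(data, params, rtol = 3e-4, atol = 1e-11) {
  data <- calibration_data(data)
  studies <- unique(data$study)
  pv_base <- .pack_params(params)
  ctx <- list(params = params, studies = studies, pv_base = pv_base,
              nu = unname(params$nu_mRNA), nuP = unname(params$nu_prot),
              dm = params$delta_mRNA, dp = params$delta_prot,
              rtol = rtol, atol = atol)
  qssa_col <- function(ep) switch(ep,
    A_med = c(2L, 7L), T_med = c(3L, 8L), E1_med = c(4L, 9L),
    E2_med = c(5L, 10L), T2O = c(6L, 0L))
  ctx$study <- lapply(seq_along(studies), function(j) {
    d <- data[data$study == studies[j], , drop = FALSE]
    is_e <- d$endpoint %in% .expression_endpoints()
    key <- .condition_key(d)
    uk <- unique(key)
    obs_e <- log(d$value[is_e]); obs_h <- log(d$value[!is_e])
    e_slot <- cumsum(is_e); h_slot <- cumsum(!is_e)
    conds <- lapply(uk, function(k) {
      rows <- which(key == k)
      r1 <- d[rows[1], ]
      er <- rows[is_e[rows]]; hr <- rows[!is_e[rows]]
      list(
        Vmed = 1 / r1$cells_per_ml,
        med0 = c(r1$a0_nM, r1$t0_nM, r1$e10_nM, r1$e20_nM) / r1$cells_per_ml,
        fsh0 = r1$fsh_ng_ml * 1000 / r1$cells_per_ml,
        fM = 1 / r1$activity_fold, fC = r1$fc_cyp19, fH = r1$fc_hsd17b1,
        time = r1$time_min,
        uses_fsh = r1$fsh_ng_ml > 0,
        has_h = length(hr) > 0,
        e_slots = e_slot[er], e_endpoints = d$endpoint[er],
        e_enz = match(sub(".*_(Cyp19|Hsd17b1|Hsd17b2)$", "\\1",
                          d$endpoint[er]), .enzymes),
        e_type = ifelse(grepl("^fold_mRNA", d$endpoint[er]), 1L,
                        ifelse(grepl("^mRNA", d$endpoint[er]), 2L, 3L)),
        h_slots = h_slot[hr],
        h_cols = lapply(d$endpoint[hr], qssa_col))
    })
    list(conds = conds, obs_e = obs_e, obs_h = obs_h,
         n_e = sum(is_e), n_h = sum(!is_e))
  })
  ctx
}

# closed-form expression predictions (log scale) for one condition
.cond_expr_pred <- function(ctx, cond, theta, sl) {
  Vgc <- ctx$params$V_GC
  vr <- Vgc / ctx$params$R_oi[["FSH"]]
  Fgc <- cond$fsh0 * vr / (cond$Vmed + vr)
  ind <- c(cond$fC * (1 + theta[[1]] * Fgc),
           cond$fH * (1 + theta[[2]] * Fgc), 1)
  m0 <- sl * ctx$nu / ctx$dm
  minf <- m0 * ind
  em <- exp(-ctx$dm * cond$time)
  m <- minf + (m0 - minf) * em
  out <- numeric(length(cond$e_slots))
  for (i in seq_along(out)) {
    enz <- cond$e_enz[i]
    out[i] <- switch(cond$e_type[i],
      log(m[enz] / m0[enz]),
      log(m[enz]),
      {
        P0 <- ctx$nuP[enz] * m0[enz] / ctx$dp
        Pinf <- ctx$nuP[enz] * minf[enz] / ctx$dp
        C2 <- ctx$nuP[enz] * (m0[enz] - minf[enz]) / (ctx$dp - ctx$dm)
        log(Pinf + (P0 - Pinf - C2) * exp(-ctx$dp * cond$time) + C2 * em)
      })
  }
  out
}

# reduced-model hormone predictions (log scale) for one condition
.cond_horm_pred <- function(ctx, cond, theta, sl) {
  pv <- ctx$pv_base
  pv[1:10] <- theta
  pv[34] <- cond$Vmed; pv[35] <- cond$fM; pv[36] <- cond$fC
  pv[37] <- cond$fH; pv[38] <- sl
  m0 <- sl * ctx$nu / ctx$dm
  p0 <- ctx$nuP * m0 / ctx$dp
  sim <- .qssa_raw(pv, cond$med0, cond$fsh0, m0, p0, cond$time,
                   ctx$rtol, ctx$atol)
  vapply(cond$h_cols, function(cc) {
    v <- if (cc[2] == 0L) sim[1, cc[1]] else sim[1, cc[1]] - sim[1, cc[2]]
    # floor: extreme parameter corners can deplete a pool to exactly
    # zero (solver clamp); keep the log-likelihood finite and steeply
    # repulsive rather than undefined
    if (!is.finite(v) || v < 1e-30) v <- 1e-30
    log(v)
  }, 0)
}

# full prediction state for a parameter vector: per-study aligned
# log-prediction vectors
.predict_state <- function(ctx, v) {
  m <- length(ctx$study)
  theta <- v[1:10]
  lapply(seq_len(m), function(j) {
    st <- ctx$study[[j]]
    sl <- v[[paste0("sigma_L", j)]]
    pe <- numeric(st$n_e); ph <- numeric(st$n_h)
    for (cond in st$conds) {
      if (length(cond$e_slots))
        pe[cond$e_slots] <- .cond_expr_pred(ctx, cond, theta, sl)
      if (length(cond$h_slots))
        ph[cond$h_slots] <- .cond_horm_pred(ctx, cond, theta, sl)
    }
    list(pe = pe, ph = ph)
  })
}

.study_ll <- function(st, pred, S2, S3) {
  c(e = if (st$n_e) sum(dnorm(st$obs_e, pred$pe, S2, log = TRUE)) else 0,
    h = if (st$n_h) sum(dnorm(st$obs_h, pred$ph, S3, log = TRUE)) else 0)
}

# default update blocks: Vmax/Km pairs jointly, everything else scalar
.default_blocks <- function(n_studies) {
  blocks <- list(
    list(name = "Cyp19_A", comps = c("lambda_Cyp19_A", "xi_Cyp19_A"),
         type = "kinetic"),
    list(name = "Cyp19_T", comps = c("lambda_Cyp19_T", "xi_Cyp19_T"),
         type = "kinetic"),
    list(name = "Hsd17b1_A", comps = c("lambda_Hsd17b1_A", "xi_Hsd17b1_A"),
         type = "kinetic"),
    list(name = "Hsd17b1_E1", comps = c("lambda_Hsd17b1_E1",
                                        "xi_Hsd17b1_E1"),
         type = "kinetic"),
    list(name = "kappa_Cyp19", comps = "kappa_Cyp19", type = "kappa"),
    list(name = "kappa_Hsd17b1", comps = "kappa_Hsd17b1", type = "kappa"),
    list(name = "mu0", comps = "mu0", type = "hyper"),
    list(name = "Sigma1", comps = "Sigma1", type = "hyper"),
    list(name = "Sigma2", comps = "Sigma2", type = "Sigma2"),
    list(name = "Sigma3", comps = "Sigma3", type = "Sigma3"))
  for (j in seq_len(n_studies))
    blocks[[length(blocks) + 1]] <-
      list(name = paste0("sigma_L", j), comps = paste0("sigma_L", j),
           type = "sigma_L", study = j)
  # directional move along the soft posterior direction of the
  # hierarchy: enzyme activities up, transcription factors (and their
  # hierarchical mean) down, which leaves the hormone predictions
  # nearly invariant and is only constrained by expression data
  blocks[[length(blocks) + 1]] <- list(
    name = "activity_scale",
    comps = c("lambda_Cyp19_A", "lambda_Cyp19_T", "lambda_Hsd17b1_A",
              "lambda_Hsd17b1_E1", "mu0",
              paste0("sigma_L", seq_len(n_studies))),
    dir = c(1, 1, 1, 1, -1, rep(-1, n_studies)),
    type = "ridge")
  # the four Km values jointly: they are mostly prior-dominated and mix
  # poorly when only moved together with their data-constrained Vmax
  blocks[[length(blocks) + 1]] <- list(
    name = "km_joint",
    comps = c("xi_Cyp19_A", "xi_Cyp19_T", "xi_Hsd17b1_A",
              "xi_Hsd17b1_E1"),
    type = "kinetic")
  # all-parameter proposal with covariance adapted from the chain
  # history during burn-in (frozen afterwards); captures the remaining
  # posterior correlations the scalar/pair blocks cannot follow
  blocks[[length(blocks) + 1]] <- list(
    name = "joint_adaptive", comps = .sampled_names(n_studies),
    type = "joint")
  blocks[[length(blocks) + 1]] <- list(
    name = "joint_adaptive2", comps = .sampled_names(n_studies),
    type = "joint")
  blocks
}

#' Hierarchical Bayesian calibration by Metropolis-Hastings sampling
#'
#' Samples the joint posterior of the ten kinetic/regulatory
#' parameters, the inter-study hyperparameters, the per-study
#' transcription factors and the two measurement-error scales, given a
#' calibration dataset.  Updates are random-walk proposals on the log
#' scale, applied blockwise (each Vmax/Km pair of one reaction jointly,
#' all other components individually); proposal scales adapt towards a
#' 20-45% acceptance rate during burn-in (the first half of each
#' chain) and are frozen afterwards, preserving detailed balance for
#' the retained samples.  Model evaluations are shared across all
#' observations of an experimental condition and only the conditions a
#' block can affect are recomputed.
#'
#' @param data a [calibration_data()] table; studies are numbered
#'   `sigma_L1..` in order of first appearance.
#' @param priors a [calibration_priors()] list (its `n_studies` must
#'   match the data).
#' @param params base [gc_parameters()] (non-sampled constants).
#' @param n_iter iterations (full update sweeps) per chain.
#' @param n_chains number of chains (>= 2 for diagnostics).
#' @param seed integer; chain c uses `seed + c - 1`.
#' @param init optional named start vector (default: independent draws
#'   from the priors per chain).
#' @param target_accept acceptance-rate window targeted during
#'   adaptation.
#' @param rtol,atol reduced-model error control for the likelihood.
#' @return object of class `gc_chains`: list with `samples` (one
#'   `n_iter x n_par` matrix per chain), `log_post`, `acceptance`,
#'   `scales`, `seeds`, `n_burn`, `priors`.
#' @export
metropolis_hastings <- function(data, priors, params = gc_parameters(),
                                n_iter = 5000, n_chains = 3, seed = 1,
                                init = NULL,
                                target_accept = c(0.2, 0.45),
                                rtol = 3e-4, atol = 1e-11) {
  stopifnot(n_chains >= 1, n_iter >= 10)
  m <- priors$n_studies
  if (is.null(data) || nrow(data) == 0) {
    # no data: the sampler targets the joint prior (useful for
    # prior-recovery checks)
    ctx <- list(params = params, studies = seq_len(m),
                pv_base = .pack_params(params),
                nu = unname(params$nu_mRNA), nuP = unname(params$nu_prot),
                dm = params$delta_mRNA, dp = params$delta_prot,
                rtol = rtol, atol = atol,
                study = replicate(m, list(conds = list(),
                                          obs_e = numeric(0),
                                          obs_h = numeric(0),
                                          n_e = 0L, n_h = 0L),
                                  simplify = FALSE))
  } else {
    data <- calibration_data(data)
    if (length(unique(data$study)) != m)
      stop("priors declare ", m, " studies but the data contain ",
           length(unique(data$study)))
    ctx <- .calib_context(data, params, rtol, atol)
  }
  pnames <- .sampled_names(m)
  blocks <- .default_blocks(m)
  n_burn <- floor(n_iter / 2)
  target_mid <- mean(target_accept)

  # condition sets affected by each block (precomputed per study)
  horm_conds_l <- lapply(seq_len(m), function(j)
    which(vapply(ctx$study[[j]]$conds, function(cc) cc$has_h, TRUE)))
  fsh_conds_l <- lapply(seq_len(m), function(j)
    which(vapply(ctx$study[[j]]$conds, function(cc) cc$uses_fsh, TRUE)))
  sl_names <- paste0("sigma_L", seq_len(m))
  sl_idx <- match(sl_names, pnames)
  # per-component top-level prior specs (NULL for the sigma_L, which have
  # the hierarchical prior instead)
  spec_of <- setNames(vector("list", length(pnames)), pnames)
  for (nm in names(priors$top)) spec_of[[nm]] <- priors$top[[nm]]

  run_chain <- function(chain_seed) .with_seed(chain_seed, {
    v <- if (!is.null(init)) init[pnames] else {
      # start from the prior core (independent quantile draws between
      # 0.2 and 0.8): overdispersed across chains relative to the
      # posterior, while avoiding the extreme prior corners where the
      # depletion cliffs of the kinetic model make local moves useless
      top <- vapply(names(priors$top), function(nm)
        qprior(priors$top[[nm]], runif(1, 0.2, 0.8)), 0)
      sl <- rlnorm(m, log(top[["mu0"]]), min(max(top[["Sigma1"]], 0.05),
                                             0.5))
      setNames(c(top[1:12], sl, top[c("Sigma2", "Sigma3")]), pnames)
    }
    pred <- .predict_state(ctx, v)
    ll_parts <- t(vapply(seq_len(m), function(j)
      .study_ll(ctx$study[[j]], pred[[j]], v[["Sigma2"]], v[["Sigma3"]]),
      c(e = 0, h = 0)))
    lp <- log_prior(v, priors)
    if (!is.finite(lp)) stop("initial vector outside the prior support")

    scales <- rep(0.25, length(blocks))
    jb <- which(vapply(blocks, function(b) b$type == "joint", TRUE))
    scales[jb] <- 0.6   # multiplies the 2.38/sqrt(d)-scaled factor
    joint_chol <- NULL
    blk_chol <- vector("list", length(blocks))   # learned pair shapes
    acc <- rep(0L, length(blocks)); tries <- rep(0L, length(blocks))
    acc_win <- rep(0L, length(blocks)); tries_win <- rep(0L, length(blocks))
    samples <- matrix(NA_real_, n_iter, length(pnames),
                      dimnames = list(NULL, pnames))
    log_post <- numeric(n_iter)

    kin_par <- 0L
    for (it in seq_len(n_iter)) {
      kin_seen <- 0L
      for (b in seq_along(blocks)) {
        bl <- blocks[[b]]
        # the ridge move seeds exploration of the hierarchy's soft
        # direction during burn-in; afterwards the adaptive joint
        # proposal covers it
        if (bl$type == "ridge" && it > n_burn) next
        # round-robin: two of the four Vmax/Km pairs per sweep
        if (bl$type == "kinetic" && length(ci <- bl$comps) == 2) {
          kin_seen <- kin_seen + 1L
          if ((kin_seen + it) %% 2L == 0L) next
        }
        ci <- bl$comps
        v2 <- v
        if (bl$type == "ridge") {
          v2[ci] <- v[ci] * exp(rnorm(1, 0, scales[b]) * bl$dir)
        } else if (bl$type == "joint") {
          if (is.null(joint_chol)) next
          v2[ci] <- v[ci] * exp(scales[b] *
                                  drop(joint_chol %*% rnorm(length(ci))))
        } else if (!is.null(blk_chol[[b]])) {
          # pair proposal shaped by the learned posterior covariance
          v2[ci] <- v[ci] * exp(scales[b] *
                                  drop(blk_chol[[b]] %*% rnorm(length(ci))))
        } else {
          v2[ci] <- v[ci] * exp(rnorm(length(ci), 0, scales[b]))
        }
        tries[b] <- tries[b] + 1L; tries_win[b] <- tries_win[b] + 1L
        # incremental log-prior change
        d_lp <- 0
        for (nm in ci) {
          sp <- spec_of[[nm]]
          if (!is.null(sp)) d_lp <- d_lp + dprior(sp, v2[[nm]]) -
              dprior(sp, v[[nm]])
        }
        if (bl$type == "sigma_L") {
          d_lp <- d_lp +
            dlnorm(v2[[ci]], log(v[["mu0"]]), v[["Sigma1"]], log = TRUE) -
            dlnorm(v[[ci]], log(v[["mu0"]]), v[["Sigma1"]], log = TRUE)
        } else if (bl$type %in% c("ridge", "joint")) {
          if (v2[["Sigma1"]] <= 0) d_lp <- -Inf
          else d_lp <- d_lp +
            sum(dlnorm(v2[sl_idx], log(v2[["mu0"]]), v2[["Sigma1"]],
                       log = TRUE)) -
            sum(dlnorm(v[sl_idx], log(v[["mu0"]]), v[["Sigma1"]],
                       log = TRUE))
        } else if (bl$type == "hyper") {
          sl <- v[sl_idx]
          d_lp <- d_lp +
            sum(dlnorm(sl, log(v2[["mu0"]]), v2[["Sigma1"]], log = TRUE)) -
            sum(dlnorm(sl, log(v[["mu0"]]), v[["Sigma1"]], log = TRUE))
        }
        if (is.finite(d_lp)) {
          theta2 <- v2[1:10]
          S2n <- v2[["Sigma2"]]; S3n <- v2[["Sigma3"]]
          d_ll <- 0
          upd <- list()   # j -> list(pe=, ph=, ll=)
          if (bl$type %in% c("kinetic", "kappa")) {
            for (j in seq_len(m)) {
              st <- ctx$study[[j]]
              sl_j <- v2[[sl_idx[j]]]
              ks <- if (bl$type == "kinetic") horm_conds_l[[j]] else
                fsh_conds_l[[j]]
              if (!length(ks)) next
              pe <- pred[[j]]$pe; ph <- pred[[j]]$ph
              for (k in ks) {
                cond <- st$conds[[k]]
                if (bl$type == "kappa" && length(cond$e_slots))
                  pe[cond$e_slots] <- .cond_expr_pred(ctx, cond, theta2,
                                                      sl_j)
                if (length(cond$h_slots))
                  ph[cond$h_slots] <- .cond_horm_pred(ctx, cond, theta2,
                                                      sl_j)
              }
              nl <- .study_ll(st, list(pe = pe, ph = ph), S2n, S3n)
              d_ll <- d_ll + sum(nl) - sum(ll_parts[j, ])
              upd[[as.character(j)]] <- list(pe = pe, ph = ph, ll = nl)
            }
          } else if (bl$type == "sigma_L") {
            j <- bl$study
            st <- ctx$study[[j]]
            sl_j <- v2[[sl_idx[j]]]
            pe <- numeric(st$n_e); ph <- numeric(st$n_h)
            for (cond in st$conds) {
              if (length(cond$e_slots))
                pe[cond$e_slots] <- .cond_expr_pred(ctx, cond, theta2, sl_j)
              if (length(cond$h_slots))
                ph[cond$h_slots] <- .cond_horm_pred(ctx, cond, theta2, sl_j)
            }
            nl <- .study_ll(st, list(pe = pe, ph = ph), S2n, S3n)
            d_ll <- sum(nl) - sum(ll_parts[j, ])
            upd[[as.character(j)]] <- list(pe = pe, ph = ph, ll = nl)
          } else if (bl$type %in% c("ridge", "joint")) {
            pred2 <- .predict_state(ctx, v2)
            for (j in seq_len(m)) {
              st <- ctx$study[[j]]
              nl <- .study_ll(st, pred2[[j]], S2n, S3n)
              d_ll <- d_ll + sum(nl) - sum(ll_parts[j, ])
              upd[[as.character(j)]] <- list(pe = pred2[[j]]$pe,
                                             ph = pred2[[j]]$ph, ll = nl)
            }
          } else if (bl$type == "Sigma2") {
            for (j in seq_len(m)) {
              st <- ctx$study[[j]]
              if (!st$n_e) next
              nle <- sum(dnorm(st$obs_e, pred[[j]]$pe, S2n, log = TRUE))
              d_ll <- d_ll + nle - ll_parts[j, "e"]
              upd[[as.character(j)]] <- list(ll = c(e = nle,
                                                    h = ll_parts[j, "h"]))
            }
          } else if (bl$type == "Sigma3") {
            for (j in seq_len(m)) {
              st <- ctx$study[[j]]
              if (!st$n_h) next
              nlh <- sum(dnorm(st$obs_h, pred[[j]]$ph, S3n, log = TRUE))
              d_ll <- d_ll + nlh - ll_parts[j, "h"]
              upd[[as.character(j)]] <- list(ll = c(e = ll_parts[j, "e"],
                                                    h = nlh))
            }
          }  # hyper: likelihood unchanged
          log_alpha <- d_ll + d_lp + sum(log(v2[ci]) - log(v[ci]))
          if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
            v <- v2; lp <- lp + d_lp
            for (js in names(upd)) {
              j <- as.integer(js)
              if (!is.null(upd[[js]]$pe)) {
                pred[[j]]$pe <- upd[[js]]$pe
                pred[[j]]$ph <- upd[[js]]$ph
              }
              ll_parts[j, ] <- upd[[js]]$ll
            }
            acc[b] <- acc[b] + 1L; acc_win[b] <- acc_win[b] + 1L
          }
        }
        if (it <= n_burn && tries_win[b] >= 25L) {
          rate <- acc_win[b] / tries_win[b]
          scales[b] <- min(5, max(1e-3,
                                  scales[b] * exp(0.6 * (rate - target_mid))))
          acc_win[b] <- 0L; tries_win[b] <- 0L
        }
      }
      samples[it, ] <- v
      log_post[it] <- lp + sum(ll_parts)
      if (it <= n_burn && it >= 300 && it %% 200 == 0) {
        hist_keep <- max(100, floor(it / 2)):it
        cv <- stats::cov(log(samples[hist_keep, , drop = FALSE]))
        cv <- cv + diag(1e-8, ncol(cv))
        ch_try <- tryCatch(chol(cv), error = function(e) NULL)
        if (!is.null(ch_try))
          joint_chol <- t(ch_try) * (2.38 / sqrt(ncol(cv)))
        for (b in seq_along(blocks))
          if (blocks[[b]]$type == "kinetic") {
            ci <- match(blocks[[b]]$comps, pnames)
            sub <- cv[ci, ci] + diag(1e-10, length(ci))
            ch2 <- tryCatch(chol(sub), error = function(e) NULL)
            if (!is.null(ch2)) {
              if (is.null(blk_chol[[b]])) scales[b] <- 1
              blk_chol[[b]] <- t(ch2) * (2.38 / sqrt(length(ci)))
            }
          }
      }
    }
    rates <- acc / pmax(tries, 1L)
    stalled <- tries > 0L & acc == 0L
    if (any(stalled))
      warning("no accepted proposal for block(s): ",
              paste(vapply(blocks[stalled], `[[`, "", "name"),
                    collapse = ", "))
    list(samples = samples, log_post = log_post, acceptance = rates,
         scales = scales, final = v, final_ll = sum(ll_parts))
  })

  seeds <- seed + seq_len(n_chains) - 1L
  chains <- lapply(seeds, run_chain)
  structure(list(
    samples = lapply(chains, `[[`, "samples"),
    log_post = lapply(chains, `[[`, "log_post"),
    acceptance = do.call(rbind, lapply(chains, `[[`, "acceptance")),
    scales = do.call(rbind, lapply(chains, `[[`, "scales")),
    finals = lapply(chains, `[[`, "final"),
    final_ll = vapply(chains, `[[`, 0, "final_ll"),
    seeds = seeds, n_iter = n_iter, n_burn = n_burn,
    block_names = vapply(blocks, `[[`, "", "name"),
    priors = priors), class = "gc_chains")
}

#' @export
print.gc_chains <- function(x, ...) {
  cat("<gc_chains>", length(x$samples), "chains x", x$n_iter,
      "iterations (burn-in", x$n_burn, ")\n")
  cat("  mean acceptance:",
      paste(sprintf("%.2f", colMeans(x$acceptance)), collapse = " "), "\n")
  invisible(x)
}

#' Potential scale reduction diagnostic
#'
#' Classic between/within-chain variance ratio computed per parameter
#' on the retained tail of each chain:
#' `Rhat = sqrt(((n-1)/n * W + (1 + 1/m) * B/n) / W)`.
#' Computed on the log of the samples by default (all sampled
#' parameters are positive and proposals are log-scale random walks).
#'
#' @param chains a `gc_chains` object, or a list of chain matrices.
#' @param use_last fraction of each chain to retain (default the second
#'   half).
#' @param transform `"log"` or `"identity"`.
#' @return named vector of Rhat values.
#' @export
gelman_rubin <- function(chains, use_last = 0.5,
                         transform = c("log", "identity")) {
  transform <- match.arg(transform)
  mats <- if (inherits(chains, "gc_chains")) chains$samples else chains
  stopifnot(length(mats) >= 2)
  n_all <- nrow(mats[[1]])
  keep <- seq.int(floor(n_all * (1 - use_last)) + 1L, n_all)
  if (length(keep) < 10) stop("need at least 10 retained samples per chain")
  mats <- lapply(mats, function(mm) {
    mm <- mm[keep, , drop = FALSE]
    if (transform == "log") log(mm) else mm
  })
  n <- length(keep); m <- length(mats)
  vapply(seq_len(ncol(mats[[1]])), function(p) {
    x <- vapply(mats, function(mm) mm[, p], numeric(n))
    W <- mean(apply(x, 2, var))
    B_n <- var(colMeans(x))
    if (W == 0) {
      if (B_n == 0) return(1)
      stop("zero within-chain variance for parameter ",
           colnames(mats[[1]])[p])
    }
    sqrt(((n - 1) / n * W + (1 + 1 / m) * B_n) / W)
  }, 0) |> setNames(colnames(mats[[1]]))
}

#' Posterior summary table
#'
#' Pooled over the retained tail of all chains: mean, SD, the maximum a
#' posteriori sample (the sampled vector with the highest log
#' posterior) and percentiles 0.5, 2.5, 97.5 and 99.5.
#'
#' @param chains a `gc_chains` object.
#' @param use_last fraction of each chain to retain.
#' @return data.frame, one row per sampled parameter.
#' @export
posterior_summary <- function(chains, use_last = 0.5) {
  stopifnot(inherits(chains, "gc_chains"))
  n_all <- chains$n_iter
  keep <- seq.int(floor(n_all * (1 - use_last)) + 1L, n_all)
  pooled <- do.call(rbind, lapply(chains$samples,
                                  function(mm) mm[keep, , drop = FALSE]))
  lp <- unlist(lapply(chains$log_post, function(x) x[keep]))
  map_row <- pooled[which.max(lp), ]
  qs <- apply(pooled, 2, quantile, c(0.005, 0.025, 0.975, 0.995))
  data.frame(parameter = colnames(pooled),
             mean = colMeans(pooled),
             sd = apply(pooled, 2, sd),
             map = map_row,
             p0.5 = qs[1, ], p2.5 = qs[2, ], p97.5 = qs[3, ],
             p99.5 = qs[4, ], row.names = NULL)
}

#' Coefficient of variation implied by a log-scale error SD
#'
#' Reporting view of the measurement-error scales:
#' `cv = sqrt(exp(Sigma^2) - 1)`, approximately `Sigma` for small
#' values.
#'
#' @param sigma log-scale SD.
#' @return coefficient of variation.
#' @export
lognormal_cv <- function(sigma) sqrt(exp(sigma^2) - 1)
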