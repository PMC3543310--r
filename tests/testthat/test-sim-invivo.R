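test_that("cyclic input rate combines baseline and scaled template", {
  ci <- cyclic_input(330, 1450, function(t) exp(-0.5 * ((t - 3700) / 300)^2))
  expect_equal(hormone_input_rate(3700, ci), 1780)
  expect_equal(hormone_input_rate(3700 + 5760, ci), 1780) # periodic
  ci0 <- cyclic_input(330, 0, function(t) 1)
  expect_equal(hormone_input_rate(c(0, 2000), ci0), c(330, 330))
  ci1 <- cyclic_input(330, 1450, function(t) 0)
  expect_equal(hormone_input_rate(1234, ci1), 330)
  # sampled-pairs shape with periodic interpolation
  tab <- data.frame(t = c(0, 2880, 5760), v = c(0, 1, 0))
  ci2 <- cyclic_input(0, 10, tab)
  expect_equal(hormone_input_rate(1440, ci2), 5)
  # negative excursions clamp with a warning
  ci3 <- cyclic_input(1, 10, function(t) -1)
  expect_warning(q <- hormone_input_rate(0, ci3), "clamped")
  expect_equal(q, 0)
})

test_that("acyclic forcing converges to a constant state", {
  p <- map_params
  tm <- cycle_template()
  for (h in names(tm$inputs)) tm$inputs[[h]]$Q_scale <- 0
  tr <- simulate_cycle(p, tm, n_cycles = 3)
  expect_lt(attr(tr, "cycle_drift"), 1e-4)
  conc <- ovarian_concentrations(tr, seq(2 * 5760, 3 * 5760, by = 720))
  for (h in c("A", "T", "E1", "E2", "FSH"))
    expect_lt(diff(range(conc[, h])) / max(conc[, h]), 1e-3)
})

test_that("periodic forcing settles on a periodic orbit", {
  p <- map_params
  tr <- fixture("invivo_traj", simulate_cycle(p, n_cycles = 3))
  expect_lt(attr(tr, "cycle_drift"), 1e-3)
})

test_that("whole-ovary mass balance holds along the trajectory", {
  # bookkeeping identity: d(total steroid)/dt = input - blood clearance;
  # integrated on a fine grid after the fast initial clearance
  # transient has passed
  p <- map_params
  tm <- cycle_template()
  tr <- simulate_cycle(p, tm, n_cycles = 2, dt_out = 5)
  geom <- tm$geometry
  keep <- tr[, "time"] >= 1440
  ts <- tr[keep, "time"]
  tot <- (geom$N_GCs * (tr[, "A_GC"] + tr[, "T_GC"] + tr[, "E1_GC"] +
                        tr[, "E2_GC"]) +
    geom$N_others * (tr[, "A_oth"] + tr[, "T_oth"] + tr[, "E1_oth"] +
                     tr[, "E2_oth"]) +
    tr[, "A_ext"] + tr[, "T_ext"] + tr[, "E1_ext"] +
    tr[, "E2_ext"])[keep]
  # the solver integrates the sampled (piecewise-linear) forcing, so
  # the audit must use the same view of the input
  ft <- seq(0, max(ts), by = 5)
  qin_f <- approxfun(ft, hormone_input_rate(ft, tm$inputs$A) +
                       hormone_input_rate(ft, tm$inputs$T))
  qin <- qin_f(ts)
  clear <- p$F_ov * (tr[keep, "A_ext"] + tr[keep, "T_ext"] +
                     tr[keep, "E1_ext"] + tr[keep, "E2_ext"]) /
    p$V_ov_diestrus
  net <- qin - clear
  pred <- tot[1] +
    cumsum(c(0, diff(ts) * (head(net, -1) + tail(net, -1)) / 2))
  expect_equal(pred / tot, rep(1, length(tot)), tolerance = 2e-3)
})

test_that("the calibrated template reproduces the reference cycle fluxes", {
  p <- map_params
  tm <- cycle_template()
  tr <- fixture("invivo_traj", simulate_cycle(p, n_cycles = 3))
  ref <- c(diestrus = 6.09e-9, proestrus = 6.17e-9, estrus = 5.10e-9)
  for (s in names(ref)) {
    t_s <- 2 * 5760 + tm$stage_times[[s]]
    if (t_s > max(tr[, "time"])) t_s <- t_s - 5760
    a1 <- flux_snapshot(tr, t_s, params = p, fc = fold_changes())$flux[1]
    expect_equal(a1, ref[[s]], tolerance = 0.02)
  }
})

test_that("zero input from a zero start stays at zero", {
  p <- gc_parameters(nu_mRNA = c(Cyp19 = 1e-30, Hsd17b1 = 1e-30,
                                 Hsd17b2 = 1e-30))
  tm <- cycle_template()
  for (h in names(tm$inputs)) {
    tm$inputs[[h]]$Q_base <- 0
    tm$inputs[[h]]$Q_scale <- 0
  }
  tr <- simulate_cycle(p, tm, n_cycles = 2)
  horm_cols <- grep("^(A|T|E1|E2|FSH)_", colnames(tr), value = TRUE)
  expect_lt(max(abs(tr[, horm_cols])), 1e-12)
})

test_that("granulosa-cell kinetics are shared between the two simulators", {
  # the in vivo cell must be the same model as the in vitro cell: with
  # matched intracellular conditions the gene-expression and metabolic
  # derivatives agree
  p <- map_params
  tr <- fixture("invivo_traj", simulate_cycle(p, n_cycles = 3))
  i <- nrow(tr)
  g <- function(cn) unname(tr[i, cn])
  st <- cell_state(
    mRNA = c(Cyp19 = g("mRNA_Cyp19"), Hsd17b1 = g("mRNA_Hsd17b1"),
             Hsd17b2 = g("mRNA_Hsd17b2")),
    protein = c(Cyp19 = g("prot_Cyp19"), Hsd17b1 = g("prot_Hsd17b1"),
                Hsd17b2 = g("prot_Hsd17b2")),
    A = g("A_GC"), T = g("T_GC"), E1 = g("E1_GC"),
    E2 = g("E2_GC"), FSH = g("FSH_GC"))
  a <- reaction_fluxes(st, p)
  expect_equal(unname(a), unname(tr[i, paste0("alpha", 1:6)]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Monte-Carlo bands behave and are reproducible", {
  p <- map_params
  mc1 <- monte_carlo_predict(n = 4, seed = 9, params = p, n_cycles = 2,
                             t_grid = c(1440, 4320))
  mc2 <- monte_carlo_predict(n = 4, seed = 9, params = p, n_cycles = 2,
                             t_grid = c(1440, 4320))
  expect_identical(mc1$draws, mc2$draws)
  # collapsed variability equals the deterministic simulation
  mc0 <- monte_carlo_predict(invivo_priors = list(), n = 1, seed = 1,
                             params = p, n_cycles = 2,
                             t_grid = c(1440, 4320))
  tr <- suppressWarnings(simulate_cycle(p, n_cycles = 2))
  det <- ovarian_concentrations(tr, 5760 + c(1440, 4320))
  expect_equal(mc0$mean[, c("A", "T", "E1", "E2", "FSH")],
               det[, c("A", "T", "E1", "E2", "FSH")], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(mc1$lower <= mc1$upper + 1e-12))
})
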