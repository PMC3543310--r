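test_that("compiled and reference right-hand sides agree", {
  p <- map_params
  sys <- flux_system(fsh = 20)
  set.seed(5)
  for (i in 1:3) {
    y <- .invitro_init(sys, p)
    y[7:16] <- y[7:16] + 10^runif(10, -9, -4)
    pv <- .pack_params(p, sys$fc, sys$sigma_L, sys$V_med)
    outC <- deSolve::ode(y, c(0, 60), parms = pv,
                         func = "gc_derivs_invitro",
                         initfunc = "gc_initmod_invitro",
                         dllname = "gcsteroid", rtol = 1e-10, atol = 1e-18)
    outR <- deSolve::ode(y, c(0, 60),
                         func = function(t, s, parms)
                           invitro_rhs(t, s, p, sys),
                         parms = NULL, rtol = 1e-10, atol = 1e-18)
    expect_equal(unname(outC[2, 2:18]), unname(outR[2, 2:18]),
                 tolerance = 1e-7)
  }
})

test_that("untreated control is flat at the baseline equilibrium", {
  p <- map_params
  sys <- invitro_system(duration_min = 2880, sigma_L = 1)
  tr <- simulate_invitro(sys, p, t_grid = c(0, 1440, 2880))
  for (cn in c("mRNA_Cyp19", "prot_Cyp19", "mRNA_Hsd17b2", "prot_Hsd17b2"))
    expect_equal(tr[, cn] / tr[1, cn], rep(1, 3), tolerance = 1e-6)
  expect_equal(unname(tr[1, "mRNA_Cyp19"]), 4.96e-8, tolerance = 1e-2)
})

test_that("closed cultures conserve total steroid to solver tolerance", {
  p <- map_params
  sys <- flux_system(fsh = 20)
  tr <- simulate_invitro(sys, p)
  tot <- rowSums(tr[, c("A_GC", "T_GC", "E1_GC", "E2_GC",
                        "A_med", "T_med", "E1_med", "E2_med")])
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-6)
})

test_that("transport-only equilibrium reproduces the partition ratio", {
  # disable metabolism by zeroing the enzymes (empty-cell initial pools)
  p <- gc_parameters(nu_mRNA = c(Cyp19 = 1e-30, Hsd17b1 = 1e-30,
                                 Hsd17b2 = 1e-30))
  sys <- invitro_system(medium_nM = c(A = 200, T = 50, E1 = 20, E2 = 10),
                        fsh_ng_ml = 10, duration_min = 600)
  tr <- simulate_invitro(sys, p, t_grid = c(0, 600))
  Vgc <- p$V_GC; Vmed <- sys$V_med
  for (h in c("A", "T", "E1", "E2")) {
    c_med <- tr[2, paste0(h, "_med")] / Vmed
    c_gc <- tr[2, paste0(h, "_GC")] / Vgc
    expect_equal(unname(c_med / c_gc), p$R_oi[[h]], tolerance = 1e-3)
  }
  c_med <- tr[2, "FSH_med"] / Vmed
  expect_equal(unname(c_med / (tr[2, "FSH_GC"] / Vgc)), 1,
               tolerance = 1e-3)
})

test_that("48-h fluxes reproduce the reference values with and without FSH", {
  p <- map_params
  tr0 <- fixture("flux_traj_nofsh", simulate_invitro(flux_system(0), p))
  a0 <- flux_snapshot(tr0, 2880)$flux[1]
  tr1 <- fixture("flux_traj_fsh", simulate_invitro(flux_system(20), p))
  a1 <- flux_snapshot(tr1, 2880)$flux[1]
  expect_equal(a0, 7.29e-9, tolerance = 0.025)
  expect_equal(a1, 8.72e-8, tolerance = 0.025)
  expect_equal(a1 / a0, 12, tolerance = 0.03)
})

test_that("tritiated water equals the integral of the A->E1 flux", {
  p <- map_params
  tr <- fixture("flux_traj_nofsh", simulate_invitro(flux_system(0), p))
  tw <- tritiated_water_assay(tr)
  expect_true(all(diff(tw$T2O) >= -1e-18))
  # trapezoid quadrature oracle on the dense flux output
  a1 <- tr[, "alpha1"]
  quad <- cumsum(c(0, diff(tw$time) * (head(a1, -1) + tail(a1, -1)) / 2))
  expect_equal(tw$T2O, quad, tolerance = 1e-4)
  # a cell with no aromatase releases no label
  p0 <- gc_parameters(lambda = c(Cyp19_A = 1e-300, Cyp19_T = 1e-300))
  tr0 <- simulate_invitro(flux_system(0), p0, t_grid = c(0, 600))
  expect_equal(unname(tr0[2, "T2O"]), 0, tolerance = 1e-25)
})

test_that("the reduced fast path matches the full solver", {
  p <- map_params
  for (fsh in c(0, 20)) {
    sys <- flux_system(fsh)
    tr <- fixture(paste0("flux_traj_", if (fsh > 0) "fsh" else "nofsh"),
                  simulate_invitro(sys, p))
    qs <- simulate_invitro_qss(sys, p, t_grid = c(0, 720, 2880),
                               rtol = 1e-7, atol = 1e-14)
    for (h in c("A", "T", "E1", "E2")) {
      full_med <- approx(tr[, "time"], tr[, paste0(h, "_med")],
                         c(720, 2880))$y
      red_med <- qs[2:3, paste0(h, "_tot")] - qs[2:3, paste0(h, "_GC")]
      expect_equal(red_med, full_med, tolerance = 2e-4,
                   ignore_attr = TRUE)
    }
    expect_equal(unname(qs[3, "alpha1"]),
                 unname(tr[nrow(tr), "alpha1"]), tolerance = 1e-4)
  }
})

test_that("predictions are shared across observations of one condition", {
  d <- synthetic_collection()$data
  s1 <- d[d$study == 1, ]
  solve_count(reset = TRUE)
  predict_endpoints(map_estimates(), 1, s1, map_params)
  # study 1 has three distinct conditions (with/without FSH at 48 h,
  # control expression at 4 h) but only two need the hormone solver
  expect_equal(solve_count(), 2L)
})

test_that("simulation is deterministic and rejects bad grids", {
  p <- map_params
  sys <- flux_system(0)
  t1 <- simulate_invitro(sys, p, t_grid = c(0, 100, 200))
  t2 <- simulate_invitro(sys, p, t_grid = c(0, 100, 200))
  expect_identical(unclass(t1), unclass(t2), ignore_attr = TRUE)
  expect_error(simulate_invitro(sys, p, t_grid = c(100, 200)))
})
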