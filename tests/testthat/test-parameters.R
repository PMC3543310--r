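test_that("steady-state synthesis rates follow from pools and turnover", {
  # Hsd17b2: exact printed values
  r <- derive_steady_state_rates(6.00e-3, 3.00e-3, 7.00e-9, 0.014)
  expect_equal(r[["nu_mRNA"]], 4.20e-11)
  expect_equal(r[["nu_prot"]], 6000)
  # aromatase: matches the printed value at two significant figures
  r2 <- derive_steady_state_rates(6.00e-3, 3.00e-3, 4.96e-8, 0.1)
  expect_equal(signif(r2[["nu_mRNA"]], 2), 3.0e-10)
  expect_equal(signif(r2[["nu_prot"]], 2), 6.0e3)
  # empty cell: zero by convention
  expect_equal(derive_steady_state_rates(1e-3, 1e-3, 0, 0),
               c(nu_mRNA = 0, nu_prot = 0))
  expect_error(derive_steady_state_rates(1e-3, 1e-3, 0, 0.1),
               "undefined")
})

test_that("the derived rates put the gene-expression equations at rest", {
  p <- map_params
  r <- mapply(derive_steady_state_rates,
              mRNA0 = p$mRNA0, prot0 = p$prot0,
              MoreArgs = list(delta_mRNA = p$delta_mRNA,
                              delta_prot = p$delta_prot))
  p2 <- gc_parameters(nu_mRNA = setNames(r["nu_mRNA", ], names(p$mRNA0)),
                      nu_prot = setNames(r["nu_prot", ], names(p$prot0)))
  d <- gene_expression_rhs(cell_state(), p2)
  expect_equal(max(abs(d)), 0)
})

test_that("aromatase-relative initials scale to printed absolute values", {
  sc <- scale_relative_initials(4.96e-8, 0.1,
                                mRNA_ratios = c(Cyp19 = 1, Hsd17b1 = 2.07,
                                                Hsd17b2 = 0.14),
                                prot_ratios = c(Cyp19 = 1, Hsd17b1 = 2.1,
                                                Hsd17b2 = 0.14))
  expect_equal(signif(sc$mRNA0[["Hsd17b1"]], 3), 1.03e-7)
  expect_equal(sc$mRNA0[["Cyp19"]], 4.96e-8)    # ratio 1 is the identity
  expect_equal(sc$prot0[["Hsd17b2"]], 0.014)
  expect_error(scale_relative_initials(1, 1, c(a = -1), c(a = 1)))
})

test_that("parameter sets validate and round-trip through YAML exactly", {
  p <- gc_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- read_parameters(f)
  expect_identical(unclass(p2), unclass(p)[names(p2)])
  expect_error(gc_parameters(V_GC = -1), "positive")
  expect_error(gc_parameters(nonsense = 3), "unknown parameter")
})

test_that("the alternate Hsd17b2 constant set is flagged and applied", {
  expect_message(p <- gc_parameters(hsd17b2 = "variability-set"),
                 "disagree")
  expect_equal(p$lambda[["Hsd17b2_E2"]], 7.91e-6)
  expect_equal(p$xi[["Hsd17b2_T"]], 5.67e-8)
  expect_equal(gc_parameters()$lambda[["Hsd17b2_E2"]], 7.91e-8)
})

test_that("uptake constants satisfy K_in = K_out / R_oi", {
  p <- map_params
  expect_equal(k_in(p), p$K_out / p$R_oi)
})

test_that("prior sampling is reproducible and matches closed forms", {
  sp <- prior_spec("lognormal", gm = 1.33e-7, gsd = 1.2)
  x <- sample_prior(sp, 1e5, seed = 1)
  expect_identical(x, sample_prior(sp, 1e5, seed = 1))
  # law of large numbers: sample median near the geometric mean
  expect_lt(abs(median(x) / 1.33e-7 - 1), 0.01)
  u <- sample_prior(prior_spec("uniform", min = 0, max = 1e7), 1e5,
                    seed = 2)
  expect_lt(abs(mean(u) / 5e6 - 1), 0.02)
  h <- sample_prior(prior_spec("halfnormal", sd = 0.5), 1e4, seed = 3)
  expect_true(all(h >= 0))
  expect_error(prior_spec("lognormal", gm = 1, gsd = 0.9))
  expect_error(prior_spec("uniform", min = 1, max = 0))
})

test_that("prior densities integrate support constraints", {
  sp <- prior_spec("uniform", min = 0, max = 1e7)
  expect_equal(dprior(sp, 2.5e6), dprior(sp, 5e6))   # flat inside
  expect_identical(dprior(sp, 2e7), -Inf)
  hn <- prior_spec("halfnormal", sd = 0.5)
  expect_identical(dprior(hn, -0.1), -Inf)
  # halfnormal integrates to one on the positive axis
  expect_equal(integrate(function(x) exp(dprior(hn, x)), 0, Inf)$value,
               1, tolerance = 1e-6)
  ln <- prior_spec("lognormal", gm = 2, gsd = 1.5)
  # mode of the log-density on the log scale sits at the geometric mean
  gr <- seq(log(0.5), log(8), length.out = 401)
  dens_log <- dprior(ln, exp(gr)) + gr   # density of log-variable
  expect_equal(exp(gr[which.max(dens_log)]), 2, tolerance = 0.02)
})
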