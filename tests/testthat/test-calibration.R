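test_that("log prior combines component densities and support limits", {
  pri <- calibration_priors(2)
  v <- map_estimates()[c(.sampled_names(0)[1:12], "sigma_L1", "sigma_L2",
                         "Sigma2", "Sigma3")]
  names(v) <- .sampled_names(2)
  lp <- log_prior(v, pri)
  expect_true(is.finite(lp))
  # uniform components contribute equally anywhere inside the support
  v1 <- v; v1[["kappa_Cyp19"]] <- 2.5e6
  v2 <- v; v2[["kappa_Cyp19"]] <- 5e6
  expect_equal(log_prior(v1, pri), log_prior(v2, pri))
  # outside the uniform bound the density vanishes
  v3 <- v; v3[["kappa_Cyp19"]] <- 2e7
  expect_identical(log_prior(v3, pri), -Inf)
  # hierarchical term: manual evaluation
  manual <- sum(vapply(names(pri$top), function(nm)
    dprior(pri$top[[nm]], v[[nm]]), 0)) +
    sum(dlnorm(v[c("sigma_L1", "sigma_L2")], log(v[["mu0"]]),
               v[["Sigma1"]], log = TRUE))
  expect_equal(lp, manual)
})

test_that("log likelihood is a sum of lognormal terms around predictions", {
  p <- map_params
  v <- map_estimates()
  # one datum whose value equals the model prediction
  d <- study_design(1, "expression")[1, ]
  d$value <- predict_endpoints(v, v[["sigma_L1"]], d, p)
  pri1 <- calibration_priors(1)
  v1 <- v[c(.sampled_names(0)[1:12], "sigma_L1", "Sigma2", "Sigma3")]
  ll <- log_likelihood(v1, d, p)
  # zero residual: the contribution is the normalizing constant alone
  expect_equal(ll, dnorm(0, 0, v[["Sigma2"]], log = TRUE), tolerance = 1e-6)
  # two identical data contribute exactly twice
  d2 <- rbind(d, d)
  expect_equal(log_likelihood(v1, d2, p), 2 * ll, tolerance = 1e-9)
})

test_that("likelihood responds to the error scale as the calculus says", {
  p <- map_params
  v <- map_estimates()
  col <- synthetic_collection()
  base <- log_likelihood(v, col$data, p)
  eps <- 1e-4
  v_up <- v; v_up[["Sigma3"]] <- v[["Sigma3"]] + eps
  num_grad <- (log_likelihood(v_up, col$data, p) - base) / eps
  # analytic gradient: sum over hormone rows of (r^2/S^3 - 1/S)
  d <- col$data[col$data$endpoint_class == "hormone", ]
  r <- sapply(split(d, d$study), function(dj) {
    j <- dj$study[1]
    pred <- predict_endpoints(v, v[[paste0("sigma_L", j)]], dj, p)
    log(dj$value) - log(pred)
  })
  r <- unlist(r)
  S <- v[["Sigma3"]]
  expect_equal(num_grad, sum(r^2 / S^3 - 1 / S), tolerance = 1e-2)
})

test_that("sampling without data reproduces the priors", {
  pri <- calibration_priors(3)
  ch <- fixture("prior_chains", metropolis_hastings(
    NULL, pri, map_params, n_iter = 8000, n_chains = 3, seed = 5))
  pool <- do.call(rbind, lapply(ch$samples,
                                function(mm) mm[4001:8000, ]))
  for (nm in names(pri$top)) {
    q <- quantile(pool[, nm], c(0.025, 0.5, 0.975))
    qp <- qprior(pri$top[[nm]], c(0.025, 0.5, 0.975))
    # median within a few percent of the prior scale, tails within ~15%
    expect_lt(abs(log(q[2] / qp[2])),
              0.12 * max(1, log(qp[3] / qp[1]) / 2))
    expect_lt(abs(log(q[3] / qp[3])), 0.35)
  }
})

test_that("chains are bitwise reproducible given the seed", {
  col <- synthetic_collection()
  pri <- calibration_priors(10)
  ch1 <- metropolis_hastings(col$data, pri, map_params, n_iter = 40,
                             n_chains = 2, seed = 21)
  ch2 <- metropolis_hastings(col$data, pri, map_params, n_iter = 40,
                             n_chains = 2, seed = 21)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$log_post, ch2$log_post)
})

test_that("incremental bookkeeping matches the reference likelihood", {
  col <- synthetic_collection()
  pri <- calibration_priors(10)
  ch <- metropolis_hastings(col$data, pri, map_params, n_iter = 60,
                            n_chains = 1, seed = 8)
  expect_equal(ch$final_ll[1],
               log_likelihood(ch$finals[[1]], col$data, map_params),
               tolerance = 1e-9)
  expect_equal(tail(ch$log_post[[1]], 1) - ch$final_ll[1],
               log_prior(ch$finals[[1]], pri), tolerance = 1e-9)
})

test_that("potential scale reduction matches a direct formula oracle", {
  # small fixed arrays, brute-force evaluation
  set.seed(1)
  m1 <- matrix(exp(rnorm(40)), 20, 2,
               dimnames = list(NULL, c("a", "b")))
  m2 <- matrix(exp(rnorm(40, 0.5)), 20, 2,
               dimnames = list(NULL, c("a", "b")))
  rh <- gelman_rubin(list(m1, m2), use_last = 1, transform = "log")
  oracle <- function(x1, x2) {
    n <- length(x1)
    W <- (var(x1) + var(x2)) / 2
    B_n <- var(c(mean(x1), mean(x2)))
    sqrt(((n - 1) / n * W + (1 + 1 / 2) * B_n) / W)
  }
  expect_equal(rh[["a"]], oracle(log(m1[, "a"]), log(m2[, "a"])))
  expect_equal(rh[["b"]], oracle(log(m1[, "b"]), log(m2[, "b"])))
  # chains from one distribution approach 1; disjoint chains diverge
  big1 <- matrix(exp(rnorm(4000)), ncol = 1, dimnames = list(NULL, "x"))
  big2 <- matrix(exp(rnorm(4000)), ncol = 1, dimnames = list(NULL, "x"))
  expect_lt(gelman_rubin(list(big1, big2), use_last = 1)[["x"]], 1.01)
  far <- matrix(exp(rnorm(4000, 10)), ncol = 1,
                dimnames = list(NULL, "x"))
  expect_gt(gelman_rubin(list(big1, far), use_last = 1)[["x"]], 5)
  expect_error(gelman_rubin(list(m1[1:5, ], m2[1:5, ]), use_last = 1),
               "10 retained")
})

test_that("posterior summaries are ordered and locate the MAP sample", {
  ch <- fast_chains()
  s <- posterior_summary(ch)
  expect_true(all(s$p0.5 <= s$p2.5 & s$p2.5 <= s$p97.5 &
                  s$p97.5 <= s$p99.5))
  # the reported MAP is the retained sample with the highest posterior
  keep <- (ch$n_iter / 2 + 1):ch$n_iter
  lp <- unlist(lapply(ch$log_post, function(x) x[keep]))
  pooled <- do.call(rbind, lapply(ch$samples, function(mm) mm[keep, ]))
  expect_equal(unname(s$map), unname(pooled[which.max(lp), ]))
})

test_that("error-scale reporting converts to a coefficient of variation", {
  expect_equal(lognormal_cv(0), 0)
  expect_equal(lognormal_cv(0.48), sqrt(exp(0.48^2) - 1))
  # first-order: cv ~= sigma for moderate scales
  expect_equal(lognormal_cv(0.2), 0.2, tolerance = 0.02)
})
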