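# shared fixtures: built in code, cached across test files within a run

map_params <- gc_parameters()

# the flux-analysis culture conditions (200 nM A, 600,000 cells in 2 ml)
flux_system <- function(fsh = 0, sigma_L = 0.685, ...)
  invitro_system(cells_per_ml = 3e5, volume_ml = 2,
                 medium_nM = c(A = 200), fsh_ng_ml = fsh,
                 sigma_L = sigma_L, duration_min = 2880, ...)

# small cache so expensive objects are computed once per test run
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# a state vector at the baseline gene-expression equilibrium with given
# intracellular steroids
baseline_state <- function(A = 0, T = 0, E1 = 0, E2 = 0, FSH = 0)
  cell_state(A = A, T = T, E1 = E1, E2 = E2, FSH = FSH)

# synthetic calibration collection at the shipped posterior-mode truth
synthetic_collection <- function()
  fixture("collection", generate_collection(map_estimates(), seed = 42))

# scaled-down calibration chains reused by convergence, recovery and
# summary tests
fast_chains <- function()
  fixture("fast_chains", metropolis_hastings(
    synthetic_collection()$data, calibration_priors(10), map_params,
    n_iter = 5000, n_chains = 3, seed = 11))
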