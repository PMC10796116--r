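# Shared fixtures. The baseline free-mode sweep is expensive, so it is
# computed once per test run and reused by every property test that needs it.
.fixture_cache <- new.env(parent = emptyenv())

POOLS <- c("ru", "tr", "ri", "p", "re", "lb", "gl", "ld")

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, expr, envir = .fixture_cache)
  .fixture_cache[[key]]
}

baseline_sweep <- function(step = 1, multistart = 8, seed = 0) {
  key <- sprintf("sweep_%g_%d_%d", step, multistart, seed)
  cached(key, temperature_sweep(
    phyto_params(), T_start = 5, T_end = 45, step = step, mode = "free",
    opts = solve_options(multistart_count = multistart, random_seed = seed)))
}

# Running median with window 3 (edges kept), used to damp single-point
# solver noise before asserting curve shapes.
med3 <- function(x) as.numeric(stats::runmed(x, 3))

viable_rows <- function(sweep) sweep[sweep$status == "optimal", , drop = FALSE]

# Small deterministic solve, shared across optimizer tests.
toy_fit_20C <- function() {
  cached("toy_fit_20C", solve_optimal_cell(
    toy_params(), phyto_env(20),
    solve_options(mode = "glycolysis_only", multistart_count = 4,
                  random_seed = 1)))
}

toy_grid_20C <- function() {
  cached("toy_grid_20C", grid_search_toy(toy_params(), phyto_env(20)))
}
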