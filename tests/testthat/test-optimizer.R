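test_that("solver matches the exhaustive grid search on the reduced model", {
  g <- toy_grid_20C()
  fit <- toy_fit_20C()
  expect_equal(fit$status, "optimal")
  # the continuous optimum can only improve on the grid optimum, and must
  # sit within one grid cell of it
  expect_gte(fit$mu_per_day, g$mu_day - 1e-6)
  expect_lte(fit$mu_per_day, g$mu_day * 1.05)
  cf <- coef(fit)
  expect_lt(abs(cf[["phi_tr"]] - g$phi[["tr"]]), 0.015)
  expect_lt(abs(cf[["phi_p"]] - g$phi[["p"]]), 0.015)
  beta_step <- diff(log(c(0.01, 10))) / 39    # grid spacing in log beta
  expect_lt(abs(log(cf[["beta"]]) - log(g$beta)), 1.5 * beta_step)
})

test_that("solves are deterministic given the seed", {
  o <- solve_options(mode = "glycolysis_only", multistart_count = 3,
                     random_seed = 7)
  f1 <- solve_optimal_cell(toy_params(), phyto_env(20), o)
  f2 <- solve_optimal_cell(toy_params(), phyto_env(20), o)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$mu_per_day, f2$mu_per_day)
})

test_that("warm-started single-start solve reproduces a known optimum", {
  fit <- toy_fit_20C()
  o <- solve_options(mode = "glycolysis_only", multistart_count = 1,
                     warm_start = fit$state, random_seed = 0)
  refit <- solve_optimal_cell(toy_params(), phyto_env(20), o)
  expect_equal(refit$mu_per_day, fit$mu_per_day, tolerance = 1e-4)
})

test_that("relaxing the density bound never decreases optimal growth", {
  fit <- toy_fit_20C()
  relaxed <- toy_params(D_max = phyto_params()$D_max * 10)
  fit2 <- solve_optimal_cell(relaxed, phyto_env(20),
                             solve_options(mode = "glycolysis_only",
                                           multistart_count = 4,
                                           random_seed = 1))
  expect_gte(fit2$mu_per_day, fit$mu_per_day - 1e-4)
})

test_that("no light means no viable cell", {
  fit <- solve_optimal_cell(phyto_params(), phyto_env(20, I = 0),
                            solve_options(multistart_count = 1))
  expect_equal(fit$status, "nonviable")
  expect_equal(fit$mu_per_day, 0)
})

test_that("verification recomputes residuals and catches corrupted states", {
  fit <- toy_fit_20C()
  v <- verify_solution(fit, toy_params(), phyto_env(20), tol = 1e-7)
  expect_true(v$pass)

  bad <- fit
  bad$state$p[["tr"]] <- 0
  v2 <- verify_solution(bad, toy_params(), phyto_env(20), tol = 1e-7)
  expect_false(v2$pass)
  expect_true(any(grepl("tr", v2$failures)))
})

test_that("free mode dominates each restricted mode at a test temperature", {
  bp <- phyto_params()
  env <- phyto_env(30)
  o <- function(m) solve_options(mode = m, multistart_count = 4,
                                 random_seed = 2)
  free <- solve_optimal_cell(bp, env, o("free"))
  gl <- solve_optimal_cell(bp, env, o("glycolysis_only"))
  ld <- solve_optimal_cell(bp, env, o("lipid_only"))
  expect_gte(free$mu_per_day, gl$mu_per_day - 1e-4)
  expect_gte(free$mu_per_day, ld$mu_per_day - 1e-4)
  # pathway exclusivity: at the free optimum at most one respiratory flux
  # carries meaningful energy
  fl <- free$fluxes
  carried <- c(glycolysis = bp$e_gl * fl$v_gl, lipid = bp$e_ld * fl$v_ld)
  expect_lt(min(carried), 1e-6 * max(max(carried), 1e-300))
})

test_that("optimal states satisfy the structural invariants exactly", {
  for (fit in list(toy_fit_20C())) {
    st <- fit$state
    expect_equal(sum(st$phi), 0.5, tolerance = 1e-12)
    expect_equal(sum(st$alpha), 1, tolerance = 1e-12)
    expect_lt(abs(residuals(fit)[["surface"]]), 1e-10)
    expect_true(fit$residual_report$feasible)
  }
})

test_that("random feasible states pass verification across seeds", {
  bp <- phyto_params()
  env <- phyto_env(20)
  for (seed in 1:5) {
    st <- random_feasible_state(bp, env, seed = seed)
    rep <- residual_report(st, bp, env)
    expect_lt(rep$max_abs_residual, 1e-12)
    v <- verify_solution(st, bp, env, tol = 1e-6)
    expect_true(v$pass)
  }
})
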