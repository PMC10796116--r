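bp <- phyto_params()
env20 <- phyto_env(20)

# A concrete, fully specified state used by several blocks. Values are
# arbitrary but positive; no feasibility is implied.
make_state <- function(..., params = bp) {
  args <- list(
    p = c(ru = 100, tr = 200, ri = 300, re = 10, lb = 40, gl = 20, ld = 5),
    p_p = 500, p_dp = 50, c_ic = 1e6, c_in = 2e5, c_lm = 1e6,
    c_tag = 5e5, c_gu = 1e6, c_li = 1e5,
    phi = c(ru = 0.05, tr = 0.04, ri = 0.2, p = 0.14, re = 0.01,
            lb = 0.03, gl = 0.02, ld = 0.01),
    alpha = c(0.5, 0.4, 0.1), beta = 0.4, mu = 1e-3, params = params)
  args[names(list(...))] <- list(...)
  do.call(cell_state, args)
}

test_that("fluxes vanish without catalysts and honor half-saturation", {
  st0 <- make_state(p = c(ru = 0, tr = 0, ri = 0, re = 0, lb = 0, gl = 0,
                          ld = 0), p_p = 0, p_dp = 0)
  fl0 <- compute_fluxes(st0, bp, env20)
  expect_true(all(unlist(fl0[c("v_ri", "v_ru", "v_lb", "v_gl", "v_ld",
                               "v_tr", "v_p", "v_d", "v_re")]) == 0))

  # lipid synthesis at its internal-carbon half-saturation runs at k*p/2
  st <- make_state(c_ic = bp$K_lb)
  fl <- compute_fluxes(st, bp, env20)
  k <- rates_at(bp, env20$T)$k
  expect_equal(fl$v_lb, k[["lb"]] * st$p[["lb"]] / 2)

  # saturating external substrates: uptake and fixation at their maxima
  expect_equal(fl$v_tr, k[["tr"]] * st$p[["tr"]])
  expect_equal(fl$v_ru, k[["ru"]] * st$p[["ru"]])

  # respiratory fluxes are linear in their catalysts (whole store used)
  expect_equal(fl$v_gl, k[["gl"]] * st$p[["gl"]])
  expect_equal(fl$v_ld, k[["ld"]] * st$p[["ld"]])
})

test_that("nitrogen demand per amino acid is the investment-weighted N:C", {
  phi <- c(a = 1)
  q <- c(a = 0.3)
  expect_equal(nitrogen_per_amino_acid(phi, q, 5), 1.5)
  # hand-weighted sum: 5 * (0.5*0.3 + 0.5*0.2) = 1.25
  expect_equal(nitrogen_per_amino_acid(c(j = 0.5), c(j = 0.3), 5,
                                       phi_other = 0.5, q_other = 0.2), 1.25)
  expect_equal(nitrogen_per_amino_acid(c(a = 0, b = 0), c(a = 1, b = 2), 5), 0)
  expect_error(nitrogen_per_amino_acid(c(a = -0.1), c(a = 0.3), 5),
               "non-negative")
})

test_that("forward-substitution construction yields vanishing residuals", {
  phi <- c(ru = 0.08, tr = 0.05, ri = 0.15, p = 0.13, re = 0.01,
           lb = 0.05, gl = 0.03, ld = 0.002)
  st <- build_balanced_state(bp, env20, phi, alpha_lm = 0.35, beta = 0.5)
  expect_false(is.null(st))
  rep <- residual_report(st, bp, env20)
  expect_lt(rep$max_abs_residual, 1e-12)
  expect_equal(sum(st$phi), 1 - bp$phi_other)
  expect_equal(sum(st$alpha), 1)
})

test_that("perturbing one protein pool changes exactly its balance by -mu*delta", {
  phi <- c(ru = 0.08, tr = 0.05, ri = 0.15, p = 0.13, re = 0.01,
           lb = 0.05, gl = 0.03, ld = 0.002)
  st <- build_balanced_state(bp, env20, phi, alpha_lm = 0.35, beta = 0.5)
  fl <- compute_fluxes(st, bp, env20)
  base <- steady_state_residuals(st, fl, bp)
  delta <- 0.1 * st$p[["gl"]]
  st2 <- st
  st2$p[["gl"]] <- st2$p[["gl"]] + delta
  fl2 <- compute_fluxes(st2, bp, env20)
  pert <- steady_state_residuals(st2, fl2, bp)
  expect_equal(pert[["p_gl"]] - base[["p_gl"]], -st$mu * delta)
  # glycolysis feeds the carbon balance and dark storage; all other protein
  # balances are untouched
  unchanged <- setdiff(names(base), c("p_gl", "c_ic", "c_gu"))
  expect_equal(pert[unchanged], base[unchanged], tolerance = 1e-12)
})

test_that("carbon conservation holds at a balanced state via an independent expression", {
  phi <- c(ru = 0.08, tr = 0.05, ri = 0.15, p = 0.13, re = 0.01,
           lb = 0.05, gl = 0.03, ld = 0.002)
  st <- build_balanced_state(bp, env20, phi, alpha_lm = 0.35, beta = 0.5)
  fl <- compute_fluxes(st, bp, env20)
  lhs <- fl$v_ru
  rhs <- fl$v_ri * bp$eta_aac + fl$v_lb + fl$v_gl + st$mu * st$c_ic
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("quasi-steady-state damaged fraction follows the damage/repair ratio", {
  p <- phyto_params(k_ref_d = 0.02, T_d = 293.15, E_d = 1,
                    k_ref = c(re = 1), E_a = c(re = 0))
  # at T = T_d = T_ref both rates equal their reference values:
  # 0.02 * 100 * (c_tag_max / (2 c_tag_max)) / (1 * 10) = 0.1
  st <- make_state(params = p, p_p = 100, c_tag = 2 * p$c_tag_max,
                   p = c(ru = 0, tr = 0, ri = 0, re = 10, lb = 0, gl = 0,
                         ld = 0))
  expect_equal(damaged_fraction_qss(st, p, 293.15), 0.1)
  # no damage, no damaged fraction
  p0 <- phyto_params(k_ref_d = 0)
  expect_equal(damaged_fraction_qss(st, p0, 293.15), 0)
  # boundary of validity: damage capacity equal to repair capacity
  st2 <- make_state(params = p, p_p = 500, c_tag = p$c_tag_max,
                    p = c(ru = 0, tr = 0, ri = 0, re = 10, lb = 0, gl = 0,
                          ld = 0))
  expect_equal(damaged_fraction_qss(st2, p, 293.15), 0.02 * 500 / 10)
  expect_error(damaged_fraction_qss(make_state(params = p, c_tag = 0), p,
                                    293.15), "c_tag")
})

test_that("energy balance is the cost-weighted flux sum with correct slacks", {
  fl <- structure(list(v_ri = 2, v_tr = 3, v_ru = 0, v_lb = 0, v_gl = 0,
                       v_ld = 0, v_p = 0, v_ep = 0, v_d = 0, v_re = 0,
                       e_cost = NA), class = "phyto_fluxes")
  p <- phyto_params(e_ri = 1, e_tr = 2, e_lb = 0, e_re = 0)
  en <- energy_balance(make_state(), fl, p)
  expect_equal(en$e_cost, 2 * 1 + 3 * 2)   # dot product
  expect_equal(en$rubisco_slack, 0)
  expect_equal(en$day_slack, -en$e_cost)
  # active dark constraint: e_gl v_gl exactly covers f_dr e_cost
  fl$v_gl <- p$f_dr * en$e_cost / p$e_gl
  en2 <- energy_balance(make_state(), fl, p)
  expect_equal(en2$dark_slack, 0)
  # all-zero fluxes: zero cost and zero slacks
  fl0 <- structure(as.list(stats::setNames(rep(0, 11), names(fl))),
                   class = "phyto_fluxes")
  en0 <- energy_balance(make_state(), fl0, p)
  expect_equal(unlist(en0), c(e_cost = 0, rubisco_slack = 0, day_slack = 0,
                              dark_slack = 0))
})

test_that("dark storage requirements scale with the dark period", {
  expect_equal(dark_storage_requirements(0, 0, bp), c(c_gu = 0, c_li = 0))
  p <- phyto_params(t_d = 720, n_guc = 6)
  expect_equal(dark_storage_requirements(6, 0, p)[["c_gu"]], 720)
  s1 <- dark_storage_requirements(3, 2, p)
  p2 <- phyto_params(t_d = 1440, n_guc = 6)
  expect_equal(dark_storage_requirements(3, 2, p2), 2 * s1)
  expect_error(dark_storage_requirements(-1, 0, bp), "non-negative")
})

test_that("geometry constraints recover the surface identity and volume split", {
  # (p_tr s_tr + c_lm s_lm) = 2 requires beta = 0.5 for zero residual
  p_tr <- 1 / bp$s_tr
  c_lm <- 1 / bp$s_lm
  st <- make_state(p = c(ru = 0, tr = p_tr, ri = 0, re = 0, lb = 0, gl = 0,
                         ld = 0), c_lm = c_lm, beta = 0.5,
                   p_p = 0, p_dp = 0, c_li = 0, c_tag = 0, c_gu = 0,
                   c_ic = 0, c_in = 0)
  geo <- geometry_constraints(st, bp, env20)
  expect_equal(geo$surface_residual, 0)
  expect_equal(geo$available_volume_fraction, 1)
  expect_equal(geo$density_slack, bp$D_max)
  expect_equal(geo$membrane_ratio_slack,
               rates_at(bp, env20$T)$M_bound - p_tr / c_lm)
})

test_that("linear balances are homogeneous of degree one in pools and fluxes", {
  st <- make_state()          # arbitrary state: residuals are O(1)
  fl <- compute_fluxes(st, bp, env20)
  base <- steady_state_residuals(st, fl, bp)
  s <- 3.7
  st2 <- st
  st2$p <- st2$p * s
  for (f in c("p_p", "p_dp", "c_ic", "c_in", "c_lm", "c_tag", "c_gu",
              "c_li"))
    st2[[f]] <- st2[[f]] * s
  fl2 <- fl
  for (f in setdiff(names(fl), "e_cost")) fl2[[f]] <- fl2[[f]] * s
  fl2$e_cost <- fl$e_cost * s
  scaled <- steady_state_residuals(st2, fl2, bp)
  linear <- setdiff(names(base), c("surface", "n_demand"))
  expect_equal(scaled[linear], s * base[linear],
               tolerance = 1e-9)
})

test_that("residual report flags infeasible states and scales sensibly", {
  st <- make_state()
  rep <- residual_report(st, bp, env20)
  expect_s3_class(rep, "residual_report")
  expect_false(rep$feasible)      # an arbitrary state is not balanced
  expect_true(all(is.finite(rep$equalities_rel)))
})
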