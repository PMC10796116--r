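bp <- phyto_params()

empty_state <- function(...) {
  args <- list(
    p = c(ru = 0, tr = 0, ri = 0, re = 0, lb = 0, gl = 0, ld = 0),
    p_p = 0, p_dp = 0, c_ic = 0, c_in = 0, c_lm = 0, c_tag = 0,
    c_gu = 0, c_li = 0,
    phi = c(ru = 0, tr = 0, ri = 0.5, p = 0, re = 0, lb = 0, gl = 0,
            ld = 0),
    alpha = c(1, 0, 0), beta = 1, mu = 1e-3, params = bp)
  args[names(list(...))] <- list(...)
  do.call(cell_state, args)
}

test_that("cell N:C quota is the pool-weighted average", {
  # metabolite-only cell: 2 N over 10 C
  st <- empty_state(c_in = 2, c_ic = 10)
  expect_equal(cell_stoichiometry(st, bp), 0.2)
  # single protein pool: quota equals that pool's N:C
  st2 <- empty_state(p = c(ru = 100, tr = 0, ri = 0, re = 0, lb = 0,
                           gl = 0, ld = 0))
  expect_equal(cell_stoichiometry(st2, bp), bp$q[["ru"]])
  # two pools plus stores, hand-computed
  st3 <- empty_state(p = c(ru = 10, tr = 0, ri = 5, re = 0, lb = 0,
                           gl = 0, ld = 0), c_gu = 50, c_in = 100)
  protein_C <- (10 * bp$eta[["ru"]] + 5 * bp$eta[["ri"]]) * bp$eta_aac
  protein_N <- (10 * bp$eta[["ru"]] * bp$q[["ru"]] +
                  5 * bp$eta[["ri"]] * bp$q[["ri"]]) * bp$eta_aac
  expected <- (protein_N + 100) / (protein_C + 50 * bp$n_guc)
  expect_equal(cell_stoichiometry(st3, bp), expected)
  expect_error(cell_stoichiometry(empty_state(), bp), "carbon")
})

test_that("carbon use efficiency counts respired carbon only", {
  fl <- list(v_ru = 10, v_gl = 2, v_ld = 1)
  expect_equal(carbon_use_efficiency(fl), 0.7)
  expect_equal(carbon_use_efficiency(list(v_ru = 5, v_gl = 0, v_ld = 0)), 1)
  expect_equal(carbon_use_efficiency(list(v_ru = 5, v_gl = 3, v_ld = 2)), 0)
  expect_error(carbon_use_efficiency(list(v_ru = 0, v_gl = 0, v_ld = 0)),
               "undefined")
})

test_that("chlorophyll conversion uses the per-photosystem pigment count", {
  expect_equal(chlorophyll_per_volume(empty_state(), bp), 0)
  st <- empty_state(p_p = 1)
  expect_equal(chlorophyll_per_volume(st, bp),
               140 * 893.5 / 6.02214076e23)
  st2 <- empty_state(p_p = 2)
  expect_equal(chlorophyll_per_volume(st2, bp),
               2 * chlorophyll_per_volume(st, bp))
  # damaged photosystems keep their pigments unless configured out
  st3 <- empty_state(p_p = 1, p_dp = 1)
  expect_equal(chlorophyll_per_volume(st3, bp),
               2 * chlorophyll_per_volume(st, bp))
  p2 <- phyto_params(chl_include_damaged = FALSE)
  expect_equal(chlorophyll_per_volume(st3, p2),
               chlorophyll_per_volume(st, p2))
})

test_that("spherical geometry recovers beta = r/3 identically", {
  d <- cell_dimensions(1)
  expect_equal(d$radius, 3)
  expect_equal(d$volume / d$surface_area, 1)
  d2 <- cell_dimensions(0.5)
  expect_equal(d2$radius, 1.5)
  for (beta in c(0.1, 0.7, 2.3)) {
    dd <- cell_dimensions(beta)
    expect_equal(dd$volume / dd$surface_area, beta)
  }
  expect_error(cell_dimensions(-1), "positive")
})

test_that("trait records convert units and handle nonviable results", {
  fit <- toy_fit_20C()
  rec <- assemble_trait_record(fit, toy_params(), phyto_env(20))
  expect_equal(rec$mu_per_day, fit$state$mu * 1440)
  expect_equal(rec$radius, 3 * fit$state$beta)
  expect_equal(rec$carbon_fixation,
               fit$fluxes$v_ru * 1440 / 6.02214076e23 * 1e15)
  expect_equal(rec$volume / (4 / 3 * pi), rec$radius^3)

  dead <- structure(list(status = "nonviable", state = NULL, fluxes = NULL,
                         mu_per_day = 0, tie = FALSE,
                         active_respiratory_pathway = "none"),
                    class = "optimal_cell")
  drec <- assemble_trait_record(dead, bp, phyto_env(44))
  expect_equal(drec$mu_per_day, 0)
  expect_true(is.na(drec$volume))
  expect_equal(drec$respiratory_mode, "none")
})

test_that("storage accounting sums glucose and lipid carbon", {
  st <- empty_state(c_gu = 10, c_li = 0, c_tag = 0, p_p = 1, c_ic = 1)
  fake <- structure(list(status = "optimal", state = st,
                         fluxes = structure(list(v_ru = 1, v_gl = 0,
                                                 v_ld = 0, e_cost = 0),
                                            class = "phyto_fluxes"),
                         mu_per_day = st$mu * 1440, tie = FALSE,
                         active_respiratory_pathway = "glycolysis"),
                    class = "optimal_cell")
  rec <- assemble_trait_record(fake, bp, phyto_env(20))
  expect_equal(rec$carbon_storage, 10 * bp$n_guc / 6.02214076e23)
})
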