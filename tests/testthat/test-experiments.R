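test_that("switch detection finds consecutive pathway changes", {
  tbl <- data.frame(temperature = 1:5,
                    respiratory_mode = c("glycolysis", "glycolysis",
                                         "lipid_degradation",
                                         "lipid_degradation", "glycolysis"),
                    stringsAsFactors = FALSE)
  sw <- detect_metabolic_switch(tbl)
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$temperature, c(3, 5))
  expect_equal(sw$from_pathway, c("glycolysis", "lipid_degradation"))

  none <- data.frame(temperature = 1:4,
                     respiratory_mode = rep("glycolysis", 4))
  expect_equal(nrow(detect_metabolic_switch(none)), 0L)

  # nonviable rows are skipped, not counted as switches
  holey <- data.frame(temperature = 1:5,
                      respiratory_mode = c("glycolysis", "none",
                                           "glycolysis", "none",
                                           "lipid_degradation"))
  expect_equal(nrow(detect_metabolic_switch(holey)), 1L)

  unsorted <- tbl[c(2, 1, 3, 4, 5), ]
  expect_error(detect_metabolic_switch(unsorted), "sorted")
})

test_that("adaptation scenarios modify copies and validate names", {
  base <- phyto_params()
  sc <- adaptation_scenario("warm", E_a_multiplier = 1.2,
                            c_tag_max = 5e7, k_ref_multiplier = 0.8,
                            T_d = 310)
  p2 <- apply_scenario(base, sc)
  expect_equal(p2$E_a[["ri"]], base$E_a[["ri"]] * 1.2)
  expect_equal(p2$E_a[["tr"]], base$E_a[["tr"]] * 1.2)
  expect_equal(p2$k_ref[["gl"]], base$k_ref[["gl"]] * 0.8)
  expect_equal(p2$c_tag_max, 5e7)
  expect_equal(p2$T_d, 310)
  expect_equal(base$c_tag_max, phyto_params()$c_tag_max)  # base untouched

  # per-pool multiplier
  sc2 <- adaptation_scenario("tr-only", E_a_multiplier = c(tr = 2))
  p3 <- apply_scenario(base, sc2)
  expect_equal(p3$E_a[["tr"]], base$E_a[["tr"]] * 2)
  expect_equal(p3$E_a[["ri"]], base$E_a[["ri"]])

  # no-op scenario leaves every field identical
  p4 <- apply_scenario(base, adaptation_scenario("noop"))
  expect_identical(unclass(p4), unclass(base))

  expect_error(apply_scenario(base, adaptation_scenario(
    "bad", set = list(zzz = 1))), "unknown parameter")
  expect_error(adaptation_scenario("neg", k_ref_multiplier = -1), "positive")
})

test_that("shipped presets load as scenarios", {
  ps <- adaptation_presets()
  expect_true(all(c("26C-evolved", "32C-evolved", "32C-evolved-ctag") %in%
                    names(ps)))
  sc <- adaptation_presets("26C-evolved")
  expect_s3_class(sc, "adaptation_scenario")
  expect_gt(sc$c_tag_max, phyto_params()$c_tag_max)
  expect_error(adaptation_presets("nope"), "unknown preset")
})

test_that("directional report is zero for identical temperatures", {
  sw <- baseline_sweep()
  rep0 <- directional_response_report(sw, 16, 16)
  expect_true(all(rep0$sign == 0))
  expect_error(directional_response_report(sw, 44, 16), "viable")
})

test_that("small sweeps have the right shape and single-point consistency", {
  tp <- toy_params()
  o <- solve_options(multistart_count = 2, random_seed = 3)
  sw <- temperature_sweep(tp, 18, 22, 2, mode = "glycolysis_only", opts = o,
                          two_pass = FALSE, chain_warm_start = FALSE)
  expect_s3_class(sw, "thermal_sweep")
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$temperature, c(18, 20, 22))
  single <- solve_optimal_cell(tp, phyto_env(20),
                               solve_options(mode = "glycolysis_only",
                                             multistart_count = 2,
                                             random_seed = 3))
  expect_equal(sw$mu_per_day[2], single$mu_per_day, tolerance = 1e-6)
})

test_that("sweeps with identical config and seed serialize byte-identically", {
  tp <- toy_params()
  o <- solve_options(multistart_count = 2, random_seed = 5)
  run <- function() {
    sw <- temperature_sweep(tp, 15, 25, 5, mode = "glycolysis_only",
                            opts = o, two_pass = FALSE)
    f <- tempfile(fileext = ".csv")
    write_trait_table(sw, f)
    readLines(f)
  }
  expect_identical(run(), run())
})

test_that("sensitivity scan stacks labeled sweeps", {
  tp <- toy_params()
  o <- solve_options(multistart_count = 2, random_seed = 1)
  sc <- sensitivity_scan(tp, "D_max", c(1.2e10, 1.2e11),
                         T_start = 20, T_end = 20, step = 1,
                         mode = "glycolysis_only", opts = o,
                         two_pass = FALSE)
  expect_equal(nrow(sc), 2L)
  expect_equal(unique(sc$label), c("D_max=1.2e+10", "D_max=1.2e+11"))
  expect_error(sensitivity_scan(tp, "zzz", 1), "unknown parameter")
  expect_error(sensitivity_scan(tp, "E_a.zz", 1), "unknown pool")
})

test_that("reference fixtures regenerate deterministically", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  p1 <- generate_reference_fixtures(d1, seed = 4, sweep_step = 20)
  p2 <- generate_reference_fixtures(d2, seed = 4, sweep_step = 20)
  expect_true(all(file.exists(unlist(p1))))
  for (f in c("toy_config.json", "toy_grid_optimum.json",
              "balanced_state.json", "mini_sweep.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # the stored balanced state verifies through the public model functions
  raw <- jsonlite::read_json(file.path(d1, "balanced_state.json"),
                             simplifyVector = TRUE)
  st <- cell_state(p = unlist(raw$p), p_p = raw$p_p, p_dp = raw$p_dp,
                   c_ic = raw$c_ic, c_in = raw$c_in, c_lm = raw$c_lm,
                   c_tag = raw$c_tag, c_gu = raw$c_gu, c_li = raw$c_li,
                   phi = unlist(raw$phi), alpha = unlist(raw$alpha),
                   beta = raw$beta, mu = raw$mu, eta_aan = raw$eta_aan)
  rep <- residual_report(st, phyto_params(), phyto_env(20))
  expect_lt(rep$max_abs_residual, 1e-10)
})
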