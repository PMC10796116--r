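test_that("schema defaults encode the fixed model constants", {
  p <- phyto_params()
  expect_equal(p$f_dr, 0.25)            # dark share of the energy cost
  expect_equal(p$t_d, 720)              # 12 h dark period, minutes
  expect_equal(p$phi_other, 0.5)
  expect_equal(p$chl_per_ps, 140)       # chlorophylls per photosystem
  expect_equal(p$chl_mw, 893.5)
  # transporters carry half the generic activation energy
  expect_equal(p$E_a[["tr"]], p$E_a[["ri"]] / 2)
  expect_equal(sum(p$q[POOLS]) / 8, p$q_other, tolerance = 1e-12)
})

test_that("parameter validation rejects malformed input by name", {
  expect_error(phyto_params(nonsense = 1), "unknown parameter")
  expect_error(phyto_params(k_ref = c(xx = 1)), "unknown pool")
  expect_error(phyto_params(f_dr = 1.2), "f_dr")
  expect_error(phyto_params(T_min = 400), "T_min < T_max")
  expect_error(phyto_params(c_tag_max = -1), "positive")
  # partial per-pool override keeps the others
  p <- phyto_params(k_ref = c(ri = 99))
  expect_equal(p$k_ref[["ri"]], 99)
  expect_equal(p$k_ref[["ru"]], phyto_params()$k_ref[["ru"]])
})

test_that("temperature-corrected rates exempt photon capture", {
  p <- phyto_params()
  rt_cold <- rates_at(p, 283.15)
  rt_warm <- rates_at(p, 303.15)
  expect_equal(rt_cold$k[["p"]], rt_warm$k[["p"]])      # T-independent
  expect_gt(rt_warm$k[["ri"]], rt_cold$k[["ri"]])
  expect_gt(rt_warm$k_d, rt_cold$k_d)
  expect_lt(rt_warm$M_bound, rt_cold$M_bound)
})

test_that("config files round-trip and fail with field-qualified messages", {
  p <- phyto_params(k_ref = c(ri = 123), f_dr = 0.3)
  path <- tempfile(fileext = ".json")
  write_parameter_set(p, path)
  p2 <- load_parameter_set(path)
  expect_equal(p2$k_ref, p$k_ref)
  expect_equal(p2$f_dr, 0.3)
  expect_equal(p2$density_pools, p$density_pools)

  # canonical stability: write(load(x)) is byte-identical to write(x)
  path2 <- tempfile(fileext = ".json")
  write_parameter_set(p2, path2)
  expect_identical(readLines(path), readLines(path2))

  # omitted defaults are applied
  jsonlite::write_json(list(K_in = 1e5), path, auto_unbox = TRUE)
  p3 <- load_parameter_set(path)
  expect_equal(p3$f_dr, 0.25)
  expect_equal(p3$K_in, 1e5)

  # per-pool incompleteness is named precisely
  jsonlite::write_json(list(k_ref = list(ru = 1, tr = 1, p = 1, re = 1,
                                         lb = 1, gl = 1, ld = 1)),
                       path, auto_unbox = TRUE)
  expect_error(load_parameter_set(path), "k_ref.ri")
  jsonlite::write_json(list(whatever = 1), path, auto_unbox = TRUE)
  expect_error(load_parameter_set(path), "unknown config key")
  expect_error(load_parameter_set("no/such/file.json"), "no such config")
})

test_that("trait tables serialize deterministically and round-trip", {
  sw <- data.frame(temperature = c(5, 6), mu_per_day = c(1.234567890123,
                                                         pi / 7),
                   respiratory_mode = c("glycolysis", "none"),
                   tie = c(FALSE, TRUE), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_trait_table(sw, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# units:")
  expect_equal(length(lines), 4L)
  back <- read_trait_table(path)
  expect_equal(back$mu_per_day, sw$mu_per_day)           # full precision
  expect_equal(back$respiratory_mode, sw$respiratory_mode)
  # identical content => identical bytes
  path2 <- tempfile(fileext = ".csv")
  write_trait_table(sw, path2)
  expect_identical(readLines(path), readLines(path2))
  # empty handling
  expect_error(write_trait_table(sw[0, ], tempfile()), "empty")
  p3 <- tempfile(fileext = ".csv")
  write_trait_table(sw[0, ], p3, allow_empty = TRUE)
  expect_equal(length(readLines(p3)), 2L)                # units + header
})

test_that("manifests capture config hash, seed and tolerances", {
  path <- tempfile(fileext = ".json")
  opts <- solve_options(random_seed = 42, multistart_count = 3)
  write_manifest(path, phyto_params(), opts, extra = list(rows = 7))
  m <- jsonlite::read_json(path)
  expect_equal(m$seed, 42)
  expect_equal(m$multistart_count, 3)
  expect_equal(m$rows, 7)
  expect_match(m$config_md5, "^[0-9a-f]{32}$")
})

test_that("command line rejects bad usage without computing", {
  expect_equal(cli_main(character(0)), 2L)
  expect_equal(cli_main("frobnicate"), 2L)
  expect_equal(cli_main(c("sweep", "--step")), 2L)   # dangling flag
})
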