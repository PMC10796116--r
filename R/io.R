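#' @title Configuration and result I/O
#' @description Plain-text parameter configs (JSON primary, YAML accepted),
#'   deterministic trait-table CSVs with a units header, run manifests, and
#'   reference fixture generation.
#' @name io
NULL

.TRAIT_UNITS <- c(
  temperature = "degC", mu_per_day = "1/day",
  carbon_fixation = "fmol C/um^3/day", CUE = "dimensionless",
  chlorophyll_density = "g chl/um^3", q_cell = "mol N/mol C",
  volume = "um^3", radius = "um", beta = "um",
  carbon_storage = "mol C/um^3", respiratory_mode = "category",
  damaged_fraction = "dimensionless", p_ri = "molecules/um^3",
  c_tag = "molecules/um^3", status = "category", tie = "logical")

#' Load a parameter set from a config file
#'
#' Reads a JSON (or YAML, by extension) parameter config, rejects unknown
#' keys, verifies per-pool completeness with field-qualified error messages
#' (e.g. `k_ref.ri`), applies schema defaults for omitted fields and
#' validates the result.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `phyto_params`.
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- .default_params()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in c("k_ref", "eta", "q", "E_a")) {
    if (nm %in% names(raw)) {
      v <- unlist(raw[[nm]])
      missing_pools <- setdiff(POOLS, names(v))
      if (length(missing_pools))
        stop("config missing required field(s): ",
             paste(paste0(nm, ".", missing_pools), collapse = ", "),
             call. = FALSE)
      raw[[nm]] <- v
    }
  }
  do.call(phyto_params, raw)
}

#' Write a parameter set to a config file
#'
#' Canonical JSON serialization; `write(load(x))` is stable.
#'
#' @param params A `phyto_params`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  p <- unclass(params)
  for (nm in c("k_ref", "eta", "q", "E_a"))
    p[[nm]] <- as.list(p[[nm]])   # keep pool names in the JSON object
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a trait table as deterministic CSV
#'
#' RFC-4180 CSV with a leading `#`-comment line documenting units, a fixed
#' column order and full (round-trip) float precision, so identical runs
#' produce byte-identical files.
#'
#' @param records A trait data.frame (e.g. a `thermal_sweep`).
#' @param path Output path.
#' @param allow_empty Permit an empty record set (header-only file).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(records, path, allow_empty = FALSE) {
  if (nrow(records) == 0 && !allow_empty)
    stop("refusing to write an empty trait table (set allow_empty = TRUE)",
         call. = FALSE)
  cols <- names(records)
  units <- ifelse(cols %in% names(.TRAIT_UNITS), .TRAIT_UNITS[cols],
                  "unspecified")
  fmt_cell <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v)
        if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE,
                                       trim = TRUE), character(1))
      out
    } else {
      x <- as.character(x)
      needs <- grepl('[",\n]', x)
      x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
      x
    }
  }
  body <- if (nrow(records) > 0) {
    cells <- lapply(records, fmt_cell)
    do.call(paste, c(cells, sep = ","))
  } else character(0)
  lines <- c(paste0("# units: ", paste(cols, units, sep = "=",
                                       collapse = "; ")),
             paste(cols, collapse = ","), body)
  writeLines(lines, path)
  invisible(path)
}

#' Read a trait table written by [write_trait_table()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_trait_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' JSON manifest with the config hash, seed, tolerances and package version,
#' sufficient to reproduce the accompanying output table.
#'
#' @param path Output path (`.json`).
#' @param params The `phyto_params` used.
#' @param opts The `solve_options` used.
#' @param extra Named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, opts, extra = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(params), tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  manifest <- c(list(
    package = "phytoalloc",
    version = as.character(utils::packageVersion("phytoalloc")),
    config_md5 = hash,
    seed = opts$random_seed,
    mode = opts$mode,
    mu_tolerance = opts$mu_tolerance,
    feasibility_tolerance = opts$feasibility_tolerance,
    multistart_count = opts$multistart_count), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate reference fixtures
#'
#' Emits, under `out_dir`: (a) the reduced three-pool configuration and its
#' exhaustive grid-search optimum (the solver check), (b) a
#' forward-substitution-built feasible cell state with analytically
#' vanishing equality residuals, and (c) a coarse baseline sweep snapshot
#' for regression. All outputs are seeded and deterministic.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param sweep_step Temperature step of the snapshot sweep (degC).
#' @return Named list of written paths, invisibly.
#' @export
generate_reference_fixtures <- function(out_dir, seed = 1, sweep_step = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  tp <- toy_params()
  env <- phyto_env(20)
  paths$toy_config <- file.path(out_dir, "toy_config.json")
  write_parameter_set(tp, paths$toy_config)
  g <- grid_search_toy(tp, env)
  paths$toy_grid_optimum <- file.path(out_dir, "toy_grid_optimum.json")
  jsonlite::write_json(g[c("mu_day", "phi", "beta", "f_n")],
                       paths$toy_grid_optimum, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  bp <- phyto_params()
  st <- random_feasible_state(bp, env, seed = seed)
  st_out <- unclass(st)
  for (nm in c("p", "phi", "alpha"))
    st_out[[nm]] <- as.list(st_out[[nm]])   # keep names in the JSON object
  paths$balanced_state <- file.path(out_dir, "balanced_state.json")
  jsonlite::write_json(st_out, paths$balanced_state, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  opts <- solve_options(multistart_count = 2, random_seed = seed)
  sw <- temperature_sweep(bp, T_start = 5, T_end = 45, step = sweep_step,
                          mode = "free", opts = opts)
  paths$mini_sweep <- file.path(out_dir, "mini_sweep.csv")
  write_trait_table(sw, paths$mini_sweep)
  paths$manifest <- file.path(out_dir, "manifest.json")
  write_manifest(paths$manifest, bp, opts,
                 extra = list(fixture_seed = seed, sweep_step = sweep_step))
  invisible(paths)
}
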