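#' @title Observable traits
#' @description Maps an optimal cell state and its fluxes to the observable
#'   traits reported for phytoplankton cultures: growth rate per day, carbon
#'   fixation, carbon use efficiency, chlorophyll per biovolume, N:C quota,
#'   cell size, carbon storage and the active respiratory mode.
#' @name traits
NULL

AVOGADRO <- 6.02214076e23

#' Whole-cell N:C quota
#'
#' Weighted average of the nitrogen-to-carbon ratio over all carbon-bearing
#' pools: protein pools (concentration times amino acids per protein times C
#' per amino acid, with each pool's protein N:C), internal N, internal C,
#' lipids (membrane, stores and droplets) and the glucose store. Represents
#' the daytime cell including the carbon set aside for dark respiration.
#'
#' @param state A `cell_state`.
#' @param params A `phyto_params`.
#' @return `q_cell` (mol N : mol C).
#' @export
cell_stoichiometry <- function(state, params) {
  p_all <- c(state$p, p = state$p_p + state$p_dp)
  eta <- params$eta[names(p_all)]
  q <- params$q[names(p_all)]
  protein_C <- sum(p_all * eta) * params$eta_aac
  protein_N <- sum(p_all * eta * q) * params$eta_aac
  total_C <- protein_C + state$c_ic +
    (state$c_lm + state$c_li + state$c_tag) * params$eta_lic +
    state$c_gu * params$n_guc
  if (total_C <= 0) stop("total cellular carbon is zero", call. = FALSE)
  (protein_N + state$c_in) / total_C
}

#' Carbon use efficiency
#'
#' `1 - respiration / photosynthesis` in carbon units: the fraction of fixed
#' carbon not catabolized by the two respiratory pathways (glycolysis and
#' lipid degradation).
#'
#' @param fluxes A `phyto_fluxes`.
#' @return Dimensionless CUE in `(-Inf, 1]`.
#' @export
carbon_use_efficiency <- function(fluxes) {
  if (fluxes$v_ru <= 0)
    stop("carbon use efficiency undefined without carbon fixation",
         call. = FALSE)
  1 - (fluxes$v_gl + fluxes$v_ld) / fluxes$v_ru
}

#' Chlorophyll per biovolume
#'
#' Converts the photosystem pool to grams of chlorophyll-a per cubic
#' micrometer, assuming a fixed number of chlorophyll molecules per
#' photosystem and the chlorophyll molar mass. Damaged photosystems retain
#' their pigment bed and are included by default.
#'
#' @param state A `cell_state`.
#' @param params A `phyto_params` (uses `chl_per_ps`, `chl_mw`,
#'   `chl_include_damaged`).
#' @return g chlorophyll um^-3.
#' @export
chlorophyll_per_volume <- function(state, params) {
  pool <- state$p_p + if (params$chl_include_damaged) state$p_dp else 0
  pool * params$chl_per_ps * params$chl_mw / AVOGADRO
}

#' Cell dimensions from the volume-to-surface ratio
#'
#' For a sphere, `beta = V/SA = r/3`, so the radius is `3 * beta`.
#'
#' @param beta Volume-to-surface ratio (um), positive.
#' @return List with `radius`, `volume`, `surface_area` (um, um^3, um^2).
#' @export
cell_dimensions <- function(beta) {
  if (any(beta <= 0)) stop("'beta' must be positive", call. = FALSE)
  r <- 3 * beta
  list(radius = r, volume = 4 / 3 * pi * r^3, surface_area = 4 * pi * r^2)
}

#' Assemble the trait record of a solve
#'
#' Converts an `optimal_cell` result to one row of observable traits with
#' the standard units: growth in day^-1, carbon fixation in
#' fmol C um^-3 day^-1, chlorophyll in g um^-3, carbon storage (glucose
#' store, respiratory lipid store and stress-mitigation lipid droplets, in
#' carbon units) in mol C um^-3. Nonviable or failed rows carry zero growth
#' and missing traits.
#'
#' @param result An `optimal_cell`.
#' @param params A `phyto_params`.
#' @param env A `phyto_env`.
#' @return A one-row `data.frame`.
#' @export
assemble_trait_record <- function(result, params, env) {
  base <- data.frame(
    temperature = env$T_celsius, mu_per_day = 0, carbon_fixation = NA_real_,
    CUE = NA_real_, chlorophyll_density = NA_real_, q_cell = NA_real_,
    volume = NA_real_, radius = NA_real_, beta = NA_real_,
    carbon_storage = NA_real_, respiratory_mode = "none",
    damaged_fraction = NA_real_, p_ri = NA_real_, c_tag = NA_real_,
    status = result$status, tie = isTRUE(result$tie),
    stringsAsFactors = FALSE)
  for (pool in POOLS) base[[paste0("phi_", pool)]] <- NA_real_
  if (result$status != "optimal") return(base)
  st <- result$state; fl <- result$fluxes
  dims <- cell_dimensions(st$beta)
  base$mu_per_day <- result$mu_per_day
  base$carbon_fixation <- fl$v_ru * 1440 / AVOGADRO * 1e15
  base$CUE <- if (fl$v_ru > 0) carbon_use_efficiency(fl) else NA_real_
  base$chlorophyll_density <- chlorophyll_per_volume(st, params)
  base$q_cell <- cell_stoichiometry(st, params)
  base$volume <- dims$volume
  base$radius <- dims$radius
  base$beta <- st$beta
  base$carbon_storage <- (st$c_gu * params$n_guc +
                            (st$c_li + st$c_tag) * params$eta_lic) / AVOGADRO
  base$respiratory_mode <- result$active_respiratory_pathway
  base$damaged_fraction <- st$p_dp / max(st$p_p + st$p_dp, 1e-300)
  base$p_ri <- st$p[["ri"]]
  base$c_tag <- st$c_tag
  for (pool in POOLS) base[[paste0("phi_", pool)]] <- st$phi[[pool]]
  base
}
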