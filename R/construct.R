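#' @title Constructing balanced cell states
#' @description Forward-substitution construction of steady-state-consistent
#'   cell states: given an allocation (proteome fractions, membrane share of
#'   the lipid flux) and a cell geometry, every pool follows algebraically
#'   and the two remaining balances (internal carbon and nitrogen) are
#'   solved exactly by bracketed root finding. Used to build reference
#'   fixtures with analytically vanishing residuals, independent of the
#'   optimizer.
#' @name construct
NULL

# Close the balances on the reduced design by bracketed root finding: the
# internal-carbon balance is solved in f_c (fixation surplus falls as the
# internal pool saturates), and the nitrogen balance is solved in the
# transporter allocation phi_tr (uptake is linear in the transporter pool,
# while the implied ribosome share, and with it demand, falls as phi_tr
# grows, so the residual is monotone and always bracketable). The
# internal-N saturation f_n is a free choice of the caller. Robust but
# slower than the Newton polish; used by the constructors.
.solve_balances_robust <- function(z, ctx) {
  P <- ctx$params
  with_fc <- function(zz) {
    if (!P$track_carbon) {
      ev <- .eval_design(zz, ctx)
      if (!ev$valid) return(NULL)
      return(list(z = zz, R_N = ev$eq[[ctx$i_eq_N]]))
    }
    rc <- function(f_c) {
      zz["f_c"] <- f_c
      ev <- .eval_design(zz, ctx)
      if (!ev$valid) return(NA_real_)
      ev$eq[[ctx$i_eq_C]]
    }
    lo <- 1e-7; hi <- 1 - 1e-7
    rlo <- rc(lo); rhi <- rc(hi)
    if (is.na(rlo) || is.na(rhi) || rlo * rhi > 0) return(NULL)
    f_c <- stats::uniroot(rc, c(lo, hi), tol = 1e-15)$root
    zz["f_c"] <- f_c
    ev <- .eval_design(zz, ctx)
    if (!ev$valid) return(NULL)
    list(z = zz, R_N = ev$eq[[ctx$i_eq_N]])
  }
  rn <- function(phi_tr) {
    zz <- z; zz[2] <- phi_tr
    r <- with_fc(zz)
    if (is.null(r)) NA_real_ else r$R_N
  }
  others <- sum(z[c(1, 3:7)])
  hi_tr <- ctx$phi_budget - others - 1e-4
  if (hi_tr <= 1e-8) return(NULL)
  grid <- exp(seq(log(1e-7), log(hi_tr), length.out = 30))
  vals <- vapply(grid, rn, numeric(1))
  ok <- which(!is.na(vals))
  if (length(ok) < 2) return(NULL)
  sgn <- sign(vals[ok])
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flip)) return(NULL)
  i <- ok[flip[1]]; j <- ok[flip[1] + 1]
  phi_tr <- stats::uniroot(rn, c(grid[i], grid[j]), tol = 1e-15)$root
  z[2] <- phi_tr
  r <- with_fc(z)
  if (is.null(r)) return(NULL)
  .polish_balances(r$z, ctx)
}

#' Build a balanced cell state by forward substitution
#'
#' Constructs a `cell_state` that satisfies every equality of the model
#' exactly (to root-finding precision): the protein-pool balances, lipid
#' pools, storage requirements, the surface identity and the damage-repair
#' quasi-steady state hold by construction, and the internal carbon and
#' nitrogen balances are closed by solving for the two internal substrate
#' saturations. Inequality constraints are not imposed here; see
#' [random_feasible_state()] for a generator that also repairs them.
#'
#' @param params A `phyto_params`.
#' @param env A `phyto_env`.
#' @param phi Named investment fractions over all 8 pools; they are
#'   renormalized to sum to `1 - phi_other`. The transporter share is then
#'   re-solved so the nitrogen balance closes (with saturating uptake the
#'   balance fixes the transporter pool); the ribosome share absorbs the
#'   difference.
#' @param alpha_lm Membrane share of the lipid-synthesis flux.
#' @param beta Volume-to-surface ratio (um).
#' @param f_n Internal-nitrogen saturation, in (0, 1).
#' @return A `cell_state`, or `NULL` if no balance-consistent state exists
#'   for this allocation.
#' @export
build_balanced_state <- function(params, env, phi, alpha_lm = 0.3,
                                 beta = 0.3, f_n = 0.7) {
  stopifnot(all(POOLS %in% names(phi)), f_n > 0, f_n < 1)
  phi <- phi[POOLS] * (1 - params$phi_other) / sum(phi[POOLS])
  ctx <- .design_ctx(params, env, "unrestricted")
  z <- ctx$template
  z[1:7] <- phi[c("ru", "tr", "p", "re", "lb", "gl", "ld")]
  z["alpha_lm"] <- alpha_lm
  z["ln_beta"] <- log(beta)
  z["f_n"] <- f_n
  z[ctx$pinned] <- ctx$template[ctx$pinned]
  z2 <- .solve_balances_robust(z, ctx)
  if (is.null(z2)) return(NULL)
  .design_state(z2, ctx)
}

#' Generate a random feasible cell state
#'
#' Draws a random allocation around a physiological center, closes the
#' balances with [build_balanced_state()], and then repairs inequality
#' violations by reallocating: photosystem share is raised when daytime
#' energy is short, respiratory share when the dark budget is short, the
#' membrane lipid share and geometry when the membrane, density or volume
#' constraints are violated. Deterministic given `seed`. Intended for
#' regression fixtures and property tests, not as a solver.
#'
#' @param params A `phyto_params`.
#' @param env A `phyto_env`.
#' @param seed Integer seed.
#' @param max_repair Maximum repair iterations.
#' @return A feasible `cell_state` (equalities at root-finding precision,
#'   slacks non-negative), or error if repair fails.
#' @export
random_feasible_state <- function(params, env, seed = 1, max_repair = 80) {
  .with_seed(seed, {
    center <- c(ru = 0.10, tr = 0.06, ri = 0.14, p = 0.16, re = 0.01,
                lb = 0.05, gl = 0.05, ld = 0.004)
    w <- stats::rgamma(8, shape = 60 * center)
    phi <- stats::setNames(w / sum(w), names(center))
    alpha_lm <- stats::runif(1, 0.2, 0.5)
    beta <- exp(stats::runif(1, log(0.15), log(0.8)))
    f_n <- stats::runif(1, 0.5, 0.85)
    for (i in seq_len(max_repair)) {
      st <- build_balanced_state(params, env, phi, alpha_lm, beta, f_n)
      if (is.null(st)) { # allocation cannot close balances; recenter
        phi <- 0.7 * phi + 0.3 * center / sum(center)
        next
      }
      rep <- residual_report(st, params, env)
      sl <- rep$slacks
      # alpha_ld may legitimately sit at zero; everything else needs a
      # strictly positive margin
      margin <- 1e-6
      strict <- setdiff(names(sl), "alpha_nonneg")
      if (all(sl[strict] > margin) && all(sl >= -1e-9)) return(st)
      dmg <- st$p_dp / max(st$p_p + st$p_dp, 1e-300)
      if (dmg > 0.3) {
        # damage spiral: feed the repair pool and the lipid droplets
        phi["re"] <- phi["re"] * 1.5
        phi["lb"] <- phi["lb"] * 1.2
        alpha_lm <- alpha_lm * 0.9
      } else if (sl[["day"]] <= margin || sl[["rubisco"]] <= margin) {
        phi["p"] <- phi["p"] * 1.2
      }
      if (sl[["dark"]] <= margin) phi["gl"] <- phi["gl"] * 1.3
      if (params$lipids_enabled) {
        if (sl[["membrane"]] <= margin) {
          alpha_lm <- min(0.9, alpha_lm * 1.25)
          phi["lb"] <- phi["lb"] * 1.1
        }
        if (sl[["c_tag_upper"]] <= margin) phi["lb"] <- phi["lb"] * 0.8
        if (sl[["alpha_nonneg"]] < -1e-9) {
          phi["ld"] <- phi["ld"] * 0.7
          alpha_lm <- alpha_lm * 0.95
        }
      }
      if (sl[["density"]] <= margin || sl[["volume_fraction"]] <= margin)
        beta <- beta * 1.3
      phi <- phi / sum(phi)
    }
    stop("random_feasible_state: repair failed to reach feasibility",
         call. = FALSE)
  })
}
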