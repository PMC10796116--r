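#' @title Growth-maximization solver
#' @description Finds the cell state that maximizes steady-state growth rate
#'   subject to all mass balances and energy/space constraints. The decision
#'   space is reduced by forward substitution: given the proteome fractions,
#'   the membrane share of the lipid-synthesis flux, the internal-substrate
#'   saturations and the volume-to-surface ratio, every pool concentration
#'   and flux follows algebraically (the surface identity sets the absolute
#'   scale and the damage-repair quasi-steady state has a closed form), so
#'   only the carbon and nitrogen balances remain as nonlinear equalities.
#'   These are handled, together with the inequality constraints, by a
#'   multistart augmented-Lagrangian method over L-BFGS-B.
#' @name optimizer
NULL

# Decision vector layout (full problem, free entries depend on mode):
#   1..7  phi_ru, phi_tr, phi_p, phi_re, phi_lb, phi_gl, phi_ld
#   8     alpha_lm
#   9,10  f_c, f_n   (internal C and N saturation, in (0,1))
#   11    log(beta)
# phi_ri = (1 - phi_other) - sum(other phis), kept positive via a constraint.
.Z_NAMES <- c("phi_ru", "phi_tr", "phi_p", "phi_re", "phi_lb", "phi_gl",
              "phi_ld", "alpha_lm", "f_c", "f_n", "ln_beta")

#' Solver options
#'
#' @param mode One of `"free"`, `"glycolysis_only"`, `"lipid_only"`,
#'   `"unrestricted"`. In `"free"` mode the best of the two restricted
#'   solves and one unrestricted solve is returned, so the discrete
#'   respiratory-pathway choice is scanned explicitly rather than relying on
#'   the continuous solver to cross a nonconvex ridge.
#' @param mu_tolerance Growth-rate tolerance (day^-1) below which a solution
#'   is reported nonviable; also the tie margin between pathways.
#' @param feasibility_tolerance Relative feasibility tolerance for equality
#'   residuals and inequality slacks.
#' @param multistart_count Number of starts per restricted solve (>= 1).
#' @param random_seed Seed making the multistart deterministic.
#' @param warm_start Optional `cell_state` (or decision vector) used as the
#'   first start.
#' @return A `solve_options` list.
#' @export
solve_options <- function(mode = c("free", "glycolysis_only", "lipid_only",
                                   "unrestricted"),
                          mu_tolerance = 1e-4,
                          feasibility_tolerance = 1e-8,
                          multistart_count = 8,
                          random_seed = 0,
                          warm_start = NULL) {
  mode <- match.arg(mode)
  stopifnot(mu_tolerance > 0, feasibility_tolerance > 0, multistart_count >= 1)
  structure(list(mode = mode, mu_tolerance = mu_tolerance,
                 feasibility_tolerance = feasibility_tolerance,
                 multistart_count = as.integer(multistart_count),
                 random_seed = as.integer(random_seed),
                 warm_start = warm_start),
            class = "solve_options")
}

# Precomputed, temperature-resolved problem context for one (params, env,
# submode) triple. All constants used by the hot evaluation path are
# unpacked into plain scalars in `cs`.
.design_ctx <- function(params, env, submode) {
  rt <- rates_at(params, env$T)
  pinned <- logical(11)
  names(pinned) <- .Z_NAMES
  if (!params$lipids_enabled)
    pinned[c("phi_lb", "phi_gl", "phi_ld", "alpha_lm")] <- TRUE
  if (!params$damage_enabled) pinned["phi_re"] <- TRUE
  if (!params$track_carbon) pinned[c("phi_ru", "f_c")] <- TRUE
  if (submode == "glycolysis_only") pinned["phi_ld"] <- TRUE
  if (submode == "lipid_only") pinned["phi_gl"] <- TRUE
  template <- stats::setNames(numeric(11), .Z_NAMES)
  template["f_c"] <- if (params$track_carbon) 0.5 else 1
  template["f_n"] <- 0.5
  phi_budget <- 1 - params$phi_other
  f_I <- env$I / (env$I + params$K_p)
  f_DIC <- if (env$saturating_C) 1 else env$DIC / (env$DIC + params$K_ru)
  f_DIN <- if (env$saturating_N) 1 else env$DIN / (env$DIN + params$K_tr)
  k <- rt$k; eta <- params$eta; q <- params$q
  cs <- list(
    k_ru = k[["ru"]], k_tr = k[["tr"]], k_ri = k[["ri"]], k_p = k[["p"]],
    k_re = k[["re"]], k_lb = k[["lb"]], k_gl = k[["gl"]], k_ld = k[["ld"]],
    k_d = rt$k_d, M_bound = rt$M_bound,
    eta_ru = eta[["ru"]], eta_tr = eta[["tr"]], eta_ri = eta[["ri"]],
    eta_p = eta[["p"]], eta_re = eta[["re"]], eta_lb = eta[["lb"]],
    eta_gl = eta[["gl"]], eta_ld = eta[["ld"]],
    q_ru = q[["ru"]], q_tr = q[["tr"]], q_ri = q[["ri"]], q_p = q[["p"]],
    q_re = q[["re"]], q_lb = q[["lb"]], q_gl = q[["gl"]], q_ld = q[["ld"]],
    q_other_w = params$phi_other * params$q_other,
    K_ic = params$K_ic, K_in = params$K_in, K_lb = params$K_lb,
    eta_aac = params$eta_aac, eta_aa = params$eta_aa,
    eta_lic = params$eta_lic, n_guc = params$n_guc,
    e_p = params$e_p, e_ru = params$e_ru, e_ri = params$e_ri,
    e_tr = params$e_tr, e_lb = params$e_lb, e_re = params$e_re,
    e_gl = params$e_gl, e_ld = params$e_ld, f_dr = params$f_dr,
    t_d = params$t_d, s_tr = params$s_tr, s_lm = params$s_lm,
    V_p = params$V_p, V_li = params$V_li, D_max = params$D_max,
    w_ic = params$w_ic, w_in = params$w_in, w_gu = params$w_gu,
    c_tag_min = params$c_tag_min, c_tag_max = params$c_tag_max,
    track_carbon = params$track_carbon,
    lipids_enabled = params$lipids_enabled)
  eps_tag <- 1e-9 * params$c_tag_max
  ctx <- list(params = params, env = env, submode = submode, rt = rt,
              pinned = pinned, template = template, phi_budget = phi_budget,
              f_I = f_I, f_DIC = f_DIC, f_DIN = f_DIN, eps_tag = eps_tag,
              cs = cs,
              i_eq_C = if (params$track_carbon) 1L else 0L,
              i_eq_N = if (params$track_carbon) 2L else 1L)
  ctx$eval <- .compile_eval(ctx)
  ctx$eval_mat <- .compile_eval_mat(ctx)
  ctx
}

# Bind every constant of the evaluation into the closure's environment so
# the hot path pays plain symbol lookups instead of list indexing.
.compile_eval <- function(ctx) {
  en <- list2env(ctx$cs, parent = asNamespace("phytoalloc"))
  en$phi_budget <- ctx$phi_budget
  en$f_I <- ctx$f_I; en$f_DIC <- ctx$f_DIC; en$f_DIN <- ctx$f_DIN
  en$eps_tag <- ctx$eps_tag
  fn <- eval(.EVAL_BODY, en)
  compiler::cmpfun(fn)
}

.compile_eval_mat <- function(ctx) {
  en <- list2env(ctx$cs, parent = asNamespace("phytoalloc"))
  en$phi_budget <- ctx$phi_budget
  en$f_I <- ctx$f_I; en$f_DIC <- ctx$f_DIC; en$f_DIN <- ctx$f_DIN
  en$eps_tag <- ctx$eps_tag
  compiler::cmpfun(eval(.EVAL_MAT_BODY, en))
}

# Forward-substitution evaluation of a full decision vector z (length 11,
# pinned entries at template values). Returns objective (growth, day^-1),
# scaled equality residuals and inequality slacks. Pure scalar arithmetic:
# this is the solver's hot path, compiled per-context by .compile_eval().
# Equality order: (C), N. Inequality order: phi_ri, day, volume, density,
# (dark), (membrane, tag_upper, tag_lower, alpha_tag).
.EVAL_BODY <- quote(function(z) {
  phi_ru <- z[[1]]; phi_tr <- z[[2]]; phi_p <- z[[3]]; phi_re <- z[[4]]
  phi_lb <- z[[5]]; phi_gl <- z[[6]]; phi_ld <- z[[7]]
  alpha_lm <- z[[8]]; f_c <- z[[9]]; f_n <- z[[10]]; beta <- exp(z[[11]])
  phi_ri <- phi_budget - (phi_ru + phi_tr + phi_p + phi_re +
                            phi_lb + phi_gl + phi_ld)
  if (phi_ri <= 0 || f_n <= 0 || f_n >= 1 ||
      (track_carbon && (f_c <= 0 || f_c >= 1)))
    return(list(valid = FALSE, pen = 1 + abs(min(phi_ri, 0))))

  mu <- k_ri * phi_ri * f_c * f_n / eta_ri
  c_ic <- if (track_carbon) K_ic * f_c / (1 - f_c) else 0
  c_in <- K_in * f_n / (1 - f_n)
  f_lb <- if (track_carbon) c_ic / (c_ic + K_lb) else 1

  # surface identity sets the absolute scale (protein synthesis flux)
  A <- s_tr * phi_tr / (eta_tr * mu) +
    s_lm * alpha_lm * k_lb * phi_lb * f_lb /
      (eta_lb * mu * eta_lic * mu)
  if (!is.finite(A) || A <= 0)
    return(list(valid = FALSE, pen = 1))
  v_ri <- 1 / (beta * A)

  inv_mu <- v_ri / mu
  p_ru <- phi_ru * inv_mu / eta_ru
  p_tr <- phi_tr * inv_mu / eta_tr
  p_ri <- phi_ri * inv_mu / eta_ri
  p_re <- phi_re * inv_mu / eta_re
  p_lb <- phi_lb * inv_mu / eta_lb
  p_gl <- phi_gl * inv_mu / eta_gl
  p_ld <- phi_ld * inv_mu / eta_ld
  ps_tot <- phi_p * inv_mu / eta_p

  v_lb <- k_lb * p_lb * f_lb
  v_gl <- k_gl * p_gl
  v_ld <- k_ld * p_ld
  alpha_ld <- if (v_lb > 0) v_ld / v_lb else if (v_ld > 0) Inf else 0
  if (!is.finite(alpha_ld)) return(list(valid = FALSE, pen = 1))
  alpha_tag <- 1 - alpha_lm - alpha_ld
  c_lm <- alpha_lm * v_lb / (eta_lic * mu)
  c_tag <- alpha_tag * v_lb / (eta_lic * mu)

  # damage-repair quasi-steady state (closed form)
  if (k_d > 0) {
    gamma_tag <- c_tag_max / max(c_tag, 1e-300)
    x_d <- k_d * ps_tot * gamma_tag / (k_re * max(p_re, 1e-300))
    dmg <- x_d / (1 + x_d)
    if (!is.finite(dmg)) dmg <- 1
  } else dmg <- 0
  p_p <- (1 - dmg) * ps_tot

  v_ru <- k_ru * p_ru * f_DIC
  v_tr <- k_tr * p_tr * f_DIN
  v_p <- k_p * p_p * f_I
  v_re <- k_re * p_re * dmg
  c_gu <- v_gl * t_d / n_guc
  c_li <- v_ld * t_d / eta_lic

  eta_aan <- eta_aac *
    (phi_ru * q_ru + phi_tr * q_tr + phi_ri * q_ri + phi_p * q_p +
       phi_re * q_re + phi_lb * q_lb + phi_gl * q_gl + phi_ld * q_ld +
       q_other_w)

  e_cost <- e_ri * v_ri + e_tr * v_tr + e_lb * v_lb + e_re * v_re
  e_supply <- e_p * v_p
  e_scale <- e_supply + e_ru * v_ru + e_cost + 1e-300

  # equality residuals (relative scale)
  cons_N <- v_ri * eta_aan + mu * c_in
  r_N <- (v_tr - cons_N) / max(v_tr, cons_N, 1e-300)
  eq <- if (track_carbon) {
    cons_C <- v_ri * eta_aac + v_lb + v_gl + mu * c_ic
    c((v_ru - cons_C) / max(v_ru, cons_C, 1e-300), r_N)
  } else r_N

  # inequality slacks (>= 0 feasible), all O(1)
  vf <- 1 - ps_tot * V_p - (c_li + c_tag) * V_li
  dens <- (p_ru * eta_ru + p_tr * eta_tr + p_ri * eta_ri + p_re * eta_re +
             p_lb * eta_lb + p_gl * eta_gl + p_ld * eta_ld) * eta_aa +
    c_ic * w_ic + c_in * w_in + c_gu * w_gu
  ineq <- c(
    (phi_ri - 1e-6) / phi_budget,
    (e_supply - e_ru * v_ru - e_cost) / e_scale,
    vf - 1e-6,
    (D_max * vf - dens) / D_max)
  if (f_dr > 0)
    ineq <- c(ineq, (e_gl * v_gl + e_ld * v_ld - f_dr * e_cost) / e_scale)
  if (lipids_enabled) {
    ineq <- c(ineq,
              (M_bound * c_lm - p_tr) / (M_bound * c_lm + p_tr + 1e-300),
              (c_tag_min + c_tag_max - c_tag) / c_tag_max,
              (c_tag - eps_tag) / c_tag_max,
              alpha_tag)
  }

  list(valid = TRUE, mu = mu, mu_day = mu * 1440, eq = eq, ineq = ineq,
       phi_ri = phi_ri, dmg = dmg, v_ri = v_ri, beta = beta)
})

.eval_design <- function(z, ctx) ctx$eval(z)

# Vectorized twin of .EVAL_BODY operating on a matrix of decision vectors
# (11 rows, one column per point). Used to evaluate all finite-difference
# points of the augmented-Lagrangian gradient in one pass. Invalid columns
# are flagged; their numeric outputs are computed on clamped inputs and
# must be ignored by the caller.
.EVAL_MAT_BODY <- quote(function(Z) {
  m <- ncol(Z)
  phi_ru <- Z[1, ]; phi_tr <- Z[2, ]; phi_p <- Z[3, ]; phi_re <- Z[4, ]
  phi_lb <- Z[5, ]; phi_gl <- Z[6, ]; phi_ld <- Z[7, ]
  alpha_lm <- Z[8, ]; f_c <- Z[9, ]; f_n <- Z[10, ]; beta <- exp(Z[11, ])
  phi_ri <- phi_budget - (phi_ru + phi_tr + phi_p + phi_re +
                            phi_lb + phi_gl + phi_ld)
  valid <- phi_ri > 0 & f_n > 0 & f_n < 1
  if (track_carbon) valid <- valid & f_c > 0 & f_c < 1
  pen <- 1 + pmax(0, -phi_ri)
  phi_ri <- pmax(phi_ri, 1e-12)
  f_n <- pmin(pmax(f_n, 1e-12), 1 - 1e-12)
  f_c <- pmin(pmax(f_c, 1e-12), 1 - 1e-12)

  mu <- k_ri * phi_ri * f_c * f_n / eta_ri
  c_ic <- if (track_carbon) K_ic * f_c / (1 - f_c) else numeric(m)
  c_in <- K_in * f_n / (1 - f_n)
  f_lb <- if (track_carbon) c_ic / (c_ic + K_lb) else rep(1, m)

  A <- s_tr * phi_tr / (eta_tr * mu) +
    s_lm * alpha_lm * k_lb * phi_lb * f_lb / (eta_lb * mu * eta_lic * mu)
  valid <- valid & is.finite(A) & A > 0
  A <- pmax(A, 1e-300)
  v_ri <- 1 / (beta * A)

  inv_mu <- v_ri / mu
  p_ru <- phi_ru * inv_mu / eta_ru
  p_tr <- phi_tr * inv_mu / eta_tr
  p_ri <- phi_ri * inv_mu / eta_ri
  p_re <- phi_re * inv_mu / eta_re
  p_lb <- phi_lb * inv_mu / eta_lb
  p_gl <- phi_gl * inv_mu / eta_gl
  p_ld <- phi_ld * inv_mu / eta_ld
  ps_tot <- phi_p * inv_mu / eta_p

  v_lb <- k_lb * p_lb * f_lb
  v_gl <- k_gl * p_gl
  v_ld <- k_ld * p_ld
  alpha_ld <- ifelse(v_lb > 0, v_ld / pmax(v_lb, 1e-300),
                     ifelse(v_ld > 0, Inf, 0))
  valid <- valid & is.finite(alpha_ld)
  alpha_ld[!is.finite(alpha_ld)] <- 0
  alpha_tag <- 1 - alpha_lm - alpha_ld
  c_lm <- alpha_lm * v_lb / (eta_lic * mu)
  c_tag <- alpha_tag * v_lb / (eta_lic * mu)

  if (k_d > 0) {
    gamma_tag <- c_tag_max / pmax(c_tag, 1e-300)
    x_d <- k_d * ps_tot * gamma_tag / (k_re * pmax(p_re, 1e-300))
    dmg <- x_d / (1 + x_d)
    dmg[!is.finite(dmg)] <- 1
  } else dmg <- numeric(m)
  p_p <- (1 - dmg) * ps_tot

  v_ru <- k_ru * p_ru * f_DIC
  v_tr <- k_tr * p_tr * f_DIN
  v_p <- k_p * p_p * f_I
  v_re <- k_re * p_re * dmg
  c_gu <- v_gl * t_d / n_guc
  c_li <- v_ld * t_d / eta_lic

  eta_aan <- eta_aac *
    (phi_ru * q_ru + phi_tr * q_tr + phi_ri * q_ri + phi_p * q_p +
       phi_re * q_re + phi_lb * q_lb + phi_gl * q_gl + phi_ld * q_ld +
       q_other_w)

  e_cost <- e_ri * v_ri + e_tr * v_tr + e_lb * v_lb + e_re * v_re
  e_supply <- e_p * v_p
  e_scale <- e_supply + e_ru * v_ru + e_cost + 1e-300

  cons_N <- v_ri * eta_aan + mu * c_in
  r_N <- (v_tr - cons_N) / pmax(v_tr, cons_N, 1e-300)
  eq <- if (track_carbon) {
    cons_C <- v_ri * eta_aac + v_lb + v_gl + mu * c_ic
    rbind((v_ru - cons_C) / pmax(v_ru, cons_C, 1e-300), r_N)
  } else rbind(r_N)

  vf <- 1 - ps_tot * V_p - (c_li + c_tag) * V_li
  dens <- (p_ru * eta_ru + p_tr * eta_tr + p_ri * eta_ri + p_re * eta_re +
             p_lb * eta_lb + p_gl * eta_gl + p_ld * eta_ld) * eta_aa +
    c_ic * w_ic + c_in * w_in + c_gu * w_gu
  ineq <- rbind(
    (phi_ri - 1e-6) / phi_budget,
    (e_supply - e_ru * v_ru - e_cost) / e_scale,
    vf - 1e-6,
    (D_max * vf - dens) / D_max)
  if (f_dr > 0)
    ineq <- rbind(ineq, (e_gl * v_gl + e_ld * v_ld - f_dr * e_cost) /
                    e_scale)
  if (lipids_enabled) {
    ineq <- rbind(ineq,
                  (M_bound * c_lm - p_tr) / (M_bound * c_lm + p_tr + 1e-300),
                  (c_tag_min + c_tag_max - c_tag) / c_tag_max,
                  (c_tag - eps_tag) / c_tag_max,
                  alpha_tag)
  }
  list(valid = valid, pen = pen, mu_day = mu * 1440, eq = eq, ineq = ineq)
})

# Build the full cell_state (public containers) from a decision vector.
.design_state <- function(z, ctx) {
  P <- ctx$params
  ev <- .eval_design(z, ctx)
  if (!ev$valid) stop("cannot materialize an invalid design", call. = FALSE)
  k <- ctx$rt$k
  mu <- ev$mu; v_ri <- ev$v_ri; phi_ri <- ev$phi_ri
  phi <- c(ru = z[[1]], tr = z[[2]], ri = phi_ri, p = z[[3]], re = z[[4]],
           lb = z[[5]], gl = z[[6]], ld = z[[7]])[POOLS]
  p <- stats::setNames(phi[NONPS_POOLS] * v_ri / (P$eta[NONPS_POOLS] * mu),
                       NONPS_POOLS)
  ps_tot <- phi[["p"]] * v_ri / (P$eta[["p"]] * mu)
  f_c <- z[[9]]; f_n <- z[[10]]
  c_ic <- if (P$track_carbon) P$K_ic * f_c / (1 - f_c) else 0
  c_in <- P$K_in * f_n / (1 - f_n)
  f_lb <- if (P$track_carbon) c_ic / (c_ic + P$K_lb) else 1
  v_lb <- k[["lb"]] * p[["lb"]] * f_lb
  v_gl <- k[["gl"]] * p[["gl"]]
  v_ld <- k[["ld"]] * p[["ld"]]
  alpha_lm <- z[[8]]
  alpha_ld <- if (v_lb > 0) v_ld / v_lb else 0
  alpha <- c(lm = alpha_lm, tag = 1 - alpha_lm - alpha_ld, ld = alpha_ld)
  c_lm <- alpha[["lm"]] * v_lb / (P$eta_lic * mu)
  c_tag <- alpha[["tag"]] * v_lb / (P$eta_lic * mu)
  stor <- dark_storage_requirements(v_gl, v_ld, P)
  cell_state(p = p, p_p = (1 - ev$dmg) * ps_tot, p_dp = ev$dmg * ps_tot,
             c_ic = c_ic, c_in = c_in, c_lm = c_lm, c_tag = c_tag,
             c_gu = stor[["c_gu"]], c_li = stor[["c_li"]],
             phi = phi, alpha = alpha, beta = exp(z[[11]]), mu = mu,
             params = P)
}

# Augmented-Lagrangian outer loop over L-BFGS-B. Equalities h(z)=0 carry
# multipliers lambda; inequalities g(z)>=0 use the Rockafellar shifted
# quadratic penalty. Returns the final point, its evaluation and diagnostics.
.auglag <- function(z0, ctx, lb, ub, feas_tol = 1e-9,
                    outer_max = 25, inner_maxit = 200, rho0 = 100) {
  free <- !ctx$pinned
  n_free <- sum(free)
  z <- ctx$template
  z[free] <- z0[free]
  n_eq <- 1L + as.integer(ctx$cs$track_carbon)
  n_in <- 4L + as.integer(ctx$cs$f_dr > 0) +
    if (ctx$cs$lipids_enabled) 4L else 0L
  lambda <- numeric(n_eq)
  mults <- numeric(n_in)
  rho <- rho0
  viol_prev <- Inf
  mu_prev <- NA_real_
  total_fn <- 0L
  evalf <- ctx$eval

  best_valid <- NULL   # least-infeasible valid iterate seen anywhere
  best_valid_score <- Inf
  al_value <- function(zf) {
    zz <- z
    zz[free] <- zf
    ev <- evalf(zz)
    total_fn <<- total_fn + 1L
    if (!ev$valid) return(1e8 * ev$pen)
    h <- ev$eq; g <- ev$ineq
    viol <- max(c(abs(h), pmax(0, -g), 0))
    score <- viol - 1e-4 * ev$mu_day
    if (score < best_valid_score) {
      best_valid_score <<- score
      best_valid <<- zz
    }
    val <- -ev$mu_day + sum(lambda * h) + 0.5 * rho * sum(h * h) +
      sum((pmax(0, mults - rho * g)^2 - mults^2)) / (2 * rho)
    if (!is.finite(val)) 1e8 else val
  }

  evalm <- ctx$eval_mat
  free_idx <- which(free)
  al_grad <- function(zf) {
    zz <- z
    zz[free] <- zf
    hstep <- 1e-7 * (1 + abs(zf))
    Z <- matrix(zz, nrow = 11L, ncol = 2L * n_free)
    for (j in seq_len(n_free)) {
      Z[free_idx[j], j] <- zz[free_idx[j]] + hstep[j]
      Z[free_idx[j], n_free + j] <- zz[free_idx[j]] - hstep[j]
    }
    me <- evalm(Z)
    pm <- mults - rho * me$ineq   # matrix; clamp below at 0 keeping dims
    pm[pm < 0] <- 0
    val <- -me$mu_day + as.vector(lambda %*% me$eq) +
      0.5 * rho * .colSums(me$eq * me$eq, nrow(me$eq), ncol(me$eq)) +
      (.colSums(pm * pm, nrow(pm), ncol(pm)) - sum(mults * mults)) /
        (2 * rho)
    bad <- !me$valid | !is.finite(val)
    if (any(bad)) val[bad] <- 1e8 * me$pen[bad]
    (val[seq_len(n_free)] - val[n_free + seq_len(n_free)]) / (2 * hstep)
  }

  # work in scaled coordinates: proteome fractions are an order of
  # magnitude smaller than the saturation/geometry coordinates
  sc <- c(rep(10, 8), 2, 2, 1)[free]
  converged <- FALSE
  it <- 0L
  for (it in seq_len(outer_max)) {
    opt <- stats::optim(z[free] * sc,
                        function(w) al_value(w / sc),
                        gr = function(w) al_grad(w / sc) / sc,
                        method = "L-BFGS-B",
                        lower = lb[free] * sc, upper = ub[free] * sc,
                        control = list(maxit = inner_maxit, factr = 1e3))
    z[free] <- opt$par / sc
    ev <- evalf(z)
    if (!ev$valid) { rho <- min(rho * 10, 1e10); next }
    viol <- max(c(abs(ev$eq), pmax(0, -ev$ineq), 0))
    lambda <- lambda + rho * ev$eq
    mults <- pmax(0, mults - rho * ev$ineq)
    if (viol < feas_tol && !is.na(mu_prev) &&
        abs(ev$mu_day - mu_prev) < 1e-7 * max(1, abs(ev$mu_day))) {
      converged <- TRUE; break
    }
    mu_prev <- ev$mu_day
    if (viol > 0.2 * viol_prev) rho <- min(rho * 10, 1e10)
    viol_prev <- min(viol_prev, viol)
  }
  ev <- .eval_design(z, ctx)
  if (!ev$valid && !is.null(best_valid)) {
    z <- best_valid
    ev <- .eval_design(z, ctx)
  }
  list(z = z, ev = ev, iterations = it, fn_evals = total_fn,
       converged = converged)
}

# Re-solve the carbon and nitrogen balances exactly in (f_c, f_n) at fixed
# allocation and geometry (damped Newton with numerical Jacobian). Polishes
# the equality residuals of a near-feasible solution to ~1e-12 relative.
.polish_balances <- function(z, ctx, max_iter = 40) {
  P <- ctx$params
  idx <- if (P$track_carbon) c(9L, 10L) else 10L
  resid <- function(vals) {
    zz <- z; zz[idx] <- vals
    ev <- .eval_design(zz, ctx)
    if (!ev$valid) return(NULL)
    ev$eq
  }
  vals <- z[idx]
  for (i in seq_len(max_iter)) {
    r <- resid(vals)
    if (is.null(r)) return(z)
    if (max(abs(r)) < 1e-13) break
    n <- length(vals)
    J <- matrix(0, length(r), n)
    hstep <- pmax(1e-9, abs(vals) * 1e-8)
    for (j in seq_len(n)) {
      vp <- vals; vp[j] <- vp[j] + hstep[j]
      rp <- resid(vp)
      if (is.null(rp)) return(z)
      J[, j] <- (rp - r) / hstep[j]
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- vals + lam * step
      if (all(cand > 1e-9) && all(cand < 1 - 1e-9)) {
        rc <- resid(cand)
        if (!is.null(rc) && max(abs(rc)) < max(abs(r))) { vals <- cand; break }
      }
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) break
  }
  z[idx] <- vals
  z
}

# Shrink the cell (reduce beta) to the point where a crowding constraint
# (macromolecular density, occupied volume or the stored-lipid cap) becomes
# active. Growth is weakly increasing as the cell shrinks -- the only
# scale-breaking terms are the dilution losses -- so the optimum sits at the
# crowding bound; the smooth solver stalls on this nearly flat direction and
# this structured step finishes the job. Balances are re-solved at every
# trial scale.
.crowd_beta <- function(z, ctx, tol = 1e-9) {
  ev_at <- function(lnb) {
    zz <- z; zz[11] <- lnb
    zz <- .polish_balances(zz, ctx, max_iter = 15)
    ev <- .eval_design(zz, ctx)
    list(z = zz, ev = ev)
  }
  ok <- function(r) r$ev$valid &&
    max(abs(r$ev$eq)) < 1e-10 && all(r$ev$ineq > -tol)
  cur <- ev_at(z[11])
  if (!ok(cur)) return(z)
  lo <- log(1e-3); hi <- z[11]
  r_lo <- ev_at(lo)
  if (ok(r_lo)) return(r_lo$z)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- ev_at(mid)
    if (ok(r)) { hi <- mid; cur <- r } else lo <- mid
    if (hi - lo < 1e-10) break
  }
  if (cur$ev$mu_day >= .eval_design(z, ctx)$mu_day - 1e-9) cur$z else z
}

# Random and heuristic starting points in the reduced decision space.
.random_start <- function(ctx) {
  P <- ctx$params
  w <- stats::rgamma(8, shape = 1.5)
  phi <- ctx$phi_budget * w / sum(w)
  z <- ctx$template
  z[1:7] <- phi[1:7]  # eighth share goes to ribosomes implicitly
  z["alpha_lm"] <- stats::runif(1, 0.05, 0.7)
  if (P$track_carbon) z["f_c"] <- stats::runif(1, 0.3, 0.95)
  z["f_n"] <- stats::runif(1, 0.3, 0.95)
  z["ln_beta"] <- stats::runif(1, log(0.05), log(5))
  z[ctx$pinned] <- ctx$template[ctx$pinned]
  z
}

.default_start <- function(ctx) {
  z <- ctx$template
  z[c("phi_ru", "phi_tr", "phi_p", "phi_re", "phi_lb", "phi_gl", "phi_ld")] <-
    c(0.05, 0.05, 0.22, 0.01, 0.04, 0.02, 0.01)
  z["alpha_lm"] <- 0.3
  if (ctx$params$track_carbon) z["f_c"] <- 0.7
  z["f_n"] <- 0.7
  z["ln_beta"] <- log(0.3)
  z[ctx$pinned] <- ctx$template[ctx$pinned]
  # keep the implied ribosome share sensible
  s <- sum(z[1:7])
  if (s > 0.8 * ctx$phi_budget) z[1:7] <- z[1:7] * 0.8 * ctx$phi_budget / s
  z
}

# Heat-stress-oriented start: heavy photosystem, repair and stored-lipid
# investment. Near-fatal temperatures have a narrow feasible basin that
# growth-oriented starts often miss.
.stress_start <- function(ctx) {
  z <- ctx$template
  z[c("phi_ru", "phi_tr", "phi_p", "phi_re", "phi_lb", "phi_gl", "phi_ld")] <-
    c(0.03, 0.04, 0.30, 0.05, 0.06, 0.03, 0.005)
  z["alpha_lm"] <- 0.15
  if (ctx$params$track_carbon) z["f_c"] <- 0.6
  z["f_n"] <- 0.6
  z["ln_beta"] <- log(0.5)
  z[ctx$pinned] <- ctx$template[ctx$pinned]
  z
}

.state_to_z <- function(state, ctx) {
  P <- ctx$params
  z <- ctx$template
  z[1:7] <- state$phi[c("ru", "tr", "p", "re", "lb", "gl", "ld")]
  z["alpha_lm"] <- state$alpha[["lm"]]
  if (P$track_carbon) z["f_c"] <- state$c_ic / (state$c_ic + P$K_ic)
  z["f_n"] <- state$c_in / (state$c_in + P$K_in)
  z["ln_beta"] <- log(state$beta)
  z[ctx$pinned] <- ctx$template[ctx$pinned]
  z
}

.z_bounds <- function(ctx) {
  lb <- stats::setNames(rep(0, 11), .Z_NAMES)
  ub <- stats::setNames(rep(ctx$phi_budget, 11), .Z_NAMES)
  lb["alpha_lm"] <- 0; ub["alpha_lm"] <- 1
  lb[c("f_c", "f_n")] <- 1e-6; ub[c("f_c", "f_n")] <- 1 - 1e-6
  lb["ln_beta"] <- log(1e-3); ub["ln_beta"] <- log(1e3)
  list(lb = lb, ub = ub)
}

# One restricted solve (fixed submode) with multistart. Every start gets a
# short screening run of the augmented Lagrangian; the most promising
# candidates are then driven to full convergence and polished.
.solve_submode <- function(params, env, opts, submode, n_polish = 3L) {
  ctx <- .design_ctx(params, env, submode)
  b <- .z_bounds(ctx)
  starts <- list(.default_start(ctx), .stress_start(ctx))
  n_protected <- 2L
  if (!is.null(opts$warm_start)) {
    ws <- opts$warm_start
    zw <- if (inherits(ws, "cell_state")) .state_to_z(ws, ctx) else ws
    starts <- c(list(zw), starts)
    n_protected <- 3L
  }
  n_rand <- max(0, opts$multistart_count - length(starts))
  if (n_rand > 0)
    starts <- c(starts, replicate(n_rand, .random_start(ctx),
                                  simplify = FALSE))
  feas_target <- min(opts$feasibility_tolerance * 0.1, 1e-9)
  diag <- list(starts_used = length(starts), fn_evals = 0L)

  screened <- lapply(seq_along(starts), function(i) {
    # a warm start is near-optimal already: keep the penalty stiff so the
    # first unconstrained excursion cannot leave its basin
    r0 <- if (i == 1L && n_protected == 3L) 1e4 else 100
    res <- tryCatch(.auglag(starts[[i]], ctx, b$lb, b$ub, feas_tol = 1e-6,
                            outer_max = 5, inner_maxit = 60, rho0 = r0),
                    error = function(e) NULL)
    if (is.null(res) || !res$ev$valid) return(NULL)
    diag$fn_evals <<- diag$fn_evals + res$fn_evals
    viol <- max(c(abs(res$ev$eq), pmax(0, -res$ev$ineq), 0))
    list(z = res$z, score = res$ev$mu_day - 1e4 * max(0, viol - 1e-6),
         rho0 = r0,
         protected = i <= n_protected)  # warm/heuristic starts always polished
  })
  screened <- Filter(Negate(is.null), screened)
  if (!length(screened))
    return(list(best = NULL, ctx = ctx, diagnostics = diag))
  ord <- order(vapply(screened, `[[`, numeric(1), "score"),
               decreasing = TRUE)
  protected <- which(vapply(screened, `[[`, logical(1), "protected"))
  queue <- unique(c(ord[seq_len(min(n_polish, length(ord)))], protected,
                    ord))

  best <- NULL
  polished <- 0L
  for (idx in queue) {
    # stop once enough candidates are polished and one of them is feasible
    if (polished >= max(n_polish, length(protected)) &&
        !is.null(best) && best$feasible) break
    cand0 <- screened[[idx]]
    res <- tryCatch(.auglag(cand0$z, ctx, b$lb, b$ub,
                            feas_tol = feas_target,
                            outer_max = 30, inner_maxit = 250,
                            rho0 = cand0$rho0),
                    error = function(e) NULL)
    polished <- polished + 1L
    if (is.null(res) || !res$ev$valid) next
    diag$fn_evals <- diag$fn_evals + res$fn_evals
    z <- .polish_balances(res$z, ctx)
    z <- .crowd_beta(z, ctx)
    ev <- .eval_design(z, ctx)
    if (!ev$valid) { z <- res$z; ev <- res$ev }
    viol <- max(c(abs(ev$eq), pmax(0, -ev$ineq), 0))
    feasible <- viol <= opts$feasibility_tolerance
    cand <- list(z = z, ev = ev, viol = viol, feasible = feasible,
                 iterations = res$iterations, converged = res$converged)
    if (is.null(best)) best <- cand
    else if (feasible && (!best$feasible || ev$mu_day > best$ev$mu_day))
      best <- cand
    else if (!best$feasible && viol < best$viol) best <- cand
  }
  diag$polished <- polished
  list(best = best, ctx = ctx, diagnostics = diag)
}

.package_result <- function(sub, params, env, opts, submode) {
  best <- sub$best
  if (is.null(best)) {
    return(structure(list(status = "failed", state = NULL, fluxes = NULL,
                          residual_report = NULL, mu_per_day = 0,
                          active_respiratory_pathway = "none",
                          mode = submode, opts = opts, params = params,
                          env = env, diagnostics = sub$diagnostics,
                          tie = FALSE),
                     class = "optimal_cell"))
  }
  state <- .design_state(best$z, sub$ctx)
  fluxes <- compute_fluxes(state, params, env)
  report <- residual_report(state, params, env,
                            tol = opts$feasibility_tolerance)
  mu_day <- state$mu * 1440
  nonviable <- !best$feasible || mu_day < opts$mu_tolerance
  pw <- if (params$e_gl * fluxes$v_gl + params$e_ld * fluxes$v_ld <=
              1e-12 * fluxes$e_cost) "none"
  else if (params$e_gl * fluxes$v_gl >= params$e_ld * fluxes$v_ld)
    "glycolysis" else "lipid_degradation"
  structure(list(
    status = if (nonviable) "nonviable" else "optimal",
    state = state, fluxes = fluxes, residual_report = report,
    mu_per_day = if (nonviable) 0 else mu_day,
    active_respiratory_pathway = if (nonviable) "none" else pw,
    mode = submode, opts = opts, params = params, env = env,
    diagnostics = c(sub$diagnostics,
                    list(iterations = best$iterations,
                         violation = best$viol,
                         converged = best$converged)),
    tie = FALSE),
    class = "optimal_cell")
}

#' Solve for the growth-optimal cell
#'
#' Maximizes steady-state growth rate over proteome allocation, lipid-flux
#' splits, internal metabolite levels and cell geometry, subject to the mass
#' balances, the energy constraints (daytime photochemistry and dark
#' respiration), the membrane transporter-to-lipid bound, the stored-lipid
#' bounds and the space/density constraints. In `"free"` mode the problem is
#' solved three times (glycolysis-only, lipid-degradation-only,
#' unrestricted) and the best feasible solution is returned, which resolves
#' the discrete choice of dark respiratory pathway.
#'
#' @param params A `phyto_params`.
#' @param env A `phyto_env`.
#' @param opts A [solve_options()] list.
#' @return An object of class `optimal_cell` with fields `status`
#'   (`"optimal"`, `"nonviable"` or `"failed"`), `state`, `fluxes`,
#'   `residual_report`, `mu_per_day`, `active_respiratory_pathway`, `tie`
#'   (both pathways within tolerance) and solver diagnostics.
#' @examples
#' \donttest{
#' fit <- solve_optimal_cell(phyto_params(), phyto_env(20),
#'                           solve_options(multistart_count = 2))
#' fit$mu_per_day
#' }
#' @export
solve_optimal_cell <- function(params, env, opts = solve_options()) {
  stopifnot(inherits(params, "phyto_params"), inherits(env, "phyto_env"))
  if (env$I <= 0) {
    return(structure(list(status = "nonviable", state = NULL, fluxes = NULL,
                          residual_report = NULL, mu_per_day = 0,
                          active_respiratory_pathway = "none",
                          mode = opts$mode, opts = opts, params = params,
                          env = env, diagnostics = list(reason = "no light"),
                          tie = FALSE),
                     class = "optimal_cell"))
  }
  solve_one <- function(opts, submode) {
    sub <- .solve_submode(params, env, opts, submode)
    ok <- !is.null(sub$best) && sub$best$feasible
    if (!ok) {  # escalate once: fresh start pool, doubled
      opts2 <- opts
      opts2$multistart_count <- opts$multistart_count * 2L
      set.seed(opts$random_seed + 1000L)
      sub2 <- .solve_submode(params, env, opts2, submode)
      ok2 <- !is.null(sub2$best) && sub2$best$feasible
      if (ok2) sub <- sub2
    }
    sub
  }
  .with_seed(opts$random_seed, {
    if (opts$mode != "free") {
      sub <- solve_one(opts, opts$mode)
      return(.package_result(sub, params, env, opts, opts$mode))
    }
    submodes <- if (params$lipids_enabled)
      c("glycolysis_only", "lipid_only", "unrestricted") else "glycolysis_only"
    results <- lapply(submodes, function(sm) {
      sub <- solve_one(opts, sm)
      .package_result(sub, params, env, opts, sm)
    })
    mus <- vapply(results, function(r)
      if (r$status == "optimal") r$mu_per_day else -Inf, numeric(1))
    if (all(!is.finite(mus))) {
      best <- results[[1]]
      best$mode <- "free"
      return(best)
    }
    best <- results[[which.max(mus)]]
    best$mode <- "free"
    # tie between the two restricted pathways marks the metabolic switch
    if (length(results) >= 2) {
      two <- sort(mus[1:2], decreasing = TRUE)
      if (is.finite(two[2]) && (two[1] - two[2]) < opts$mu_tolerance)
        best$tie <- TRUE
    }
    best
  })
}

#' Multistart convenience wrapper
#'
#' Runs [solve_optimal_cell()] with the given number of random starts (plus
#' the warm start, when provided) and returns the feasible result with the
#' largest growth rate; deterministic given `opts$random_seed`.
#'
#' @inheritParams solve_optimal_cell
#' @return An `optimal_cell` object.
#' @export
multistart_solve <- function(params, env, opts = solve_options()) {
  solve_optimal_cell(params, env, opts)
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Independently verify a solver result
#'
#' Recomputes every residual and slack through the public model functions
#' (not the solver's internal algebra) and re-asserts the structural
#' invariants: proteome normalization, lipid-split normalization,
#' damage-repair consistency and non-negative energy slacks.
#'
#' @param result An `optimal_cell` (or a list with a `state` field).
#' @param params A `phyto_params`.
#' @param env A `phyto_env`.
#' @param tol Feasibility tolerance.
#' @return List with `pass` (logical) and `failures` (character), plus the
#'   recomputed `residual_report`.
#' @export
verify_solution <- function(result, params, env, tol = 1e-8) {
  state <- if (inherits(result, "cell_state")) result else result$state
  if (is.null(state)) return(list(pass = FALSE, failures = "no state"))
  report <- residual_report(state, params, env, tol = tol)
  failures <- character(0)
  bad_eq <- names(report$equalities_rel)[abs(report$equalities_rel) > tol]
  if (length(bad_eq))
    failures <- c(failures, paste0("equality residual too large: ", bad_eq))
  bad <- names(report$slacks)[report$slacks < -tol]
  if (length(bad))
    failures <- c(failures, paste0("negative slack: ", bad))
  if (abs(sum(state$phi) - (1 - params$phi_other)) > tol)
    failures <- c(failures, "proteome normalization (sum phi)")
  if (abs(sum(state$alpha) - 1) > tol)
    failures <- c(failures, "lipid split normalization (sum alpha)")
  # damage-repair consistency through the closed-form fraction
  if (params$damage_enabled && state$p_p + state$p_dp > 0 &&
      state$p["re"] > 0) {
    frac <- damaged_fraction_qss(state, params, env$T)
    obs <- state$p_dp / (state$p_p + state$p_dp)
    if (abs(frac - obs) > tol * max(1, frac))
      failures <- c(failures, "quasi-steady-state damaged fraction")
  }
  list(pass = length(failures) == 0, failures = failures, report = report)
}

#' Exhaustive grid search for the reduced three-pool model
#'
#' Brute-force scan of the reduced configuration ([toy_params()]): proteome
#' fractions for photosystems and transporters on a regular grid (ribosomes
#' take the remainder), volume-to-surface ratio on a log grid, and the
#' internal-N saturation solved from the nitrogen balance by bisection at
#' every node. Returns the feasible node with the largest growth rate.
#' Written as an independent check on the nonlinear solver.
#'
#' @param params A reduced `phyto_params` (see [toy_params()]).
#' @param env A `phyto_env`.
#' @param phi_step Grid resolution on the proteome fractions.
#' @param beta_grid Log-spaced grid for the volume-to-surface ratio (um).
#' @param slack_tol Tolerance on constraint violation at grid nodes.
#' @return List with `mu_day`, `phi` (named), `beta`, `f_n`, and the full
#'   grid of evaluated nodes (`table`).
#' @export
grid_search_toy <- function(params, env,
                            phi_step = 0.01,
                            beta_grid = exp(seq(log(0.01), log(10),
                                                length.out = 40)),
                            slack_tol = 0) {
  stopifnot(!params$lipids_enabled, !params$damage_enabled,
            !params$track_carbon)
  P <- params
  rt <- rates_at(P, env$T)
  k <- rt$k
  f_I <- env$I / (env$I + P$K_p)
  budget <- 1 - P$phi_other
  phis <- seq(phi_step, budget - 2 * phi_step, by = phi_step)
  best <- list(mu_day = -Inf)
  rows <- list(); ri <- 0L
  for (phi_tr in phis) {
    for (phi_p in phis) {
      phi_ri <- budget - phi_tr - phi_p
      if (phi_ri < phi_step - 1e-12) next
      eta_aan <- P$eta_aac * (phi_tr * P$q[["tr"]] + phi_p * P$q[["p"]] +
                                phi_ri * P$q[["ri"]] +
                                P$phi_other * P$q_other)
      for (beta in beta_grid) {
        # nitrogen balance in f_n (everything per unit of v_ri, with
        # v_ri = eta_tr mu / (phi_tr s_tr beta) from the surface identity):
        #   k_tr phi_tr/(eta_tr mu) = eta_aan + c_in phi_tr s_tr beta/eta_tr
        g <- function(f_n) {
          mu <- k[["ri"]] * phi_ri * f_n / P$eta[["ri"]]
          c_in <- P$K_in * f_n / (1 - f_n)
          k[["tr"]] * phi_tr / (P$eta[["tr"]] * mu) - eta_aan -
            c_in * phi_tr * P$s_tr * beta / P$eta[["tr"]]
        }
        lo <- 1e-8; hi <- 1 - 1e-8
        if (g(lo) < 0 || g(hi) > 0) next
        f_n <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
        mu <- k[["ri"]] * phi_ri * f_n / P$eta[["ri"]]
        v_ri <- P$eta[["tr"]] * mu / (phi_tr * P$s_tr * beta)
        inv_mu <- v_ri / mu
        p_tr <- phi_tr * inv_mu / P$eta[["tr"]]
        p_ri <- phi_ri * inv_mu / P$eta[["ri"]]
        ps_tot <- phi_p * inv_mu / P$eta[["p"]]
        v_tr <- k[["tr"]] * p_tr
        v_p <- k[["p"]] * ps_tot * f_I
        e_cost <- P$e_ri * v_ri + P$e_tr * v_tr
        day_slack <- P$e_p * v_p - e_cost
        vf <- 1 - ps_tot * P$V_p
        c_in <- P$K_in * f_n / (1 - f_n)
        dens <- (if ("tr" %in% P$density_pools) p_tr * P$eta[["tr"]] else 0) *
          P$eta_aa +
          (if ("ri" %in% P$density_pools) p_ri * P$eta[["ri"]] else 0) *
          P$eta_aa + c_in * P$w_in
        dens_slack <- P$D_max * vf - dens
        feas <- day_slack >= -slack_tol * abs(P$e_p * v_p) &&
          vf > 0 && dens_slack >= -slack_tol * P$D_max
        ri <- ri + 1L
        rows[[ri]] <- c(phi_tr = phi_tr, phi_p = phi_p, phi_ri = phi_ri,
                        beta = beta, f_n = f_n, mu_day = mu * 1440,
                        feasible = as.numeric(feas))
        if (feas && mu * 1440 > best$mu_day)
          best <- list(mu_day = mu * 1440,
                       phi = c(tr = phi_tr, p = phi_p, ri = phi_ri),
                       beta = beta, f_n = f_n)
      }
    }
  }
  best$table <- if (ri) as.data.frame(do.call(rbind, rows)) else NULL
  best
}
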