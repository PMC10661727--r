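## Structural, covariate and variability model for serum total IgG:
## two-compartment disposition, first-order subcutaneous absorption with
## formulation-specific bioavailability, zero-order endogenous synthesis into
## the central compartment, allometric fat-free-mass scaling, lognormal
## inter-individual variability. Linear kinetics allow the multi-dose solution
## to be assembled analytically by superposition.

#' Population-level PK parameters
#'
#' Reference-scale parameters of the serum IgG model together with their
#' variability terms. Disposition parameters are expressed at a reference
#' fat-free mass `lbm_ref`; clearance terms (`cl`, `q`, `ksyn`) scale as
#' `(lbm/lbm_ref)^theta_cl` and volumes (`vc`, `vp`) as
#' `(lbm/lbm_ref)^theta_v`. Omegas are standard deviations of the associated
#' log-normal random effects.
#'
#' @param cl_ref Clearance at `lbm_ref`, L/day.
#' @param vc_ref Central volume, L.
#' @param q_ref Inter-compartmental clearance, L/day.
#' @param vp_ref Peripheral volume, L.
#' @param ka_scig,ka_fscig First-order absorption rate constants, 1/day.
#' @param f_scig,f_fscig Subcutaneous bioavailability fractions in (0, 1].
#' @param ksyn_ref Zero-order endogenous IgG synthesis, g/day; the endogenous
#'   baseline is `ksyn/cl` (about 2 g/L at reference).
#' @param lbm_ref Reference fat-free mass, kg.
#' @param theta_cl,theta_v Allometric exponents for clearances and volumes.
#' @param omega_cl,omega_vc,omega_ka,omega_ksyn Lognormal inter-individual
#'   variability SDs (>= 0).
#' @return An object of class `igsim_parameters` (a validated named list).
#' @export
pop_parameters <- function(cl_ref = 0.10, vc_ref = 3.0, q_ref = 0.3,
                           vp_ref = 3.0, ka_scig = 0.25, ka_fscig = 0.20,
                           f_scig = 0.70, f_fscig = 0.73, ksyn_ref = 0.20,
                           lbm_ref = 56, theta_cl = 0.88, theta_v = 1.0,
                           omega_cl = 0.25, omega_vc = 0.25,
                           omega_ka = 0.30, omega_ksyn = 0.30) {
  p <- list(cl_ref = cl_ref, vc_ref = vc_ref, q_ref = q_ref, vp_ref = vp_ref,
            ka_scig = ka_scig, ka_fscig = ka_fscig, f_scig = f_scig,
            f_fscig = f_fscig, ksyn_ref = ksyn_ref, lbm_ref = lbm_ref,
            theta_cl = theta_cl, theta_v = theta_v, omega_cl = omega_cl,
            omega_vc = omega_vc, omega_ka = omega_ka, omega_ksyn = omega_ksyn)
  for (nm in c("cl_ref", "vc_ref", "q_ref", "vp_ref", "ka_scig", "ka_fscig",
               "ksyn_ref", "lbm_ref")) {
    assert_number(p[[nm]], nm, positive = TRUE)
  }
  for (nm in c("f_scig", "f_fscig")) {
    if (p[[nm]] <= 0 || p[[nm]] > 1) stopf("`%s` must lie in (0, 1]", nm)
  }
  for (nm in c("omega_cl", "omega_vc", "omega_ka", "omega_ksyn")) {
    if (p[[nm]] < 0) stopf("`%s` must be >= 0", nm)
  }
  structure(p, class = "igsim_parameters")
}

#' @export
print.igsim_parameters <- function(x, ...) {
  cat("<igsim_parameters>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 11), " ", signif(v, 5), "\n"), sep = "")
  invisible(x)
}

#' Nominal starting parameter set
#'
#' The documented starting point for [calibrate_defaults()]: plausible IgG
#' kinetics (terminal half-life of a few weeks, endogenous baseline about
#' 2 g/L) prior to anchoring against published stratum-level trough
#' summaries. For simulation use the calibrated packaged set,
#' [default_parameters()].
#'
#' @return An `igsim_parameters` object.
#' @export
reference_parameters <- function() pop_parameters()

#' Realize individual parameters from covariates and random effects
#'
#' Applies allometric fat-free-mass scaling and lognormal inter-individual
#' variability: `cl = cl_ref * (lbm/lbm_ref)^theta_cl * exp(omega_cl * eta1)`,
#' `vc = vc_ref * (lbm/lbm_ref)^theta_v * exp(omega_vc * eta2)`; `q` and `vp`
#' scale with the same exponents as `cl` and `vc` without added variability;
#' `ka = ka_formulation * exp(omega_ka * eta3)` and
#' `ksyn = ksyn_ref * (lbm/lbm_ref)^theta_cl * exp(omega_ksyn * eta4)`.
#'
#' @param pop An [pop_parameters()] object.
#' @param lbm Subject fat-free mass in kg (> 0), or an `igsim_subjects` row.
#' @param formulation `"scig"` or `"fscig"` (selects `ka` and `f`).
#' @param etas Numeric vector of four standard-normal draws
#'   `(eta_cl, eta_vc, eta_ka, eta_ksyn)`; defaults to zeros.
#' @return An object of class `igsim_individual` with elements
#'   `cl, vc, q, vp, ka, f, ksyn`.
#' @export
individualize <- function(pop, lbm, formulation = c("scig", "fscig"),
                          etas = c(0, 0, 0, 0)) {
  formulation <- match.arg(formulation)
  if (is.data.frame(lbm)) lbm <- lbm$lbm_kg
  assert_number(lbm, "lbm", positive = TRUE)
  stopifnot(length(etas) == 4)
  r <- lbm / pop$lbm_ref
  structure(list(
    cl = pop$cl_ref * r^pop$theta_cl * exp(pop$omega_cl * etas[1]),
    vc = pop$vc_ref * r^pop$theta_v * exp(pop$omega_vc * etas[2]),
    q = pop$q_ref * r^pop$theta_cl,
    vp = pop$vp_ref * r^pop$theta_v,
    ka = pop[[paste0("ka_", formulation)]] * exp(pop$omega_ka * etas[3]),
    f = pop[[paste0("f_", formulation)]],
    ksyn = pop$ksyn_ref * r^pop$theta_cl * exp(pop$omega_ksyn * etas[4])
  ), class = "igsim_individual")
}

#' Endogenous steady-state IgG concentration
#'
#' Baseline produced by zero-order synthesis balanced by first-order
#' clearance: `ksyn / cl` in g/L.
#'
#' @param ind An [individualize()]d parameter set (or any list with `ksyn`,
#'   `cl`).
#' @return Concentration in g/L.
#' @export
endogenous_css <- function(ind) {
  assert_number(ind$cl, "cl", positive = TRUE)
  ind$ksyn / ind$cl
}

## Disposition micro-constants and eigenvalues; perturbs ka away from a
## removable singularity when it collides with an eigenvalue.
disposition <- function(ind) {
  k10 <- ind$cl / ind$vc
  k12 <- ind$q / ind$vc
  k21 <- ind$q / ind$vp
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  l1 <- (s + disc) / 2
  l2 <- (s - disc) / 2
  ka <- ind$ka
  if (abs(ka - l1) / l1 < 1e-9 || abs(ka - l2) / l2 < 1e-9) {
    ka <- ka * (1 + 1e-8)
  }
  list(k10 = k10, k12 = k12, k21 = k21, l1 = l1, l2 = l2, ka = ka)
}

#' Unit subcutaneous dose response
#'
#' Central-compartment concentration at time `t` after a unit (1 g)
#' subcutaneous dose at `t = 0`: the tri-exponential analytic solution of the
#' two-compartment model with first-order absorption,
#' `f*ka/vc * sum_j A_j exp(-lambda_j t)` over the two disposition
#' eigenvalues and `ka`. Equals 0 at `t = 0`; its integral over `[0, Inf)` is
#' `f/cl`.
#'
#' @param ind An [individualize()]d parameter set.
#' @param t Time(s) after the dose in days (>= 0).
#' @return Concentration in g/L per gram dosed (vectorized over `t`).
#' @export
sc_unit_response <- function(ind, t) {
  assert_number(t, "t")
  if (any(t < 0)) stopf("`t` must be >= 0")
  d <- disposition(ind)
  a1 <- (d$k21 - d$l1) / ((d$ka - d$l1) * (d$l2 - d$l1))
  a2 <- (d$k21 - d$l2) / ((d$ka - d$l2) * (d$l1 - d$l2))
  a3 <- (d$k21 - d$ka) / ((d$l1 - d$ka) * (d$l2 - d$ka))
  resp <- ind$f * d$ka / ind$vc *
    (a1 * exp(-d$l1 * t) + a2 * exp(-d$l2 * t) + a3 * exp(-d$ka * t))
  pmax(resp, 0)
}

#' Decay of the switch-time IgG excess
#'
#' Concentration arising from the IgG present at the switch from IVIG in
#' excess of the endogenous baseline. The start is taken as distribution
#' pseudo-equilibrium (equal central and peripheral concentrations
#' `c0_excess`, depot empty), consistent with a trough on stable IVIG, and
#' evolves under two-compartment disposition; the value at `t = 0` is
#' `c0_excess` and the curve is monotone non-increasing.
#'
#' @param ind An [individualize()]d parameter set.
#' @param c0_excess Initial excess concentration in g/L (>= 0).
#' @param t Time(s) in days.
#' @return Concentration in g/L (vectorized over `t`).
#' @export
initial_excess_response <- function(ind, c0_excess, t) {
  assert_number(c0_excess, "c0_excess")
  if (c0_excess < 0) stopf("`c0_excess` must be >= 0")
  if (c0_excess == 0) return(numeric(length(t)) * t^0) # 0, keeps NA semantics
  d <- disposition(ind)
  ac0 <- c0_excess * ind$vc
  ap0 <- c0_excess * ind$vp
  c1 <- ((d$l2 - (d$k10 + d$k12)) * ac0 + d$k21 * ap0) / (d$l2 - d$l1)
  c2 <- ac0 - c1
  (c1 * exp(-d$l1 * t) + c2 * exp(-d$l2 * t)) / ind$vc
}

## Superposition of an equally spaced dose train, evaluated in closed form:
## sum over doses d = 0..k(t) of exp(-lambda (t - t0 - d tau)) equals
## exp(-lambda s) expm1(lambda tau (k+1)) / expm1(lambda tau), s = t - t0.
## Stable for small lambda via expm1.
geo_exp_sum <- function(lambda, s, k, tau) {
  out <- numeric(length(s))
  on <- k >= 0
  out[on] <- exp(-lambda * s[on]) *
    expm1(lambda * tau * (k[on] + 1)) / expm1(lambda * tau)
  out
}

## Indices of the last dose at or before each time point.
dose_index <- function(t, t0, tau, n_dose) {
  k <- floor((t - t0) / tau + 1e-12)
  pmin(pmax(k, -1), n_dose - 1)
}

n_doses <- function(regimen) {
  ceiling((regimen$horizon - regimen$first_dose_time) / regimen$interval - 1e-12)
}

#' Simulate a single-subject concentration-time profile
#'
#' Assembles the total serum IgG profile under repeated subcutaneous dosing by
#' superposition: the exogenous component is the closed-form sum of
#' single-dose responses over all past doses plus the decaying switch-time
#' excess ([initial_excess_response()]); the endogenous component is the
#' constant baseline [endogenous_css()].
#'
#' @param ind An [individualize()]d parameter set.
#' @param regimen An [regimen()] object (interval, horizon, first dose time).
#' @param dose_g Dose per administration in grams.
#' @param c0 Total IgG concentration at the switch, g/L; must be at or above
#'   the subject's endogenous baseline.
#' @param tgrid Strictly increasing time grid in days within
#'   `[0, regimen$horizon]`.
#' @return A data.frame of class `igsim_profile` with columns `times`,
#'   `conc_total`, `conc_endogenous`, `conc_exogenous`.
#' @export
simulate_profile <- function(ind, regimen, dose_g, c0, tgrid) {
  assert_number(dose_g, "dose_g")
  if (dose_g < 0) stopf("`dose_g` must be >= 0")
  if (any(diff(tgrid) <= 0)) stopf("`tgrid` must be strictly increasing")
  if (min(tgrid) < 0 || max(tgrid) > regimen$horizon + 1e-9) {
    stopf("`tgrid` must lie within [0, horizon]")
  }
  css <- endogenous_css(ind)
  if (c0 < css - 1e-9) {
    stopf("starting concentration c0 = %.3g g/L is below the endogenous baseline %.3g g/L",
          c0, css)
  }
  d <- disposition(ind)
  nd <- n_doses(regimen)
  k <- dose_index(tgrid, regimen$first_dose_time, regimen$interval, nd)
  s <- tgrid - regimen$first_dose_time
  a1 <- (d$k21 - d$l1) / ((d$ka - d$l1) * (d$l2 - d$l1))
  a2 <- (d$k21 - d$l2) / ((d$ka - d$l2) * (d$l1 - d$l2))
  a3 <- (d$k21 - d$ka) / ((d$l1 - d$ka) * (d$l2 - d$ka))
  scale <- ind$f * d$ka * dose_g / ind$vc
  exog <- scale * (a1 * geo_exp_sum(d$l1, s, k, regimen$interval) +
                   a2 * geo_exp_sum(d$l2, s, k, regimen$interval) +
                   a3 * geo_exp_sum(d$ka, s, k, regimen$interval))
  exog <- pmax(exog, 0) + initial_excess_response(ind, max(c0 - css, 0), tgrid)
  structure(
    data.frame(times = tgrid, conc_total = css + exog,
               conc_endogenous = css, conc_exogenous = exog),
    class = c("igsim_profile", "data.frame")
  )
}

## Vectorized cohort simulator: one row per subject, one column per grid
## point. Parameter arguments are equal-length vectors; the dose-train
## geometry (k, s) is shared across subjects.
simulate_cohort_matrix <- function(cl, vc, q, vp, ka, f, ksyn, dose_g,
                                   c0, regimen, tgrid) {
  n <- length(cl)
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  ssum <- k10 + k12 + k21
  disc <- sqrt(ssum^2 - 4 * k10 * k21)
  l1 <- (ssum + disc) / 2
  l2 <- (ssum - disc) / 2
  clash <- (abs(ka - l1) / l1 < 1e-9) | (abs(ka - l2) / l2 < 1e-9)
  ka[clash] <- ka[clash] * (1 + 1e-8)
  css <- ksyn / cl
  low <- c0 < css - 1e-9
  if (any(low)) {
    stopf("starting concentration below endogenous baseline for subject(s): %s",
          paste(which(low), collapse = ", "))
  }
  nd <- n_doses(regimen)
  tau <- regimen$interval
  s <- tgrid - regimen$first_dose_time
  k <- dose_index(tgrid, regimen$first_dose_time, tau, nd)
  a1 <- (k21 - l1) / ((ka - l1) * (l2 - l1))
  a2 <- (k21 - l2) / ((ka - l2) * (l1 - l2))
  a3 <- (k21 - ka) / ((l1 - ka) * (l2 - ka))
  scale <- f * ka * dose_g / vc
  c0ex <- c0 - css
  b1 <- ((l2 - (k10 + k12)) * c0ex * vc + k21 * c0ex * vp) / (l2 - l1) / vc
  b2 <- c0ex - b1
  conc <- matrix(0, n, length(tgrid))
  for (i in seq_len(n)) {
    exog <- scale[i] * (a1[i] * geo_exp_sum(l1[i], s, k, tau) +
                        a2[i] * geo_exp_sum(l2[i], s, k, tau) +
                        a3[i] * geo_exp_sum(ka[i], s, k, tau))
    conc[i, ] <- css[i] + pmax(exog, 0) +
      b1[i] * exp(-l1[i] * tgrid) + b2[i] * exp(-l2[i] * tgrid)
  }
  list(conc = conc, css = css)
}
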