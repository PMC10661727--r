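# Brute-force ODE oracle (deSolve) for the depot/central/peripheral system
# with zero-order endogenous synthesis, plus helpers to build arbitrary
# individual parameter sets. Independent of the analytic superposition path.

make_ind <- function(cl, vc, q, vp, ka, f, ksyn) {
  structure(list(cl = cl, vc = vc, q = q, vp = vp, ka = ka, f = f, ksyn = ksyn),
            class = "igsim_individual")
}

rand_ind <- function() {
  make_ind(
    cl = stats::runif(1, 0.05, 0.3), vc = stats::runif(1, 2, 5),
    q = stats::runif(1, 0.1, 0.6), vp = stats::runif(1, 2, 6),
    ka = stats::runif(1, 0.1, 0.5), f = stats::runif(1, 0.5, 1),
    ksyn = stats::runif(1, 0.1, 0.4)
  )
}

dose_times <- function(regimen) {
  dt <- seq(regimen$first_dose_time, regimen$horizon, by = regimen$interval)
  dt[dt < regimen$horizon - 1e-9]
}

# Numerical integration of the full ODE system; returns concentrations at
# tgrid plus the final depot amount and cumulative absorbed mass.
ode_oracle <- function(ind, regimen, dose_g, c0, tgrid) {
  rhs <- function(t, y, p) {
    with(as.list(c(y, p)), {
      list(c(
        depot = -ka * depot,
        ac = ka * depot + ksyn - (cl / vc + q / vc) * ac + (q / vp) * ap,
        ap = (q / vc) * ac - (q / vp) * ap,
        absorbed = ka * depot
      ))
    })
  }
  y0 <- c(depot = 0, ac = c0 * ind$vc, ap = c0 * ind$vp, absorbed = 0)
  dt <- dose_times(regimen)
  ev <- data.frame(var = "depot", time = dt, value = ind$f * dose_g,
                   method = "add")
  times <- sort(unique(c(tgrid, dt)))
  out <- deSolve::ode(y0, times, rhs, unlist(ind), events = list(data = ev),
                      rtol = 1e-10, atol = 1e-10, maxsteps = 50000)
  i <- match(round(tgrid, 9), round(out[, "time"], 9))
  list(conc = unname(out[i, "ac"]) / ind$vc,
       depot_final = unname(out[nrow(out), "depot"]),
       absorbed_final = unname(out[nrow(out), "absorbed"]),
       n_doses = length(dt))
}
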