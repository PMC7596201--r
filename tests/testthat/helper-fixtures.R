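# Shared fixtures: a 26-frame schedule and a smooth analytic plasma input
# (tri-exponential decay after a 1-min linear rise), built once per run.

fixture_schedule <- build_frame_schedule(pbr28_frame_spec())

# closed-form test input: rise to peak at 1 min, tri-exponential decay
fixture_cp_fn <- function(t) {
  t <- pmax(t, 0)
  pk <- 60
  dec <- pk * (0.7 * exp(-3 * (t - 1)) + 0.2 * exp(-0.3 * (t - 1)) +
                 0.1 * exp(-0.012 * (t - 1)))
  ifelse(t < 1, pk * t, dec)
}
fixture_cwb_fn <- function(t) fixture_cp_fn(t) / 1.3

fixture_input <- plasma_input_from_functions(fixture_cp_fn, fixture_cwb_fn)

# frame-averaged oracle via deSolve adaptive integration (tissue states +
# vascular accumulator), independent of the analytic-convolution path
ode_oracle_tac <- function(params, cp_fn, cwb_fn, schedule,
                           blood_weighted = TRUE) {
  rhs <- function(t, y, parms) {
    cp <- cp_fn(t)
    list(c(params$K1 * cp - (params$k2 + params$k3) * y[1] + params$k4 * y[2],
           params$k3 * y[1] - params$k4 * y[2],
           (if (is.na(params$Kb)) 0 else params$Kb) * cp))
  }
  tt <- seq(0, attr(schedule, "t_end"), by = 1 / 120)
  sol <- deSolve::ode(c(0, 0, 0), tt, rhs, NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-12)
  cv <- sol[, 4]
  y <- if (blood_weighted)
    (1 - params$Vb) * (sol[, 2] + sol[, 3]) + params$Vb * (cwb_fn(tt) + cv)
  else
    (1 - params$Vb) * (sol[, 2] + sol[, 3]) + params$Vb * cwb_fn(tt) + cv
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * (1 / 120)))
  Fi <- stats::approxfun(tt, cum)
  (Fi(schedule$end) - Fi(schedule$start)) / schedule$duration
}
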