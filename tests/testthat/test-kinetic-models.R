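test_that("frame schedule layout matches its specification", {
  sched <- fixture_schedule
  expect_equal(nrow(sched), 26)
  expect_equal(attr(sched, "t_end"), 90)
  expect_equal(sched$start[1], 0)
  expect_equal(sched$end, cumsum(sched$duration))
  expect_equal(sched$duration[1:8], rep(0.25, 8))
  expect_equal(sched$duration[22:26], rep(10, 5))

  one <- build_frame_schedule(list(c(1, 1)))
  expect_equal(nrow(one), 1)
  expect_equal(one$mid, 0.5)
  expect_error(build_frame_schedule(list()), "empty")
})

test_that("frame weights are duration-decay weighted, mean one", {
  w <- tac_weights(fixture_schedule)
  expect_equal(mean(w), 1)
  raw <- fixture_schedule$duration * exp(-c11_lambda() * fixture_schedule$mid)
  expect_equal(w, raw / mean(raw))
  expect_equal(tac_weights(fixture_schedule, "uniform"), rep(1, 26))
})

test_that("no extraction means pure blood signal", {
  p <- kinetic_params(0, 0.1, 0.02, 0.01, 0.07)
  tac <- tcm2_forward(p, fixture_input, fixture_schedule)
  # frame-averaged Vb * Cwb computed independently by quadrature
  tt <- seq(0, 90, by = 1 / 240)
  y <- 0.07 * fixture_cwb_fn(tt)
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * (1 / 240)))
  Fi <- approxfun(tt, cum)
  oracle <- (Fi(fixture_schedule$end) - Fi(fixture_schedule$start)) /
    fixture_schedule$duration
  expect_equal(tac, oracle, tolerance = 1e-4)
})

test_that("k3 = 0 reduces to the one-tissue model (analytic convolution)", {
  # exponential plasma input: closed-form K1 exp(-k2 t) (*) Cp
  beta <- 0.1; K1 <- 0.12; k2 <- 0.35
  inp <- plasma_input_from_functions(function(t) exp(-beta * pmax(t, 0)),
                                     function(t) rep(0, length(t)))
  p <- kinetic_params(K1, k2, 0, 0.01, 0)
  tac <- tcm2_forward(p, inp, fixture_schedule)
  # frame-averaged closed form, integrated analytically
  ct <- function(t) K1 / (k2 - beta) * (exp(-beta * t) - exp(-k2 * t))
  Ict <- function(t) K1 / (k2 - beta) *
    ((1 - exp(-beta * t)) / beta - (1 - exp(-k2 * t)) / k2)
  oracle <- (Ict(fixture_schedule$end) - Ict(fixture_schedule$start)) /
    fixture_schedule$duration
  expect_equal(tac, oracle, tolerance = 1e-4)
})

test_that("forward model agrees with the adaptive ODE oracle", {
  p <- kinetic_params(0.1, 0.2, 0.05, 0.03, 0.05, 0.05)
  tac <- tcm2_1k_forward(p, fixture_input, fixture_schedule)
  oracle <- ode_oracle_tac(p, fixture_cp_fn, fixture_cwb_fn, fixture_schedule)
  expect_lt(max(abs(tac - oracle) / oracle), 1e-3)
})

test_that("2TCM-1K nests the 2TCM exactly at Kb = 0", {
  p <- kinetic_params(0.1, 0.2, 0.05, 0.03, 0.05, 0)
  a <- tcm2_1k_forward(p, fixture_input, fixture_schedule)
  b <- tcm2_forward(p, fixture_input, fixture_schedule)
  expect_lt(max(abs(a - b)), 1e-12)
})

test_that("constant input gives linear vascular accumulation", {
  cc <- 3
  inp <- plasma_input_from_functions(function(t) rep(cc, length(t)),
                                     function(t) rep(cc, length(t)))
  Vb <- 0.05; Kb <- 0.04
  p1 <- kinetic_params(0.1, 0.2, 0.05, 0.03, Vb, Kb)
  p0 <- kinetic_params(0.1, 0.2, 0.05, 0.03, Vb, 0)
  d <- tcm2_1k_forward(p1, inp, fixture_schedule) -
    tcm2_1k_forward(p0, inp, fixture_schedule)
  # Cvasc = Kb c t exactly; frame average of Vb Kb c t is Vb Kb c t_mid
  expect_equal(d, Vb * Kb * cc * fixture_schedule$mid, tolerance = 1e-10)
})

test_that("Kb difference equals the Vb-weighted running integral of Cp", {
  Vb <- 0.06; Kb <- 0.05
  p1 <- kinetic_params(0.1, 0.2, 0.05, 0.03, Vb, Kb)
  p0 <- kinetic_params(0.1, 0.2, 0.05, 0.03, Vb, 0)
  d <- tcm2_1k_forward(p1, fixture_input, fixture_schedule) -
    tcm2_1k_forward(p0, fixture_input, fixture_schedule)
  # quadrature oracle: frame-average of Vb*Kb*int_0^t Cp
  tt <- seq(0, 90, by = 1 / 240)
  icp <- c(0, cumsum((fixture_cp_fn(tt)[-1] + fixture_cp_fn(tt)[-length(tt)]) /
                       2 * (1 / 240)))
  y <- Vb * Kb * icp
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * (1 / 240)))
  Fi <- approxfun(tt, cum)
  oracle <- (Fi(fixture_schedule$end) - Fi(fixture_schedule$start)) /
    fixture_schedule$duration
  expect_lt(max(abs(d - oracle)), 1e-4 * max(oracle))
})

test_that("linearity: scaling the input scales the output exactly", {
  s <- 3.7
  inp2 <- plasma_input_from_functions(function(t) s * fixture_cp_fn(t),
                                      function(t) s * fixture_cwb_fn(t))
  p <- kinetic_params(0.1, 0.2, 0.05, 0.03, 0.05, 0.05)
  a <- tcm2_1k_forward(p, fixture_input, fixture_schedule)
  b <- tcm2_1k_forward(p, inp2, fixture_schedule)
  expect_equal(b, s * a, tolerance = 1e-12)
})

test_that("grid refinement changes frame values by less than 0.05%", {
  p <- kinetic_params(0.1, 0.2, 0.05, 0.03, 0.05, 0.05)
  a <- tcm2_1k_forward(p, fixture_input, fixture_schedule, dt = 1 / 60)
  b <- tcm2_1k_forward(p, fixture_input, fixture_schedule, dt = 1 / 120)
  expect_lt(max(abs(a - b) / b), 5e-4)
})

test_that("VT closed form, limits and monotonicity", {
  expect_equal(total_volume_of_distribution(
    kinetic_params(0.1, 0.05, 0.02, 0.01, 0)), 6.0)
  expect_equal(total_volume_of_distribution(
    kinetic_params(0.1, 0.2, 0, 0.01, 0)), 0.5)  # one-tissue limit K1/k2
  expect_error(total_volume_of_distribution(
    kinetic_params(0.1, 0, 0, 0.01, 0)), "undefined")
  set.seed(31)
  for (i in 1:10) {
    K1 <- runif(1, 0.02, 0.3); k2 <- runif(1, 0.05, 0.5)
    k3 <- runif(1, 0.01, 0.2); k4 <- runif(1, 0.01, 0.2)
    v0 <- total_volume_of_distribution(kinetic_params(K1, k2, k3, k4, 0))
    expect_gt(total_volume_of_distribution(
      kinetic_params(K1, k2, k3 * 1.3, k4, 0)), v0)
    expect_lt(total_volume_of_distribution(
      kinetic_params(K1, k2, k3, k4 * 1.3, 0)), v0)
  }
})

test_that("VT equals the steady-state tissue-to-plasma ratio", {
  p <- kinetic_params(0.1, 0.1, 0.04, 0.02, 0)
  vt <- total_volume_of_distribution(p)
  Tmax <- 50 / min(p$k2, p$k4)
  sched <- build_frame_schedule(list(c(1, Tmax - 10), c(1, 10)))
  cc <- 2
  inp <- plasma_input_from_functions(function(t) rep(cc, length(t)),
                                     function(t) rep(0, length(t)),
                                     t_end = Tmax, dt = 0.05)
  tac <- tcm2_forward(p, inp, sched, dt = 0.05)
  expect_equal(tac[2] / cc, vt, tolerance = 0.01)
})

test_that("parameter validation flags bad configurations", {
  expect_error(kinetic_params(-0.1, 0.2, 0, 0, 0.05), "non-negative")
  expect_error(kinetic_params(0.1, 0.2, 0, 0, 1), "Vb")
  expect_warning(kinetic_params(0.1, 0, 0.05, 0.01, 0.05), "non-identifiable")
  expect_error(tcm2_1k_forward(kinetic_params(0.1, 0.2, 0, 0.01, 0.05),
                               fixture_input, fixture_schedule), "Kb")
})

test_that("C++ kernel matches the R reference convolution", {
  g <- tspopet:::input_on_grid(fixture_input, 90, 1 / 60)
  p <- list(K1 = 0.1, k2 = 0.22, k3 = 0.04, k4 = 0.03, Vb = 0.06, Kb = 0.03)
  kern <- tspopet:::tcm2_kernel(p$K1, p$k2, p$k3, p$k4)
  ct <- kern$phi1 * tspopet:::conv_exp_plin(g$cp, 1 / 60, kern$a1) +
    kern$phi2 * tspopet:::conv_exp_plin(g$cp, 1 / 60, kern$a2)
  cv <- p$Kb * tspopet:::conv_exp_plin(g$cp, 1 / 60, 0)
  yR <- (1 - p$Vb) * ct + p$Vb * (g$cwb + cv)
  yC <- tspopet:::cpp_forward_signal(g$cp, g$cwb, 1 / 60, p$K1, p$k2, p$k3,
                                     p$k4, p$Vb, p$Kb, TRUE, TRUE)
  expect_lt(max(abs(yR - yC)), 1e-12)
})
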