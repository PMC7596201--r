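make_samples <- function(plasma_fn, pf_fn = function(t) rep(1, length(t)),
                         wb_fn = plasma_fn, fp = 0.02, noise = 0) {
  t_auto <- seq(0, 15, by = 0.25)
  t_man <- manual_sample_times()
  df <- rbind(
    data.frame(time_min = t_auto, whole_blood_kBq_ml = wb_fn(t_auto),
               plasma_kBq_ml = plasma_fn(t_auto), parent_fraction = NA_real_,
               source = "automated"),
    data.frame(time_min = t_man, whole_blood_kBq_ml = wb_fn(t_man),
               plasma_kBq_ml = plasma_fn(t_man),
               parent_fraction = pf_fn(t_man), source = "manual"))
  blood_samples(df, fp = fp)
}

test_that("blood_samples validates invariants", {
  df <- data.frame(time_min = c(1, 2), whole_blood_kBq_ml = c(1, 2),
                   source = "manual")
  expect_s3_class(blood_samples(df, fp = 0.02), "blood_samples")
  expect_error(blood_samples(df, fp = 0), "fp")
  expect_error(blood_samples(transform(df, whole_blood_kBq_ml = c(-1, 2)),
                             fp = 0.02), "negative")
  expect_error(blood_samples(df[c(2, 1), ], fp = 0.02), "increasing")
  dfp <- transform(df, parent_fraction = c(0.5, 1.2))
  expect_error(blood_samples(dfp, fp = 0.02), "parent_fraction")
})

test_that("parent fraction fit handles no-metabolism and recovers truth", {
  s1 <- make_samples(function(t) rep(1, length(t)))
  fit1 <- fit_parent_fraction(s1)
  expect_equal(unname(fit1$params["pf_inf"]), 1)
  expect_equal(fit1$fn(c(0, 10, 90)), rep(1, 3))

  truth <- c(pf_inf = 0.1, tau = 20, h = 2)
  pf_fn <- function(t) truth[1] + (1 - truth[1]) / (1 + (t / truth[2])^truth[3])
  s2 <- make_samples(function(t) rep(1, length(t)), pf_fn = pf_fn)
  fit2 <- fit_parent_fraction(s2)
  expect_lt(max(abs(fit2$params - truth) / truth), 0.01)
})

test_that("parent fraction fit matches a dense grid-search oracle", {
  tt <- c(5, 30, 90); pv <- c(0.9, 0.5, 0.2)
  df <- data.frame(time_min = tt, whole_blood_kBq_ml = 1,
                   plasma_kBq_ml = 1, parent_fraction = pv, source = "manual")
  s <- suppressWarnings(blood_samples(df, fp = 0.02))
  fit <- fit_parent_fraction(s)
  # independent oracle: exhaustive grid over (pf_inf, tau, h)
  grid <- expand.grid(pf_inf = seq(0, 0.5, by = 0.02),
                      tau = seq(5, 120, by = 2.5), h = seq(0.3, 4, by = 0.1))
  sse <- mapply(function(p0, tau, h) {
    sum((p0 + (1 - p0) / (1 + (tt / tau)^h) - pv)^2)
  }, grid$pf_inf, grid$tau, grid$h)
  best <- grid[which.min(sse), ]
  oracle <- function(t) best$pf_inf + (1 - best$pf_inf) / (1 + (t / best$tau)^best$h)
  expect_lt(max(abs(fit$fn(tt) - pv)), 0.05)
  expect_lt(max(abs(oracle(tt) - pv)), 0.05)   # oracle agrees with data too
  expect_lt(sum((fit$fn(tt) - pv)^2), min(sse) + 1e-6)  # fit at least as good
})

test_that("parent fraction fit is monotone and needs 3 points", {
  s <- make_samples(function(t) rep(1, length(t)),
                    pf_fn = function(t) 0.2 + 0.8 / (1 + (t / 15)^1.5))
  fit <- fit_parent_fraction(s)
  tt <- seq(0, 90, by = 0.5)
  expect_true(all(diff(fit$fn(tt)) <= 1e-12))
  expect_equal(fit$fn(0), 1)
  df <- data.frame(time_min = c(5, 30), whole_blood_kBq_ml = 1,
                   plasma_kBq_ml = 1, parent_fraction = c(0.9, 0.5),
                   source = "manual")
  expect_error(fit_parent_fraction(blood_samples(df, fp = 0.02)),
               "insufficient metabolite data")
})

test_that("constant plasma with unit and half parent fractions", {
  s <- make_samples(function(t) rep(1, length(t)))
  inp <- build_plasma_input(s, tail_fit = FALSE)
  tt <- seq(1, 90, by = 1)
  expect_equal(eval_cp(inp, tt), rep(1, length(tt)), tolerance = 1e-10)
  expect_equal(eval_cp(inp, 0), 0)  # Cp(0) = 0 by construction

  s2 <- make_samples(function(t) rep(2, length(t)))
  inp2 <- build_plasma_input(s2, pf = function(t) rep(0.5, length(t)),
                             tail_fit = FALSE)
  expect_equal(eval_cp(inp2, tt), rep(1, length(tt)), tolerance = 1e-10)
})

test_that("tri-exponential plasma sampled at manual times is recovered", {
  plasma_fn <- function(t) 40 * exp(-0.8 * t) + 15 * exp(-0.15 * t) +
    6 * exp(-0.01 * t)
  t_man <- manual_sample_times()
  df <- data.frame(time_min = t_man, whole_blood_kBq_ml = plasma_fn(t_man),
                   plasma_kBq_ml = plasma_fn(t_man),
                   parent_fraction = NA_real_, source = "manual")
  s <- blood_samples(df, fp = 0.02)
  inp <- build_plasma_input(s, pf = function(t) rep(1, length(t)),
                            tail_fit = TRUE)
  set.seed(404)
  tt <- runif(100, min(t_man), 90)
  rel <- abs(eval_cp(inp, tt) - plasma_fn(tt)) / plasma_fn(tt)
  expect_lt(max(rel), 0.02)
})

test_that("integral under the built input is preserved within 2%", {
  b <- gen_blood(12, blood_spec(noise_sd = 0))
  inp <- build_plasma_input(b$samples)
  tg <- inp$times
  area_built <- sum((inp$cp[-1] + inp$cp[-length(inp$cp)]) / 2 * diff(tg))
  cp_true <- b$truth$cp_fn(tg)
  area_true <- sum((cp_true[-1] + cp_true[-length(cp_true)]) / 2 * diff(tg))
  expect_lt(abs(area_built - area_true) / area_true, 0.02)
})

test_that("lowering the parent fraction never increases Cp, and fp is metadata", {
  plasma_fn <- function(t) 10 * exp(-0.1 * pmax(t, 0)) + 2
  s <- make_samples(plasma_fn)
  pf_hi <- function(t) 0.3 + 0.7 / (1 + (t / 20)^2)
  pf_lo <- function(t) 0.9 * pf_hi(t)
  i_hi <- build_plasma_input(s, pf = pf_hi, tail_fit = FALSE)
  i_lo <- build_plasma_input(s, pf = pf_lo, tail_fit = FALSE)
  expect_true(all(i_lo$cp <= i_hi$cp + 1e-12))

  s_fp <- make_samples(plasma_fn, fp = 0.014)
  i_fp <- build_plasma_input(s_fp, pf = pf_hi, tail_fit = FALSE)
  expect_identical(i_fp$cp, i_hi$cp)
  expect_equal(i_fp$fp, 0.014)
})

test_that("missing late samples triggers the tail warning", {
  df <- data.frame(time_min = c(1, 5, 20, 40),
                   whole_blood_kBq_ml = c(5, 4, 2, 1),
                   plasma_kBq_ml = c(5, 4, 2, 1),
                   parent_fraction = NA_real_, source = "manual")
  s <- blood_samples(df, fp = 0.02)
  expect_warning(build_plasma_input(s, pf = function(t) rep(1, length(t)),
                                    tail_fit = FALSE),
                 "tail extrapolation unreliable")
})
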