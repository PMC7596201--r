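#' Default parameter bounds for compartment-model fitting
#'
#' Physiologic ranges for second-generation TSPO tracers; all
#' configurable through the `bounds` argument of [fit_tac()].
#'
#' @return List with `lower` and `upper` named vectors over
#'   (K1, k2, k3, k4, Vb, Kb).
#' @export
default_fit_bounds <- function() {
  list(lower = c(K1 = 1e-6, k2 = 1e-6, k3 = 0, k4 = 1e-6, Vb = 0, Kb = 0),
       upper = c(K1 = 1, k2 = 2, k3 = 1, k4 = 1, Vb = 0.2, Kb = 1))
}

model_par_names <- function(model) {
  if (model == "2TCM-1K") c("K1", "k2", "k3", "k4", "Vb", "Kb")
  else c("K1", "k2", "k3", "k4", "Vb")
}

# Validation-free inner loop used by the optimizer; the public wrappers
# tcm2_forward / tcm2_1k_forward validate their inputs.
model_forward <- function(theta, model, input, schedule, dt, vascular_term) {
  p <- list(K1 = theta[[1]], k2 = theta[[2]], k3 = theta[[3]],
            k4 = theta[[4]], Vb = theta[[5]],
            Kb = if (length(theta) >= 6) theta[[6]] else NA_real_)
  g <- forward_grid(p, input, schedule, dt, vascular_term,
                    with_kb = model == "2TCM-1K")
  frame_average(g$times, g$y, schedule)
}

#' Fit a compartment model to a time-activity curve
#'
#' Weighted nonlinear least squares: minimizes
#' \eqn{\sum_i w_i (y_i - model_i)^2} over bounded parameters by
#' Levenberg-Marquardt, restarted from `n_starts` initial points (one
#' deterministic mid-range start plus seeded random draws within the
#' bounds); the lowest-WRSS converged solution wins.  The Akaike
#' information criterion is computed as
#' \eqn{AIC = n \ln(WRSS/n) + 2p}.
#'
#' @param tac A `time_activity_curve` (see [time_activity_curve()]).
#' @param input A `plasma_input`.
#' @param model `"2TCM"` or `"2TCM-1K"`.
#' @param n_starts Number of multi-start initial points (default 10).
#' @param seed Seed for the random starts (default 42); fitting is
#'   deterministic given the seed.
#' @param bounds Parameter bounds, as [default_fit_bounds()].
#' @param dt Forward-model grid step (min).
#' @param vascular_term Passed to the forward model.
#' @return Object of class `kinetic_fit`: `model`, `params`
#'   (`kinetic_params`), `VT`, `wrss`, `aic`, `se`, `converged`,
#'   `at_bound`, `excluded`, `reason`.
#' @export
fit_tac <- function(tac, input, model = c("2TCM-1K", "2TCM"), n_starts = 10,
                    seed = 42, bounds = default_fit_bounds(), dt = 1 / 60,
                    vascular_term = "blood_weighted") {
  model <- match.arg(model)
  stop_if_not(inherits(tac, "time_activity_curve"), "tac must be a time_activity_curve")
  schedule <- tac$schedule
  stop_if_not(abs(attr(schedule, "t_end") - max(input$times)) < 1e-6 ||
                attr(schedule, "t_end") <= max(input$times),
              "input does not cover the frame schedule span")
  y <- tac$values
  w <- tac$weights
  sw <- sqrt(w)
  pn <- model_par_names(model)
  lower <- bounds$lower[pn]; upper <- bounds$upper[pn]

  # Precompute the input grid and frame boundary indices once; each
  # optimizer step then needs only one C++ call.
  grid <- input_on_grid(input, attr(schedule, "t_end"), dt)
  i0 <- schedule$start / dt + 1
  i1 <- schedule$end / dt + 1
  aligned <- max(abs(c(i0 - round(i0), i1 - round(i1)))) < 1e-9
  with_kb <- model == "2TCM-1K"
  bw <- vascular_term == "blood_weighted"
  fwd <- if (aligned) {
    i0 <- as.integer(round(i0)); i1 <- as.integer(round(i1))
    function(theta)
      cpp_forward_frames(grid$cp, grid$cwb, dt, theta[[1]], theta[[2]],
                         theta[[3]], theta[[4]], theta[[5]],
                         if (with_kb) theta[[6]] else 0, with_kb, bw,
                         i0, i1, schedule$duration)
  } else {
    function(theta) model_forward(theta, model, input, schedule, dt,
                                  vascular_term)
  }
  resid_fn <- function(theta) sw * (y - fwd(theta))

  # Start portfolio: geometric mid-range, three physiologic presets
  # (white-matter-, gray-matter- and lesion-like), then seeded draws --
  # log-uniform for rate constants so slow kinetics are well represented.
  mid <- sqrt(pmax(lower, 1e-4) * upper)
  presets <- rbind(
    c(K1 = 0.08, k2 = 0.15, k3 = 0.03, k4 = 0.03, Vb = 0.04, Kb = 0.01),
    c(K1 = 0.15, k2 = 0.35, k3 = 0.06, k4 = 0.08, Vb = 0.08, Kb = 0.05),
    c(K1 = 0.05, k2 = 0.25, k3 = 0.01, k4 = 0.015, Vb = 0.03, Kb = 0.10))
  n_rand <- max(n_starts - 4, 0)
  rand <- with_seed(seed, {
    lo_r <- pmax(lower, c(K1 = 0.01, k2 = 0.02, k3 = 1e-3, k4 = 5e-3,
                          Vb = 0.005, Kb = 1e-3)[pn])
    t(replicate(max(n_rand, 1), {
      v <- exp(runif(length(pn), log(lo_r), log(upper)))
      v[pn == "Vb"] <- runif(1, 0.005, min(0.15, upper[pn == "Vb"]))
      v
    }))
  })
  starts <- rbind(mid, presets[, pn, drop = FALSE],
                  if (n_rand > 0) rand else NULL)
  starts <- pmin(pmax(starts, matrix(lower, nrow(starts), length(pn),
                                     byrow = TRUE)),
                 matrix(upper, nrow(starts), length(pn), byrow = TRUE))
  colnames(starts) <- pn

  best <- NULL; n_conv <- 0
  for (i in seq_len(min(n_starts, nrow(starts)))) {
    res <- try(minpack.lm::nls.lm(
      par = starts[i, ], lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                           ptol = 1e-10)), silent = TRUE)
    if (inherits(res, "try-error")) next
    conv <- res$info %in% 1:4
    if (conv) n_conv <- n_conv + 1
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(res = res, rss = rss, conv = conv)
    if (rss < 1e-24) break  # perfect fit, no better start exists
  }
  if (is.null(best)) {
    return(structure(list(model = model, params = NULL, VT = NA_real_,
                          wrss = NA_real_, aic = NA_real_, se = NULL,
                          converged = FALSE, at_bound = character(0),
                          excluded = FALSE, reason = ""),
                     class = "kinetic_fit"))
  }
  theta <- best$res$par; names(theta) <- pn
  wrss <- best$rss
  n <- length(y); p <- length(pn)
  aic <- n * log(max(wrss, 1e-300) / n) + 2 * p

  tol_b <- 1e-8 * pmax(upper - lower, 1)
  at_bound <- pn[theta <= lower + tol_b & lower > 0 | theta >= upper - tol_b]
  if (length(at_bound))
    warning("parameter at bound: ", paste(at_bound, collapse = ", "))

  se <- rep(NA_real_, p); names(se) <- pn
  jtj <- try(best$res$hessian, silent = TRUE)
  if (!inherits(jtj, "try-error") && !is.null(jtj)) {
    s2 <- wrss / max(n - p, 1)
    covm <- try(solve(jtj) * 2 * s2, silent = TRUE)
    if (!inherits(covm, "try-error")) {
      d <- diag(covm); se[d >= 0] <- sqrt(d[d >= 0])
    }
  }
  params <- kinetic_params(theta[["K1"]], theta[["k2"]], theta[["k3"]],
                           theta[["k4"]], theta[["Vb"]],
                           Kb = if ("Kb" %in% pn) theta[["Kb"]] else NA_real_)
  VT <- if (theta[["k2"]] > 0 && theta[["k4"]] > 0)
    total_volume_of_distribution(params) else NA_real_
  structure(list(model = model, params = params, VT = VT, wrss = wrss,
                 aic = aic, se = se,
                 converged = best$conv || wrss < 1e-20,
                 at_bound = at_bound, excluded = FALSE, reason = ""),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit %s>  converged: %s\n", x$model, x$converged))
  if (!is.null(x$params)) {
    pv <- unlist(x$params)
    cat("  ", paste(sprintf("%s=%.4g", names(pv), pv), collapse = "  "), "\n")
    cat(sprintf("  VT=%.4g  WRSS=%.4g  AIC=%.2f\n", x$VT, x$wrss, x$aic))
  }
  invisible(x)
}

#' Compare two compartment-model fits by AIC
#'
#' Returns the model with the lower Akaike information criterion; on a
#' numerical tie the simpler model (fewer parameters) is preferred.
#'
#' @param fit_a,fit_b `kinetic_fit` objects for the same TAC and input.
#' @return The preferred model name (`"2TCM"` or `"2TCM-1K"`).
#' @export
compare_models <- function(fit_a, fit_b) {
  stop_if_not(isTRUE(fit_a$converged) && isTRUE(fit_b$converged),
              "cannot compare unconverged fits")
  npar <- function(f) length(model_par_names(f$model))
  d <- fit_a$aic - fit_b$aic
  if (abs(d) < 1e-9) {
    if (npar(fit_a) <= npar(fit_b)) fit_a$model else fit_b$model
  } else if (d < 0) fit_a$model else fit_b$model
}

# Tukey hinges (the quartile convention of the five-number summary).
tukey_hinges <- function(x) {
  fn <- stats::fivenum(x)
  c(q1 = fn[2], q3 = fn[4])
}

#' Apply study exclusion rules to a table of kinetic fits
#'
#' A subject x ROI entry is excluded if any parameter value is extreme --
#' more than three interquartile ranges outside the interquartile range
#' (Tukey-hinge quartiles, fences \eqn{Q_1 - 3 IQR} and
#' \eqn{Q_3 + 3 IQR}, computed per ROI and per parameter) -- or
#' physiologically implausible (\eqn{K_b > 1} min\eqn{^{-1}} or
#' \eqn{K_b} below `kb_floor`, operationalizing "close to 0").
#' Exclusions are made on a by-ROI basis: one invalid parameter excludes
#' all parameters of that ROI for that subject.  Fences are computed once
#' from the full input, so the operation is idempotent.
#'
#' @param fits Data frame with columns `subject`, `roi` and parameter
#'   columns among `K1, k2, k3, k4, Vb, Kb, VT`.
#' @param kb_floor Lower plausibility bound for Kb (min^-1).
#' @param iqr_mult Fence multiplier (default 3).
#' @param params Parameter columns to screen; default those present.
#' @return `fits` with logical `excluded` and character `reason` columns.
#' @export
apply_exclusions <- function(fits, kb_floor = 1e-3, iqr_mult = 3,
                             params = NULL) {
  stop_if_not(all(c("subject", "roi") %in% names(fits)),
              "fits must have subject and roi columns")
  cand <- c("K1", "k2", "k3", "k4", "Vb", "Kb", "VT")
  if (is.null(params)) params <- intersect(cand, names(fits))
  excluded <- rep(FALSE, nrow(fits))
  reason <- rep("", nrow(fits))
  add_reason <- function(i, msg) {
    reason[i] <<- ifelse(reason[i] == "", msg, paste(reason[i], msg, sep = "; "))
    excluded[i] <<- TRUE
  }
  if ("Kb" %in% names(fits)) {
    bad <- which(!is.na(fits$Kb) & (fits$Kb > 1 | fits$Kb < kb_floor))
    for (i in bad) add_reason(i, "Kb out of range")
  }
  for (r in unique(fits$roi)) {
    rows <- which(fits$roi == r)
    for (p in params) {
      v <- fits[[p]][rows]
      vv <- v[!is.na(v)]
      if (length(vv) < 4) next  # fence needs >= 4 values
      h <- tukey_hinges(vv)
      iqr <- h["q3"] - h["q1"]
      lo <- h["q1"] - iqr_mult * iqr
      hi <- h["q3"] + iqr_mult * iqr
      bad <- rows[!is.na(v) & (v < lo | v > hi)]
      for (i in bad) add_reason(i, sprintf("%s extreme (3xIQR fence)", p))
    }
  }
  fits$excluded <- excluded
  fits$reason <- reason
  if (all(excluded) && nrow(fits) > 0) stop("empty analysis set", call. = FALSE)
  fits
}

#' Tabulate kinetic fits
#'
#' Flattens a list of `kinetic_fit` objects (with subject/ROI metadata)
#' into the tidy table consumed by [apply_exclusions()] and the group
#' statistics.
#'
#' @param fits Named list of `kinetic_fit`.
#' @param subject,roi Character vectors parallel to `fits`.
#' @return Data frame, one row per fit.
#' @export
fits_to_table <- function(fits, subject, roi) {
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    p <- f$params
    data.frame(subject = subject[i], roi = roi[i], model = f$model,
               K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4, Vb = p$Vb,
               Kb = p$Kb, VT = f$VT, wrss = f$wrss, aic = f$aic,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
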