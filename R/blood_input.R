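#' Arterial blood sample container
#'
#' Combined automated (continuous withdrawal, typically 0-15 min) and
#' manual arterial samples from a dynamic PET study.  Activities are
#' assumed decay-corrected to injection time; set `decay_correct = TRUE`
#' if they are raw.
#'
#' @param df Data frame with columns `time_min`, `whole_blood_kBq_ml`,
#'   optional `plasma_kBq_ml`, optional `parent_fraction` (fraction of
#'   plasma activity that is unmetabolized parent tracer, in \[0,1\]) and
#'   `source` (`"automated"` or `"manual"`).
#' @param fp Free (protein-unbound) plasma fraction, in (0, 1\]; carried
#'   as metadata and never applied to the curves.
#' @param decay_correct Apply carbon-11 decay correction to activities.
#' @return The validated data frame with class `blood_samples` and
#'   attribute `fp`.
#' @export
blood_samples <- function(df, fp, decay_correct = FALSE) {
  need <- c("time_min", "whole_blood_kBq_ml", "source")
  stop_if_not(all(need %in% names(df)),
              paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (is.null(df$plasma_kBq_ml)) df$plasma_kBq_ml <- NA_real_
  if (is.null(df$parent_fraction)) df$parent_fraction <- NA_real_
  stop_if_not(all(df$source %in% c("automated", "manual")),
              "source must be 'automated' or 'manual'")
  for (src in unique(df$source)) {
    tt <- df$time_min[df$source == src]
    stop_if_not(all(diff(tt) > 0), "times must be strictly increasing within each source")
  }
  acts <- c(df$whole_blood_kBq_ml, df$plasma_kBq_ml)
  stop_if_not(all(acts[!is.na(acts)] >= 0), "negative activity concentration")
  pfv <- df$parent_fraction[!is.na(df$parent_fraction)]
  stop_if_not(all(pfv >= 0 & pfv <= 1), "parent_fraction must lie in [0, 1]")
  stop_if_not(is.numeric(fp) && length(fp) == 1 && fp > 0 && fp <= 1,
              "fp must lie in (0, 1]")
  if (decay_correct) {
    fac <- exp(c11_lambda() * df$time_min)
    df$whole_blood_kBq_ml <- df$whole_blood_kBq_ml * fac
    df$plasma_kBq_ml <- df$plasma_kBq_ml * fac
  }
  structure(df, class = c("blood_samples", "data.frame"), fp = fp)
}

#' Read blood samples from CSV
#'
#' Expects the columns documented in [blood_samples()] plus an optional
#' `fp` column (constant per subject) or an `fp` argument.
#'
#' @param path CSV file path.
#' @param fp Free plasma fraction; overrides any `fp` column.
#' @param ... Passed to [blood_samples()].
#' @return A `blood_samples` object.
#' @export
read_blood_samples <- function(path, fp = NULL, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(fp)) {
    stop_if_not("fp" %in% names(df), "fp not given and no fp column in file")
    fp <- df$fp[1]
    df$fp <- NULL
  }
  blood_samples(df, fp = fp, ...)
}

#' Fit a Hill-type parent-fraction model
#'
#' Radiolabeled metabolites accumulate in plasma over the scan; the
#' parent fraction pf(t) is the proportion of plasma activity that is
#' still unmetabolized tracer.  A Hill sigmoid
#' \deqn{pf(t) = pf_\infty + (1 - pf_\infty) / (1 + (t/\tau)^h)}
#' is fitted to the measured fractions by least squares.  The form
#' guarantees pf(0) = 1 and a monotone non-increasing decline to the
#' plateau \eqn{pf_\infty}.
#'
#' @param samples `blood_samples` with at least 3 non-missing
#'   `parent_fraction` values at distinct times.
#' @param model Currently only `"hill"`.
#' @return List of class `parent_fraction_fit` with elements `fn`
#'   (vectorized pf(t)), `params` (`pf_inf`, `tau`, `h`), `rss`,
#'   `converged`.
#' @export
fit_parent_fraction <- function(samples, model = "hill") {
  model <- match.arg(model, "hill")
  ok <- !is.na(samples$parent_fraction)
  tt <- samples$time_min[ok]
  pfv <- samples$parent_fraction[ok]
  keep <- !duplicated(tt)
  tt <- tt[keep]; pfv <- pfv[keep]
  if (length(tt) < 3) stop("insufficient metabolite data", call. = FALSE)

  hill <- function(p, t) p[1] + (1 - p[1]) / (1 + (t / p[2])^p[3])
  if (all(abs(pfv - 1) < 1e-12)) {
    # no metabolism observed: pf is identically 1, shape parameters moot
    fit <- list(fn = function(t) rep(1, length(t)),
                params = c(pf_inf = 1, tau = NA_real_, h = NA_real_),
                rss = 0, converged = TRUE, degenerate = TRUE)
    class(fit) <- "parent_fraction_fit"
    return(fit)
  }
  lower <- c(0, 1e-3, 0.1); upper <- c(1, 500, 10)
  starts <- rbind(
    c(min(pfv), stats::median(tt), 1.5),
    c(0.05, 10, 1), c(0.1, 20, 2), c(0.3, 40, 3), c(0.2, 60, 0.8))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[i, ], lower), upper)
    res <- try(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper,
      fn = function(p) hill(p, tt) - pfv,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(res, "try-error")) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(res = res, rss = rss)
  }
  if (is.null(best))
    stop("parent-fraction fit failed to converge from all starts", call. = FALSE)
  p <- best$res$par
  fit <- list(fn = function(t) hill(p, pmax(t, 0)),
              params = c(pf_inf = p[1], tau = p[2], h = p[3]),
              rss = best$rss, converged = best$res$info %in% 1:4,
              degenerate = FALSE)
  class(fit) <- "parent_fraction_fit"
  fit
}

# Tri-exponential fit A1 e^{-l1 t} + A2 e^{-l2 t} + A3 e^{-l3 t} to the
# decaying portion of a sampled curve; multi-start Levenberg-Marquardt
# with curve-peeling-flavoured initial values.
fit_triexp <- function(tt, yy) {
  f <- function(p, t) p[1] * exp(-p[4] * t) + p[2] * exp(-p[5] * t) +
    p[3] * exp(-p[6] * t)
  y0 <- max(yy)
  lower <- c(0, 0, 0, 1e-5, 1e-5, 1e-5)
  upper <- c(rep(50 * y0 + 1, 3), 20, 5, 1)
  starts <- rbind(
    c(0.6, 0.3, 0.1, 2, 0.2, 0.01) * c(rep(y0, 3), 1, 1, 1),
    c(0.5, 0.3, 0.2, 1, 0.1, 0.02) * c(rep(y0, 3), 1, 1, 1),
    c(0.8, 0.15, 0.05, 4, 0.3, 0.005) * c(rep(y0, 3), 1, 1, 1),
    c(0.4, 0.4, 0.2, 0.5, 0.05, 0.01) * c(rep(y0, 3), 1, 1, 1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- try(minpack.lm::nls.lm(
      par = pmin(pmax(starts[i, ], lower), upper), lower = lower, upper = upper,
      fn = function(p) f(p, tt) - yy,
      control = minpack.lm::nls.lm.control(maxiter = 1000)), silent = TRUE)
    if (inherits(res, "try-error")) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = res$par, rss = rss)
  }
  if (is.null(best)) return(NULL)
  list(fn = function(t) f(best$par, t), params = best$par, rss = best$rss)
}

#' Build a time-continuous metabolite-corrected plasma input function
#'
#' Merges automated and manual samples into continuous whole-blood and
#' plasma curves (the automated curve is authoritative where it exists,
#' manual samples are interpolated thereafter), applies the fitted parent
#' fraction, and optionally replaces the interpolated plasma curve beyond
#' its peak with a smooth tri-exponential tail fit.  The result is the
#' metabolite-free parent plasma input \eqn{C_p(t) = plasma(t) \cdot pf(t)}
#' used to drive all compartment models.
#'
#' If plasma activity was not sampled, it is reconstructed from whole
#' blood via a constant plasma-over-blood ratio (`pob`).
#'
#' @param samples `blood_samples`.
#' @param pf A `parent_fraction_fit`, a function of time, or `NULL`
#'   (fit from `samples`; if no parent-fraction data, pf is taken as 1).
#' @param t_end End of the modeled interval (min).
#' @param dt Internal sampling grid step (min); default 1 s.
#' @param tail_fit Replace interpolation beyond the plasma peak with a
#'   tri-exponential fit (default `TRUE`).
#' @param pob Constant plasma-over-blood ratio used when plasma activity
#'   is missing (default 1.4).
#' @return Object of class `plasma_input`: fine-grid curves plus
#'   provenance (pf and tail parameters, fp).
#' @export
build_plasma_input <- function(samples, pf = NULL, t_end = 90, dt = 1 / 60,
                               tail_fit = TRUE, pob = 1.4) {
  stop_if_not(inherits(samples, "blood_samples"), "samples must be blood_samples")
  if (max(samples$time_min) < 60)
    warning("tail extrapolation unreliable: no samples after 60 min")
  pf_prov <- NULL
  if (is.null(pf)) {
    if (any(!is.na(samples$parent_fraction))) {
      pffit <- fit_parent_fraction(samples)
      pf_fn <- pffit$fn; pf_prov <- pffit$params
    } else pf_fn <- function(t) rep(1, length(t))
  } else if (inherits(pf, "parent_fraction_fit")) {
    pf_fn <- pf$fn; pf_prov <- pf$params
  } else {
    stop_if_not(is.function(pf), "pf must be NULL, a fit, or a function")
    pf_fn <- pf
  }

  auto <- samples[samples$source == "automated", , drop = FALSE]
  man <- samples[samples$source == "manual", , drop = FALSE]
  t_auto_end <- if (nrow(auto)) max(auto$time_min) else -Inf
  merged <- rbind(auto, man[man$time_min > t_auto_end, , drop = FALSE])
  merged <- merged[order(merged$time_min), , drop = FALSE]

  pl <- merged$plasma_kBq_ml
  missing_pl <- is.na(pl)
  pl[missing_pl] <- merged$whole_blood_kBq_ml[missing_pl] * pob
  ts <- merged$time_min
  if (ts[1] > 0) { ts <- c(0, ts); pl <- c(0, pl) }

  tg <- seq(0, t_end, by = dt)
  plasma_g <- stats::approx(ts, pl, tg, rule = 2)$y
  tail_prov <- NULL
  if (tail_fit) {
    ipk <- which.max(pl)
    t_pk <- ts[ipk]
    sel <- ts >= t_pk
    if (sum(sel) >= 6) {
      tf <- fit_triexp(ts[sel], pl[sel])
      if (!is.null(tf)) {
        plasma_g[tg >= t_pk] <- tf$fn(tg[tg >= t_pk])
        tail_prov <- tf$params
      }
    }
  }
  plasma_g <- pmax(plasma_g, 0)
  cp <- plasma_g * pf_fn(tg)
  cp[1] <- 0  # Cp(0) = 0 by construction

  wb_ts <- merged$time_min; wb <- merged$whole_blood_kBq_ml
  if (wb_ts[1] > 0) { wb_ts <- c(0, wb_ts); wb <- c(0, wb) }
  cwb <- pmax(stats::approx(wb_ts, wb, tg, rule = 2)$y, 0)

  structure(list(times = tg, cp = cp, cwb = cwb,
                 fp = attr(samples, "fp"),
                 provenance = list(pf = pf_prov, tail = tail_prov, pob = pob)),
            class = "plasma_input")
}

#' Construct a plasma input directly from functions
#'
#' Convenience constructor used by simulations and tests: supply closed
#' forms for the parent plasma and whole-blood curves.
#'
#' @param cp_fn,cwb_fn Vectorized functions of time (min).
#' @param t_end,dt Grid span and step (min).
#' @param fp Free plasma fraction metadata.
#' @return A `plasma_input`.
#' @export
plasma_input_from_functions <- function(cp_fn, cwb_fn = cp_fn, t_end = 90,
                                        dt = 1 / 60, fp = 1) {
  tg <- seq(0, t_end, by = dt)
  structure(list(times = tg, cp = pmax(cp_fn(tg), 0),
                 cwb = pmax(cwb_fn(tg), 0), fp = fp,
                 provenance = list(analytic = TRUE)),
            class = "plasma_input")
}

#' Evaluate the metabolite-corrected plasma input
#' @param input A `plasma_input`.
#' @param t Times (min).
#' @return Cp(t) in kBq/mL.
#' @export
eval_cp <- function(input, t) {
  stats::approx(input$times, input$cp, pmin(pmax(t, 0), max(input$times)),
                rule = 2)$y
}

#' Evaluate the whole-blood activity curve
#' @inheritParams eval_cp
#' @return Cwb(t) in kBq/mL.
#' @export
eval_cwb <- function(input, t) {
  stats::approx(input$times, input$cwb, pmin(pmax(t, 0), max(input$times)),
                rule = 2)$y
}

#' Write the sampled input curves and provenance to disk
#'
#' @param input A `plasma_input`.
#' @param csv_path Output CSV (time_min, cp_kBq_ml, cwb_kBq_ml).
#' @param json_path Optional JSON sidecar with fp and fitted parameters.
#' @return `csv_path`, invisibly.
#' @export
write_plasma_input <- function(input, csv_path, json_path = NULL) {
  utils::write.csv(data.frame(time_min = input$times, cp_kBq_ml = input$cp,
                              cwb_kBq_ml = input$cwb),
                   csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(fp = input$fp, provenance = input$provenance),
                         json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}
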