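#' Blood-curve generator specification
#'
#' Defaults emulate a bolus [11C] tracer injection: a whole-blood curve
#' rising linearly to a peak near 1 min and decaying tri-exponentially,
#' automated samples at 1-s spacing over 0-15 min, manual samples at
#' 5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80 and 90 min, a Hill parent
#' fraction, and a free plasma fraction drawn uniformly from the
#' observed 1.4-2.7% range.
#'
#' @param peak_time,peak Bolus peak location (min) and height (kBq/mL).
#' @param decay_weights,decay_rates Tri-exponential decay mixture
#'   (weights sum to 1; rates in min^-1).
#' @param pob Plasma-over-blood ratio (constant).
#' @param pf_inf,pf_tau,pf_h Hill parent-fraction parameters.
#' @param fp_range Range for the free plasma fraction draw.
#' @param jitter Relative between-subject jitter on curve parameters.
#' @param noise_sd Additive measurement noise on sampled activities
#'   (kBq/mL); default 0 (noiseless sampling).
#' @return List of class `blood_spec`.
#' @export
blood_spec <- function(peak_time = 1, peak = 55,
                       decay_weights = c(0.75, 0.18, 0.07),
                       decay_rates = c(3.5, 0.35, 0.012),
                       pob = 1.4, pf_inf = 0.10, pf_tau = 20, pf_h = 2,
                       fp_range = c(0.014, 0.027), jitter = 0.1,
                       noise_sd = 0) {
  structure(as.list(environment()), class = "blood_spec")
}

#' Standard manual arterial sampling times
#' @return Sampling times in minutes.
#' @export
manual_sample_times <- function() c(5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90)

#' Generate synthetic arterial blood samples
#'
#' Pure function of (seed, spec): draws subject-level curve parameters,
#' samples the whole-blood curve on the automated (1-s, 0-15 min) and
#' manual schedules, attaches plasma activity (constant
#' plasma-over-blood ratio), Hill parent fractions at the manual times,
#' and a free plasma fraction.
#'
#' @param seed Integer seed.
#' @param spec A [blood_spec()].
#' @return List: `samples` (a [blood_samples()]), `truth` (closed-form
#'   `cwb_fn`, `plasma_fn`, `cp_fn`, `pf_fn` and drawn parameters).
#' @export
gen_blood <- function(seed, spec = blood_spec()) {
  stop_if_not(inherits(spec, "blood_spec"), "spec must be a blood_spec")
  with_seed(seed, {
    jit <- function(x, f = spec$jitter) x * exp(rnorm(length(x), 0, f))
    tp <- jit(spec$peak_time)
    pk <- jit(spec$peak)
    w <- spec$decay_weights; w <- w / sum(w)
    lr <- jit(spec$decay_rates)
    pfp <- c(pf_inf = min(max(jit(spec$pf_inf), 0.02), 0.5),
             tau = jit(spec$pf_tau), h = min(max(jit(spec$pf_h), 0.5), 6))
    fp <- runif(1, spec$fp_range[1], spec$fp_range[2])

    cwb_fn <- function(t) {
      t <- pmax(t, 0)
      rise <- pk * t / tp
      dec <- pk * (w[1] * exp(-lr[1] * (t - tp)) + w[2] * exp(-lr[2] * (t - tp)) +
                     w[3] * exp(-lr[3] * (t - tp)))
      ifelse(t < tp, rise, dec)
    }
    plasma_fn <- function(t) spec$pob * cwb_fn(t)
    pf_fn <- function(t) pfp[1] + (1 - pfp[1]) / (1 + (pmax(t, 0) / pfp[2])^pfp[3])
    cp_fn <- function(t) plasma_fn(t) * pf_fn(t)

    t_auto <- seq(0, 15, by = 1 / 60)
    t_man <- manual_sample_times()
    nz <- function(x) pmax(x + rnorm(length(x), 0, spec$noise_sd), 0)
    df <- rbind(
      data.frame(time_min = t_auto, whole_blood_kBq_ml = nz(cwb_fn(t_auto)),
                 plasma_kBq_ml = nz(plasma_fn(t_auto)),
                 parent_fraction = NA_real_, source = "automated"),
      data.frame(time_min = t_man, whole_blood_kBq_ml = nz(cwb_fn(t_man)),
                 plasma_kBq_ml = nz(plasma_fn(t_man)),
                 parent_fraction = pf_fn(t_man), source = "manual"))
    list(samples = blood_samples(df, fp = fp),
         truth = list(cwb_fn = cwb_fn, plasma_fn = plasma_fn, cp_fn = cp_fn,
                      pf_fn = pf_fn, pf_params = pfp, fp = fp,
                      peak_time = tp, peak = pk, decay_rates = lr,
                      decay_weights = w, pob = spec$pob))
  })
}

#' Cohort generator specification
#'
#' Defines the study conditions the synthetic cohort emulates: 6
#' asymptomatic + 5 symptomatic SVD participants and 21 healthy
#' controls; per-region two-tissue kinetic truths; WMH effects relative
#' to NAWM (lower VT, Vb and K1, higher Kb); and regional CBF of
#' 31.4 +/- 3.8 (WMH) vs 43.0 +/- 4.5 (NAWM) mL/100 g/min.  Kinetic
#' means are calibration choices in the physiologic range of
#' second-generation TSPO tracers (no published per-region values exist
#' to anchor them); effect sizes follow the reported direction of group
#' differences.
#'
#' @param n_svd_asymptomatic,n_svd_symptomatic,n_controls Group sizes.
#' @param region_means Named list of per-region kinetic parameter means
#'   (NAWM also serves as healthy-control white matter).
#' @param between_cv Between-subject lognormal coefficient of variation.
#' @param wmh_effect Multiplicative WMH-vs-NAWM shifts for `K1`, `Vb`,
#'   `VT` and the additive `Kb_add` increment (min^-1).
#' @param effect_jitter Within-subject lognormal jitter on the effect
#'   multipliers.
#' @param cbf_means,cbf_sds CBF means/SDs for (WMH, NAWM).
#' @param noise_level Relative voxel/TAC noise level.
#' @param pet_grid Phantom grid dimensions.
#' @param frame_spec Frame binning specification.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_svd_asymptomatic = 6, n_svd_symptomatic = 5,
                        n_controls = 21,
                        region_means = list(
                          NAWM = c(K1 = 0.10, k2 = 0.18, k3 = 0.035,
                                   k4 = 0.035, Vb = 0.05, Kb = 0.010),
                          striatum = c(K1 = 0.14, k2 = 0.16, k3 = 0.05,
                                       k4 = 0.04, Vb = 0.06, Kb = 0.010),
                          infarct = c(K1 = 0.05, k2 = 0.20, k3 = 0.02,
                                      k4 = 0.03, Vb = 0.03, Kb = 0.020)),
                        between_cv = 0.12,
                        wmh_effect = c(K1 = 0.70, Vb = 0.60, VT = 0.75,
                                       Kb_add = 0.020),
                        effect_jitter = 0.04,
                        cbf_means = c(WMH = 31.4, NAWM = 43.0),
                        cbf_sds = c(WMH = 3.8, NAWM = 4.5),
                        noise_level = 0.05,
                        pet_grid = c(40, 40, 20),
                        frame_spec = pbr28_frame_spec()) {
  stop_if_not(n_svd_asymptomatic >= 0 && n_svd_symptomatic >= 0 &&
                n_controls >= 0, "group sizes must be non-negative")
  structure(as.list(environment()), class = "cohort_spec")
}

# Draw one subject's per-region kinetic truths.  WMH parameters are the
# subject's NAWM parameters scaled by the effect multipliers; the VT
# reduction beyond what K1 explains is absorbed into k3.
draw_subject_truth <- function(spec, group) {
  ln <- function(mu, cv) mu * exp(rnorm(length(mu), 0, cv))
  regs <- list()
  for (r in names(spec$region_means)) {
    m <- spec$region_means[[r]]
    p <- ln(m, spec$between_cv)
    names(p) <- names(m)
    p["Vb"] <- min(p[["Vb"]], 0.19)
    regs[[r]] <- p
  }
  if (group != "control") {
    eff <- spec$wmh_effect
    j <- function(x) x * exp(rnorm(1, 0, spec$effect_jitter))
    nawm <- regs$NAWM
    wmh <- nawm
    k1m <- j(eff[["K1"]]); vbm <- j(eff[["Vb"]]); vtm <- j(eff[["VT"]])
    wmh["K1"] <- nawm[["K1"]] * k1m
    wmh["Vb"] <- min(nawm[["Vb"]] * vbm, 0.19)
    wmh["Kb"] <- nawm[["Kb"]] + j(eff[["Kb_add"]])
    vt_target <- (nawm[["K1"]] / nawm[["k2"]]) *
      (1 + nawm[["k3"]] / nawm[["k4"]]) * vtm
    wmh["k3"] <- max(wmh[["k4"]] *
                       (vt_target * wmh[["k2"]] / wmh[["K1"]] - 1), 0)
    regs$WMH <- wmh
  }
  regs
}

truth_to_table <- function(regs, subject, group) {
  do.call(rbind, lapply(names(regs), function(r) {
    p <- regs[[r]]
    vt <- (p[["K1"]] / p[["k2"]]) * (1 + p[["k3"]] / p[["k4"]])
    data.frame(subject = subject, group = group, roi = r,
               K1 = p[["K1"]], k2 = p[["k2"]], k3 = p[["k3"]],
               k4 = p[["k4"]], Vb = p[["Vb"]], Kb = p[["Kb"]], VT = vt,
               stringsAsFactors = FALSE)
  }))
}

# Deterministic phantom geometry: a white-matter slab containing a WMH
# block, a central striatal block and (symptomatic subjects) a small
# infarct.  Geometry depends on the grid only, not on the seed.
phantom_labels <- function(grid, group) {
  lab <- array(0L, grid)
  ix <- function(f1, f2, n) max(1, round(f1 * n)):min(n, round(f2 * n))
  wm_x <- ix(0.12, 0.9, grid[1]); wm_y <- ix(0.12, 0.9, grid[2])
  wm_z <- ix(0.15, 0.9, grid[3])
  lab[wm_x, wm_y, wm_z] <- roi_labels()[["NAWM"]]
  st_x <- ix(0.4, 0.62, grid[1]); st_y <- ix(0.4, 0.62, grid[2])
  st_z <- ix(0.4, 0.65, grid[3])
  lab[st_x, st_y, st_z] <- roi_labels()[["striatum"]]
  wh_x <- ix(0.15, 0.38, grid[1]); wh_y <- ix(0.15, 0.85, grid[2])
  wh_z <- ix(0.2, 0.85, grid[3])
  lab[wh_x, wh_y, wh_z] <- roi_labels()[["WMH"]]
  if (group == "svd_symptomatic") {
    in_x <- ix(0.7, 0.8, grid[1]); in_y <- ix(0.7, 0.8, grid[2])
    in_z <- ix(0.45, 0.6, grid[3])
    lab[in_x, in_y, in_z] <- roi_labels()[["infarct"]]
  }
  lab
}

#' Generate a dynamic PET phantom for one subject
#'
#' Draws the subject's regional kinetic truths, builds the plasma input
#' from the subject's synthetic blood curves, paints every voxel of each
#' region with the region's 2TCM-1K forward TAC plus Gaussian noise with
#' variance proportional to 1/(frame duration), and returns the phantom
#' with its label volume and ground-truth parameter table.
#'
#' @param seed Integer seed (pure function of seed and spec).
#' @param spec A [cohort_spec()].
#' @param subject Subject identifier string.
#' @param group `"svd_asymptomatic"`, `"svd_symptomatic"` or `"control"`.
#' @param make_voxels If `FALSE`, skip the voxel phantom and return
#'   region-level TACs only (fast path for large simulation studies).
#' @return List: `pet` (4-D array or NULL), `labels`, `wm_mask`,
#'   `truth` (parameter table), `region_tacs` (named list of
#'   noiseless forward TACs), `input`, `blood`, `cbf`, `schedule`.
#' @export
gen_dynamic_pet <- function(seed, spec = cohort_spec(), subject = "P1",
                            group = c("svd_asymptomatic", "svd_symptomatic",
                                      "control"),
                            make_voxels = TRUE) {
  group <- match.arg(group)
  schedule <- build_frame_schedule(spec$frame_spec)
  blood <- gen_blood(seed, blood_spec())
  input <- plasma_input_from_functions(blood$truth$cp_fn, blood$truth$cwb_fn,
                                       t_end = attr(schedule, "t_end"),
                                       fp = blood$truth$fp)
  with_seed(seed + 1L, {
    regs <- draw_subject_truth(spec, group)
    if (group == "control") regs$infarct <- NULL
    present <- if (group == "control") c("NAWM", "striatum")
               else c("WMH", "NAWM", "striatum",
                      if (group == "svd_symptomatic") "infarct")
    regs <- regs[present]
    truth <- truth_to_table(regs, subject, group)

    region_tacs <- lapply(regs, function(p) {
      tcm2_1k_forward(kinetic_params(p[["K1"]], p[["k2"]], p[["k3"]],
                                     p[["k4"]], p[["Vb"]], p[["Kb"]]),
                      input, schedule)
    })

    labels <- phantom_labels(spec$pet_grid, group)
    wm_mask <- labels == roi_labels()[["WMH"]] |
      labels == roi_labels()[["NAWM"]] |
      labels == roi_labels()[["infarct"]]

    pet <- NULL
    if (make_voxels) {
      nf <- nrow(schedule)
      pet <- array(0, c(spec$pet_grid, nf))
      nvox <- prod(spec$pet_grid)
      petm <- matrix(0, nvox, nf)
      dur_ref <- mean(schedule$duration)
      for (r in names(region_tacs)) {
        idx <- which(labels == roi_labels()[[r]])
        tac <- region_tacs[[r]]
        if (spec$noise_level > 0) {
          sdv <- spec$noise_level * mean(tac) * sqrt(dur_ref / schedule$duration)
          noise <- matrix(rnorm(length(idx) * nf), length(idx), nf)
          noise <- sweep(noise, 2, sdv, `*`)
          petm[idx, ] <- rep(tac, each = length(idx)) + noise
        } else {
          petm[idx, ] <- rep(tac, each = length(idx))
        }
      }
      pet <- array(petm, c(spec$pet_grid, nf))
    }

    # CBF map: WMH hypoperfused relative to NAWM, correlated within subject
    u <- rnorm(1)
    cbf_wmh <- spec$cbf_means[["WMH"]] +
      spec$cbf_sds[["WMH"]] * (0.8 * u + 0.6 * rnorm(1))
    cbf_nawm <- spec$cbf_means[["NAWM"]] +
      spec$cbf_sds[["NAWM"]] * (0.8 * u + 0.6 * rnorm(1))
    cbf <- array(50, spec$pet_grid)   # gray-matter-like elsewhere
    cbf[labels == roi_labels()[["NAWM"]]] <- cbf_nawm
    cbf[labels == roi_labels()[["WMH"]]] <- cbf_wmh
    cbf <- cbf + array(rnorm(prod(spec$pet_grid), 0, 1.5), spec$pet_grid)

    list(subject = subject, group = group, pet = pet, labels = labels,
         wm_mask = wm_mask, truth = truth, region_tacs = region_tacs,
         input = input, blood = blood, schedule = schedule, cbf = cbf,
         cbf_truth = c(WMH = cbf_wmh, NAWM = cbf_nawm))
  })
}

#' Add frame-duration-scaled Gaussian noise to a TAC
#'
#' Noise standard deviation per frame is proportional to the frame
#' value, scaled by the square root of the inverse frame duration:
#' \eqn{\sigma_i = level \cdot y_i \sqrt{\bar{\Delta t}/\Delta t_i}},
#' i.e. variance proportional to 1/(frame duration), emulating
#' count-limited PET frames.  Uses the current RNG stream.
#'
#' @param values Noiseless frame values.
#' @param schedule `frame_schedule`.
#' @param level Relative noise level (e.g. 0.05 for "5% noise").
#' @return Noisy frame values.
#' @export
add_tac_noise <- function(values, schedule, level) {
  if (level <= 0) return(values)
  sdv <- level * abs(values) * sqrt(mean(schedule$duration) / schedule$duration)
  values + rnorm(length(values), 0, sdv)
}

#' Generate a paired Iba1/TSPO stained-tissue image
#'
#' Composites an H-DAB image by Beer-Lambert mixing: a faint tissue
#' background, hematoxylin-stained nuclei, and DAB-positive elliptical
#' cell profiles added until the positive-pixel fraction reaches the
#' target.  The actual painted fraction is recorded as ground truth.
#'
#' @param seed Integer seed.
#' @param target_iba1_pct,target_tspo_pct Target positive-area percents.
#' @param size Image side length in pixels (square image).
#' @return List with `iba1`, `tspo` (RGB arrays in \[0,255\]) and
#'   `truth` (achieved positive fractions, percent).
#' @export
gen_ihc_image <- function(seed, target_iba1_pct, target_tspo_pct, size = 256) {
  stop_if_not(target_iba1_pct >= 0 && target_iba1_pct <= 100 &&
                target_tspo_pct >= 0 && target_tspo_pct <= 100,
              "targets must lie in [0, 100]")
  with_seed(seed, {
    mk <- function(target_pct) {
      h_od <- matrix(0.05, size, size)
      d_od <- matrix(0, size, size)
      # hematoxylin nuclei
      n_nuc <- round(size^2 / 2500)
      for (i in seq_len(n_nuc)) {
        cx <- runif(1, 1, size); cy <- runif(1, 1, size)
        r <- runif(1, 2, 4)
        xs <- max(1, floor(cx - r)):min(size, ceiling(cx + r))
        ys <- max(1, floor(cy - r)):min(size, ceiling(cy + r))
        blob <- outer(xs, ys, function(x, y) ((x - cx)^2 + (y - cy)^2) <= r^2)
        h_od[xs, ys] <- h_od[xs, ys] + 0.65 * blob
      }
      painted <- matrix(FALSE, size, size)
      target <- target_pct / 100
      it <- 0
      while (mean(painted) < target && it < 50000) {
        it <- it + 1
        cx <- runif(1, 1, size); cy <- runif(1, 1, size)
        a <- runif(1, 3, 8); b <- runif(1, 3, 8); th <- runif(1, 0, pi)
        r <- max(a, b)
        xs <- max(1, floor(cx - r)):min(size, ceiling(cx + r))
        ys <- max(1, floor(cy - r)):min(size, ceiling(cy + r))
        ell <- outer(xs, ys, function(x, y) {
          xr <- (x - cx) * cos(th) + (y - cy) * sin(th)
          yr <- -(x - cx) * sin(th) + (y - cy) * cos(th)
          (xr / a)^2 + (yr / b)^2 <= 1
        })
        d_od[xs, ys][ell] <- 0.8
        painted[xs, ys] <- painted[xs, ys] | ell
      }
      if (mean(painted) < target - 0.015)
        stop("target positive fraction infeasible for this image size",
             call. = FALSE)
      sm <- hdab_stain_matrix()
      conc <- cbind(as.vector(h_od), as.vector(d_od), 0)
      img <- array(round(255 * 10^(-(conc %*% sm))), c(size, size, 3))
      img <- pmin(pmax(img, 0), 255)
      list(img = img, frac = 100 * mean(painted))
    }
    iba1 <- mk(target_iba1_pct)
    tspo <- mk(target_tspo_pct)
    list(iba1 = iba1$img, tspo = tspo$img,
         truth = c(iba1_pct = iba1$frac, tspo_pct = tspo$frac))
  })
}

#' Generate a full synthetic cohort
#'
#' Pure function of (seed, spec): all PET subjects (blood curves,
#' dynamic phantoms, CBF maps) and a post-mortem set of stained-tissue
#' images (five SVD cases over four basal-ganglia regions, two control
#' cases over three).  When `dir` is given, everything is written in the
#' formats the pipeline reads (NIfTI, CSV, PNG, YAML manifest);
#' otherwise the bundle is returned in memory.
#'
#' @param seed Integer seed.
#' @param spec A [cohort_spec()].
#' @param dir Output directory, or `NULL` for an in-memory bundle.
#' @param include Components to generate, subset of
#'   `c("pet", "ihc")`.
#' @param make_voxels Build voxel phantoms (else region TACs only).
#' @param ihc_size Stained image side length (pixels).
#' @return List: `subjects` (per-subject bundles), `truth` (cohort truth
#'   table), `ihc` (image set + truth), `manifest`.
#' @export
gen_cohort <- function(seed, spec = cohort_spec(), dir = NULL,
                       include = c("pet", "ihc"), make_voxels = TRUE,
                       ihc_size = 128) {
  groups <- c(rep("svd_asymptomatic", spec$n_svd_asymptomatic),
              rep("svd_symptomatic", spec$n_svd_symptomatic),
              rep("control", spec$n_controls))
  ids <- c(sprintf("P%02d", seq_len(spec$n_svd_asymptomatic +
                                      spec$n_svd_symptomatic)),
           sprintf("C%02d", seq_len(spec$n_controls)))
  subjects <- list()
  truth <- NULL
  if ("pet" %in% include && length(ids)) {
    for (i in seq_along(ids)) {
      s <- gen_dynamic_pet(seed + 1000L * i, spec, subject = ids[i],
                           group = groups[i], make_voxels = make_voxels)
      subjects[[ids[i]]] <- s
      truth <- rbind(truth, s$truth)
    }
  }

  ihc <- NULL
  if ("ihc" %in% include) {
    # SVD tissue: dense Iba1 staining but sparse TSPO; controls the
    # reverse pattern (lower density, higher TSPO:Iba1 ratio).
    cases <- data.frame(
      case = c(sprintf("SVD%d", 1:5), sprintf("HC%d", 1:2)),
      group = c(rep("SVD", 5), rep("HC", 2)), stringsAsFactors = FALSE)
    regions <- list(SVD = c("caudate", "internal_capsule", "pallidus", "putamen"),
                    HC = c("internal_capsule", "pallidus", "putamen"))
    iba1_targets <- list(SVD = c(caudate = 4.6, internal_capsule = 10.2,
                                 pallidus = 7.6, putamen = 4.2),
                         HC = c(internal_capsule = 3.7, pallidus = 2.4,
                                putamen = 1.7))
    tspo_targets <- list(SVD = c(caudate = 0.7, internal_capsule = 0.7,
                                 pallidus = 2.4, putamen = 0.4),
                         HC = c(internal_capsule = 1.2, pallidus = 1.7,
                                putamen = 1.4))
    imgs <- list(); ihc_truth <- NULL
    k <- 0
    for (ci in seq_len(nrow(cases))) {
      g <- cases$group[ci]
      for (r in regions[[g]]) {
        k <- k + 1
        im <- gen_ihc_image(seed + 77000L + 13L * k,
                            iba1_targets[[g]][[r]], tspo_targets[[g]][[r]],
                            size = ihc_size)
        key <- paste(cases$case[ci], r, sep = "_")
        imgs[[key]] <- im
        ihc_truth <- rbind(ihc_truth, data.frame(
          case = cases$case[ci], group = g, region = r,
          iba1_true_pct = im$truth[["iba1_pct"]],
          tspo_true_pct = im$truth[["tspo_pct"]], stringsAsFactors = FALSE))
      }
    }
    ihc <- list(images = imgs, truth = ihc_truth)
  }

  manifest <- list(seed = seed,
                   groups = as.list(table(groups)),
                   subjects = ids,
                   truth = if (!is.null(truth)) truth else NULL,
                   ihc_truth = if (!is.null(ihc)) ihc$truth else NULL)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sched <- build_frame_schedule(spec$frame_spec)
    write_frame_schedule(sched, file.path(dir, "frames.csv"))
    files <- character(0)
    for (id in names(subjects)) {
      s <- subjects[[id]]
      sd <- file.path(dir, id)
      dir.create(sd, showWarnings = FALSE)
      bdf <- as.data.frame(s$blood$samples)
      bdf$fp <- attr(s$blood$samples, "fp")
      utils::write.csv(bdf, file.path(sd, "blood.csv"), row.names = FALSE)
      if (!is.null(s$pet)) write_volume(s$pet, file.path(sd, "pet.nii.gz"))
      write_volume(s$labels, file.path(sd, "labels.nii.gz"))
      write_volume(s$cbf, file.path(sd, "cbf.nii.gz"))
      files <- c(files, file.path(id, c("blood.csv", "labels.nii.gz", "cbf.nii.gz")))
    }
    if (!is.null(truth))
      utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    if (!is.null(ihc)) {
      ihd <- file.path(dir, "ihc")
      dir.create(ihd, showWarnings = FALSE)
      for (key in names(ihc$images)) {
        write_rgb_image(ihc$images[[key]]$iba1,
                        file.path(ihd, paste0(key, "_iba1.png")))
        write_rgb_image(ihc$images[[key]]$tspo,
                        file.path(ihd, paste0(key, "_tspo.png")))
      }
      utils::write.csv(ihc$truth, file.path(ihd, "truth.csv"), row.names = FALSE)
    }
    manifest$files <- files
    yaml::write_yaml(list(seed = seed, subjects = ids,
                          groups = as.list(table(groups)), files = files),
                     file.path(dir, "manifest.yaml"))
  }

  list(subjects = subjects, truth = truth, ihc = ihc, manifest = manifest,
       spec = spec)
}
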