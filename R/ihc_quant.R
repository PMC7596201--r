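#' H-DAB stain matrix
#'
#' Standard hematoxylin / DAB optical-density vectors (rows, unit norm):
#' hematoxylin (0.650, 0.704, 0.286), DAB (0.269, 0.568, 0.778), and a
#' residual third vector taken as the normalized cross product of the
#' first two.
#'
#' @return 3x3 matrix, rows = (hematoxylin, dab, residual), columns = RGB.
#' @export
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  r <- r / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(m) <- c("R", "G", "B")
  m
}

#' Color deconvolution of an H-DAB stained RGB image
#'
#' Converts 8-bit RGB intensities to optical densities
#' \eqn{OD_c = -\log_{10}(\max(I_c, 1)/255)} and unmixes them into
#' per-stain densities by inverting the stain matrix (Beer-Lambert
#' model): \eqn{OD = C S}, so \eqn{C = OD\, S^{-1}}.  The DAB channel
#' carries the brown positive-staining signal.
#'
#' @param image Numeric array h x w x 3 with values in \[0, 255\].
#' @param stain_matrix Rows = stain OD vectors; default [hdab_stain_matrix()].
#' @return List of class `stain_od` with matrices `hematoxylin`, `dab`,
#'   `residual` (h x w optical densities) and logical `saturated`.
#' @export
color_deconvolve <- function(image, stain_matrix = hdab_stain_matrix()) {
  d <- dim(image)
  stop_if_not(length(d) == 3 && d[3] == 3, "image must be h x w x 3 RGB")
  stop_if_not(d[1] > 0 && d[2] > 0, "image has zero extent")
  saturated <- all(image <= 0)
  if (saturated)
    warning("all-black image: optical densities capped at -log10(1/255)")
  od <- -log10(pmax(image, 1) / 255)
  odm <- matrix(od, ncol = 3)            # pixels x RGB
  conc <- odm %*% solve(stain_matrix)    # pixels x stains
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(hematoxylin = shape(conc[, 1]), dab = shape(conc[, 2]),
                 residual = shape(conc[, 3]), saturated = saturated,
                 stain_matrix = stain_matrix),
            class = "stain_od")
}

#' Recompose an RGB image from stain densities
#'
#' Forward Beer-Lambert transform with the same stain matrix; inverse of
#' [color_deconvolve()] for unsaturated pixels (agreement within one
#' gray level).
#'
#' @param od A `stain_od`.
#' @return Numeric array h x w x 3 in \[0, 255\].
#' @export
stain_recompose <- function(od) {
  conc <- cbind(as.vector(od$hematoxylin), as.vector(od$dab),
                as.vector(od$residual))
  odm <- conc %*% od$stain_matrix
  d <- dim(od$dab)
  array(255 * 10^(-odm), c(d[1], d[2], 3))
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so components
# that touch only diagonally are merged afterwards with a union-find
# over the provisional labels.
label_components8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nmax <- max(lab)
  if (nmax <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  for (dc in c(-1L, 1L)) {
    a <- lab[-nr, , drop = FALSE]
    b <- lab[-1, , drop = FALSE]
    if (dc == 1L) { a <- a[, -nc, drop = FALSE]; b <- b[, -1, drop = FALSE] }
    else { a <- a[, -1, drop = FALSE]; b <- b[, -nc, drop = FALSE] }
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Threshold a DAB density field and filter small particles
#'
#' Pixels with DAB optical density at or above `threshold` are positive;
#' 8-connected components smaller than `min_particle_px` pixels are
#' removed (the particle-analysis step that suppresses background
#' staining specks).
#'
#' @param dab_od Matrix of DAB optical densities.
#' @param threshold Positive OD threshold (default 0.3).
#' @param min_particle_px Minimum particle size in pixels (default 10).
#' @return List of class `stain_mask`: logical `mask`, integer
#'   `n_particles`, integer vector `particle_sizes`,
#'   `threshold_used`.
#' @export
binarize_and_filter <- function(dab_od, threshold = 0.3, min_particle_px = 10) {
  stop_if_not(threshold > 0, "threshold must be positive")
  raw <- dab_od >= threshold
  if (!any(raw)) {
    return(structure(list(mask = raw, n_particles = 0L,
                          particle_sizes = integer(0),
                          threshold_used = threshold),
                     class = "stain_mask"))
  }
  lab <- label_components8(raw)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_particle_px)
  mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  structure(list(mask = mask, n_particles = length(keep),
                 particle_sizes = sizes[keep], threshold_used = threshold),
            class = "stain_mask")
}

#' Percent area of positive staining
#'
#' \eqn{100 \cdot |positives| / |ROI|}.
#'
#' @param mask Logical matrix or `stain_mask`.
#' @param roi_extent Number of ROI pixels; defaults to the full image.
#' @return Percent in \[0, 100\].
#' @export
percent_area <- function(mask, roi_extent = NULL) {
  if (inherits(mask, "stain_mask")) mask <- mask$mask
  if (is.null(roi_extent)) roi_extent <- length(mask)
  stop_if_not(roi_extent >= 1, "roi_extent must be at least 1 pixel")
  100 * sum(mask) / roi_extent
}

#' Quantify one stained ROI image
#'
#' Runs deconvolution, thresholding and particle filtering and returns
#' the percent-area density.  `channel = "red"` skips the deconvolution
#' and thresholds the literal RGB red channel (as 255 minus intensity,
#' rescaled to a pseudo-OD) for auditing against naive channel
#' thresholding; the default is the DAB deconvolution channel.
#'
#' @param image RGB array in \[0, 255\].
#' @param threshold OD threshold.
#' @param min_particle_px Particle size filter.
#' @param channel `"dab"` (default) or `"red"`.
#' @return List of class `stain_quantification`: `percent_area`,
#'   `n_particles`, `threshold_used`.
#' @export
quantify_stain <- function(image, threshold = 0.3, min_particle_px = 10,
                           channel = c("dab", "red")) {
  channel <- match.arg(channel)
  field <- if (channel == "dab") color_deconvolve(image)$dab
           else -log10(pmax(image[, , 1], 1) / 255)
  bm <- binarize_and_filter(field, threshold, min_particle_px)
  structure(list(percent_area = percent_area(bm),
                 n_particles = bm$n_particles,
                 threshold_used = threshold),
            class = "stain_quantification")
}

#' Regional density and TSPO:Iba1 ratio tables
#'
#' Aggregates paired Iba1/TSPO percent-area densities into the regional
#' and group summary used to compare microglial density with TSPO
#' expression.  Per ROI the ratio is \eqn{100 \cdot TSPO / Iba1}; the
#' regional value of each quantity is the mean over its ROIs; the group
#' density is the mean over regional densities and the group ratio the
#' mean over regional ratios (not the ratio of group densities -- the
#' two differ whenever densities vary across ROIs).
#'
#' @param df Data frame with columns `group`, `region`, `iba1`, `tspo`
#'   (percent areas) and optionally a precomputed per-ROI `ratio`
#'   (percent).  One row per ROI; a single row per region represents an
#'   already-aggregated regional summary.
#' @return List with data frames `regional` (group, region, iba1, tspo,
#'   ratio, plus rounded report columns) and `group` (per-group means,
#'   densities rounded to 2 decimals, ratios to whole percent).
#' @export
density_ratio_tables <- function(df) {
  need <- c("group", "region", "iba1", "tspo")
  stop_if_not(all(need %in% names(df)),
              paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (is.null(df$ratio)) df$ratio <- NA_real_
  zero <- !is.na(df$iba1) & df$iba1 == 0 & is.na(df$ratio)
  if (any(zero)) {
    message(sum(zero), " ROI(s) dropped: Iba1 density 0, ratio undefined")
    df <- df[!zero, , drop = FALSE]
  }
  miss <- is.na(df$ratio)
  df$ratio[miss] <- 100 * df$tspo[miss] / df$iba1[miss]

  key <- interaction(df$group, df$region, drop = TRUE)
  regional <- do.call(rbind, lapply(split(df, key), function(s) {
    data.frame(group = s$group[1], region = s$region[1],
               iba1 = mean(s$iba1), tspo = mean(s$tspo),
               ratio = mean(s$ratio), n_roi = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(regional) <- NULL
  regional <- regional[order(regional$group, regional$region), , drop = FALSE]

  grp <- do.call(rbind, lapply(split(regional, regional$group), function(s) {
    data.frame(group = s$group[1],
               iba1 = mean(s$iba1), tspo = mean(s$tspo),
               ratio = mean(s$ratio), n_regions = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(grp) <- NULL
  # report rounding in the half-away-from-zero convention of the tables
  roundp <- function(x, d = 0) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
  regional$iba1_report <- roundp(regional$iba1, 2)
  regional$tspo_report <- roundp(regional$tspo, 2)
  regional$ratio_report <- roundp(regional$ratio)
  grp$iba1_report <- roundp(grp$iba1, 2)
  grp$tspo_report <- roundp(grp$tspo, 2)
  grp$ratio_report <- roundp(grp$ratio)
  list(regional = regional, group = grp)
}

#' Read an RGB image (PNG) as a 0-255 array
#' @param path PNG file path.
#' @return h x w x 3 numeric array in \[0, 255\].
#' @export
read_rgb_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' Write a 0-255 RGB array as PNG
#' @param image h x w x 3 array in \[0, 255\].
#' @param path Output path.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
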