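#' Nanobar layout table
#'
#' Describes the nanobar array geometry in image coordinates. Coordinates are
#' 0-based with pixel centers at integer positions, x = column, y = row.
#'
#' @param x_px,y_px Bar center coordinates (0-based pixels).
#' @param angle_rad Bar long-axis orientation (rad, counter-clockwise from
#'   the +x axis).
#' @param width_nm,length_nm Bar dimensions (nm); widths of 200-1000 nm are
#'   typical, the bar-end radius of curvature is width/2.
#' @param pixel_size_nm Image pixel size (nm/pixel).
#' @return A `nanobar_layout` data.frame with attribute `pixel_size_nm`.
#' @export
nanobar_layout <- function(x_px, y_px, angle_rad, width_nm, length_nm,
                           pixel_size_nm = 65) {
  df <- data.frame(bar_id = seq_along(x_px), x_px = x_px, y_px = y_px,
                   angle_rad = angle_rad, width_nm = width_nm,
                   length_nm = length_nm)
  attr(df, "pixel_size_nm") <- pixel_size_nm
  class(df) <- c("nanobar_layout", "data.frame")
  df
}

#' Read / write a layout CSV
#' @param path File path (columns `bar_id,x_px,y_px,angle_rad,width_nm,length_nm`).
#' @param pixel_size_nm Pixel size (nm).
#' @export
read_layout_csv <- function(path, pixel_size_nm = 65) {
  df <- utils::read.csv(path)
  nanobar_layout(df$x_px, df$y_px, df$angle_rad, df$width_nm, df$length_nm,
                 pixel_size_nm)
}

#' @rdname read_layout_csv
#' @param layout A [nanobar_layout()].
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}

# image[y + 1, x + 1] holds pixel (x, y), 0-based, x = column.
px <- function(image, x, y) image[cbind(y + 1L, x + 1L)]

#' Crop square windows centred on each nanobar
#'
#' Extracts a `size` x `size` window around each bar center, rotated so the
#' bar long axis is horizontal in the crop (nearest-neighbour sampling, so
#' intensities are preserved). Bars whose window leaves the image are skipped
#' with a warning.
#'
#' @param image 2-D numeric matrix (one channel), indexed `[y + 1, x + 1]`.
#' @param layout A [nanobar_layout()].
#' @param size Window size in pixels (odd; default 71).
#' @return Named list of crops (`bar_<id>`), each with attributes `width_nm`,
#'   `length_nm`, `bar_id`.
#' @export
crop_nanobars <- function(image, layout, size = 71) {
  stopifnot(is.matrix(image), size %% 2 == 1)
  half <- (size - 1) / 2
  off <- seq(-half, half)
  grid_x <- matrix(off, size, size, byrow = TRUE)   # crop x (along bar)
  grid_y <- matrix(off, size, size)                 # crop y
  out <- list()
  for (i in seq_len(nrow(layout))) {
    th <- layout$angle_rad[i]
    sx <- layout$x_px[i] + grid_x * cos(th) - grid_y * sin(th)
    sy <- layout$y_px[i] + grid_x * sin(th) + grid_y * cos(th)
    ix <- round(sx); iy <- round(sy)
    if (any(ix < 0) || any(iy < 0) || any(ix >= ncol(image)) ||
        any(iy >= nrow(image))) {
      warning(sprintf("bar %d window exceeds image bounds; skipped",
                      layout$bar_id[i]))
      next
    }
    cr <- matrix(px(image, as.integer(ix), as.integer(iy)), size, size)
    attr(cr, "bar_id") <- layout$bar_id[i]
    attr(cr, "width_nm") <- layout$width_nm[i]
    attr(cr, "length_nm") <- layout$length_nm[i]
    out[[paste0("bar_", layout$bar_id[i])]] <- cr
  }
  out
}

#' Corner-mesh background correction
#'
#' Subtracts a bilinear background surface fitted through the mean
#' intensities of four square ROIs at the crop corners. A pure plane is
#' removed exactly (up to corner-ROI sampling); flat backgrounds leave
#' corrected corners at ~0.
#'
#' @param crop 2-D matrix (at least `2 * corner` in each dimension).
#' @param corner Corner ROI edge length in pixels (default 8).
#' @param saturation Intensity treated as saturated; a saturated corner's
#'   mean is replaced by the median of the non-saturated corners (flagged via
#'   attribute `saturated_corners`).
#' @return Corrected crop (same dim); attributes `background_corners`,
#'   `saturated_corners`.
#' @export
background_correct <- function(crop, corner = 8, saturation = Inf) {
  stopifnot(is.matrix(crop), nrow(crop) >= 2 * corner,
            ncol(crop) >= 2 * corner)
  n <- nrow(crop); m <- ncol(crop)
  rois <- list(
    tl = crop[1:corner, 1:corner],
    tr = crop[1:corner, (m - corner + 1):m],
    bl = crop[(n - corner + 1):n, 1:corner],
    br = crop[(n - corner + 1):n, (m - corner + 1):m])
  mean_int <- vapply(rois, mean, numeric(1))
  sat <- vapply(rois, function(r) any(r >= saturation), logical(1))
  if (any(sat)) {
    if (all(sat)) stop("all corner ROIs saturated")
    mean_int[sat] <- stats::median(mean_int[!sat])
  }
  # corner ROI centers (0-based pixel coordinates)
  c0 <- (corner - 1) / 2
  x0 <- c0; x1 <- (m - 1) - c0
  y0 <- c0; y1 <- (n - 1) - c0
  xs <- (seq_len(m) - 1 - x0) / (x1 - x0)
  ys <- (seq_len(n) - 1 - y0) / (y1 - y0)
  fy <- matrix(ys, n, m)
  fx <- matrix(xs, n, m, byrow = TRUE)
  bg <- (1 - fy) * ((1 - fx) * mean_int["tl"] + fx * mean_int["tr"]) +
    fy * ((1 - fx) * mean_int["bl"] + fx * mean_int["br"])
  out <- crop - bg
  attributes(out) <- attributes(crop)
  dim(out) <- dim(crop)
  attr(out, "background_corners") <- mean_int
  attr(out, "saturated_corners") <- names(sat)[sat]
  out
}

#' Average background-corrected crops by bar width
#'
#' @param crops List of equally sized crops carrying a `width_nm` attribute
#'   (as produced by [crop_nanobars()]).
#' @return Named list (by width) of pixelwise mean images, each with
#'   attributes `width_nm` and `n` (group size).
#' @export
average_nanobar_stack <- function(crops) {
  stopifnot(length(crops) >= 1)
  dims <- vapply(crops, function(x) dim(x), integer(2))
  if (any(dims != dims[, 1])) stop("crops have mixed shapes")
  widths <- vapply(crops, function(x) attr(x, "width_nm"), numeric(1))
  out <- list()
  for (w in sort(unique(widths))) {
    grp <- crops[widths == w]
    avg <- Reduce(`+`, grp) / length(grp)
    attr(avg, "width_nm") <- w
    attr(avg, "length_nm") <- attr(grp[[1]], "length_nm")
    attr(avg, "n") <- length(grp)
    out[[as.character(w)]] <- avg
  }
  out
}

#' ROI masks for a canonical (horizontal) nanobar crop
#'
#' Two semicircular end caps of diameter `width + 2 px` at the bar
#' extremities, a center ROI covering the middle third of the bar body, and
#' (for cell-mode quantification) the center split at the midline into two
#' averaged center ROIs. The end ROI scales with the bar so it does not cover
#' the non-curved center.
#'
#' @param width_nm,length_nm Bar dimensions (nm).
#' @param pixel_size_nm Pixel size (nm).
#' @param size Crop size (pixels).
#' @return List of logical matrices: `end1`, `end2`, `center`, `center1`,
#'   `center2`.
#' @export
nanobar_rois <- function(width_nm, length_nm, pixel_size_nm = 65, size = 71) {
  half <- (size - 1) / 2
  off <- seq(-half, half)
  xg <- matrix(off, size, size, byrow = TRUE)
  yg <- matrix(off, size, size)
  w_px <- width_nm / pixel_size_nm
  l_px <- length_nm / pixel_size_nm
  hx <- (l_px - w_px) / 2          # cap centers at +/- hx
  r_end <- w_px / 2 + 1            # cap diameter = width + 2 px
  end1 <- ((xg + hx)^2 + yg^2 <= r_end^2) & (xg <= -hx)
  end2 <- ((xg - hx)^2 + yg^2 <= r_end^2) & (xg >= hx)
  center <- abs(xg) <= l_px / 6 & abs(yg) <= w_px / 2
  list(end1 = end1, end2 = end2, center = center,
       center1 = center & xg < 0, center2 = center & xg >= 0)
}

#' End/center quantification of a nanobar crop pair
#'
#' SLB mode: integrated ROI intensities of both channels are normalized to
#' the 600-nm-bar center intensity of the same image/channel; the
#' (dimensionless) end density is the ratio of normalized protein to
#' normalized lipid intensity. Cell mode: the end mean intensity is
#' normalized to the average of the two center ROI means of the protein
#' channel alone.
#'
#' @param protein Background-corrected protein-channel crop (canonical
#'   orientation).
#' @param lipid Background-corrected lipid-channel crop (SLB mode).
#' @param width_nm,length_nm Bar dimensions.
#' @param mode "slb" or "cell".
#' @param ref For SLB mode, the 600-nm reference: named vector
#'   `c(lipid = , protein = )` of center-ROI sums from the same image.
#' @param pixel_size_nm Pixel size (nm).
#' @return One-row data.frame: per-end and pooled end densities (SLB) or
#'   end-to-center ratios (cell), plus raw ROI sums.
#' @export
quantify_end_center <- function(protein, lipid = NULL, width_nm, length_nm,
                                mode = c("slb", "cell"), ref = NULL,
                                pixel_size_nm = 65) {
  mode <- match.arg(mode)
  size <- nrow(protein)
  rois <- nanobar_rois(width_nm, length_nm, pixel_size_nm, size)
  s <- function(img, m) sum(img[m])
  if (mode == "slb") {
    if (is.null(lipid)) stop("SLB mode needs the lipid channel")
    if (is.null(ref)) stop("SLB mode needs the 600-nm center reference")
    lip1 <- s(lipid, rois$end1); lip2 <- s(lipid, rois$end2)
    if (lip1 <= 0 || lip2 <= 0) {
      warning("zero lipid signal in an end ROI; density undefined")
      return(data.frame(width_nm = width_nm, end1 = NA, end2 = NA,
                        end_density = NA))
    }
    p1 <- s(protein, rois$end1) / ref[["protein"]]
    p2 <- s(protein, rois$end2) / ref[["protein"]]
    l1 <- lip1 / ref[["lipid"]]
    l2 <- lip2 / ref[["lipid"]]
    d1 <- p1 / l1; d2 <- p2 / l2
    data.frame(width_nm = width_nm, end1 = d1, end2 = d2,
               end_density = (d1 + d2) / 2,
               protein_center = s(protein, rois$center),
               lipid_center = s(lipid, rois$center))
  } else {
    c1 <- mean(protein[rois$center1]); c2 <- mean(protein[rois$center2])
    cc <- (c1 + c2) / 2
    e1 <- mean(protein[rois$end1]) / cc
    e2 <- mean(protein[rois$end2]) / cc
    data.frame(width_nm = width_nm, end1 = e1, end2 = e2,
               end_to_center = (e1 + e2) / 2)
  }
}

#' Full nanobar-array measurement pipeline
#'
#' crop -> corner-mesh background correction -> per-width averaging ->
#' end/center quantification, with the 600-nm bar (or `ref_width`) of the
#' same image as the SLB normalization reference.
#'
#' @param protein,lipid 2-D channel images.
#' @param layout A [nanobar_layout()].
#' @param mode "slb" or "cell".
#' @param ref_width Reference bar width (nm) for SLB normalization.
#' @param size Crop size (pixels).
#' @param corner Corner-ROI size for background correction.
#' @return data.frame with one row per bar width: pooled end density
#'   (SLB) or end-to-center ratio (cell), per-end values and group sizes.
#' @export
measure_nanobar_array <- function(protein, lipid = NULL, layout,
                                  mode = c("slb", "cell"), ref_width = 600,
                                  size = 71, corner = 8) {
  mode <- match.arg(mode)
  psz <- attr(layout, "pixel_size_nm")
  crop_p <- lapply(crop_nanobars(protein, layout, size), background_correct,
                   corner = corner)
  avg_p <- average_nanobar_stack(crop_p)
  if (mode == "slb") {
    crop_l <- lapply(crop_nanobars(lipid, layout, size), background_correct,
                     corner = corner)
    avg_l <- average_nanobar_stack(crop_l)
    wref <- as.character(ref_width)
    if (!wref %in% names(avg_p)) stop("reference width absent from layout")
    rois_ref <- nanobar_rois(ref_width, attr(avg_p[[wref]], "length_nm"),
                             psz, size)
    ref <- c(lipid = sum(avg_l[[wref]][rois_ref$center]),
             protein = sum(avg_p[[wref]][rois_ref$center]))
    rows <- lapply(names(avg_p), function(w) {
      r <- quantify_end_center(avg_p[[w]], avg_l[[w]],
                               width_nm = as.numeric(w),
                               length_nm = attr(avg_p[[w]], "length_nm"),
                               mode = "slb", ref = ref, pixel_size_nm = psz)
      r$n_bars <- attr(avg_p[[w]], "n")
      r
    })
  } else {
    rows <- lapply(names(avg_p), function(w) {
      r <- quantify_end_center(avg_p[[w]], width_nm = as.numeric(w),
                               length_nm = attr(avg_p[[w]], "length_nm"),
                               mode = "cell", pixel_size_nm = psz)
      r$n_bars <- attr(avg_p[[w]], "n")
      r
    })
  }
  do.call(rbind, rows)
}

#' Linear curvature-response fit
#'
#' Ordinary least squares of a density measure on curvature, using the
#' reciprocal bar width (1/width) as the curvature measure. Optionally tests
#' whether two proteins' slopes differ (F-test on the interaction term).
#'
#' @param density Response values.
#' @param width_nm Bar widths (nm); >= 3 distinct values required.
#' @param density2 Optional second series on the same widths for a
#'   slope-difference test.
#' @return List: `slope`, `se`, `p.value`, `intercept`, `fit` (the `lm`),
#'   and when `density2` is given `slope_diff_F`, `slope_diff_p`.
#' @export
curvature_response_fit <- function(density, width_nm, density2 = NULL) {
  if (length(unique(width_nm)) < 3) stop("need >= 3 distinct widths")
  inv <- 1 / width_nm
  fit <- stats::lm(density ~ inv)
  sm <- summary(fit)$coefficients
  out <- list(slope = sm["inv", 1], se = sm["inv", 2],
              p.value = sm["inv", 4], intercept = sm["(Intercept)", 1],
              fit = fit)
  if (!is.null(density2)) {
    y <- c(density, density2)
    g <- factor(rep(c("a", "b"), c(length(density), length(density2))))
    x <- c(inv, inv)
    full <- stats::lm(y ~ x * g)
    null <- stats::lm(y ~ x + g)
    an <- stats::anova(null, full)
    out$slope_diff_F <- an$F[2]
    out$slope_diff_p <- an$`Pr(>F)`[2]
  }
  out
}

#' Hill / Gaussian binding-curve fit
#'
#' Nonlinear least squares of end densities against concentration:
#' Hill \eqn{y = plateau\, c^n / (K^n + c^n)} or Gaussian
#' \eqn{y = A \exp(-(c-\mu)^2 / 2\sigma^2)} (used for the curvature-response
#' coefficient peak). Deterministic data-driven starting values.
#'
#' @param conc Concentrations (same units as `K_half` / `mu`).
#' @param y Responses.
#' @param model "hill" or "gaussian".
#' @return List with `coefficients` (estimate, se), `fitted`, `residuals`,
#'   `fit` (the `nls` object), and `flagged` (TRUE when a parameter is
#'   unidentifiable: relative SE > 1, e.g. all-saturated designs).
#' @export
binding_curve_fit <- function(conc, y, model = c("hill", "gaussian")) {
  model <- match.arg(model)
  stopifnot(length(conc) == length(y), length(conc) >= 4)
  if (model == "hill") {
    start <- list(plateau = max(y), K_half = stats::median(conc), n = 1)
    fit <- minpack.lm::nlsLM(
      y ~ plateau * conc^n / (K_half^n + conc^n), start = start,
      lower = c(1e-9, 1e-9, 0.1), upper = c(Inf, Inf, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    start <- list(A = max(y), mu = conc[which.max(y)],
                  sigma = diff(range(conc)) / 4)
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(-(conc - mu)^2 / (2 * sigma^2)), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  sm <- summary(fit)$coefficients
  flagged <- any(abs(sm[, 2] / sm[, 1]) > 1)
  list(coefficients = sm[, 1:2, drop = FALSE], fitted = stats::fitted(fit),
       residuals = stats::residuals(fit), fit = fit, flagged = flagged)
}

#' Polymerization-rate slope of an intensity time series
#'
#' OLS slope of (normalized) intensity against time restricted to the linear
#' growth window, by default 105-350 s.
#'
#' @param time Time points (s).
#' @param intensity Intensities.
#' @param window Fitting window `c(lo, hi)` (s).
#' @return List: `slope` (intensity/s), `se`, `p.value`, `n`.
#' @export
rate_slope <- function(time, intensity, window = c(105, 350)) {
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 3) stop("fewer than 3 points in the fitting window")
  fit <- stats::lm(intensity[keep] ~ time[keep])
  sm <- summary(fit)$coefficients
  list(slope = sm[2, 1], se = sm[2, 2], p.value = sm[2, 4], n = sum(keep))
}

#' Threshold-based single-particle quantification
#'
#' Laplacian-of-Gaussian spot detection at a stated particle diameter with
#' quality thresholding, sub-pixel centroids (quadratic peak interpolation)
#' and local-background-subtracted integrated intensities (disk sum minus
#' annulus median times disk area).
#'
#' @param image 2-D matrix.
#' @param diameter_px Expected particle diameter in pixels (default 10,
#'   i.e. 0.65 um at 65 nm/pixel).
#' @param threshold_sd Detection threshold in robust SD units of the LoG
#'   response (median + k * mad).
#' @return data.frame: `x`, `y` (0-based, sub-pixel), `intensity`
#'   (background-corrected integrated), `quality` (LoG response). Empty when
#'   nothing is detected.
#' @export
particle_quantify <- function(image, diameter_px = 10, threshold_sd = 6) {
  stopifnot(is.matrix(image), diameter_px > 2)
  sigma <- diameter_px / (2 * sqrt(2))
  half <- ceiling(3 * sigma)
  ax <- seq(-half, half)
  r2 <- outer(ax^2, ax^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  log_k <- (r2 - 2 * sigma^2) / sigma^4 * g  # Laplacian of Gaussian
  log_k <- -(log_k - mean(log_k))            # bright spots -> positive peaks
  resp <- EBImage::filter2(image, log_k)
  thr <- stats::median(resp) + threshold_sd * stats::mad(resp)
  n <- nrow(resp); m <- ncol(resp)
  # 8-neighbour local maxima above threshold, away from the border
  is_max <- resp >= thr
  idx <- which(is_max, arr.ind = TRUE)
  rad <- diameter_px / 2
  # integration disk of one full diameter captures ~94% of a Gaussian spot
  # whose FWHM matches the detection diameter
  r_int <- diameter_px
  margin <- ceiling(r_int + 9)
  keep <- idx[, 1] > margin & idx[, 1] <= n - margin &
    idx[, 2] > margin & idx[, 2] <= m - margin
  idx <- idx[keep, , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    nb <- resp[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (resp[i, j] < max(nb)) next
    # sub-pixel quadratic refinement along each axis
    dy <- quad_offset(resp[i - 1, j], resp[i, j], resp[i + 1, j])
    dx <- quad_offset(resp[i, j - 1], resp[i, j], resp[i, j + 1])
    yy <- (i - 1) + dy; xx <- (j - 1) + dx
    ig <- integrate_spot(image, i, j, r_int)
    out[[length(out) + 1]] <- data.frame(x = xx, y = yy, intensity = ig,
                                         quality = resp[i, j])
  }
  if (!length(out)) {
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
                      quality = numeric(0)))
  }
  res <- do.call(rbind, out)
  # suppress duplicate maxima closer than one radius (keep the brighter)
  res <- res[order(-res$quality), ]
  kept <- rep(TRUE, nrow(res))
  for (k in seq_len(nrow(res))) {
    if (!kept[k]) next
    d2 <- (res$x - res$x[k])^2 + (res$y - res$y[k])^2
    close <- d2 < rad^2 & seq_len(nrow(res)) > k
    kept[close] <- FALSE
  }
  res <- res[kept, ]
  rownames(res) <- NULL
  res
}

quad_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (den >= 0) return(0)
  off <- 0.5 * (fm - fp) / den
  max(-0.5, min(0.5, off))
}

integrate_spot <- function(image, i, j, rad) {
  # background annulus sits clear of the spot tail (rad + 5 .. rad + 8)
  half <- ceiling(rad + 8)
  ii <- (i - half):(i + half)
  jj <- (j - half):(j + half)
  sub <- image[ii, jj]
  r <- sqrt(outer((ii - i)^2, (jj - j)^2, "+"))
  disk <- r <= rad
  annulus <- r > rad + 5 & r <= rad + 8
  bg <- stats::median(sub[annulus])
  sum(sub[disk]) - bg * sum(disk)
}

#' Draw a fixed-size subsample of detected particles
#'
#' @param detections Output of [particle_quantify()].
#' @param n Sample size (default 200).
#' @param seed Integer seed.
#' @export
sample_particles <- function(detections, n = 200, seed = 1L) {
  if (nrow(detections) <= n) return(detections)
  set.seed(as.integer(seed))
  detections[sort(sample.int(nrow(detections), n)), ]
}

#' Group-comparison wrappers for reporting
#'
#' Thin convenience wrappers over standard routines (Welch/paired t-test,
#' one-way ANOVA with Tukey HSD) used for report parity; not reimplemented
#' statistics.
#'
#' @param values Numeric response.
#' @param groups Factor of group labels.
#' @param method "t.test" or "anova".
#' @param ... Passed to the underlying routine.
#' @export
compare_groups <- function(values, groups, method = c("anova", "t.test"),
                           ...) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (method == "t.test") {
    stopifnot(nlevels(groups) == 2)
    sp <- split(values, groups)
    stats::t.test(sp[[1]], sp[[2]], ...)
  } else {
    fit <- stats::aov(values ~ groups)
    list(anova = summary(fit), tukey = stats::TukeyHSD(fit))
  }
}
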