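#' Specification for a synthetic nanobar-array image pair
#'
#' Describes the ground truth for generated two-channel (lipid, protein)
#' nanobar images: stadium-shaped bars blurred by a Gaussian PSF over a
#' planar background, with the protein channel carrying a programmed
#' curvature-dependent end enrichment E(width) at the bar caps and
#' lipid-proportional body signal. Noise is Poisson shot noise on expected
#' counts plus Gaussian read noise.
#'
#' @param image_size Image edge (pixels).
#' @param pixel_size_nm Pixel size (nm); 65 nm gives a 10-pixel 0.65-um
#'   particle scale.
#' @param widths_nm Bar widths (nm).
#' @param bars_per_width Replicate bars per width.
#' @param length_nm Bar length (nm).
#' @param enrichment Function width_nm -> end enrichment E (>= 0);
#'   default rises on sharper bars (< 500 nm).
#' @param lipid_amp Expected lipid counts per bar pixel.
#' @param body_factor Protein body signal as a fraction of lipid.
#' @param background c(offset, gx, gy): planar background offset and
#'   gradients per pixel.
#' @param psf_sigma_nm Gaussian PSF sigma (nm).
#' @param read_sd Gaussian read-noise SD (counts).
#' @param shot_noise Apply Poisson noise to expected counts.
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return A `synthetic_array_spec` list.
#' @export
synthetic_array_spec <- function(image_size = 560, pixel_size_nm = 65,
                                 widths_nm = c(200, 300, 400, 500, 600, 800,
                                               1000),
                                 bars_per_width = 3, length_nm = 2000,
                                 enrichment = function(w)
                                   1 + 1.5 * pmax(0, (500 - pmin(w, 500)) / 300),
                                 lipid_amp = 800, body_factor = 1,
                                 background = c(offset = 100, gx = 0, gy = 0),
                                 psf_sigma_nm = 150, read_sd = 3,
                                 shot_noise = TRUE, seed = 1L) {
  structure(list(image_size = as.integer(image_size),
                 pixel_size_nm = pixel_size_nm, widths_nm = widths_nm,
                 bars_per_width = as.integer(bars_per_width),
                 length_nm = length_nm, enrichment = enrichment,
                 lipid_amp = lipid_amp, body_factor = body_factor,
                 background = background, psf_sigma_nm = psf_sigma_nm,
                 read_sd = read_sd, shot_noise = shot_noise,
                 seed = as.integer(seed)),
            class = "synthetic_array_spec")
}

gaussian_kernel <- function(sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  ax <- seq(-half, half)
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma_px^2))
  k / sum(k)
}

# signed geometry of a stadium bar: distance from pixels to the bar axis
# segment, in the bar frame
stadium_masks <- function(xg, yg, cx, cy, angle, width_px, length_px) {
  dx <- xg - cx; dy <- yg - cy
  along <- dx * cos(angle) + dy * sin(angle)
  perp <- -dx * sin(angle) + dy * cos(angle)
  hx <- (length_px - width_px) / 2
  r <- width_px / 2
  body <- abs(along) <= hx & abs(perp) <= r
  cap1 <- (along + hx)^2 + perp^2 <= r^2 & along < -hx
  cap2 <- (along - hx)^2 + perp^2 <= r^2 & along > hx
  list(body = body, caps = cap1 | cap2, all = body | cap1 | cap2)
}

#' Generate a synthetic nanobar-array image pair with ground truth
#'
#' Bars are laid out on a grid (one column per width, rows are replicates),
#' at alternating orientations. Returns the two channels, the layout table
#' and a truth table holding the programmed end enrichment per bar.
#'
#' @param spec A [synthetic_array_spec()].
#' @param dir Optional output directory; when given, writes
#'   `nanobars.tif` (2-page TIFF: lipid, protein), `layout.csv`, `truth.csv`.
#' @return List: `lipid`, `protein` (matrices), `layout`
#'   ([nanobar_layout()]), `truth` (data.frame bar_id, width_nm,
#'   end_enrichment).
#' @export
gen_nanobar_images <- function(spec = synthetic_array_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_array_spec"))
  set.seed(spec$seed)
  n <- spec$image_size
  psz <- spec$pixel_size_nm
  w_px <- spec$widths_nm / psz
  l_px <- spec$length_nm / psz
  nw <- length(spec$widths_nm)
  # margin covers a rotated 71 x 71 crop (35 * sqrt(2) ~ 50 px)
  margin <- 55
  gx <- if (nw > 1) seq(margin, n - 1 - margin, length.out = nw) else
    (n - 1) / 2
  gy <- if (spec$bars_per_width > 1)
    seq(margin, n - 1 - margin, length.out = spec$bars_per_width) else
      (n - 1) / 2
  if (nw > 1 && diff(gx)[1] < max(l_px) + 6)
    stop("bars overlap: enlarge image_size or reduce widths/replicates")
  xs <- rep(gx, each = spec$bars_per_width)
  ys <- rep(gy, times = nw)
  angles <- rep_len(c(0, pi / 6, -pi / 4), length(xs))
  widths <- rep(spec$widths_nm, each = spec$bars_per_width)
  layout <- nanobar_layout(xs, ys, angles, widths,
                           rep(spec$length_nm, length(xs)), psz)
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE)
  yg <- matrix(0:(n - 1), n, n)
  lipid <- matrix(0, n, n)
  protein <- matrix(0, n, n)
  ee <- spec$enrichment(widths)
  for (i in seq_len(nrow(layout))) {
    mk <- stadium_masks(xg, yg, layout$x_px[i], layout$y_px[i],
                        layout$angle_rad[i], layout$width_nm[i] / psz,
                        layout$length_nm[i] / psz)
    lipid <- lipid + spec$lipid_amp * mk$all
    protein <- protein + spec$lipid_amp * spec$body_factor *
      (mk$body + ee[i] * mk$caps)
  }
  k <- gaussian_kernel(spec$psf_sigma_nm / psz)
  lipid <- EBImage::filter2(lipid, k)
  protein <- EBImage::filter2(protein, k)
  bg <- spec$background[["offset"]] + spec$background[["gx"]] * xg +
    spec$background[["gy"]] * yg
  lipid <- pmax(lipid + bg, 0)
  protein <- pmax(protein + bg, 0)
  # measurable (noise-free) end densities: what an ideal measurement of this
  # optical geometry yields -- sub-PSF caps mix with the bar body, so the
  # measurable profile differs from the raw programmed E at small widths
  ref_w <- if (600 %in% spec$widths_nm) 600 else max(spec$widths_nm)
  expected <- measure_nanobar_array(protein, lipid, layout, mode = "slb",
                                    ref_width = ref_w)
  if (isTRUE(spec$shot_noise)) {
    lipid <- matrix(stats::rpois(n * n, lipid), n, n)
    protein <- matrix(stats::rpois(n * n, protein), n, n)
  }
  if (spec$read_sd > 0) {
    lipid <- lipid + matrix(stats::rnorm(n * n, 0, spec$read_sd), n, n)
    protein <- protein + matrix(stats::rnorm(n * n, 0, spec$read_sd), n, n)
  }
  truth <- data.frame(bar_id = layout$bar_id, width_nm = widths,
                      end_enrichment = ee)
  truth$end_density_expected <-
    expected$end_density[match(widths, expected$width_nm)]
  out <- list(lipid = lipid, protein = protein, layout = layout,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sc <- max(c(lipid, protein)) * 1.05
    tiff::writeTIFF(list(lipid / sc, protein / sc),
                    file.path(dir, "nanobars.tif"), bits.per.sample = 16)
    write_layout_csv(layout, file.path(dir, "layout.csv"))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  out
}

#' Generate a synthetic single-particle field
#'
#' Gaussian spots (FWHM at the detection scale, default 0.65 um = 10 px at
#' 65 nm/px) at uniform random positions with a stated intensity law, over a
#' constant background with Poisson + Gaussian noise; emits a truth table of
#' positions and integrated intensities. Warns when the overlap fraction
#' (pairs closer than one FWHM) exceeds 5\%.
#'
#' @param n Number of spots.
#' @param intensity Integrated intensity per spot: a single number, a vector
#'   of length `n`, or a function(n) returning n values (e.g. a bimodal
#'   monomer/trimer law).
#' @param image_size Image edge (pixels).
#' @param fwhm_px Spot FWHM (pixels).
#' @param background Constant background (counts).
#' @param read_sd Gaussian read noise SD.
#' @param shot_noise Poisson noise on expected counts.
#' @param seed Integer seed.
#' @return List: `image`, `truth` (data.frame x, y, intensity),
#'   `overlap_fraction`.
#' @export
gen_particle_field <- function(n = 100, intensity = 2000, image_size = 1024,
                               fwhm_px = 10, background = 20, read_sd = 2,
                               shot_noise = TRUE, seed = 1L) {
  set.seed(as.integer(seed))
  m <- as.integer(image_size)
  margin <- 3 * fwhm_px
  x <- stats::runif(n, margin, m - 1 - margin)
  y <- stats::runif(n, margin, m - 1 - margin)
  ints <- if (is.function(intensity)) intensity(n) else
    rep_len(intensity, n)
  d2 <- as.matrix(stats::dist(cbind(x, y)))
  diag(d2) <- Inf
  overlap <- mean(apply(d2, 1, min) < fwhm_px)
  if (overlap > 0.05) {
    warning(sprintf("overcrowded field: %.1f%% of spots overlap",
                    100 * overlap))
  }
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  img <- matrix(background, m, m)
  half <- ceiling(4 * sigma)
  for (i in seq_len(n)) {
    ix <- round(x[i]); iy <- round(y[i])
    jj <- max(0, ix - half):min(m - 1, ix + half)
    ii <- max(0, iy - half):min(m - 1, iy + half)
    gx <- exp(-(jj - x[i])^2 / (2 * sigma^2))
    gy <- exp(-(ii - y[i])^2 / (2 * sigma^2))
    spot <- ints[i] / (2 * pi * sigma^2) * outer(gy, gx)
    img[ii + 1, jj + 1] <- img[ii + 1, jj + 1] + spot
  }
  if (isTRUE(shot_noise)) img <- matrix(stats::rpois(m * m, img), m, m)
  if (read_sd > 0) img <- img + matrix(stats::rnorm(m * m, 0, read_sd), m, m)
  list(image = img, truth = data.frame(x = x, y = y, intensity = ints),
       overlap_fraction = overlap)
}

#' Generate tabular fixtures for the curve-fitting routines
#'
#' Noisy evaluations of a Hill binding curve, a Gaussian response peak, or a
#' sigmoidal polymerization time series with a prescribed linear-phase slope;
#' the truth parameters ride along.
#'
#' @param kind "hill", "gaussian" or "timeseries".
#' @param params Named list of truth parameters. Hill: `K_half`, `n`,
#'   `plateau`; gaussian: `A`, `mu`, `sigma`; timeseries: `baseline`,
#'   `slope`, `t_on` (linear phase start), `t_off` (plateau start).
#' @param design Design points: concentrations (nM) for hill/gaussian
#'   (default the 7-point titration ladder 1, 2, 5, 10, 20, 100, 200 nM) or
#'   times (s) for the time series.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @param path Optional CSV output; truth parameters are embedded as header
#'   comments.
#' @return data.frame of the design and noisy response, with attribute
#'   `truth`.
#' @export
gen_tabular_fixtures <- function(kind = c("hill", "gaussian", "timeseries"),
                                 params = NULL, design = NULL, noise_sd = 0.1,
                                 seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  if (kind == "hill") {
    if (is.null(params)) params <- list(K_half = 50, n = 2, plateau = 10)
    if (is.null(design)) design <- c(1, 2, 5, 10, 20, 100, 200)
    y <- with(params, plateau * design^n / (K_half^n + design^n))
    df <- data.frame(conc_nM = design, response = y +
                       stats::rnorm(length(design), 0, noise_sd))
  } else if (kind == "gaussian") {
    if (is.null(params)) params <- list(A = 1, mu = 20, sigma = 25)
    if (is.null(design)) design <- c(1, 2, 5, 10, 20, 100, 200)
    y <- with(params, A * exp(-(design - mu)^2 / (2 * sigma^2)))
    df <- data.frame(conc_nM = design, response = y +
                       stats::rnorm(length(design), 0, noise_sd))
  } else {
    if (is.null(params)) params <- list(baseline = 0.2, slope = 0.02,
                                        t_on = 90, t_off = 380)
    if (is.null(design)) design <- seq(0, 450, by = 5)
    y <- with(params, baseline +
                slope * pmin(pmax(design - t_on, 0), t_off - t_on))
    df <- data.frame(time_s = design, intensity = y +
                       stats::rnorm(length(design), 0, noise_sd))
  }
  attr(df, "truth") <- params
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(paste0("# truth: ", paste(names(params), unlist(params),
                                         sep = "=", collapse = ", ")), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  df
}

#' Chemistry validation fixtures with analytic references
#'
#' Small well-mixed or two-compartment networks whose mean behaviour has a
#' closed form (or an independent ODE solution), for validating the
#' stochastic kinetics engine.
#'
#' @param kind "decay" (A -> 0, k = 1/s, N0 = 1000: N(t) = N0 e^{-kt}),
#'   "dimerize" (A + A -> B: reference from an independently integrated ODE),
#'   or "two_compartment" (pure hopping: equilibrium 50/50).
#' @return List: `net` (a [reaction_network()]), `counts0`, `reference`
#'   (function of time returning the mean prediction), `description`.
#' @export
gen_chem_fixture <- function(kind = c("decay", "dimerize",
                                      "two_compartment")) {
  kind <- match.arg(kind)
  if (kind == "decay") {
    net <- reaction_network("A", list(reaction(c(A = 1), NULL, k = 1)),
                            grid_spec(1L, 1L))
    list(net = net, counts0 = c(A = 1000L),
         reference = function(t) 1000 * exp(-t),
         description = "first-order decay, k = 1/s")
  } else if (kind == "dimerize") {
    g <- grid_spec(1L, 1L)
    k2 <- 1e6  # M^-1 s^-1
    net <- reaction_network(c("A", "B"),
                            list(reaction(c(A = 2), c(B = 1), k = k2)), g)
    v <- compartment_volume_l(g)
    n0 <- 1000
    # deterministic dimerization dA/dt = -2 c A(A-1)/2 ~ -c A^2, c = k/(NA V)
    cmeso <- mesoscopic_rate(k2, 2, v)
    ref <- function(t) n0 / (1 + cmeso * n0 * t)
    list(net = net, counts0 = c(A = 1000L, B = 0L), reference = ref,
         description = "dimerization vs independent ODE solution")
  } else {
    net <- reaction_network("A", list(), grid_spec(2L, 1L),
                            diffusion = c(A = 5))
    list(net = net,
         counts0 = matrix(c(1000L, 0L), nrow = 1),
         reference = function(t) c(500, 500),
         description = "two-compartment equilibration, 50/50 stationary")
  }
}
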