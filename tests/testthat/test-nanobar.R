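test_that("cropping is a bijection onto the layout and respects bounds", {
  img <- matrix(0, 200, 200)
  lay1 <- nanobar_layout(100, 100, 0, 300, 2000)
  cr <- crop_nanobars(img, lay1)
  expect_length(cr, 1)
  expect_identical(dim(cr[[1]]), c(71L, 71L))
  # many bars: order matches the layout
  set.seed(2)
  lay <- nanobar_layout(runif(12, 60, 140), runif(12, 60, 140),
                        runif(12, 0, pi), rep(300, 12), rep(1500, 12))
  cr12 <- crop_nanobars(img, lay)
  expect_length(cr12, 12)
  expect_identical(vapply(cr12, attr, numeric(1), "bar_id"),
                   setNames(as.numeric(1:12), names(cr12)))
  # out-of-bounds bar is skipped with a warning
  lay_bad <- nanobar_layout(c(100, 5), c(100, 5), c(0, 0), c(300, 300),
                            c(1500, 1500))
  expect_warning(cr_bad <- crop_nanobars(img, lay_bad), "skipped")
  expect_length(cr_bad, 1)
})

test_that("rotated bars come out with a horizontal major axis", {
  # build manually: one bar at 30 degrees
  n <- 240
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE)
  yg <- matrix(0:(n - 1), n, n)
  mk <- curvactin:::stadium_masks(xg, yg, 120, 120, pi / 6, 400 / 65,
                                  2000 / 65)
  chan <- EBImage::filter2(1000 * mk$all, curvactin:::gaussian_kernel(2.3))
  lay <- nanobar_layout(120, 120, pi / 6, 400, 2000)
  cr <- crop_nanobars(chan, lay)[[1]]
  cc <- background_correct(cr)
  # intensity-weighted second moments: major axis within 2 degrees of x
  w <- pmax(cc, 0)
  xs <- matrix(0:70, 71, 71, byrow = TRUE); ys <- matrix(0:70, 71, 71)
  mx <- sum(w * xs) / sum(w); my <- sum(w * ys) / sum(w)
  sxx <- sum(w * (xs - mx)^2); syy <- sum(w * (ys - my)^2)
  sxy <- sum(w * (xs - mx) * (ys - my))
  ang <- 0.5 * atan2(2 * sxy, sxx - syy)
  expect_lt(abs(ang) * 180 / pi, 2)
})

test_that("corner-mesh background correction removes planes", {
  # flat background plus an object
  set.seed(4)
  crop <- matrix(100, 71, 71)
  crop[30:40, 30:40] <- crop[30:40, 30:40] + 500
  cc <- background_correct(crop)
  expect_equal(mean(cc[1:8, 1:8]), 0, tolerance = 1e-9)
  expect_equal(max(cc), 500, tolerance = 1e-9)
  # pure linear gradient: residual mean below 1% of the range
  xg <- matrix(0:70, 71, 71, byrow = TRUE)
  yg <- matrix(0:70, 71, 71)
  plane <- 50 + 2 * xg - 1.2 * yg
  res <- background_correct(plane)
  expect_lt(abs(mean(res)), 0.01 * diff(range(plane)))
  # all-zero crop stays zero
  expect_true(all(background_correct(matrix(0, 71, 71)) == 0))
  # saturated corner falls back to the median of the others
  sat <- plane; sat[1:8, 1:8] <- 70000
  out <- background_correct(sat, saturation = 65535)
  expect_identical(attr(out, "saturated_corners"), "tl")
})

test_that("averaging is the pixelwise mean with 1/sqrt(N) noise reduction", {
  set.seed(5)
  base <- matrix(10, 71, 71)
  mk <- function(noise) {
    cr <- base + matrix(rnorm(71 * 71, sd = noise), 71, 71)
    attr(cr, "width_nm") <- 300; attr(cr, "length_nm") <- 2000
    cr
  }
  crops <- replicate(50, mk(1), simplify = FALSE)
  avg <- average_nanobar_stack(crops)[["300"]]
  expect_equal(attr(avg, "n"), 50L)
  expect_lt(sd(avg - base), 1.3 / sqrt(50))
  # identical crops average to themselves; single crop is identity
  same <- average_nanobar_stack(rep(crops[1], 4))[["300"]]
  expect_equal(unclass(same)[1:71, ], unclass(crops[[1]])[1:71, ])
  one <- average_nanobar_stack(crops[2])[["300"]]
  expect_equal(unclass(one)[1:71, ], unclass(crops[[2]])[1:71, ])
  bad <- crops[1:2]; bad[[2]] <- bad[[2]][1:51, 1:51]
  attr(bad[[2]], "width_nm") <- 300
  expect_error(average_nanobar_stack(bad), "mixed")
})

test_that("end/center quantification cancels channel-identical signals", {
  sp <- synthetic_array_spec(seed = 3, read_sd = 0, shot_noise = FALSE)
  img <- gen_nanobar_images(sp)
  # protein channel identical to lipid: density 1 for every width
  res <- measure_nanobar_array(img$lipid, img$lipid, img$layout, mode = "slb")
  expect_equal(res$end_density, rep(1, nrow(res)), tolerance = 1e-9)
  # global per-channel gain leaves densities invariant
  res_gain <- measure_nanobar_array(3.7 * img$protein, 0.4 * img$lipid,
                                    img$layout, mode = "slb")
  res_ref <- measure_nanobar_array(img$protein, img$lipid, img$layout,
                                   mode = "slb")
  expect_equal(res_gain$end_density, res_ref$end_density, tolerance = 1e-9)
  # uniform protein crop in cell mode: end-to-center ratio 1
  flatc <- matrix(7, 71, 71)
  q <- quantify_end_center(flatc, width_nm = 400, length_nm = 2000,
                           mode = "cell")
  expect_equal(q$end_to_center, 1, tolerance = 1e-12)
})

test_that("programmed end enrichment is recovered through the full pipeline", {
  sp <- synthetic_array_spec(seed = 17)
  img <- gen_nanobar_images(sp)
  res <- measure_nanobar_array(img$protein, img$lipid, img$layout,
                               mode = "slb")
  tr <- unique(img$truth[, c("width_nm", "end_density_expected",
                             "end_enrichment")])
  m <- merge(res, tr, by = "width_nm")
  expect_true(all(abs(m$end_density / m$end_density_expected - 1) < 0.05))
  # the recovered profile is monotone where the programmed one is
  m <- m[order(m$width_nm), ]
  expect_true(all(diff(m$end_density[m$width_nm <= 500]) < 0))
})

test_that("curvature-response regression matches lm and flags flat series", {
  w <- c(200, 300, 400, 500, 600, 800, 1000)
  set.seed(31)
  flat <- curvature_response_fit(rep(2, 7) + rnorm(7, sd = 1e-6), w)
  expect_lt(abs(flat$slope), 1e-3)
  expect_gt(flat$p.value, 0.05)
  set.seed(6)
  y <- 1 + 100 / w + rnorm(7, sd = 0.01)
  fit <- curvature_response_fit(y, w)
  expect_lt(abs(fit$slope - 100), 3 * fit$se)
  expect_lt(fit$p.value, 0.01)
  # identical series: slope-difference F ~ 0
  two <- curvature_response_fit(y, w, density2 = y)
  expect_lt(two$slope_diff_F, 1e-9)
  expect_error(curvature_response_fit(c(1, 2), c(200, 300)), "distinct")
})

test_that("Hill and Gaussian fits recover generator truth within 3 SE", {
  hf <- gen_tabular_fixtures("hill", params = list(K_half = 50, n = 2,
                                                   plateau = 10),
                             noise_sd = 0.1, seed = 21)
  fit <- binding_curve_fit(hf$conc_nM, hf$response, model = "hill")
  co <- fit$coefficients
  expect_lt(abs(co["K_half", 1] - 50), 3 * co["K_half", 2])
  expect_lt(abs(co["n", 1] - 2), 3 * co["n", 2])
  expect_lt(abs(co["plateau", 1] - 10), 3 * co["plateau", 2])
  expect_false(fit$flagged)
  # saturated design: K_half unidentifiable, flagged
  sat <- data.frame(conc_nM = c(100, 150, 200, 300),
                    response = 10 + rnorm(4, sd = 0.01))
  fit_sat <- binding_curve_fit(sat$conc_nM, sat$response, model = "hill")
  expect_true(fit_sat$flagged)
  # Gaussian peak near 20 nM
  gf <- gen_tabular_fixtures("gaussian", params = list(A = 1, mu = 20,
                                                       sigma = 25),
                             noise_sd = 0.02, seed = 22)
  fitg <- binding_curve_fit(gf$conc_nM, gf$response, model = "gaussian")
  cg <- fitg$coefficients
  expect_lt(abs(cg["mu", 1] - 20), 3 * cg["mu", 2])
})

test_that("rate_slope fits the linear window", {
  tt <- seq(0, 450, by = 5)
  suppressWarnings({
    expect_lt(abs(rate_slope(tt, rep(3, length(tt)))$slope), 1e-12)
    y <- 0.5 + 0.02 * tt
    expect_equal(rate_slope(tt, y)$slope, 0.02, tolerance = 1e-12)
  })
  ts <- gen_tabular_fixtures("timeseries",
                             params = list(baseline = 0.1, slope = 0.015,
                                           t_on = 90, t_off = 380),
                             noise_sd = 0.02, seed = 9)
  rs <- rate_slope(ts$time_s, ts$intensity)
  expect_lt(abs(rs$slope - 0.015), 3 * rs$se)
  expect_error(rate_slope(c(0, 500), c(1, 2)), "window")
})

test_that("spot detection hits planted particles and stays quiet on blanks", {
  set.seed(10)
  blank <- matrix(rnorm(512^2, 100, 5), 512, 512)
  expect_identical(nrow(particle_quantify(blank)), 0L)
  pf <- gen_particle_field(n = 100, intensity = 2000, seed = 13)
  det <- particle_quantify(pf$image)
  expect_gte(nrow(det), 95)
  expect_lt(abs(median(det$intensity) / 2000 - 1), 0.1)
  # intensity integration is linear: 3x spots give a 3x median
  pf3 <- gen_particle_field(n = 100, intensity = 6000, seed = 13)
  det3 <- particle_quantify(pf3$image)
  expect_equal(median(det3$intensity) / median(det$intensity), 3,
               tolerance = 0.1)
  # detections match planted positions within a pixel
  near <- vapply(seq_len(nrow(det)), function(k) {
    min(sqrt((pf$truth$x - det$x[k])^2 + (pf$truth$y - det$y[k])^2))
  }, numeric(1))
  expect_lt(median(near), 1)
  sub <- sample_particles(det, n = 20, seed = 2)
  expect_identical(nrow(sub), 20L)
})
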