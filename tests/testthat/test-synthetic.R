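test_that("generators are pure functions of (spec, seed)", {
  sp <- synthetic_array_spec(image_size = 280, widths_nm = c(300, 600),
                             bars_per_width = 1, seed = 31)
  a <- gen_nanobar_images(sp)
  b <- gen_nanobar_images(sp)
  expect_identical(a$lipid, b$lipid)
  expect_identical(a$protein, b$protein)
  sp2 <- sp; sp2$seed <- 32L
  c_ <- gen_nanobar_images(sp2)
  expect_false(identical(a$protein, c_$protein))
  suppressWarnings({
    p1 <- gen_particle_field(n = 20, seed = 3)
    p2 <- gen_particle_field(n = 20, seed = 3)
  })
  expect_identical(p1$image, p2$image)
  t1 <- gen_tabular_fixtures("hill", seed = 5)
  t2 <- gen_tabular_fixtures("hill", seed = 5)
  expect_identical(t1, t2)
})

test_that("nanobar generator writes the TIFF/CSV bundle with truth sidecar", {
  dir <- tempfile("arr")
  sp <- synthetic_array_spec(image_size = 280, widths_nm = c(300, 600),
                             bars_per_width = 1, seed = 7)
  out <- gen_nanobar_images(sp, dir = dir)
  expect_true(file.exists(file.path(dir, "nanobars.tif")))
  expect_true(file.exists(file.path(dir, "layout.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  pages <- tiff::readTIFF(file.path(dir, "nanobars.tif"), all = TRUE)
  expect_length(pages, 2)
  lay <- read_layout_csv(file.path(dir, "layout.csv"))
  expect_identical(nrow(lay), nrow(out$layout))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_true(all(c("end_enrichment", "end_density_expected") %in%
                    names(truth)))
})

test_that("the null (no-enrichment) array measures ratio ~ 1 everywhere", {
  sp <- synthetic_array_spec(seed = 41,
                             enrichment = function(w) rep(1, length(w)))
  img <- gen_nanobar_images(sp)
  res <- measure_nanobar_array(img$protein, img$lipid, img$layout,
                               mode = "slb")
  expect_true(all(abs(res$end_density - 1) < 0.05))
})

test_that("generated images meet the stated noise model", {
  # SNR at the bar: signal / sd over a uniform bar region, measured post hoc
  sp <- synthetic_array_spec(image_size = 280, widths_nm = 600,
                             bars_per_width = 1, length_nm = 2000,
                             background = c(offset = 100, gx = 0, gy = 0),
                             seed = 51)
  img <- gen_nanobar_images(sp)
  sp_clean <- sp
  sp_clean$shot_noise <- FALSE
  sp_clean$read_sd <- 0
  clean <- gen_nanobar_images(sp_clean)  # same deterministic layout/optics
  # central body pixels of the single bar
  cx <- round(img$layout$x_px[1]) + 1
  cy <- round(img$layout$y_px[1]) + 1
  ii <- cy + (-2:2); jj <- cx + (-6:6)
  noise <- img$lipid[ii, jj] - clean$lipid[ii, jj]
  signal <- mean(clean$lipid[ii, jj]) - sp$background[["offset"]]
  expect_gt(signal / sd(noise), 10)
  # shot-noise dominated: noise variance tracks the expected counts
  ratio <- var(as.numeric(noise)) /
    (mean(clean$lipid[ii, jj]) + sp$read_sd^2)
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.6)
})

test_that("particle fields report overlap and bimodal laws survive detection", {
  expect_warning(gen_particle_field(n = 400, image_size = 512, seed = 2),
                 "overcrowded")
  law <- function(n) sample(c(1000, 3000), n, replace = TRUE, prob = c(.5, .5))
  pf <- gen_particle_field(n = 80, intensity = law, seed = 5)
  det <- particle_quantify(pf$image)
  km <- stats::kmeans(det$intensity, centers = 2)
  expect_equal(max(km$centers) / min(km$centers), 3, tolerance = 0.15)
  # truth table holds n rows and the total flux
  expect_identical(nrow(pf$truth), 80L)
})

test_that("tabular fixtures embed truth and honor zero noise", {
  exact <- gen_tabular_fixtures("hill", noise_sd = 0, seed = 1)
  tr <- attr(exact, "truth")
  y <- tr$plateau * exact$conc_nM^tr$n / (tr$K_half^tr$n + exact$conc_nM^tr$n)
  expect_equal(exact$response, y)
  expect_identical(exact$conc_nM, c(1, 2, 5, 10, 20, 100, 200))
  f <- tempfile(fileext = ".csv")
  gen_tabular_fixtures("timeseries", noise_sd = 0, seed = 1, path = f)
  lines <- readLines(f)
  expect_match(lines[1], "^# truth")
})

test_that("chemistry fixtures expose their analytic references", {
  d <- gen_chem_fixture("decay")
  expect_equal(d$reference(0), 1000)
  expect_equal(d$reference(1), 1000 * exp(-1))
  tc <- gen_chem_fixture("two_compartment")
  expect_equal(tc$reference(10), c(500, 500))
  dm <- gen_chem_fixture("dimerize")
  expect_lt(dm$reference(10), 1000)
})
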