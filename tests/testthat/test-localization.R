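test_that("Shannon entropy has the analytic values and bounds", {
  g <- grid_spec()
  n <- g$nx * g$ny
  expect_equal(shannon_entropy(rep(1 / n, n)), log(256))
  expect_equal(shannon_entropy(c(1, rep(0, 99))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, rep(0, 10))), log(2))
  # bounds across random distributions
  set.seed(1)
  for (i in 1:20) {
    p <- stats::rexp(64); p <- p / sum(p)
    s <- shannon_entropy(p)
    expect_gte(s, 0)
    expect_lte(s, log(64) + 1e-12)
  }
})

test_that("invalid distributions are rejected", {
  expect_error(shannon_entropy(c(0.5, 0.6)), "invalid")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "invalid")
})

test_that("optimize_density hits the entropy target for all studied f", {
  g <- grid_spec()
  s_max <- log(256)
  for (f in c(1.0, 0.99, 0.95, 0.8, 0.5)) {
    d <- optimize_density(g, f, seed = 11)
    expect_lte(abs(d$entropy - f * s_max) / s_max, 1e-3)
    expect_true(all(d$p >= 0))
    expect_equal(sum(d$p), 1, tolerance = 1e-9)
    # stored entropy consistent with recomputation
    expect_equal(shannon_entropy(d$p), d$entropy, tolerance = 1e-9)
  }
  # f = 1 is the exact uniform maximizer
  d1 <- optimize_density(g, 1, seed = 1)
  expect_equal(as.numeric(d1$p), rep(1 / 256, 256))
})

test_that("optimizer is deterministic and rejects degenerate f", {
  g <- grid_spec()
  a <- optimize_density(g, 0.8, seed = 5, restarts = 4)
  b <- optimize_density(g, 0.8, seed = 5, restarts = 4)
  expect_identical(a$p, b$p)
  expect_error(optimize_density(g, 0), "localization factor")
  expect_error(optimize_density(g, 1.2), "localization factor")
  expect_error(optimize_density(g, 0.01), "degenerate")
})

test_that("entropy constraint is log-base invariant", {
  d <- optimize_density(grid_spec(), 0.6, seed = 2)
  s2 <- -sum(d$p[d$p > 0] * log2(d$p[d$p > 0]))
  expect_equal(s2 / log2(256), 0.6, tolerance = 1e-3)
})

test_that("copy totals follow the unit conversion", {
  g <- grid_spec()
  # independent hand computation: c * N_A * V
  expect_identical(copies_from_concentration(1, g),
                   as.integer(round(1e-6 * AVOGADRO_TEST * 3.2e-14)))
  expect_identical(copies_from_concentration(1, g), 19271L)
  expect_identical(copies_from_concentration(0.01, g), 193L)
  expect_error(copies_from_concentration(0, g), "positive")
})

test_that("multinomial sampling respects the total and the support", {
  g <- grid_spec()
  d <- optimize_density(g, 0.8, seed = 3)
  m <- sample_copy_map(d, 1000L, seed = 4)
  expect_identical(sum(m$counts), 1000L)
  m0 <- sample_copy_map(d, 0L, seed = 4)
  expect_true(all(m0$counts == 0L))
  # degenerate density forces all mass into one compartment
  dg <- d
  p <- matrix(0, g$ny, g$nx); p[3, 5] <- 1
  dg$p <- p; dg$entropy <- 0
  md <- sample_copy_map(dg, 100L, seed = 1)
  expect_identical(md$counts[3, 5], 100L)
  expect_identical(sum(md$counts), 100L)
})

test_that("uniform sampling matches multinomial moments", {
  g <- grid_spec()
  d1 <- optimize_density(g, 1, seed = 1)
  means <- replicate(100, {
    m <- sample_copy_map(d1, 19271L, seed = sample.int(1e6, 1))
    mean(m$counts)
  })
  expect_equal(mean(means), 19271 / 256, tolerance = 1e-6)  # exact by total
})

test_that("relative entropy error is small at 1 uM and vanishes at huge totals", {
  g <- grid_spec()
  d <- optimize_density(g, 0.5, seed = 6)
  err_huge <- relative_entropy_error(sample_copy_map(d, 1e8, seed = 1), d)
  expect_lt(err_huge, 0.01)
  err_1um <- relative_entropy_error(
    sample_copy_map(d, copies_from_concentration(1, g), seed = 2), d)
  expect_lt(err_1um, 1)
  err_small <- relative_entropy_error(sample_copy_map(d, 193L, seed = 2), d)
  expect_gt(err_small, err_1um)
})

test_that("median sampling error is non-increasing in the total", {
  g <- grid_spec()
  d <- optimize_density(g, 0.8, seed = 7)
  med <- vapply(c(200L, 2000L, 19271L), function(total) {
    stats::median(vapply(1:20, function(s)
      as.numeric(relative_entropy_error(
        sample_copy_map(d, total, seed = s), d)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("map CSV serialization round-trips", {
  g <- grid_spec()
  d <- optimize_density(g, 0.9, seed = 8)
  f <- tempfile(fileext = ".csv")
  write_map_csv(d, f)
  expect_equal(read_map_csv(f, g), unname(d$p), tolerance = 1e-12)
})
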