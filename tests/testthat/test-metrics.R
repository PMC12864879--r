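# minimal trajectory stub with a chosen final filament count
stub_traj <- function(counts, times = 0:4) {
  structure(list(
    series = data.frame(time = times,
                        n_filaments = rep_len(counts, length(times)),
                        n_branches = 0),
    snapshot = list(beads = matrix(numeric(0), 0, 3), fil = integer(0),
                    bonds = data.frame(parent = integer(0),
                                       child = integer(0)))),
    class = "actin_trajectory")
}

test_that("filament series mean and SEM follow hand computation", {
  trs <- lapply(c(8, 9, 10, 11, 12), stub_traj)
  fc <- filament_count_series(trs)
  expect_equal(fc$mean, rep(10, 5))
  expect_equal(fc$sem, rep(stats::sd(8:12) / sqrt(5), 5))
  expect_equal(fc$sem[1], 0.7071, tolerance = 1e-4)
  # single trajectory: SEM 0 by convention
  one <- filament_count_series(trs[1])
  expect_true(all(one$sem == 0))
  ident <- filament_count_series(rep(trs[3], 5))
  expect_true(all(ident$sem == 0))
  bad <- stub_traj(5, times = c(0, 2, 4, 6, 8))
  expect_error(filament_count_series(list(trs[[1]], bad)), "misaligned")
})

# hand-built snapshot: filaments as short vertical segments at given xy
make_snapshot <- function(fil_xy, bonds) {
  beads <- NULL; fil <- NULL
  for (i in seq_len(nrow(fil_xy))) {
    beads <- rbind(beads, c(fil_xy[i, 1], fil_xy[i, 2], 0),
                   c(fil_xy[i, 1] + 27, fil_xy[i, 2], 0))
    fil <- c(fil, i, i)
  }
  list(beads = beads, fil = fil, bonds = bonds)
}

test_that("branch clusters are connected components of the bond graph", {
  # star: filament 1 with offspring 2, 3, 4; filaments 5, 6 unbranched
  xy <- cbind(c(0, 50, 100, 150, 4000, 5000), c(0, 50, 100, 150, 4000, 5000))
  snap <- make_snapshot(xy, data.frame(parent = c(1, 1, 1),
                                       child = c(2, 3, 4)))
  cl <- identify_branch_clusters(snap)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_filaments, 4L)
  expect_identical(cl$n_branches, 3L)
  # unbranched-only snapshot: no clusters
  snap0 <- make_snapshot(xy[5:6, , drop = FALSE],
                         data.frame(parent = integer(0), child = integer(0)))
  expect_identical(nrow(identify_branch_clusters(snap0)), 0L)
  # binary cascade of depth 3: 8 filaments, 7 branches, one cluster
  bonds <- data.frame(parent = c(1, 1, 2, 2, 3, 3, 4),
                      child = c(2, 3, 4, 5, 6, 7, 8))
  xy8 <- cbind(seq(0, 700, by = 100), seq(0, 700, by = 100))
  snap8 <- make_snapshot(xy8, bonds)
  cl8 <- identify_branch_clusters(snap8)
  expect_identical(nrow(cl8), 1L)
  expect_identical(cl8$n_branches, 7L)
  # cluster branch counts sum to the global bond count across components
  bonds2 <- rbind(bonds, data.frame(parent = c(9, 9), child = c(10, 11)))
  xy11 <- cbind(seq(0, 1000, by = 100), rep(0, 11))
  cl2 <- identify_branch_clusters(make_snapshot(xy11, bonds2))
  expect_identical(sum(cl2$n_branches), nrow(bonds2))
})

test_that("branch density scaling is homogeneous and floored", {
  cl <- data.frame(n_branches = 5, hull_area_um2 = 1)
  expect_equal(branches_per_area_scaled(cl, 400), 2000)
  # degree-1 homogeneity in the reference area
  expect_equal(branches_per_area_scaled(cl, 800),
               2 * branches_per_area_scaled(cl, 400))
  # doubling branches and hull leaves the density unchanged
  cl2 <- data.frame(n_branches = 10, hull_area_um2 = 2)
  expect_equal(branches_per_area_scaled(cl2, 400),
               branches_per_area_scaled(cl, 400))
  # tiny hulls use the floor
  cl3 <- data.frame(n_branches = 2, hull_area_um2 = 0.01)
  expect_equal(branches_per_area_scaled(cl3, 400, area_floor = 0.25),
               2 / 0.25 * 400)
  expect_length(branches_per_area_scaled(cl[0, ], 400), 0)
})

test_that("poisson-process snapshots recover the programmed branch density", {
  # one big cluster: spatial Poisson branches over a known hull
  set.seed(8)
  n_b <- 400; side <- 4000  # 4 x 4 um, density 25 branches / um^2
  beads <- cbind(stats::runif(n_b + 1, 0, side),
                 stats::runif(n_b + 1, 0, side), 0)
  # chain bonds so all filaments form one component
  snap <- list(beads = rbind(beads, beads + c(13.5, 0, 0)),
               fil = rep(seq_len(n_b + 1), 2),
               bonds = data.frame(parent = seq_len(n_b), child = 2:(n_b + 1)))
  cl <- identify_branch_clusters(snap)
  scaled <- branches_per_area_scaled(cl, 400)
  expect_equal(scaled, 400 * 25, tolerance = 0.15)
})

test_that("localization summary ranks metrics against f", {
  mk <- function(f_counts) {
    out <- list()
    for (nm in names(f_counts)) {
      out[[nm]] <- lapply(f_counts[[nm]], stub_traj)
    }
    out
  }
  # strictly decreasing in f: rho = -1
  res <- mk(list("0.5" = c(30, 31), "0.8" = c(20, 21), "1" = c(10, 11)))
  sm <- localization_response_summary(res)
  rho <- sm$spearman$rho[sm$spearman$metric == "filaments"]
  # ties within f cap |rho| slightly below 1
  expect_lt(rho, -0.9)
  expect_lt(sm$spearman$p.value[sm$spearman$metric == "filaments"], 0.05)
  expect_true(all(diff(sm$table$mean_filaments) < 0))
  # identical results: rho undefined/flagged
  res2 <- mk(list("0.5" = c(10, 10), "1" = c(10, 10)))
  sm2 <- localization_response_summary(res2)
  expect_true(is.na(sm2$spearman$rho[sm2$spearman$metric == "filaments"]))
  # single f value: table only
  sm3 <- localization_response_summary(mk(list("0.8" = c(5, 6))))
  expect_null(sm3$spearman)
})
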