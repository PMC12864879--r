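test_that("closed-form energies at reference and displaced geometries", {
  expect_equal(stretch_energy(27, 27, 100), 0)
  expect_equal(stretch_energy(28, 27, 100), 50)
  expect_equal(stretch_gradient(28, 27, 100), 100)
  expect_equal(bend_energy(0, 1000), 0)
  expect_equal(bend_energy(pi / 2, 1000), 1000)
  th <- seq(0, pi, length.out = 50)
  expect_true(all(diff(bend_energy(th, 10)) > 0))
  expect_equal(boundary_energy(0, 100, 2.7), 100)
  expect_equal(boundary_energy(2.7, 100, 2.7), 100 * exp(-1))
  # force matches a finite difference of the energy
  d <- 2.7; h <- 1e-6
  fd <- -(boundary_energy(d + h) - boundary_energy(d - h)) / (2 * h)
  expect_equal(boundary_force(d), fd, tolerance = 1e-6)
})

test_that("bending constant derives from the persistence length", {
  expect_equal(k_bend_from_persistence(17000, 4.11, 27), 17000 * 4.11 / 27)
})

test_that("excluded volume decays as the 4th power and matches quadrature oracle", {
  s1 <- rbind(c(0, 0, 0), c(1, 0, 0))
  s2 <- function(d) rbind(c(0, d, 0), c(1, d, 0))
  e10 <- excluded_volume_energy(s1, s2(10))
  e20 <- excluded_volume_energy(s1, s2(20))
  expect_equal(e10 / e20, 16, tolerance = 0.01)
  expect_lt(excluded_volume_energy(s1, s2(1e6)),
            1e-12 * excluded_volume_energy(s1, s2(100)))
  # adaptive double-quadrature oracle on skew segments
  p0 <- c(0, 0, 0); p1 <- c(27, 3, 1); q0 <- c(5, 12, 4); q1 <- c(30, 18, -6)
  fd <- function(s, t) {  # elementwise in (s, t), as integral2 requires
    r2 <- 0
    for (m in 1:3) {
      r2 <- r2 + (((1 - s) * p0[m] + s * p1[m]) -
                    ((1 - t) * q0[m] + t * q1[m]))^2
    }
    1 / r2^2
  }
  oracle <- pracma::integral2(fd, 0, 1, 0, 1, reltol = 1e-10)$Q
  ev <- excluded_volume_energy(rbind(p0, p1), rbind(q0, q1), kvol = 1)
  expect_equal(ev, oracle, tolerance = 0.01)
  # near-intersecting axes stay finite (singularity cap)
  touching <- excluded_volume_energy(rbind(c(0, 0, 0), c(10, 0, 0)),
                                     rbind(c(5, 0.01, 0), c(5, 10, 0)))
  expect_true(is.finite(touching))
  expect_error(excluded_volume_energy(rbind(c(0, 0, 0), c(0, 0, 0)), s1),
               "degenerate")
})

test_that("branch energies vanish at the ideal 70-degree geometry", {
  parent <- rbind(c(0, 0, 0), c(27, 0, 0))
  p <- mech_params()
  # offspring at 90-degree bond, 70-degree tilt, in plane
  bdir <- c(0, 1, 0)
  v <- cos(1.222) * c(1, 0, 0) + sin(1.222) * bdir
  C <- c(13.5, 0, 0) + p$L0_bond * bdir
  off <- rbind(C, C + 2.7 * v)
  be <- branch_energies(parent, 0.5, off, p)
  expect_equal(be$stretch, 0, tolerance = 1e-9)
  expect_equal(be$bend_I, 0, tolerance = 1e-9)
  expect_equal(be$bend_II, 0, tolerance = 1e-9)
  # dihedral sits at its minimum -k for the coplanar branch
  expect_equal(be$dihedral, -p$k_branch_dihedral, tolerance = 1e-9)
  # 90-degree tilt instead of 70: bend_II = k (1 - cos(0.3488))
  v2 <- c(0, 1, 0)
  off2 <- rbind(C, C + 2.7 * v2)
  be2 <- branch_energies(parent, 0.5, off2, p)
  expect_equal(be2$bend_II, p$k_branch_bend2 * (1 - cos(pi / 2 - 1.222)),
               tolerance = 1e-9)
  # collinear parent and bond: dihedral undefined, skipped with a flag
  off3 <- rbind(c(40, 0, 0), c(45, 3, 0))
  be3 <- branch_energies(parent, 0.5, off3, p)
  expect_true(be3$dihedral_skipped)
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:5) {
    sys <- random_branched_system(seed)
    gr <- mech_gradient(sys)
    fd <- fd_gradient(sys)
    scale <- max(abs(fd))
    expect_lt(max(abs(gr - fd)) / scale, 1e-5)
  }
})

test_that("internal energies are invariant under rigid-body transforms", {
  sys <- random_branched_system(7)
  sys$params$eps_boundary <- 0  # boundary term is frame-dependent
  e0 <- mech_energy(sys)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  sys2 <- sys
  sys2$beads <- sweep(sys$beads %*% t(R %*% R2), 2, c(123, -77, 31), "+")
  e1 <- mech_energy(sys2)
  for (term in c("stretch", "bend", "excluded", "branch_stretch",
                 "branch_bend_I", "branch_bend_II", "branch_dihedral")) {
    expect_equal(e1[[term]], e0[[term]], tolerance = 1e-9)
  }
})

test_that("energy is additive over filaments", {
  sf1 <- straight_filament(3, start = c(1000, 1000, 250))
  sf2 <- straight_filament(3, start = c(5000, 5000, 250), dir = c(0, 1, 0))
  both <- filament_system(rbind(sf1$beads, sf2$beads),
                          c(sf1$fil, rep(2L, 4)))
  single1 <- filament_system(sf1$beads, sf1$fil)
  single2 <- filament_system(sf2$beads, rep(1L, 4))
  # filaments are farther apart than the excluded-volume cutoff
  expect_equal(mech_energy(both)$total,
               mech_energy(single1)$total + mech_energy(single2)$total,
               tolerance = 1e-9)
})

test_that("minimization relaxes perturbations with a non-increasing trace", {
  sf <- straight_filament(4, start = c(3000, 3000, 250))
  sys <- filament_system(sf$beads, sf$fil)
  # already relaxed: converged immediately
  r0 <- minimize_energy(sys, tol = 1)
  expect_true(attr(r0, "converged"))
  expect_identical(attr(r0, "iters"), 0L)
  # single displaced bead relaxes back
  sysd <- sys
  sysd$beads[2, 2] <- sysd$beads[2, 2] + 5
  rel <- minimize_energy(sysd, tol = 0.01)
  e <- mech_energy(rel)
  expect_lt(e$stretch + e$bend, 1e-3)
  expect_true(all(diff(attr(rel, "energy_trace")) <= 1e-9))
  # random 3-filament tangle: strictly monotone trace
  set.seed(42)
  beads <- NULL; fil <- NULL
  for (k in 1:3) {
    sfk <- straight_filament(4, start = c(3800, 3800, 230) +
                               stats::runif(3, 0, 80),
                             dir = stats::rnorm(3))
    beads <- rbind(beads, sfk$beads + matrix(stats::rnorm(15, sd = 2), 5, 3))
    fil <- c(fil, rep(k, 5))
  }
  tangle <- filament_system(beads, fil)
  relt <- minimize_energy(tangle, tol = 0.5)
  expect_true(all(diff(attr(relt, "energy_trace")) <= 1e-9))
  expect_lt(mech_energy(relt)$total, mech_energy(tangle)$total)
})

test_that("ratchet factor follows the exponential force law", {
  expect_identical(ratchet_rate(1, 0), 1)
  expect_identical(ratchet_rate(2, 1.5, 1.5), 2 * exp(-1))
  expect_equal(ratchet_rate(1, 15, 1.5), exp(-10), tolerance = 1e-12)
  # negative projections clamp to zero load
  expect_identical(ratchet_rate(1, -3), 1)
})
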