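test_that("the network instantiates the stated copy numbers", {
  net <- build_dendritic_network(dendritic_config())
  expect_identical(net$initial_copies[["G_actin"]], 19271L)
  expect_identical(net$initial_copies[["Arp23_inactive"]], 193L)
  expect_identical(net$initial_copies[["NWASP"]], 19271L)
  expect_false(net$species$diffusible[net$species$name == "NWASP"])
  expect_false(net$species$diffusible[net$species$name == "Arp23_active"])
  expect_warning(
    build_dendritic_network(dendritic_config(n_seeds = 0, k_nucleate = 0)),
    "absorbing")
})

test_that("confining the activator raises the local activation propensity", {
  g <- grid_spec()
  vr <- compartment_volume_l(g)
  act <- reaction(c(NWASP = 1, ArpI = 1), c(NWASP = 1, ArpA = 1), k = 1e5)
  nw_total <- 19271
  # all N-WASP in one compartment vs spread over 256 (one inactive Arp2/3
  # present locally in either case)
  a_conf <- propensity(act, c(NWASP = nw_total, ArpI = 1), vr)
  a_unif_sum <- 256 * propensity(act, c(NWASP = nw_total / 256, ArpI = 1), vr)
  expect_equal(a_conf, a_unif_sum, tolerance = 1e-12)  # same total
  # but the local rate in the confined compartment dominates any single
  # uniform compartment by the localization factor
  a_unif_one <- propensity(act, c(NWASP = nw_total / 256, ArpI = 1), vr)
  expect_gt(a_conf, 250 * a_unif_one)
})

test_that("event geometry: polymerization, inversion and branching", {
  sf <- straight_filament(2, start = c(3000, 3000, 250))
  sys <- filament_system(sf$beads, sf$fil)
  contour <- function(s) {
    rows <- which(s$fil == 1)
    sum(sqrt(rowSums((s$beads[rows[-1], , drop = FALSE] -
                        s$beads[rows[-length(rows)], , drop = FALSE])^2)))
  }
  c0 <- contour(sys)
  s10 <- sys
  for (i in 1:10) s10 <- apply_event_geometry(s10, list(type = "polymerize",
                                                        filament = 1))
  expect_equal(contour(s10), c0 + 27, tolerance = 1e-9)
  expect_identical(sum(s10$fil == 1), 4L)  # one new bead
  # polymerize then depolymerize restores the geometry
  s1 <- apply_event_geometry(sys, list(type = "polymerize", filament = 1))
  s2 <- apply_event_geometry(s1, list(type = "depolymerize", filament = 1))
  expect_equal(unname(s2$beads), unname(sys$beads), tolerance = 1e-9)
  # branch at 70 degrees before minimization
  sb <- apply_event_geometry(sys, list(type = "branch", filament = 1,
                                       arc = 13.5, azimuth = 0.4))
  rows_p <- which(sb$fil == 1); rows_o <- which(sb$fil == 2)
  u <- sb$beads[rows_p[2], ] - sb$beads[rows_p[1], ]
  v <- sb$beads[rows_o[2], ] - sb$beads[rows_o[1], ]
  ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  expect_equal(ang, sys$params$theta_branch, tolerance = 1e-6)
  expect_identical(nrow(sb$bonds), 1L)
})

test_that("ablations: no branching reactions means no new filaments", {
  cfg <- tiny_sim_config(k_branch = 0)
  tr <- run_simulation(cfg, f = 1, seed = 3)
  expect_true(all(tr$series$n_branches == 0))
  cfg2 <- tiny_sim_config(k_act = 0)
  tr2 <- run_simulation(cfg2, f = 1, seed = 3)
  expect_true(all(tr2$series$Arp23_active == 0))
  expect_true(all(tr2$series$n_filaments <= cfg2$n_seeds))
})

test_that("mass conservation holds at every snapshot", {
  tr <- run_simulation(tiny_sim_config(), f = 0.8, seed = 5)
  s <- tr$series
  expect_true(all(s$G_actin + s$polymerized ==
                    s$G_actin[1] + s$polymerized[1]))
  # Arp2/3 pools: inactive + active + branch-incorporated + de novo caps
  expect_true(all(s$Arp23_inactive + s$Arp23_active + s$n_branches +
                    s$n_denovo == s$Arp23_inactive[1]))
  # filament count ties to the event log
  expect_identical(
    s$n_filaments[nrow(s)],
    tr$config$n_seeds + tr$counts$branch + tr$counts$denovo +
      tr$counts$spontaneous - tr$counts$removed)
})

test_that("nucleation pathways create filaments as configured", {
  # de novo only: new filaments without any branch bonds
  cfg <- tiny_sim_config(k_branch = 0, k_nucleate = 5)
  tr <- run_simulation(cfg, f = 0.5, seed = 4)
  expect_gt(tr$counts$denovo, 0)
  expect_identical(tr$counts$branch, 0)
  expect_gt(tail(tr$series$n_filaments, 1), cfg$n_seeds)
  # spontaneous pathway works without any Arp2/3 activation
  cfg0 <- tiny_sim_config(k_act = 0, k_nucleate = 0, n_seeds = 0,
                          spontaneous_nucleation = TRUE, k_spont = 0.05)
  tr0 <- run_simulation(cfg0, f = 1, seed = 4)
  expect_gt(tr0$counts$spontaneous, 0)
  expect_identical(tr0$counts$denovo, 0)
})

test_that("trajectories are bit-identical under a fixed seed", {
  cfg <- tiny_sim_config()
  a <- run_simulation(cfg, f = 0.8, seed = 11)
  b <- run_simulation(cfg, f = 0.8, seed = 11)
  expect_identical(a$series, b$series)
  expect_identical(a$snapshot$beads, b$snapshot$beads)
  c_ <- run_simulation(cfg, f = 0.8, seed = 12)
  expect_false(identical(a$series, c_$series))
})

test_that("snapshot times are strictly increasing and energy is finite", {
  tr <- run_simulation(tiny_sim_config(), f = 0.9, seed = 2)
  expect_true(all(diff(tr$series$time) > 0))
  expect_true(all(is.finite(tr$series$energy)))
})
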