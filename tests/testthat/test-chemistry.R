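test_that("mesoscopic rates follow the volume scaling", {
  expect_equal(mesoscopic_rate(1, 1, 1e-15), 1)
  # k = 10 uM^-1 s^-1 in a 0.125 um^3 compartment
  expect_equal(mesoscopic_rate(1e7, 2, 1.25e-16),
               1e7 / (AVOGADRO_TEST * 1.25e-16), tolerance = 1e-12)
  expect_equal(mesoscopic_rate(1e7, 2, 1.25e-16), 0.1329, tolerance = 1e-3)
  expect_equal(mesoscopic_rate(1e7, 2, 2 * 1.25e-16),
               mesoscopic_rate(1e7, 2, 1.25e-16) / 2)
  expect_error(mesoscopic_rate(1, 3, 1e-15), "not implemented")
})

test_that("propensities carry the right degeneracy", {
  v <- 1.25e-16
  hetero <- reaction(c(A = 1, B = 1), c(C = 1), k = 1 / mesoscopic_rate(1, 2, v))
  # A + B with N_A = 2, N_B = 3 and c = 1 gives a = 6
  expect_equal(propensity(hetero, c(A = 2, B = 3, C = 0), v), 6,
               tolerance = 1e-9)
  expect_equal(propensity(hetero, c(A = 0, B = 3, C = 0), v), 0)
  homo <- reaction(c(A = 2), c(B = 1), k = 1 / mesoscopic_rate(1, 2, v))
  # A + A with N = 4: gamma = C(4, 2) = 6
  expect_equal(propensity(homo, c(A = 4, B = 0), v), 6, tolerance = 1e-9)
  expect_equal(propensity(homo, c(A = 1, B = 0), v), 0)
})

test_that("tentative times follow the exponential closed form", {
  expect_equal(draw_tentative_time(2, exp(-2)), 1)
  expect_identical(draw_tentative_time(0, 0.5), Inf)
  expect_error(draw_tentative_time(1, 0), "strictly")
  expect_error(draw_tentative_time(1, 1), "strictly")
  set.seed(3)
  taus <- vapply(stats::runif(1e5), function(r) draw_tentative_time(1, r),
                 numeric(1))
  expect_lt(abs(mean(taus) - 1), 3 / sqrt(1e5))
})

test_that("hop rates are D/h^2 per neighbour and immobile species error", {
  g <- grid_spec()
  expect_equal(diffusion_hop_rates(TRUE, 20, g), 80)
  expect_error(diffusion_hop_rates(FALSE, 20, g), "contract violation")
})

test_that("a single-step NRM consumes the reactant and advances the clock", {
  net <- reaction_network(c("A", "B"),
                          list(reaction(c(A = 1), c(B = 1), k = 1)),
                          grid_spec(1L, 1L))
  st <- nrm_state(net, c(A = 1L), seed = 2)
  st2 <- next_reaction_step(st)
  expect_identical(unname(st2$counts["A"]), 0L)
  expect_identical(unname(st2$counts["B"]), 1L)
  expect_gt(st2$t, 0)
  # absorbing afterwards
  st3 <- next_reaction_step(st2)
  expect_true(is.na(st3$last_event))
})

test_that("well-mixed decay matches the analytic mean", {
  fx <- gen_chem_fixture("decay")
  survivors <- vapply(1:200, function(s) {
    r <- nrm_simulate(fx$net, fx$counts0, t_end = 1, save_times = c(0, 1),
                      seed = s)
    r$totals[1, 2]
  }, numeric(1))
  se <- stats::sd(survivors) / sqrt(200)
  expect_lt(abs(mean(survivors) - fx$reference(1)), 3 * se)
})

test_that("dimerization mean tracks the independent ODE solution", {
  fx <- gen_chem_fixture("dimerize")
  finals <- vapply(1:100, function(s) {
    r <- nrm_simulate(fx$net, fx$counts0, t_end = 2, save_times = c(0, 2),
                      seed = s)
    r$totals[1, 2]
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(100)
  # the ODE reference ignores the (N-1)/N finite-size factor; allow 3 SE + 1%
  expect_lt(abs(mean(finals) - fx$reference(2)),
            3 * se + 0.01 * fx$reference(2))
})

test_that("two-compartment hopping reaches detailed-balance occupancy", {
  fx <- gen_chem_fixture("two_compartment")
  r <- nrm_simulate(fx$net, fx$counts0, t_end = 5, save_times = c(0, 5),
                    seed = 9)
  final <- r$counts[1, , 2]
  expect_identical(sum(final), 1000)
  expect_lt(abs(final[1] - 500), 5 * sqrt(1000 * 0.25))
})

test_that("NRM event times match an independent direct-SSA implementation", {
  net <- toy_network()
  counts0 <- c(A = 60L, B = 40L)
  r_nrm <- nrm_simulate(net, counts0, t_end = Inf, save_times = c(0),
                        seed = 21, max_events = 5000, record_events = TRUE)
  r_ssa <- ssa_direct(net, counts0, t_end = Inf, seed = 99, max_events = 5000)
  expect_gte(length(r_nrm$event_times), 4999)
  expect_gte(length(r_ssa$event_times), 4999)
  # inter-event waiting times sample the same law in the two implementations
  ks <- suppressWarnings(stats::ks.test(diff(r_nrm$event_times),
                                        diff(r_ssa$event_times)))
  expect_gt(ks$p.value, 0.01)
})

test_that("propensity cache stays coherent over long runs", {
  net <- toy_network()
  r <- nrm_simulate(net, c(A = 300L, B = 200L), t_end = Inf,
                    save_times = c(0), seed = 4, max_events = 1e4)
  expect_lt(r$propensity_max_rel_err, 1e-9)
  # spatial variant with hopping
  net2 <- reaction_network(c("A", "B"),
                           list(reaction(c(A = 1), c(B = 1), k = 0.5)),
                           grid_spec(4L, 4L), diffusion = c(A = 5, B = 5))
  m0 <- matrix(0L, 2, 16); m0[1, 1] <- 2000L
  r2 <- nrm_simulate(net2, m0, t_end = Inf, save_times = c(0), seed = 5,
                     max_events = 1e4)
  expect_lt(r2$propensity_max_rel_err, 1e-9)
})

test_that("mass is conserved by the generic engine", {
  net <- toy_network()
  r <- nrm_simulate(net, c(A = 100L, B = 50L), t_end = 10,
                    save_times = c(0, 5, 10), seed = 7)
  # A + B invariant under all three reactions
  inv <- r$totals["A", ] + r$totals["B", ]
  expect_true(all(inv == inv[1]))
})
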