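# Shared fixtures: built in code, deterministic under fixed seeds.

AVOGADRO_TEST <- 6.02214076e23  # independent of the package constant

# A small well-mixed three-reaction network with sustained activity
# (A <-> B plus a homo-bimolecular conversion conserving the total) for
# stochastic-kinetics equivalence checks.
toy_network <- function() {
  reaction_network(
    c("A", "B"),
    list(reaction(c(A = 1), c(B = 1), k = 1),
         reaction(c(B = 1), c(A = 1), k = 0.8),
         reaction(c(A = 2), c(A = 1, B = 1), k = 5e6)),
    grid_spec(1L, 1L))
}

# Randomized branched filament system for gradient property tests.
random_branched_system <- function(seed, jitter = 2) {
  set.seed(seed)
  sf <- straight_filament(4, start = c(3000, 3000, 250),
                          dir = stats::rnorm(3))
  sys <- filament_system(sf$beads, sf$fil)
  sys <- apply_event_geometry(
    sys, list(type = "branch", filament = 1, arc = 40.5,
              azimuth = stats::runif(1, 0, 2 * pi)))
  for (i in 1:4) {
    sys <- apply_event_geometry(sys, list(type = "polymerize", filament = 2))
  }
  sys$beads <- sys$beads + matrix(stats::rnorm(length(sys$beads), sd = jitter),
                                  ncol = 3)
  sys
}

# Central finite-difference gradient of the total mechanical energy.
fd_gradient <- function(sys, h = 1e-4) {
  g <- matrix(0, nrow(sys$beads), 3)
  for (i in seq_len(nrow(sys$beads))) {
    for (m in 1:3) {
      sp <- sys; sp$beads[i, m] <- sp$beads[i, m] + h
      sm_ <- sys; sm_$beads[i, m] <- sm_$beads[i, m] - h
      g[i, m] <- (mech_energy(sp)$total - mech_energy(sm_)$total) / (2 * h)
    }
  }
  g
}

# Reduced-scale simulation config for engine unit tests (seconds, not the
# full acceptance sweep).
tiny_sim_config <- function(...) {
  dendritic_config(t_end = 2, snapshot_dt = 0.5, ...)
}
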