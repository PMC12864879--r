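#' Mesoscopic rate constant for a compartmental reaction
#'
#' Converts a macroscopic rate constant (s^-1 for first order, M^-1 s^-1 for
#' second order) into the per-compartment stochastic rate constant
#' \eqn{c_\mu = k_\mu / (N_A V_r)^{n-1}}, the dimensionally consistent form
#' (so that bimolecular propensities carry units of 1/s).
#'
#' @param k_mu Macroscopic rate constant.
#' @param order Reaction order (1 or 2).
#' @param volume_l Compartment volume in litres.
#' @return Mesoscopic rate constant (1/s at unit degeneracy).
#' @export
mesoscopic_rate <- function(k_mu, order, volume_l) {
  stopifnot(k_mu > 0, volume_l > 0)
  order <- as.integer(order)
  if (order < 1L) stop("reaction order must be >= 1")
  if (order > 2L) stop("reaction orders above 2 are not implemented")
  k_mu / (AVOGADRO * volume_l)^(order - 1L)
}

#' Define a reaction
#'
#' @param reactants,products Named integer vectors of stoichiometries, e.g.
#'   `c(A = 1, B = 1)`. Empty (`NULL`) products describe degradation.
#' @param k Macroscopic rate constant (units set by the order).
#' @param kind Label: activation, nucleation, polymerization,
#'   depolymerization, or generic.
#' @return A `reaction` object.
#' @export
reaction <- function(reactants, products = NULL, k,
                     kind = c("generic", "activation", "nucleation",
                              "polymerization", "depolymerization")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(k), k > 0)
  reactants <- as.integer(c(reactants)) |> stats::setNames(names(c(reactants)))
  if (length(reactants) == 0L || is.null(names(reactants)))
    stop("reactants must be a named stoichiometry vector")
  if (!is.null(products)) {
    products <- as.integer(c(products)) |> stats::setNames(names(c(products)))
  }
  structure(list(reactants = reactants, products = products,
                 order = sum(reactants), k = k, kind = kind),
            class = "reaction")
}

#' Reaction propensity from copy numbers
#'
#' \eqn{a_\mu = c_\mu \gamma_\mu} where \eqn{\gamma_\mu} is the degeneracy:
#' for A + B, \eqn{N_A N_B}; for A + A, \eqn{N(N-1)/2}; zero whenever any
#' reactant is absent.
#'
#' @param rx A [reaction()].
#' @param counts Named copy numbers of the species present in one compartment.
#' @param volume_l Compartment volume in litres.
#' @return Propensity in 1/s.
#' @export
propensity <- function(rx, counts, volume_l) {
  stopifnot(inherits(rx, "reaction"), all(counts >= 0))
  cm <- mesoscopic_rate(rx$k, rx$order, volume_l)
  gam <- 1
  for (sp in names(rx$reactants)) {
    n <- counts[[sp]]
    st <- rx$reactants[[sp]]
    if (n < st) return(0)
    gam <- gam * if (st == 1L) n else n * (n - 1) / 2
  }
  cm * gam
}

#' Tentative firing time of a reaction channel
#'
#' \eqn{\tau = (1/a_\mu) \ln(1/r)} relative to the current clock; infinite
#' when the propensity is zero.
#'
#' @param a_mu Propensity (1/s), >= 0.
#' @param r Uniform random number strictly inside (0, 1).
#' @return Waiting time in seconds (possibly `Inf`).
#' @export
draw_tentative_time <- function(a_mu, r) {
  stopifnot(a_mu >= 0)
  if (r <= 0 || r >= 1) stop("r must lie strictly in (0, 1)")
  if (a_mu == 0) return(Inf)
  log(1 / r) / a_mu
}

#' Diffusion hop rate to a neighbouring compartment
#'
#' Stochastic diffusion is modeled as random hopping between 4-connected
#' lattice neighbours at rate \eqn{D / h^2} per neighbour, with reflecting
#' boundaries (boundary compartments simply have fewer hop channels).
#'
#' @param diffusible Logical; immobile species (membrane-bound N-WASP,
#'   activated Arp2/3) may not hop.
#' @param D Diffusion coefficient in um^2/s.
#' @param grid A [grid_spec()].
#' @return Hop rate (1/s) per neighbour channel.
#' @export
diffusion_hop_rates <- function(diffusible, D, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!isTRUE(diffusible)) {
    stop("contract violation: hop rates requested for a non-diffusible species")
  }
  stopifnot(D > 0)
  h_um <- grid$compartment_edge / 1000
  D / h_um^2
}

#' Assemble a compartmental reaction network
#'
#' @param species Character vector of species names.
#' @param reactions List of [reaction()] objects (applied in every
#'   compartment).
#' @param grid A [grid_spec()]; use `grid_spec(1, 1)` for a well-mixed system.
#' @param diffusion Named numeric vector of diffusion coefficients (um^2/s)
#'   for the diffusible species; omitted species are immobile.
#' @return A `reaction_network` object.
#' @export
reaction_network <- function(species, reactions, grid = grid_spec(1L, 1L),
                             diffusion = NULL) {
  stopifnot(is.character(species), length(species) >= 1L)
  for (rx in reactions) {
    stopifnot(inherits(rx, "reaction"))
    bad <- setdiff(names(c(rx$reactants, rx$products)), species)
    if (length(bad)) stop("unknown species in reaction: ", paste(bad, collapse = ", "))
  }
  if (!is.null(diffusion)) {
    bad <- setdiff(names(diffusion), species)
    if (length(bad)) stop("unknown species in diffusion: ", paste(bad, collapse = ", "))
  }
  structure(list(species = species, reactions = reactions, grid = grid,
                 diffusion = diffusion),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions, %d x %d grid\n",
              length(x$species), length(x$reactions), x$grid$nx, x$grid$ny))
  for (rx in x$reactions) {
    lhs <- paste(sprintf("%d %s", rx$reactants, names(rx$reactants)), collapse = " + ")
    rhs <- if (is.null(rx$products)) "0" else
      paste(sprintf("%d %s", rx$products, names(rx$products)), collapse = " + ")
    cat(sprintf("  %s -> %s  (k = %g, %s)\n", lhs, rhs, rx$k, rx$kind))
  }
  invisible(x)
}

reactions_for_cpp <- function(net) {
  vr <- compartment_volume_l(net$grid)
  lapply(net$reactions, function(rx) {
    list(re_sp = match(names(rx$reactants), net$species),
         re_st = unname(rx$reactants),
         pr_sp = if (is.null(rx$products)) integer(0) else
           match(names(rx$products), net$species),
         pr_st = if (is.null(rx$products)) integer(0) else unname(rx$products),
         c_meso = mesoscopic_rate(rx$k, rx$order, vr))
  })
}

hop_rates_for_cpp <- function(net) {
  h <- rep(0, length(net$species))
  if (!is.null(net$diffusion)) {
    idx <- match(names(net$diffusion), net$species)
    h[idx] <- vapply(names(net$diffusion), function(sp)
      diffusion_hop_rates(TRUE, net$diffusion[[sp]], net$grid), numeric(1))
  }
  h
}

#' Simulate a network with the next-reaction method
#'
#' Exact stochastic simulation (Gibson-Bruck next-reaction method): every
#' channel keeps a tentative firing time in an indexed priority queue; after
#' each event only dependency-graph neighbours are updated, reusing unfired
#' waiting times by propensity rescaling.
#'
#' @param net A [reaction_network()].
#' @param counts0 Initial counts: either a named vector (replicated/placed as
#'   a species x compartment matrix with all copies uniform per compartment is
#'   NOT assumed -- a vector is interpreted as a well-mixed single compartment
#'   or recycled across compartments if it matches) or a species x compartment
#'   matrix.
#' @param t_end Simulation end time (s).
#' @param save_times Times at which to record full counts (defaults to
#'   `c(0, t_end)`).
#' @param seed Integer seed.
#' @param max_events Event budget guard.
#' @param record_events Record individual event times (for distributional
#'   checks); capped at `max_record`.
#' @param max_record Cap on recorded events.
#' @return List with `counts` (species x compartment x time array), `totals`
#'   (species x time), `save_times`, `n_events`, `event_times`,
#'   `propensity_max_rel_err` (cache-coherence audit).
#' @export
nrm_simulate <- function(net, counts0, t_end, save_times = NULL, seed = 1L,
                         max_events = 1e9, record_events = FALSE,
                         max_record = 1e6) {
  stopifnot(inherits(net, "reaction_network"))
  n_comp <- net$grid$nx * net$grid$ny
  m <- counts_matrix(net, counts0)
  if (is.null(save_times)) save_times <- c(0, t_end)
  res <- cpp_nrm_run(m, reactions_for_cpp(net), hop_rates_for_cpp(net),
                     net$grid$nx, net$grid$ny, t_end, as.numeric(save_times),
                     as.integer(seed), max_events, record_events,
                     as.integer(max_record))
  counts <- array(res$counts, dim = c(length(net$species), n_comp,
                                      length(save_times)),
                  dimnames = list(net$species, NULL, NULL))
  totals <- apply(counts, c(1, 3), sum)
  list(counts = counts, totals = totals, save_times = as.numeric(save_times),
       t_final = res$t_final, n_events = res$n_events,
       event_times = res$event_times, event_types = res$event_types,
       propensity_max_rel_err = res$propensity_max_rel_err)
}

counts_matrix <- function(net, counts0) {
  n_comp <- net$grid$nx * net$grid$ny
  if (is.matrix(counts0)) {
    stopifnot(nrow(counts0) == length(net$species), ncol(counts0) == n_comp)
    m <- counts0
  } else {
    stopifnot(!is.null(names(counts0)))
    v <- rep(0L, length(net$species))
    v[match(names(counts0), net$species)] <- as.integer(counts0)
    if (n_comp != 1L) stop("per-compartment matrix required for spatial grids")
    m <- matrix(v, ncol = 1L)
  }
  storage.mode(m) <- "integer"
  m
}

#' One next-reaction-method step (reference R implementation)
#'
#' A transparent, pure-R state machine over a well-mixed network, exposing the
#' per-event semantics of the next-reaction method (minimum tentative time,
#' stoichiometric update, dependency-limited propensity refresh). Intended for
#' inspection and small systems; long runs go through [nrm_simulate()].
#'
#' @param net A well-mixed [reaction_network()] (1 x 1 grid).
#' @param counts0 Named initial counts.
#' @param seed Integer seed.
#' @return An `nrm_state` to pass to [next_reaction_step()].
#' @export
nrm_state <- function(net, counts0, seed = 1L) {
  stopifnot(inherits(net, "reaction_network"),
            net$grid$nx == 1L, net$grid$ny == 1L)
  v <- rep(0L, length(net$species)); names(v) <- net$species
  v[names(counts0)] <- as.integer(counts0)
  vr <- compartment_volume_l(net$grid)
  set.seed(as.integer(seed))
  a <- vapply(net$reactions, propensity, numeric(1), counts = v, volume_l = vr)
  tau <- vapply(a, function(ai)
    if (ai > 0) draw_tentative_time(ai, stats::runif(1)) else Inf, numeric(1))
  structure(list(net = net, counts = v, t = 0, a = a, tau = tau, vr = vr),
            class = "nrm_state")
}

#' @rdname nrm_state
#' @param state An `nrm_state`.
#' @return Updated state with attributes `event` (index of executed reaction,
#'   or `NA` if the system is absorbing) recorded in `state$last_event`.
#' @export
next_reaction_step <- function(state) {
  stopifnot(inherits(state, "nrm_state"))
  if (all(!is.finite(state$tau))) {
    state$last_event <- NA_integer_
    return(state)
  }
  mu <- which.min(state$tau)
  t_new <- state$tau[mu]
  rx <- state$net$reactions[[mu]]
  for (sp in names(rx$reactants))
    state$counts[sp] <- state$counts[sp] - rx$reactants[[sp]]
  if (any(state$counts < 0)) stop("internal consistency error: negative count")
  for (sp in names(rx$products))
    state$counts[sp] <- state$counts[sp] + rx$products[[sp]]
  # dependency set: channels sharing species with the executed reaction
  touched <- names(c(rx$reactants, rx$products))
  state$t <- t_new
  for (j in seq_along(state$net$reactions)) {
    rxj <- state$net$reactions[[j]]
    if (j != mu &&
        !length(intersect(names(rxj$reactants), touched))) next
    a_new <- propensity(rxj, state$counts, state$vr)
    if (j == mu) {
      state$tau[j] <- if (a_new > 0)
        t_new + draw_tentative_time(a_new, stats::runif(1)) else Inf
    } else if (a_new <= 0) {
      state$tau[j] <- Inf
    } else if (!is.finite(state$tau[j]) || state$a[j] <= 0) {
      state$tau[j] <- t_new + draw_tentative_time(a_new, stats::runif(1))
    } else {
      state$tau[j] <- t_new + (state$a[j] / a_new) * (state$tau[j] - t_new)
    }
    state$a[j] <- a_new
  }
  state$last_event <- mu
  state
}

#' Direct Gillespie SSA (independent reference implementation)
#'
#' First-reaction-free direct method: total propensity, exponential waiting
#' time, categorical channel choice. Serves as an independent cross-check of
#' the next-reaction machinery on small networks.
#'
#' @inheritParams nrm_state
#' @param t_end End time.
#' @param max_events Cap on events.
#' @return List with `counts` (final), `event_times`, `t_final`.
#' @export
ssa_direct <- function(net, counts0, t_end, seed = 1L, max_events = 1e6) {
  stopifnot(inherits(net, "reaction_network"),
            net$grid$nx == 1L, net$grid$ny == 1L)
  v <- rep(0L, length(net$species)); names(v) <- net$species
  v[names(counts0)] <- as.integer(counts0)
  vr <- compartment_volume_l(net$grid)
  set.seed(as.integer(seed))
  t <- 0
  ev <- numeric(0)
  n_rx <- length(net$reactions)
  repeat {
    a <- vapply(net$reactions, propensity, numeric(1), counts = v, volume_l = vr)
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1, rate = a0)
    if (t > t_end || length(ev) >= max_events) break
    mu <- sample.int(n_rx, 1L, prob = a / a0)
    rx <- net$reactions[[mu]]
    for (sp in names(rx$reactants)) v[sp] <- v[sp] - rx$reactants[[sp]]
    for (sp in names(rx$products)) v[sp] <- v[sp] + rx$products[[sp]]
    ev <- c(ev, t)
  }
  list(counts = v, event_times = ev, t_final = min(t, t_end))
}
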