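#' Configuration for the dendritic nucleation simulation
#'
#' All chemistry rates, concentrations and mechanical constants are exposed
#' here; nothing is hard-coded in the engine. Defaults describe the study
#' conditions: 1 uM G-actin and 1 uM (immobile) N-WASP, 10 nM inactive
#' Arp2/3, on the 16 x 16 x 1 grid of 500-nm compartments, with plus-end
#' kinetics 11.6 uM^-1 s^-1 / 1.4 s^-1, and mechanical relaxation every 5 ms
#' of chemistry.
#'
#' @param grid A [grid_spec()].
#' @param g_actin_um,arp_um,nwasp_um Total concentrations (uM).
#' @param k_act Arp2/3 activation rate by N-WASP (uM^-1 s^-1). The
#'   localization-driven enhancement requires an adequate activation rate;
#'   the default sits in the calibrated adequate regime (activation
#'   completes well inside the observation window, so activated Arp2/3 is
#'   deposited where N-WASP sits) -- see the methods vignette.
#' @param k_branch Dendritic branching rate per (active Arp2/3, free binding
#'   site) pair (uM^-1 s^-1); consumes one local G-actin. Default calibrated
#'   so a branching cascade ignites promptly once filaments reach an
#'   activator hotspot.
#' @param k_nucleate De novo nucleation rate by activated Arp2/3
#'   (uM^-1 s^-1): Arp_active + G-actin seeds a fresh filament in place, with
#'   the Arp2/3 retained at its minus end. This is how first filaments arise
#'   from the activator field itself; the default is slow relative to
#'   branching, so dendritic amplification dominates wherever binding sites
#'   exist.
#' @param k_spont Spontaneous (Arp2/3-independent) dimer-seeding rate
#'   (uM^-1 s^-1), active only when `spontaneous_nucleation = TRUE`.
#' @param k_poly,k_depoly Plus-end kinetics (uM^-1 s^-1 and s^-1).
#' @param D Diffusion coefficient of G-actin and inactive Arp2/3 (um^2/s).
#' @param n_seeds Number of pre-placed seed filaments.
#' @param seed_segments Segments per seed filament.
#' @param t_end Simulated time (s); desk-scale default 100 s (the 400 s
#'   production setting is a preset, pass `t_end = 400`).
#' @param dt_mech Chemistry interval between mechanical relaxations (s).
#' @param snapshot_dt Snapshot interval (s).
#' @param full_relax_dt Interval between whole-network relaxations (s);
#'   between them only event-touched neighbourhoods are relaxed each
#'   chemistry interval (frozen-frozen energy terms are constant, so local
#'   relaxation also lowers the total energy).
#' @param F0 Brownian-ratchet characteristic force (pN).
#' @param cg_tol,cg_max_iter Minimizer force tolerance (pN) and iteration cap
#'   per relaxation.
#' @param spontaneous_nucleation If `TRUE`, seeds may also arise by the
#'   spontaneous (Arp2/3-independent) `k_spont` pathway; off by default.
#' @param mech Mechanical parameter list from [mech_params()].
#' @param max_events Hard event budget guard.
#' @return A `dendritic_config` list.
#' @export
dendritic_config <- function(grid = grid_spec(),
                             g_actin_um = 1, arp_um = 0.01, nwasp_um = 1,
                             k_act = 1, k_branch = 5, k_nucleate = 0.01,
                             k_spont = 1e-3,
                             k_poly = 11.6, k_depoly = 1.4, D = 5,
                             n_seeds = 10, seed_segments = 2,
                             t_end = 100, dt_mech = 0.005, snapshot_dt = 1,
                             full_relax_dt = 10,
                             F0 = 1.5, cg_tol = 1, cg_max_iter = 100,
                             spontaneous_nucleation = FALSE,
                             mech = NULL, max_events = 5e8) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(mech)) {
    # production-engine numerics: 4-point quadrature and a 50-nm
    # excluded-volume cutoff (truncation error ~1e-6 of contact scale with
    # the 1/r^4 kernel) keep dense branch clusters tractable at the 5-ms
    # relaxation cadence
    mech <- mech_params(box = c(grid$nx * grid$compartment_edge,
                                grid$ny * grid$compartment_edge,
                                grid$slab_height),
                        nquad = 4, ev_cutoff = 50)
  }
  cfg <- list(grid = grid, nx = grid$nx, ny = grid$ny,
              compartment_edge = grid$compartment_edge,
              slab_height = grid$slab_height,
              g_actin_um = g_actin_um, arp_um = arp_um, nwasp_um = nwasp_um,
              k_act = k_act, k_branch = k_branch, k_nucleate = k_nucleate,
              k_spont = k_spont, k_poly = k_poly,
              k_depoly = k_depoly, D = D,
              n_seeds = as.integer(n_seeds),
              seed_segments = as.integer(seed_segments),
              t_end = t_end, dt_mech = dt_mech, snapshot_dt = snapshot_dt,
              full_relax_dt = full_relax_dt,
              F0 = F0, cg_tol = cg_tol, cg_max_iter = as.integer(cg_max_iter),
              spontaneous_nucleation = spontaneous_nucleation,
              mech = mech, max_events = max_events)
  class(cfg) <- "dendritic_config"
  cfg
}

#' Instantiate the dendritic nucleation network
#'
#' Builds the per-compartment reaction scheme and initial copy numbers:
#' N-WASP-dependent Arp2/3 activation (product immobile), dendritic branching
#' at filament binding sites (one site per 27 nm of filament), plus-end
#' polymerization and depolymerization, and diffusion hopping of G-actin and
#' inactive Arp2/3 (N-WASP and activated Arp2/3 do not diffuse).
#'
#' @param config A [dendritic_config()].
#' @return A `dendritic_network` summary: species table, reaction table,
#'   initial copy totals.
#' @export
build_dendritic_network <- function(config = dendritic_config()) {
  stopifnot(inherits(config, "dendritic_config"))
  with(config, stopifnot(k_act >= 0, k_branch >= 0, k_poly > 0, k_depoly > 0,
                         D > 0))
  copies <- c(
    G_actin = copies_from_concentration(config$g_actin_um, config$grid),
    Arp23_inactive = copies_from_concentration(config$arp_um, config$grid),
    NWASP = copies_from_concentration(config$nwasp_um, config$grid))
  species <- data.frame(
    name = c("G_actin", "Arp23_inactive", "Arp23_active", "NWASP"),
    diffusible = c(TRUE, TRUE, FALSE, FALSE),
    D = c(config$D, config$D, 0, 0))
  reactions <- data.frame(
    id = c("R1_activation", "R2_branch", "R5_denovo_nucleation",
           "R3_polymerize", "R4_depolymerize"),
    scheme = c("NWASP + Arp23_inactive -> NWASP + Arp23_active",
               "Arp23_active + site + G_actin -> offspring filament (70 deg)",
               "Arp23_active + G_actin -> new filament (Arp-capped minus end)",
               "plus end + G_actin -> +2.7 nm",
               "plus end -> -2.7 nm + G_actin"),
    k = c(config$k_act, config$k_branch, config$k_nucleate, config$k_poly,
          config$k_depoly),
    units = c("uM^-1 s^-1", "uM^-1 s^-1", "uM^-1 s^-1", "uM^-1 s^-1", "s^-1"))
  if (isTRUE(config$spontaneous_nucleation)) {
    reactions <- rbind(reactions, data.frame(
      id = "R0_spontaneous", scheme = "G_actin + G_actin -> seed filament",
      k = config$k_spont, units = "uM^-1 s^-1"))
  }
  if (config$n_seeds == 0 && config$k_nucleate == 0 &&
      !isTRUE(config$spontaneous_nucleation)) {
    warning("no seed filaments and all nucleation pathways disabled: ",
            "absorbing no-filament state")
  }
  structure(list(species = species, reactions = reactions,
                 initial_copies = copies, config = config),
            class = "dendritic_network")
}

#' @export
print.dendritic_network <- function(x, ...) {
  cat("Dendritic nucleation network\n")
  cat(sprintf("  initial copies: G-actin %d, Arp2/3 %d, N-WASP %d\n",
              x$initial_copies[["G_actin"]],
              x$initial_copies[["Arp23_inactive"]],
              x$initial_copies[["NWASP"]]))
  for (i in seq_len(nrow(x$reactions))) {
    cat(sprintf("  %-16s %s  (k = %g %s)\n", x$reactions$id[i],
                x$reactions$scheme[i], x$reactions$k[i], x$reactions$units[i]))
  }
  invisible(x)
}

#' Apply a chemical event's geometric consequence to a filament system
#'
#' Polymerization extends the plus-end segment by 2.7 nm along the tip
#' tangent (a new bead is added once the segment reaches 27 nm);
#' depolymerization is the exact inverse; a branch event creates a 2-bead
#' offspring filament at 70 degrees to the parent tangent at the binding
#' site, azimuth as given, minus end tethered at the site.
#'
#' @param sys A [filament_system()].
#' @param event List with `type` ("polymerize", "depolymerize", "branch"),
#'   `filament` (id), and for branches `arc` (nm along the parent) and
#'   `azimuth` (rad).
#' @return Updated system. Depolymerizing a filament down from a single
#'   monomer removes it.
#' @export
apply_event_geometry <- function(sys, event) {
  stopifnot(inherits(sys, "filament_system"))
  id <- event$filament
  rows <- which(sys$fil == id)
  if (!length(rows)) stop("event references a dead filament")
  key <- as.character(id)
  tip <- sys$tip_monomers[[key]]
  nb <- length(rows)
  if (event$type == "polymerize") {
    tipb <- sys$beads[rows[nb], ]
    prev <- sys$beads[rows[nb - 1], ]
    dir <- tipb - prev
    dir <- dir / sqrt(sum(dir^2))
    if (tip >= 10) {
      newb <- tipb + 2.7 * dir
      sys$beads <- rbind(sys$beads[seq_len(rows[nb]), , drop = FALSE], newb,
                         if (rows[nb] < nrow(sys$beads))
                           sys$beads[(rows[nb] + 1):nrow(sys$beads), , drop = FALSE])
      sys$fil <- append(sys$fil, id, after = rows[nb])
      sys$tip_monomers[[key]] <- 1L
    } else {
      sys$beads[rows[nb], ] <- tipb + 2.7 * dir
      sys$tip_monomers[[key]] <- tip + 1L
    }
  } else if (event$type == "depolymerize") {
    if (nb == 2 && tip == 1) {
      keep <- sys$fil != id
      sys$beads <- sys$beads[keep, , drop = FALSE]
      sys$fil <- sys$fil[keep]
      sys$tip_monomers[[key]] <- NULL
      sys$bonds <- sys$bonds[sys$bonds$parent != id & sys$bonds$child != id, ,
                             drop = FALSE]
      return(sys)
    }
    if (tip <= 1) {
      sys$beads <- sys$beads[-rows[nb], , drop = FALSE]
      sys$fil <- sys$fil[-rows[nb]]
      sys$tip_monomers[[key]] <- 10L
    } else {
      tipb <- sys$beads[rows[nb], ]
      prev <- sys$beads[rows[nb - 1], ]
      dir <- tipb - prev
      dir <- dir / sqrt(sum(dir^2))
      sys$beads[rows[nb], ] <- tipb - 2.7 * dir
      sys$tip_monomers[[key]] <- tip - 1L
    }
  } else if (event$type == "branch") {
    arc <- event$arc
    az <- if (is.null(event$azimuth)) 0 else event$azimuth
    nseg <- nb - 1
    k <- min(floor(arc / 27), nseg - 1)
    frac <- min(1, max(0, (arc - 27 * k) / 27))
    A <- sys$beads[rows[k + 1], ]; B <- sys$beads[rows[k + 2], ]
    P <- (1 - frac) * A + frac * B
    u <- B - A; u <- u / sqrt(sum(u^2))
    ref <- if (abs(u[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
    e1 <- c(u[2] * ref[3] - u[3] * ref[2], u[3] * ref[1] - u[1] * ref[3],
            u[1] * ref[2] - u[2] * ref[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    bdir <- cos(az) * e1 + sin(az) * e2
    th <- sys$params$theta_branch
    v <- cos(th) * u + sin(th) * bdir
    newid <- max(sys$fil) + 1L
    C <- P + sys$params$L0_bond * bdir
    D <- C + 2.7 * v
    sys$beads <- rbind(sys$beads, C, D)
    sys$fil <- c(sys$fil, newid, newid)
    sys$tip_monomers[[as.character(newid)]] <- 1L
    sys$bonds <- rbind(sys$bonds,
                       data.frame(parent = id, child = newid, arc = arc))
  } else {
    stop("unknown event type: ", event$type)
  }
  rownames(sys$beads) <- NULL
  sys
}

#' Run a coupled mechanochemical simulation
#'
#' Generates (or accepts) the N-WASP copy-number map at localization factor
#' `f`, instantiates uniformly distributed G-actin and inactive Arp2/3 plus
#' seed filaments, and evolves the system: exact next-reaction-method
#' chemistry in 5-ms intervals alternating with conjugate-gradient mechanical
#' relaxation, with Brownian-ratchet polymerization scaling at
#' boundary-loaded tips recomputed after each relaxation. Deterministic for a
#' fixed `(config, f, seed)`.
#'
#' @param config A [dendritic_config()].
#' @param f Localization factor in (0, 1].
#' @param seed Integer seed (drives field optimization start points, copy
#'   sampling and the event sequence).
#' @param nwasp_map Optional pre-sampled [sample_copy_map()]; when supplied,
#'   `f` is taken from its provenance and no field is generated.
#' @return An `actin_trajectory`: snapshot `series` (data.frame), final
#'   `snapshot` (a [filament_system()] plus compartment assignment), event
#'   `counts`, and provenance (`f`, `seed`, `config`).
#' @export
run_simulation <- function(config = dendritic_config(), f = 1, seed = 1L,
                           nwasp_map = NULL) {
  stopifnot(inherits(config, "dendritic_config"))
  if (is.null(nwasp_map)) {
    stopifnot(f > 0, f <= 1)
    density <- optimize_density(config$grid, f, seed = seed)
    total <- copies_from_concentration(config$nwasp_um, config$grid)
    nwasp_map <- sample_copy_map(density, total, seed = seed,
                                 species = "NWASP",
                                 concentration_um = config$nwasp_um)
  }
  cfg <- config
  cfg$g_actin_copies <- as.numeric(
    copies_from_concentration(config$g_actin_um, config$grid))
  cfg$arp_copies <- as.numeric(
    copies_from_concentration(config$arp_um, config$grid))
  res <- cpp_run_dendritic(nwasp_map$counts, unclass(cfg), as.integer(seed))
  series <- data.frame(
    time = res$times, G_actin = res$G, Arp23_inactive = res$Arp_inactive,
    Arp23_active = res$Arp_active, n_filaments = res$n_filaments,
    n_branches = res$n_branches, n_denovo = res$n_denovo,
    polymerized = res$polymerized,
    energy = res$energy)
  snapshot <- list(
    beads = res$beads, fil = res$bead_fil,
    filaments = data.frame(id = res$fil_id, n_beads = res$fil_nb,
                           tip_monomers = res$fil_tip_monomers,
                           is_offspring = res$fil_is_offspring),
    bonds = data.frame(parent = res$bond_parent, child = res$bond_child,
                       arc = res$bond_arc))
  structure(list(series = series, snapshot = snapshot, counts = res$counts,
                 n_events = res$n_events, f = f, seed = seed, config = config),
            class = "actin_trajectory")
}

#' @export
print.actin_trajectory <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("Mechanochemical trajectory: f = %g, seed = %d, t = 0..%g s\n",
              x$f, x$seed, x$series$time[n]))
  cat(sprintf("  final: %d filaments, %d branches, %d polymerized monomers\n",
              x$series$n_filaments[n], x$series$n_branches[n],
              x$series$polymerized[n]))
  cat(sprintf("  events: %.3g (%.0f activations, %.0f branches, %.0f poly)\n",
              x$n_events, x$counts$activation, x$counts$branch,
              x$counts$poly))
  invisible(x)
}

#' @export
plot.actin_trajectory <- function(x, what = "n_filaments", ...) {
  graphics::plot(x$series$time, x$series[[what]], type = "l",
                 xlab = "time (s)", ylab = what,
                 main = sprintf("f = %g", x$f), ...)
  invisible(x)
}

#' Write a filament snapshot as JSON
#'
#' Plain-text serialization of a trajectory's final snapshot: bead
#' coordinates, per-bead filament assignment, filament registry and branch
#' bonds.
#'
#' @param snapshot The `snapshot` element of an `actin_trajectory`.
#' @param path Output file.
#' @export
write_snapshot_json <- function(snapshot, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON snapshot export")
  }
  obj <- list(beads = unname(as.matrix(snapshot$beads)),
              filament = as.integer(snapshot$fil),
              filaments = snapshot$filaments,
              bonds = snapshot$bonds)
  jsonlite::write_json(obj, path, digits = 10)
  invisible(path)
}
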