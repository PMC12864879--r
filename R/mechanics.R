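#' Mechanical parameters of the filament model
#'
#' Defaults follow the explicit-filament convention: 27-nm cylindrical
#' segments (10 actin monomers of 2.7 nm) joined by hinges, harmonic segment
#' stretching with stiff springs, cosine bending with stiffness derived from
#' the persistence length via \eqn{l_{cyl} k_{bend} = L_p k_B T}, a
#' \eqn{1/r^4} pairwise excluded-volume potential between non-adjacent
#' segments, exponential boundary repulsion from the slab faces, and branch
#' bond terms (stretch without the 1/2 factor, two angular terms referenced
#' to 90 degrees and 70 degrees = 1.222 rad, and a plane-normal dihedral
#' penalty).
#'
#' @param k_str Segment stretching stiffness (pN/nm).
#' @param Lp Persistence length (nm); actin ~ 17 um.
#' @param kBT Thermal energy (pN nm) at T = 298 K.
#' @param kvol Excluded-volume constant.
#' @param eps_boundary Boundary repulsion at contact (pN nm).
#' @param lambda Boundary screening length (nm).
#' @param box Slab dimensions c(Lx, Ly, Lz) in nm.
#' @param ev_cutoff Neighbour cutoff for excluded volume (nm); the
#'   \eqn{1/r^4} kernel makes truncation error at 100 nm ~ 1e-5 of
#'   contact-scale energies.
#' @param rmin Singularity cap (nm) for near-intersecting segments.
#' @param k_branch_str,k_branch_bend1,k_branch_bend2,k_branch_dihedral Branch
#'   bond stiffnesses (pN/nm and pN nm).
#' @param theta_branch Parent-offspring reference angle (rad), 70 degrees.
#' @param L0_bond Branch bond resting length (nm).
#' @param nquad Gauss-Legendre order per segment for the excluded-volume
#'   quadrature (2, 4 or 8).
#' @return Named list of parameters (includes derived `k_bend`).
#' @export
mech_params <- function(k_str = 100, Lp = 17000, kBT = 4.11, kvol = 1680,
                        eps_boundary = 100, lambda = 2.7,
                        box = c(8000, 8000, 500), ev_cutoff = 100, rmin = 1,
                        k_branch_str = 100, k_branch_bend1 = 100,
                        k_branch_bend2 = 480, k_branch_dihedral = 50,
                        theta_branch = 1.222, L0_bond = 6, nquad = 8) {
  list(k_str = k_str, Lp = Lp, kBT = kBT,
       k_bend = k_bend_from_persistence(Lp, kBT),
       kvol = kvol, eps_boundary = eps_boundary, lambda = lambda, box = box,
       ev_cutoff = ev_cutoff, rmin = rmin, k_branch_str = k_branch_str,
       k_branch_bend1 = k_branch_bend1, k_branch_bend2 = k_branch_bend2,
       k_branch_dihedral = k_branch_dihedral, theta_branch = theta_branch,
       L0_bond = L0_bond, nquad = as.integer(nquad))
}

#' Bending stiffness from the persistence length
#'
#' \eqn{k_{bend} = L_p k_B T / l_{cyl}}.
#' @param Lp Persistence length (nm).
#' @param kBT Thermal energy (pN nm).
#' @param l_cyl Segment length (nm).
#' @export
k_bend_from_persistence <- function(Lp, kBT = 4.11, l_cyl = 27) {
  stopifnot(Lp > 0, kBT > 0, l_cyl > 0)
  Lp * kBT / l_cyl
}

#' Segment stretching energy
#'
#' \eqn{U = (k_{str}/2)(l - l_0)^2} (pN nm); [stretch_gradient()] gives
#' \eqn{dU/dl = k_{str}(l - l_0)}.
#' @param l Current segment length (nm), >= 0.
#' @param l0 Resting length (nm); 27 nm for a full 10-monomer segment.
#' @param k_str Stiffness (pN/nm).
#' @export
stretch_energy <- function(l, l0 = 27, k_str = 100) {
  stopifnot(all(l >= 0))
  0.5 * k_str * (l - l0)^2
}

#' @rdname stretch_energy
#' @export
stretch_gradient <- function(l, l0 = 27, k_str = 100) k_str * (l - l0)

#' Hinge bending energy
#'
#' \eqn{U = k_{bend}(1 - \cos\theta)}; zero for a collinear continuation,
#' monotone increasing on \eqn{[0, \pi]}. [bend_gradient()] gives
#' \eqn{dU/d\theta = k_{bend}\sin\theta}.
#' @param theta Hinge angle (rad) in \eqn{[0, \pi]}; 0 = straight.
#' @param k_bend Bending stiffness (pN nm).
#' @export
bend_energy <- function(theta, k_bend) {
  stopifnot(all(theta >= 0), all(theta <= pi + 1e-12))
  k_bend * (1 - cos(theta))
}

#' @rdname bend_energy
#' @export
bend_gradient <- function(theta, k_bend) k_bend * sin(theta)

#' Excluded-volume energy between two cylinder segments
#'
#' \eqn{U = K_{vol}\int_0^1\int_0^1 ds\,dt / |r_i(s) - r_j(t)|^4}, evaluated
#' by fixed-order Gauss-Legendre quadrature; pair distances below `rmin` are
#' capped (large-but-finite energy near intersecting axes).
#'
#' @param seg_i,seg_j 2 x 3 matrices of segment endpoint coordinates (nm).
#' @param kvol Excluded-volume constant.
#' @param nquad Quadrature order per axis (default 8).
#' @param rmin Singularity cap (nm).
#' @return Energy (pN nm).
#' @export
excluded_volume_energy <- function(seg_i, seg_j, kvol = 1680, nquad = 8,
                                   rmin = 1) {
  seg_i <- as.matrix(seg_i); seg_j <- as.matrix(seg_j)
  stopifnot(dim(seg_i) == c(2, 3), dim(seg_j) == c(2, 3))
  if (sum((seg_i[1, ] - seg_i[2, ])^2) == 0 ||
      sum((seg_j[1, ] - seg_j[2, ])^2) == 0)
    stop("degenerate segment (zero length)")
  cpp_ev_pair_energy(seg_i[1, ], seg_i[2, ], seg_j[1, ], seg_j[2, ],
                     kvol, as.integer(nquad), rmin)
}

#' Boundary repulsion energy and force
#'
#' \eqn{U = \epsilon e^{-d/\lambda}} for distance `d` from a slab face; the
#' force magnitude is \eqn{(\epsilon/\lambda) e^{-d/\lambda}}, directed
#' inward.
#' @param d Distance to the wall (nm), >= 0.
#' @param eps Contact energy (pN nm).
#' @param lambda Screening length (nm).
#' @export
boundary_energy <- function(d, eps = 100, lambda = 2.7) {
  stopifnot(all(d >= 0))
  eps * exp(-d / lambda)
}

#' @rdname boundary_energy
#' @export
boundary_force <- function(d, eps = 100, lambda = 2.7) {
  (eps / lambda) * exp(-d / lambda)
}

#' Branch-bond energies
#'
#' The four terms tying an offspring filament's minus end to its parent's
#' binding site: bond stretch \eqn{k(L_{bond} - L_0)^2} (no 1/2 factor),
#' parent-bond angle referenced to \eqn{\pi/2}, parent-offspring angle
#' referenced to 1.222 rad (70 degrees), and a dihedral term
#' \eqn{k\cos(n_1, n_2)} penalizing twist of the plane normals. At the ideal
#' branch geometry the three harmonic-like terms vanish and the dihedral sits
#' at its minimum \eqn{-k}.
#'
#' @param parent_seg 2 x 3 matrix: the parent segment carrying the site.
#' @param s Site position as a fraction along the parent segment, in `[0,1]`.
#' @param offspring_seg 2 x 3 matrix: offspring minus-end bead and next bead.
#' @param params [mech_params()].
#' @return List with `stretch`, `bend_I`, `bend_II`, `dihedral`,
#'   `dihedral_skipped` (TRUE when parent and bond are collinear so the plane
#'   normal is undefined).
#' @export
branch_energies <- function(parent_seg, s, offspring_seg,
                            params = mech_params()) {
  parent_seg <- as.matrix(parent_seg); offspring_seg <- as.matrix(offspring_seg)
  stopifnot(dim(parent_seg) == c(2, 3), dim(offspring_seg) == c(2, 3),
            s >= 0, s <= 1)
  P <- (1 - s) * parent_seg[1, ] + s * parent_seg[2, ]
  u <- parent_seg[2, ] - parent_seg[1, ]
  b <- offspring_seg[1, ] - P
  v <- offspring_seg[2, ] - offspring_seg[1, ]
  if (sqrt(sum(u^2)) < 1e-12 || sqrt(sum(v^2)) < 1e-12)
    stop("degenerate parent or offspring direction")
  Lb <- sqrt(sum(b^2))
  ang <- function(a, b2) {
    ct <- sum(a * b2) / (sqrt(sum(a^2)) * sqrt(sum(b2^2)))
    acos(pmin(1, pmax(-1, ct)))
  }
  th_pb <- ang(u, b)
  th_po <- ang(u, v)
  n1 <- c(u[2] * b[3] - u[3] * b[2], u[3] * b[1] - u[1] * b[3],
          u[1] * b[2] - u[2] * b[1])
  n2 <- c(b[2] * v[3] - b[3] * v[2], b[3] * v[1] - b[1] * v[3],
          b[1] * v[2] - b[2] * v[1])
  skipped <- sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9
  dih <- if (skipped) 0 else
    params$k_branch_dihedral * sum(n1 * n2) /
      (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  list(
    stretch = params$k_branch_str * (Lb - params$L0_bond)^2,
    bend_I = params$k_branch_bend1 * (1 - cos(th_pb - pi / 2)),
    bend_II = params$k_branch_bend2 * (1 - cos(th_po - params$theta_branch)),
    dihedral = dih,
    dihedral_skipped = skipped
  )
}

#' Brownian-ratchet polymerization rate under load
#'
#' \eqn{k_{poly} = k_{poly,F=0}\, e^{-F/F_0}} for a tip pressing a boundary
#' with load `F` along the filament axis (negative projections clamp to 0);
#' characteristic force `F0` = 1.5 pN.
#'
#' @param k_poly_0 Zero-force polymerization rate.
#' @param F Load force (pN).
#' @param F0 Characteristic force (pN).
#' @export
ratchet_rate <- function(k_poly_0, F, F0 = 1.5) {
  stopifnot(k_poly_0 > 0, F0 > 0)
  k_poly_0 * exp(-pmax(F, 0) / F0)
}

#' Explicit filament system
#'
#' Container for beads-and-segments filaments with branch bonds, used by the
#' energy, gradient and minimization routines. Beads of each filament are
#' contiguous rows ordered minus end to plus end; all interior segments rest
#' at 27 nm and the tip segment at `2.7 * tip_monomers`.
#'
#' @param beads N x 3 matrix of bead coordinates (nm).
#' @param fil Integer filament id per bead (contiguous blocks).
#' @param tip_monomers Named (by filament id) or per-filament vector of
#'   monomers in the tip segment (1..10); default full (10).
#' @param bonds `data.frame(parent, child, arc)` of branch bonds: the
#'   offspring (`child`) minus end is tethered to the site at arc-length
#'   `arc` (nm from the parent minus end).
#' @param params [mech_params()].
#' @return A `filament_system`.
#' @export
filament_system <- function(beads, fil = rep(1L, nrow(beads)),
                            tip_monomers = NULL, bonds = NULL,
                            params = mech_params()) {
  beads <- as.matrix(beads)
  stopifnot(ncol(beads) == 3, all(is.finite(beads)))
  fil <- as.integer(fil)
  stopifnot(length(fil) == nrow(beads))
  ids <- unique(fil)
  if (any(table(fil) < 2)) stop("every filament needs at least 2 beads")
  if (is.null(tip_monomers)) tip_monomers <- stats::setNames(
    rep(10L, length(ids)), ids)
  if (is.null(names(tip_monomers))) names(tip_monomers) <- ids
  if (is.null(bonds)) bonds <- data.frame(parent = integer(0),
                                          child = integer(0),
                                          arc = numeric(0))
  structure(list(beads = beads, fil = fil,
                 tip_monomers = tip_monomers, bonds = bonds,
                 params = params),
            class = "filament_system")
}

#' Straight filament constructor
#'
#' @param n_segments Number of 27-nm segments.
#' @param start Minus-end position (nm).
#' @param dir Direction (normalized internally).
#' @param id Filament id.
#' @export
straight_filament <- function(n_segments = 2, start = c(0, 0, 0),
                              dir = c(1, 0, 0), id = 1L) {
  dir <- dir / sqrt(sum(dir^2))
  beads <- t(vapply(0:n_segments, function(i) start + i * 27 * dir,
                    numeric(3)))
  list(beads = beads, fil = rep(as.integer(id), n_segments + 1))
}

segments_of <- function(sys) {
  out <- list(a = integer(0), b = integer(0), fil = integer(0),
              idx = integer(0), rest = numeric(0))
  for (id in unique(sys$fil)) {
    rows <- which(sys$fil == id)
    nb <- length(rows)
    tip <- sys$tip_monomers[[as.character(id)]]
    if (is.null(tip) || is.na(tip)) tip <- 10L
    for (i in seq_len(nb - 1)) {
      out$a <- c(out$a, rows[i]); out$b <- c(out$b, rows[i + 1])
      out$fil <- c(out$fil, id); out$idx <- c(out$idx, i - 1L)
      out$rest <- c(out$rest, if (i == nb - 1) 2.7 * tip else 27)
    }
  }
  out
}

bonds_of <- function(sys) {
  bd <- sys$bonds
  if (nrow(bd) == 0) return(list())
  a <- b <- cc <- d <- integer(nrow(bd)); s <- numeric(nrow(bd))
  for (i in seq_len(nrow(bd))) {
    prow <- which(sys$fil == bd$parent[i])
    crow <- which(sys$fil == bd$child[i])
    nseg <- length(prow) - 1
    k <- min(floor(bd$arc[i] / 27), nseg - 1)
    s[i] <- min(1, max(0, (bd$arc[i] - 27 * k) / 27))
    a[i] <- prow[k + 1]; b[i] <- prow[k + 2]
    cc[i] <- crow[1]; d[i] <- crow[2]
  }
  list(a = a, b = b, s = s, c = cc, d = d,
       L0 = rep(sys$params$L0_bond, nrow(bd)))
}

#' Total mechanical energy of a filament system
#'
#' @param sys A [filament_system()].
#' @return Named list of per-term energies (pN nm) and their `total`.
#' @export
mech_energy <- function(sys) {
  stopifnot(inherits(sys, "filament_system"))
  sg <- segments_of(sys)
  cpp_mech_terms(sys$beads, sg$a, sg$b, sg$fil, sg$idx, sg$rest,
                 bonds_of(sys), sys$params)
}

#' Energy gradient (dU/dx, pN) per bead
#'
#' @param sys A [filament_system()].
#' @return N x 3 matrix; forces are the negative of this.
#' @export
mech_gradient <- function(sys) {
  stopifnot(inherits(sys, "filament_system"))
  sg <- segments_of(sys)
  cpp_mech_grad(sys$beads, sg$a, sg$b, sg$fil, sg$idx, sg$rest,
                bonds_of(sys), sys$params)
}

#' Conjugate-gradient energy minimization
#'
#' Polak-Ribiere conjugate gradient with a backtracking (Armijo) line search;
#' the energy trace is non-increasing and iteration stops when the largest
#' per-bead force drops below `tol` or at `max_iter`.
#'
#' @param sys A [filament_system()].
#' @param tol Convergence tolerance on the max per-bead force (pN).
#' @param max_iter Iteration cap.
#' @return The relaxed system, with attributes `energy_trace`, `iters`,
#'   `converged`, `max_force`.
#' @export
minimize_energy <- function(sys, tol = 1, max_iter = 5000) {
  stopifnot(inherits(sys, "filament_system"))
  sg <- segments_of(sys)
  res <- cpp_mech_minimize(sys$beads, sg$a, sg$b, sg$fil, sg$idx, sg$rest,
                           bonds_of(sys), sys$params, tol,
                           as.integer(max_iter))
  out <- sys
  out$beads <- res$x
  attr(out, "energy_trace") <- res$energy_trace
  attr(out, "iters") <- res$iters
  attr(out, "converged") <- res$converged
  attr(out, "max_force") <- res$max_force
  out
}

#' @export
print.filament_system <- function(x, ...) {
  cat(sprintf("Filament system: %d filaments, %d beads, %d branch bonds\n",
              length(unique(x$fil)), nrow(x$beads), nrow(x$bonds)))
  invisible(x)
}
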