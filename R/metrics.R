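#' Filament-count time series across replicates
#'
#' @param trajectories List of `actin_trajectory` objects (or any objects
#'   with `$series$time` and the chosen column) on a common snapshot grid.
#' @param what Series column to summarize.
#' @return data.frame with `time`, `mean`, `sem` (SD/sqrt(N); 0 for N = 1)
#'   and per-replicate columns.
#' @export
filament_count_series <- function(trajectories, what = "n_filaments") {
  stopifnot(length(trajectories) >= 1)
  times <- trajectories[[1]]$series$time
  for (tr in trajectories) {
    if (!isTRUE(all.equal(tr$series$time, times)))
      stop("trajectories have misaligned snapshot time grids")
  }
  m <- vapply(trajectories, function(tr) tr$series[[what]],
              numeric(length(times)))
  m <- matrix(m, nrow = length(times))
  n <- ncol(m)
  mu <- rowMeans(m)
  sem <- if (n == 1) rep(0, length(times)) else
    apply(m, 1, stats::sd) / sqrt(n)
  out <- data.frame(time = times, mean = mu, sem = sem)
  colnames(m) <- paste0("rep", seq_len(n))
  cbind(out, m)
}

#' Identify branch clusters in a final snapshot
#'
#' A branch cluster is a connected component of the branch-bond graph
#' (filaments are nodes, bonds are edges); unbranched singleton filaments are
#' excluded. For each cluster the branch count (= members - roots) and the
#' convex-hull footprint area of its bead xy-projection are computed (the
#' slab is one compartment thick).
#'
#' @param snapshot The `snapshot` element of an `actin_trajectory` (fields
#'   `beads`, `fil`, `filaments`, `bonds`).
#' @return data.frame with one row per cluster: `cluster`, `n_filaments`,
#'   `n_branches`, `hull_area_um2`, `centroid_x`, `centroid_y` (nm).
#' @export
identify_branch_clusters <- function(snapshot) {
  bonds <- snapshot$bonds
  if (is.null(bonds) || nrow(bonds) == 0) {
    return(data.frame(cluster = integer(0), n_filaments = integer(0),
                      n_branches = integer(0), hull_area_um2 = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0)))
  }
  ids <- sort(unique(c(bonds$parent, bonds$child)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(bonds$parent),
               to = as.character(bonds$child)),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(k) {
    members <- as.integer(names(comp$membership)[comp$membership == k])
    nb <- sum(bonds$parent %in% members | bonds$child %in% members)
    rows <- snapshot$fil %in% members
    xy <- snapshot$beads[rows, 1:2, drop = FALSE]
    data.frame(cluster = k, n_filaments = length(members), n_branches = nb,
               hull_area_um2 = hull_area(xy) * 1e-6,
               centroid_x = mean(xy[, 1]), centroid_y = mean(xy[, 2]))
  })
  do.call(rbind, out)
}

hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3) return(0)
  ch <- grDevices::chull(xy)
  v <- xy[ch, , drop = FALSE]
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Branch density per cluster, scaled to a reference area
#'
#' Per-cluster branch density (branches per um^2 of convex-hull footprint)
#' multiplied by a reference area (default 20 x 20 um^2 = 400 um^2) for
#' comparison across conditions. Hull areas below `area_floor` (default one
#' compartment footprint, 0.25 um^2) use the floor.
#'
#' @param clusters Output of [identify_branch_clusters()].
#' @param reference_area_um2 Reference area (um^2).
#' @param area_floor Minimum hull area (um^2).
#' @return Numeric vector of scaled per-cluster branch densities.
#' @export
branches_per_area_scaled <- function(clusters, reference_area_um2 = 400,
                                     area_floor = 0.25) {
  stopifnot(reference_area_um2 > 0)
  if (nrow(clusters) == 0) return(numeric(0))
  area <- pmax(clusters$hull_area_um2, area_floor)
  clusters$n_branches / area * reference_area_um2
}

#' Localization-response summary across localization factors
#'
#' Tabulates nucleation metrics per localization factor and tests the
#' monotone response with a replicate-level Spearman rank correlation of each
#' metric against f (negative correlation = enhancement with localization).
#'
#' @param results Named list: one element per f value (names are the f
#'   values), each a list of replicate `actin_trajectory` objects.
#' @return List with `table` (per-f means) and, when >= 2 f values are
#'   present, `spearman` (per metric: rho, p.value over replicate-level
#'   points).
#' @export
localization_response_summary <- function(results) {
  fs <- as.numeric(names(results))
  stopifnot(!any(is.na(fs)))
  rows <- list(); pts <- list()
  for (i in seq_along(results)) {
    reps <- results[[i]]
    fin <- vapply(reps, function(tr) {
      n <- nrow(tr$series)
      c(fil = tr$series$n_filaments[n], br = tr$series$n_branches[n])
    }, numeric(2))
    med_bpc <- vapply(reps, function(tr) {
      cl <- identify_branch_clusters(tr$snapshot)
      if (nrow(cl) == 0) return(0)
      stats::median(branches_per_area_scaled(cl))
    }, numeric(1))
    rows[[i]] <- data.frame(
      f = fs[i], n_replicates = length(reps),
      mean_filaments = mean(fin["fil", ]), sem_filaments =
        if (length(reps) > 1) stats::sd(fin["fil", ]) / sqrt(length(reps)) else 0,
      mean_branches = mean(fin["br", ]),
      median_branches_per_area = stats::median(med_bpc))
    pts[[i]] <- data.frame(f = fs[i], filaments = fin["fil", ],
                           branches = fin["br", ], branch_density = med_bpc)
  }
  tab <- do.call(rbind, rows)
  out <- list(table = tab[order(tab$f), ])
  pts <- do.call(rbind, pts)
  if (length(unique(pts$f)) >= 2) {
    sp <- lapply(c("filaments", "branches", "branch_density"), function(mm) {
      if (stats::sd(pts[[mm]]) == 0) {
        return(data.frame(metric = mm, rho = NA_real_, p.value = NA_real_))
      }
      ct <- suppressWarnings(
        stats::cor.test(pts$f, pts[[mm]], method = "spearman", exact = FALSE))
      data.frame(metric = mm, rho = unname(ct$estimate),
                 p.value = ct$p.value)
    })
    out$spearman <- do.call(rbind, sp)
    out$points <- pts
  }
  out
}

#' Box-plot summary statistics (median, quartiles, 95\% whiskers)
#'
#' @param x Numeric vector.
#' @return One-row data.frame with `median`, `q1`, `q3`, `lo95`, `hi95`,
#'   `n_outliers`.
#' @export
box_summary <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  data.frame(median = q[3], q1 = q[2], q3 = q[4], lo95 = q[1], hi95 = q[5],
             n_outliers = sum(x < q[1] | x > q[5]))
}
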