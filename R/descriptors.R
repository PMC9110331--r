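# Local-structure descriptors: LSI, probe-sphere local density, RDFs.

#' Local structure index (LSI) of a molecule
#'
#' Orders the oxygen neighbors of a molecule by distance,
#' r_1 < r_2 < ... < r_n < cutoff < r_{n+1}, forms the consecutive gaps
#' Delta(i) = r_{i+1} - r_i for i = 1..n (note the last gap straddles the
#' cutoff), and returns their population variance
#' LSI = (1/n) sum (Delta(i) - mean Delta)^2. High LSI marks a tetrahedral,
#' gap-opened first shell; low LSI a disordered one. Ties (equal distances)
#' contribute zero gaps and are kept.
#'
#' @param frame a [water_frame()].
#' @param molecule molecule index.
#' @param shell_cutoff first-shell cutoff (Angstrom, default 3.7).
#' @return List with `lsi` (Angstrom^2), `n` (neighbors inside the shell),
#'   `r` (ordered distances used, n+1 values), `gaps` and `mean_gap`; or
#'   `NULL` when the molecule has no neighbor inside the cutoff or none
#'   beyond it (LSI undefined; excluded from averages).
#' @export
lsi <- function(frame, molecule, shell_cutoff = 3.7) {
  o <- frame$oxygen
  n_all <- nrow(o)
  d <- min_image_dist(o[rep(molecule, n_all - 1L), , drop = FALSE],
                      o[-molecule, , drop = FALSE], frame$box)
  d <- sort(d)
  n <- sum(d < shell_cutoff)
  if (n < 1L || n >= length(d)) return(NULL)
  r <- d[seq_len(n + 1L)]
  gaps <- diff(r)
  mg <- mean(gaps)
  list(lsi = mean((gaps - mg)^2), n = n, r = r, gaps = gaps, mean_gap = mg)
}

#' LSI values for a set of molecules
#' @param frame a [water_frame()].
#' @param molecules molecule indices (default all).
#' @param shell_cutoff first-shell cutoff (Angstrom).
#' @return Numeric vector (NA where the LSI is undefined).
#' @export
lsi_profile <- function(frame, molecules = seq_len(n_molecules(frame)),
                        shell_cutoff = 3.7) {
  vapply(molecules, function(m) {
    res <- lsi(frame, m, shell_cutoff)
    if (is.null(res)) NA_real_ else res$lsi
  }, numeric(1))
}

#' Local density profile around a cluster's geometric center
#'
#' Places a probe sphere (radius `probe_radius`, default 4.6 Angstrom) at
#' probe centers and reports the local number density (oxygen count inside
#' the probe divided by the probe volume), averaged in radial bins of
#' distance from the cluster's geometric center. Probe centers are either
#' the cluster's own oxygen atoms (`centers = "oxygen"`, default) or
#' regularly spaced points along random rays from the center
#' (`centers = "grid"`).
#'
#' @param frame a [water_frame()].
#' @param cluster a cluster object (list with `molecules`) or molecule
#'   indices.
#' @param graph the frame's `hbond_graph`, used to unwrap the cluster.
#' @param probe_radius probe-sphere radius (Angstrom).
#' @param bin_width radial bin width (Angstrom, default 0.5).
#' @param centers probe placement mode.
#' @return `data.frame(r, rho_local, n_probes)`; `rho_local` in
#'   molecules/Angstrom^3.
#' @export
local_density_profile <- function(frame, cluster, graph, probe_radius = 4.6,
                                  bin_width = 0.5,
                                  centers = c("oxygen", "grid")) {
  centers <- match.arg(centers)
  if (probe_radius > min(frame$box) / 2)
    stop("probe radius exceeds half the smallest box length")
  molecules <- if (is.list(cluster)) cluster$molecules else as.integer(cluster)
  pts <- unwrap_molecules(frame, molecules, graph)
  ctr <- colMeans(pts)
  probes <- if (centers == "oxygen") pts
  else {
    rmax <- max(min_image_dist(matrix(ctr, nrow(pts), 3, byrow = TRUE),
                               pts, frame$box))
    k <- max(2L, ceiling(rmax / bin_width) + 1L)
    sweep(matrix(seq(0, rmax, length.out = k), k, 3) *
            matrix(rep(c(1, 0, 0), each = k), k, 3), 2L, ctr, "+")
  }
  dist_ctr <- sqrt(rowSums(sweep(probes, 2L, ctr)^2))
  vol <- (4 / 3) * pi * probe_radius^3
  counts <- vapply(seq_len(nrow(probes)), function(k) {
    d <- min_image_dist(matrix(probes[k, ], n_molecules(frame), 3,
                               byrow = TRUE),
                        frame$oxygen, frame$box)
    sum(d < probe_radius)
  }, numeric(1))
  rho <- counts / vol
  bin <- floor(dist_ctr / bin_width)
  agg <- tapply(rho, bin, mean)
  out <- data.frame(r = (as.numeric(names(agg)) + 0.5) * bin_width,
                    rho_local = as.numeric(agg),
                    n_probes = as.integer(table(bin)))
  out[order(out$r), , drop = FALSE]
}

#' Radial distribution function between two selections
#'
#' Standard pair-distance histogram normalized by the ideal-gas expectation
#' at the selections' densities: g(r) = V / (N_a N_b') * h(r) / (4 pi r^2
#' dr), with N_b' = N_b - 1 for identical selections (self pairs excluded).
#'
#' @param frame a [water_frame()] (supplies the box); or `NULL` when `box`
#'   is given.
#' @param selection_a,selection_b coordinate matrices, or molecule index
#'   vectors resolved against the frame's oxygens; `selection_b = NULL`
#'   reuses `selection_a`.
#' @param r_max histogram range (Angstrom, at most half the smallest box
#'   edge).
#' @param bin_width histogram bin width (Angstrom, default 0.1).
#' @param box optional explicit box (Angstrom) overriding the frame's.
#' @return `data.frame(r, g)` with bin centers and g(r).
#' @export
rdf <- function(frame, selection_a, selection_b = NULL, r_max = NULL,
                bin_width = 0.1, box = NULL) {
  if (is.null(box)) box <- frame$box
  resolve <- function(sel) {
    if (is.null(sel)) return(NULL)
    if (is.matrix(sel)) sel else frame$oxygen[as.integer(sel), , drop = FALSE]
  }
  xa <- resolve(selection_a)
  xb <- resolve(selection_b)
  same <- is.null(xb)
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box length")
  na <- nrow(xa)
  nb <- if (same) na else nrow(xb)
  if (na < 1L || nb < 1L || (same && na < 2L))
    stop("empty selection for rdf")
  pairs <- pair_search(xa, if (same) NULL else xb, box, r_max)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  h <- hist(pairs$d, breaks = edges, plot = FALSE)$counts
  if (same) h <- 2 * h  # ordered pairs
  vol_box <- prod(box)
  shell <- (4 / 3) * pi * diff(edges^3)
  norm <- na * (if (same) nb - 1L else nb) / vol_box
  data.frame(r = (edges[-length(edges)] + edges[-1]) / 2,
             g = h / (norm * shell))
}

#' Geometric or mass center of a molecule set
#' @param frame a [water_frame()].
#' @param molecules molecule indices.
#' @param graph `hbond_graph` for unwrapping.
#' @param mode `"geometric"` (unweighted oxygen mean, default) or `"mass"`
#'   (full-molecule center of mass).
#' @return Numeric 3-vector.
#' @export
cluster_center <- function(frame, molecules, graph,
                           mode = c("geometric", "mass")) {
  mode <- match.arg(mode)
  pts <- unwrap_molecules(frame, molecules, graph)
  if (mode == "geometric") return(colMeans(pts))
  # center of mass including hydrogens (m_O = 15.999, m_H = 1.008)
  tot <- matrix(0, 1, 3)
  msum <- 0
  for (k in seq_along(molecules)) {
    m <- molecules[k]
    hs <- which(frame$h_owner == m)
    o <- pts[k, ]
    h1 <- o + wrap_displacement(frame$hydrogen[hs[1], ] - o, frame$box)
    h2 <- o + wrap_displacement(frame$hydrogen[hs[2], ] - o, frame$box)
    tot <- tot + 15.999 * o + 1.008 * (h1 + h2)
    msum <- msum + 15.999 + 2 * 1.008
  }
  as.numeric(tot / msum)
}
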