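# Cluster morphology: periodic unwrapping, maximum diameter, alpha-shape
# metrics per cluster, and the scaling fits relating size, radius, volume
# and surface area.

# Unwrap a molecule set into contiguous real-space coordinates: BFS over the
# hydrogen-bond graph restricted to the set, placing each neighbor at its
# minimum-image position relative to its parent. Disconnected parts (rare;
# a community can in principle contain non-adjacent fragments) are unwrapped
# independently from their own roots.
unwrap_molecules <- function(frame, molecules, graph) {
  molecules <- as.integer(molecules)
  pos <- frame$oxygen[molecules, , drop = FALSE]
  box <- frame$box
  idx <- match(seq_len(graph$n), molecules)   # global -> local or NA
  adj <- adjacency_list(graph)
  out <- matrix(NA_real_, length(molecules), 3L)
  placed <- logical(length(molecules))
  for (start in seq_along(molecules)) {
    if (placed[start]) next
    out[start, ] <- pos[start, ]
    placed[start] <- TRUE
    frontier <- start
    while (length(frontier)) {
      nxt <- integer(0)
      for (loc in frontier) {
        g <- molecules[loc]
        for (nb in adj[[g]]) {
          nloc <- idx[nb]
          if (!is.na(nloc) && !placed[nloc]) {
            out[nloc, ] <- out[loc, ] +
              wrap_displacement(pos[nloc, ] - out[loc, ], box)
            placed[nloc] <- TRUE
            nxt <- c(nxt, nloc)
          }
        }
      }
      frontier <- nxt
    }
  }
  out
}

#' Maximum diameter of a point set
#'
#' The longest pairwise distance (for clusters: between oxygen positions of
#' the unwrapped cluster). Zero for a single point.
#'
#' @param points numeric n x 3 matrix of unwrapped positions.
#' @return Largest pairwise Euclidean distance.
#' @export
max_diameter <- function(points) {
  points <- as_coord_matrix(points, "input")
  n <- nrow(points)
  if (n < 2L) return(0)
  max(stats::dist(points))
}

#' Shape, size and diameter of every cluster in a frame
#'
#' Unwraps each cluster across the periodic boundary, computes its
#' alpha-shape volume and area, maximum diameter L and radius r = L/2.
#' Clusters whose shape is degenerate (< 4 molecules or coplanar) get NA
#' volume and area.
#'
#' @param clusters a `water_clusters` object.
#' @param frame the `water_frame`.
#' @param graph the frame's `hbond_graph` (used for unwrapping).
#' @param alpha_radius alpha radius (Angstrom), default 3.5.
#' @return `data.frame(cluster_id, S, V, A, L, r)`.
#' @export
cluster_shapes <- function(clusters, frame, graph, alpha_radius = 3.5) {
  rows <- lapply(clusters, function(cl) {
    pts <- unwrap_molecules(frame, cl$molecules, graph)
    L <- max_diameter(pts)
    va <- tryCatch(alpha_shape_metrics(pts, alpha_radius),
                   aquaclust_degenerate_shape = function(e)
                     list(volume = NA_real_, area = NA_real_))
    data.frame(cluster_id = cl$cluster_id, S = cl$S,
               V = va$volume, A = va$area, L = L, r = L / 2)
  })
  do.call(rbind, rows)
}

#' Analytic shape factor of an ideal solid
#'
#' Intercept `b` of the surface-volume relation `ln A = (2/3) ln V + b` for
#' an ideal sphere, cube, or regular tetrahedron.
#'
#' @param solid one of `"sphere"`, `"cube"`, `"tetrahedron"`.
#' @return The analytic intercept (sphere 1.5760, cube 1.7918,
#'   tetrahedron 1.9760).
#' @export
shape_factor_reference <- function(solid = c("sphere", "cube", "tetrahedron")) {
  solid <- match.arg(solid)
  switch(solid,
         sphere = log(4 * pi) - (2 / 3) * log(4 * pi / 3),
         cube = log(6),
         tetrahedron = log(sqrt(3)) + (2 / 3) * log(6 * sqrt(2)))
}

#' Surface-volume scaling fit in two volume regimes
#'
#' Least-squares fit of `ln A = a ln V + b`, separately for small
#' (`V < split_volume`) and large (`V > split_volume`) shapes. A regime with
#' fewer than 3 usable shapes is skipped with a warning.
#'
#' @param shapes data.frame with columns `V` and `A` (as from
#'   [cluster_shapes()]).
#' @param split_volume regime boundary in Angstrom^3 (default 100).
#' @param fixed_slope optional: fix the slope and fit only the intercept.
#' @return List with elements `small` and `large`, each either `NULL`
#'   (skipped) or a list with `a`, `b`, `n`, `range_V` and `residual_sd`.
#' @export
surface_volume_fit <- function(shapes, split_volume = 100,
                               fixed_slope = NULL) {
  ok <- is.finite(shapes$V) & is.finite(shapes$A) &
    shapes$V > 0 & shapes$A > 0
  fit_one <- function(sel, label) {
    if (sum(sel) < 3L) {
      warning(sprintf("surface_volume_fit: %s regime has < 3 shapes; skipped",
                      label))
      return(NULL)
    }
    lv <- log(shapes$V[sel]); la <- log(shapes$A[sel])
    if (is.null(fixed_slope)) {
      f <- lm(la ~ lv)
      a <- unname(coef(f)[2]); b <- unname(coef(f)[1])
      rsd <- sd(stats::residuals(f))
    } else {
      a <- fixed_slope
      b <- mean(la - a * lv)
      rsd <- sd(la - a * lv - b)
    }
    list(a = a, b = b, n = sum(sel), range_V = range(shapes$V[sel]),
         residual_sd = rsd)
  }
  list(small = fit_one(ok & shapes$V < split_volume, "small"),
       large = fit_one(ok & shapes$V > split_volume, "large"))
}

#' Power-law exponent of a cluster-size distribution
#'
#' Fits the exponent tau of `n_S ~ S^-tau`. The default estimator bins the
#' sizes logarithmically, converts bin counts to densities (count / linear
#' bin width), and regresses log density on log bin center; `method = "mle"`
#' uses the continuous-Pareto maximum-likelihood estimator instead.
#'
#' @param sizes integer vector of observed cluster sizes (the sample), or a
#'   named table of counts per size.
#' @param fit_min_size smallest size included in the fit.
#' @param method `"lsq"` (log-binned least squares, default) or `"mle"`.
#' @param bins_per_decade log-bin resolution for `"lsq"`.
#' @param min_bin_count smallest bin occupancy admitted to the regression
#'   (default 10; sparsely occupied tail bins carry large multiplicative
#'   noise). Relaxed automatically when fewer than 3 bins qualify.
#' @return List with `tau`, `method`, `n` (sizes used) and, for `"lsq"`,
#'   the fitted intercept and number of occupied bins.
#' @export
powerlaw_exponent <- function(sizes, fit_min_size = 1L,
                              method = c("lsq", "mle"),
                              bins_per_decade = 8, min_bin_count = 10L) {
  method <- match.arg(method)
  if (is.table(sizes) || !is.null(names(sizes)))
    sizes <- rep(as.integer(names(sizes)), as.integer(sizes))
  sizes <- as.numeric(sizes[sizes >= fit_min_size])
  if (length(unique(sizes)) < 3L)
    stop("fit error: need at least 3 distinct sizes above fit_min_size")
  if (method == "mle") {
    smin <- min(sizes)
    tau <- 1 + length(sizes) / sum(log(sizes / (smin - 0.5)))
    return(list(tau = tau, method = "mle", n = length(sizes)))
  }
  smin <- min(sizes)
  smax <- max(sizes)
  nb <- max(3L, ceiling(log10(smax / smin) * bins_per_decade))
  edges <- smin * (smax / smin + 1e-9)^(seq(0, 1, length.out = nb + 1L))
  edges[1] <- edges[1] * (1 - 1e-12)
  h <- hist(sizes, breaks = edges, plot = FALSE)
  width <- diff(edges)
  dens <- h$counts / width
  ctr <- sqrt(edges[-length(edges)] * edges[-1])   # geometric bin centers
  occ <- h$counts >= min_bin_count
  if (sum(occ) < 3L) occ <- h$counts > 0L
  if (sum(occ) < 3L)
    stop("fit error: fewer than 3 occupied bins")
  f <- lm(log(dens[occ]) ~ log(ctr[occ]))
  list(tau = -unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       method = "lsq", n = length(sizes), n_bins = sum(occ))
}

#' Log-log scaling of volume and area with cluster radius
#'
#' Fits the exponents `d_V` (slope of ln V vs ln r) and `d_S` (slope of
#' ln A vs ln r), where r = L/2 is the cluster radius.
#'
#' @param shapes data.frame with columns `V`, `A` and `r` (as from
#'   [cluster_shapes()]).
#' @return List with `d_V`, `d_S` and `n` shapes used.
#' @export
radius_scaling_fit <- function(shapes) {
  ok <- is.finite(shapes$V) & is.finite(shapes$A) & is.finite(shapes$r) &
    shapes$V > 0 & shapes$A > 0 & shapes$r > 0
  if (sum(ok) < 3L) stop("fit error: need at least 3 shapes with r > 0")
  lr <- log(shapes$r[ok])
  if (sd(lr) == 0) stop("fit error: degenerate radii")
  d_V <- unname(coef(lm(log(shapes$V[ok]) ~ lr))[2])
  d_S <- unname(coef(lm(log(shapes$A[ok]) ~ lr))[2])
  list(d_V = d_V, d_S = d_S, n = sum(ok))
}

#' Crossing point (isosbestic point) of two distributions
#'
#' Locates where two distributions tabulated on a common grid cross: the
#' sign changes of their (optionally smoothed) difference. Used to find the
#' isosbestic cluster size S_c or length L_c separating opposite temperature
#' responses.
#'
#' @param grid common abscissa (sizes or lengths), increasing.
#' @param dist1,dist2 the two distributions on `grid`.
#' @param smooth_window moving-average window in grid points (default 5;
#'   1 disables smoothing).
#' @return List with `crossings` (interpolated locations, possibly empty)
#'   and `intervals` (two-column matrix of bracketing grid values).
#' @export
distribution_crossing <- function(grid, dist1, dist2, smooth_window = 5L) {
  stopifnot(length(grid) == length(dist1), length(grid) == length(dist2))
  sm <- function(y) {
    w <- max(1L, as.integer(smooth_window))
    if (w == 1L) return(y)
    stats::filter(y, rep(1 / w, w), sides = 2) |> as.numeric()
  }
  dif <- sm(dist1) - sm(dist2)
  # scan sign changes between consecutive nonzero values (exact zeros lie
  # on the crossing itself and carry no sign)
  ok <- which(!is.na(dif) & dif != 0)
  crossings <- numeric(0)
  intervals <- matrix(numeric(0), ncol = 2L)
  for (k in seq_along(ok)[-1]) {
    i0 <- ok[k - 1L]; i1 <- ok[k]
    if (sign(dif[i0]) * sign(dif[i1]) < 0) {
      x <- grid[i0] + (grid[i1] - grid[i0]) * abs(dif[i0]) /
        (abs(dif[i0]) + abs(dif[i1]))
      crossings <- c(crossings, x)
      intervals <- rbind(intervals, c(grid[i0], grid[i1]))
    }
  }
  list(crossings = crossings, intervals = intervals)
}
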