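# Synthetic water structures with known topology.
#
# These builders produce coordinate fixtures whose hydrogen-bond graph is
# known by construction, so every downstream stage (rings, fragments,
# clusters, shapes, dynamics) can be validated without trajectory data:
# theta cages realizing given ring signatures, hexagonal-ice lattices,
# random packings, ideal-solid surface samples, and power-law size samples.

#' Build a theta cage realizing a target ring signature
#'
#' A theta cage consists of two degree-3 "pole" molecules joined by three
#' internally disjoint hydrogen-bonded paths with `p1, p2, p3` edges; its
#' three cycles have sizes `p1+p2`, `p1+p3`, `p2+p3`. Path spec `(2,2,3)`
#' yields the 6-molecule (4,5,5) cage; `(3,3,4)` the 9-molecule (6,7,7)
#' cage; `(2,2,6)` the 9-molecule (4,8,8) cage. The poles sit on the z axis
#' and each path is laid on a meridional circular arc (azimuths 120 degrees
#' apart), scaled so that every intended O-O contact is exactly the bond
#' length and all other O-O distances exceed 3.5 Angstrom; donors are
#' oriented so no molecule donates more than twice, and each donor hydrogen
#' sits 1.0 Angstrom from its oxygen along the bond. The construction is
#' deterministic, and the returned graph is verified against
#' [detect_hbonds()].
#'
#' @param paths integer vector `c(p1, p2, p3)` of path edge counts (all
#'   positive, at most one equal to 1).
#' @param box box edge lengths (Angstrom, default 30).
#' @param bond_length intended O-O hydrogen-bond distance (default 2.8).
#' @param max_ring_size largest admissible implied ring size (default 8).
#' @return List with `frame` (a [water_frame()]), `edges` (intended
#'   hydrogen-bond pairs), `expected_signature` (sorted implied ring sizes)
#'   and `n_molecules` (`2 + sum(paths - 1)`).
#' @examples
#' cage <- build_theta_cage(c(2, 2, 3))
#' cage$expected_signature  # 4 5 5
#' @export
build_theta_cage <- function(paths, box = c(30, 30, 30), bond_length = 2.8,
                             max_ring_size = 8L) {
  paths <- as.integer(paths)
  if (length(paths) != 3L || any(paths < 1L))
    stop("spec error: need three path edge counts >= 1")
  if (sum(paths == 1L) > 1L)
    stop("spec error: at most one path may be a single edge (no multi-edges)")
  ring_sizes <- sort(c(paths[1] + paths[2], paths[1] + paths[3],
                       paths[2] + paths[3]))
  if (any(ring_sizes > max_ring_size))
    stop(sprintf("spec error: implied ring size %d exceeds max ring size %d",
                 max(ring_sizes), max_ring_size))
  box <- rep(as.numeric(box), length.out = 3L)
  d <- bond_length
  min_sep <- 3.5

  # pole separation: bonded poles (p = 1 path) sit at bond length; otherwise
  # far enough apart to be non-bonded but inside every arc's reach
  H <- if (any(paths == 1L)) d else 1.06 * min_sep
  half <- H / 2
  # internal vertices of a p-edge path lie on a circular arc through both
  # poles in the meridian plane at azimuth phi; the arc's center offset c
  # (< 0, bulging outward) is solved so consecutive points are d apart
  arc_points <- function(p, phi) {
    if (p == 1L) return(NULL)
    chord_gap <- function(cc) {
      rho <- sqrt(cc^2 + half^2)
      gamma <- atan2(half, -cc)           # pole angular position
      2 * rho * sin(gamma / p) - d
    }
    # bracket: cc -> -Inf gives straight line (gap H/p - d < 0 for p*d > H);
    # cc -> 0- gives half-circle arcs with gap pi*half/p-ish
    lo <- -50 * d
    hi <- 50 * d
    if (chord_gap(lo) * chord_gap(hi) > 0)
      stop("geometry error: cannot embed path arc")
    cc <- stats::uniroot(chord_gap, c(lo, hi), tol = 1e-12)$root
    rho <- sqrt(cc^2 + half^2)
    gamma <- atan2(half, -cc)
    ang <- gamma - (1:(p - 1L)) * (2 * gamma / p)   # from +z pole downwards
    x_loc <- cc + rho * cos(ang)
    z_loc <- rho * sin(ang)
    cbind(x_loc * cos(phi), x_loc * sin(phi), z_loc)
  }

  pts <- rbind(c(0, 0, half), c(0, 0, -half))   # poles: molecules 1, 2
  path_ids <- vector("list", 3L)
  phis <- c(0, 2 * pi / 3, 4 * pi / 3)
  for (k in 1:3) {
    internal <- arc_points(paths[k], phis[k])
    ids <- integer(0)
    if (!is.null(internal)) {
      ids <- nrow(pts) + seq_len(nrow(internal))
      pts <- rbind(pts, internal)
    }
    path_ids[[k]] <- c(1L, ids, 2L)
  }
  edges <- do.call(rbind, lapply(path_ids, function(ids)
    cbind(ids[-length(ids)], ids[-1L])))

  # verify separation: non-bonded O-O must exceed min_sep
  dm <- as.matrix(stats::dist(pts))
  bonded <- matrix(FALSE, nrow(pts), nrow(pts))
  bonded[edges] <- TRUE
  bonded <- bonded | t(bonded)
  nonbond <- dm[!bonded & upper.tri(dm)]
  if (length(nonbond) && min(nonbond) <= min_sep)
    stop(sprintf("geometry error: non-bonded O-O contact at %.2f A", min(nonbond)))

  pts <- sweep(pts, 2L, box / 2, "+")   # center in the box
  frame <- place_hydrogens(pts, edges, box)
  # verify that geometric detection reconstructs the intended graph
  got <- detect_hbonds(frame)$edges
  want <- unique(data.frame(i = pmin(edges[, 1], edges[, 2]),
                            j = pmax(edges[, 1], edges[, 2])))
  if (!identical(nrow(got), nrow(want)) ||
      !all(paste(got$i, got$j) %in% paste(want$i, want$j)))
    stop("geometry error: detected hydrogen bonds differ from intended graph")
  sp <- sort(paths)
  list(frame = frame, edges = want,
       expected_signature = ring_sizes,
       n_molecules = 2L + sum(paths - 1L),
       # all three cycles are shortest-path rings (and hence close into a
       # cage fragment) only when the two shortest paths are equally long;
       # otherwise the largest cycle is short-cuttable and rejected
       closes = sp[1] == sp[2])
}

# Orient edges so that no molecule donates more than twice, then place a
# donor hydrogen 1.0 A from its oxygen along each bond and park remaining
# hydrogens (2 per molecule) pointing away from every other molecule.
place_hydrogens <- function(o_pts, edges, box) {
  n <- nrow(o_pts)
  m <- nrow(edges)
  # greedy orientation with local repair: works for max degree <= 4
  don <- integer(m)
  count <- integer(n)
  deg <- tabulate(c(edges[, 1], edges[, 2]), n)
  ord <- order(-pmax(deg[edges[, 1]], deg[edges[, 2]]))
  for (e in ord) {
    a <- edges[e, 1]; b <- edges[e, 2]
    don[e] <- if (count[a] <= count[b]) a else b
    count[don[e]] <- count[don[e]] + 1L
  }
  # repair any molecule donating 3+ by flipping an edge to an under-donor
  repeat {
    over <- which(count > 2L)
    if (!length(over)) break
    fixed <- FALSE
    for (v in over) {
      es <- which(don == v)
      for (e in es) {
        other <- setdiff(edges[e, ], v)
        if (count[other] < 2L) {
          don[e] <- other
          count[v] <- count[v] - 1L
          count[other] <- count[other] + 1L
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) stop("geometry error: cannot orient donors (degree too high)")
  }
  ctr <- colMeans(o_pts)
  h_list <- vector("list", n)
  for (e in seq_len(m)) {
    a <- don[e]; b <- setdiff(edges[e, ], a)
    u <- o_pts[b, ] - o_pts[a, ]
    u <- u / sqrt(sum(u^2))
    h_list[[a]] <- rbind(h_list[[a]], o_pts[a, ] + u)
  }
  for (v in seq_len(n)) {
    have <- if (is.null(h_list[[v]])) 0L else nrow(h_list[[v]])
    while (have < 2L) {
      u <- o_pts[v, ] - ctr
      nu <- sqrt(sum(u^2))
      u <- if (nu < 1e-9) c(0, 0, 1) else u / nu
      if (have == 1L) {
        # second spare H: rotate away from the first
        u <- u + c(0.3, 0.4, 0.5)
        u <- u / sqrt(sum(u^2))
      }
      h_list[[v]] <- rbind(h_list[[v]], o_pts[v, ] + u)
      have <- have + 1L
    }
  }
  h <- do.call(rbind, h_list)
  owner <- rep(seq_len(n), vapply(h_list, nrow, integer(1)))
  water_frame(o_pts, h, owner, box)
}

#' Build a hexagonal-ice-like lattice frame
#'
#' Oxygens on the hexagonal-diamond (ice Ih) lattice with nearest-neighbor
#' distance `bond_length` (default 2.75 Angstrom), in an orthorhombic cell
#' of 8 molecules repeated `repeats` times per dimension, fully periodic.
#' Hydrogen placement follows the two-donor ice rule: the 4-regular bond
#' graph is given an Eulerian orientation, so every molecule donates
#' exactly two hydrogen bonds. Every interior and boundary molecule is
#' 4-coordinated under periodic boundaries.
#'
#' @param repeats integer length-3 (or scalar) unit-cell repeats.
#' @param bond_length O-O distance (Angstrom).
#' @return List with `frame`, `edges` (intended bond pairs) and
#'   `n_molecules` (`8 * prod(repeats)`).
#' @export
build_hexagonal_lattice <- function(repeats = c(2L, 2L, 2L),
                                    bond_length = 2.75) {
  repeats <- rep(as.integer(repeats), length.out = 3L)
  if (any(repeats < 1L)) stop("repeats must be >= 1")
  d <- bond_length
  a <- d * sqrt(8 / 3)           # in-plane lattice constant
  cell <- c(a, a * sqrt(3), 8 * d / 3)
  # 8 oxygens per orthorhombic cell: two puckered honeycomb bilayers
  frac_xy_a <- rbind(c(0, 0), c(0.5, 0.5))        # honeycomb sublattice a
  frac_xy_b <- rbind(c(0, 1 / 3), c(0.5, 5 / 6))  # honeycomb sublattice b
  z <- d * c(0, 1 / 3, 4 / 3, 5 / 3)
  base <- rbind(
    cbind(frac_xy_a %*% diag(cell[1:2]), z[1]),
    cbind(frac_xy_b %*% diag(cell[1:2]), z[2]),
    cbind(frac_xy_b %*% diag(cell[1:2]), z[3]),
    cbind(frac_xy_a %*% diag(cell[1:2]), z[4]))
  shifts <- as.matrix(expand.grid(0:(repeats[1] - 1L), 0:(repeats[2] - 1L),
                                  0:(repeats[3] - 1L)))
  pts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k)
    sweep(base, 2L, shifts[k, ] * cell, "+")))
  box <- repeats * cell
  # intended bonds: all O-O pairs at the nearest-neighbor distance
  prs <- pair_search(pts, NULL, box, d * 1.05)
  edges <- cbind(prs$i, prs$j)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nrow(pts))
  if (any(deg != 4L))
    stop("internal error: ice lattice is not 4-regular")
  # Eulerian orientation => exactly two donors per molecule
  g <- igraph::make_empty_graph(n = nrow(pts), directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  vp <- as.integer(igraph::eulerian_cycle(g)$vpath)
  o_pts <- pts
  h_list <- vector("list", nrow(pts))
  for (k in seq_len(length(vp) - 1L)) {
    aa <- vp[k]; bb <- vp[k + 1L]
    u <- wrap_displacement(o_pts[bb, ] - o_pts[aa, ], box)
    u <- u / sqrt(sum(u^2))
    h_list[[aa]] <- rbind(h_list[[aa]], o_pts[aa, ] + u)
  }
  h <- do.call(rbind, h_list)
  owner <- rep(seq_len(nrow(pts)), vapply(h_list, nrow, integer(1)))
  frame <- water_frame(o_pts, h, owner, box)
  list(frame = frame,
       edges = data.frame(i = prs$i, j = prs$j),
       n_molecules = nrow(pts))
}

#' Random water packing (ring-free negative control)
#'
#' Seeded sequential random packing of `n` molecules at the given number
#' density with a hard minimum O-O separation; hydrogen orientations are
#' random. The box edge is `(n / density)^(1/3)`.
#'
#' @param n_molecules molecule count.
#' @param density number density (molecules per Angstrom^3; bulk water at
#'   298 K is about 0.0334).
#' @param min_separation hard O-O separation floor (Angstrom, default 2.5).
#' @param seed integer seed (bit-reproducible output).
#' @param max_attempts insertion attempts per molecule before giving up.
#' @return A [water_frame()].
#' @export
build_random_box <- function(n_molecules, density = 0.0334,
                             min_separation = 2.5, seed = 1L,
                             max_attempts = 2000L) {
  n <- as.integer(n_molecules)
  edge <- (n / density)^(1 / 3)
  box <- rep(edge, 3L)
  if (min_separation > edge / 2)
    stop("density not achievable at this separation")
  with_seed(seed, {
    pts <- matrix(NA_real_, n, 3L)
    placed <- 0L
    attempts <- 0L
    while (placed < n) {
      cand <- runif(3L) * box
      ok <- TRUE
      if (placed > 0L) {
        dmin <- min(min_image_dist(matrix(cand, placed, 3L, byrow = TRUE),
                                   pts[seq_len(placed), , drop = FALSE], box))
        ok <- dmin >= min_separation
      }
      if (ok) {
        placed <- placed + 1L
        pts[placed, ] <- cand
        attempts <- 0L
      } else {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("packing failure: too many rejected insertions")
      }
    }
    # random rigid-water hydrogen orientations (HOH angle 109.47 deg)
    h <- matrix(NA_real_, 2L * n, 3L)
    for (m in seq_len(n)) {
      u <- rnorm(3L); u <- u / sqrt(sum(u^2))
      v <- rnorm(3L); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
      ang <- 109.47 * pi / 180
      h1 <- u
      h2 <- cos(ang) * u + sin(ang) * v
      h[2L * m - 1L, ] <- pts[m, ] + h1
      h[2L * m, ] <- pts[m, ] + h2
    }
    water_frame(pts, h, rep(seq_len(n), each = 2L), box)
  })
}

#' Sample cluster sizes from a discrete power law
#'
#' Draws `n` i.i.d. integers from `P(S) proportional to S^-tau` for
#' `S >= s_min` (support truncated at `s_max`), by inverse-CDF sampling.
#'
#' @param tau exponent (> 1; the distribution is non-normalizable
#'   otherwise).
#' @param s_min smallest size (>= 1).
#' @param n sample count.
#' @param seed integer seed.
#' @param s_max support truncation (default 10^6).
#' @return Integer vector of length `n`.
#' @export
sample_cluster_sizes <- function(tau, s_min = 1L, n, seed = 1L,
                                 s_max = 1e6) {
  if (tau <= 1) stop("parameter error: tau must exceed 1")
  s_min <- as.integer(s_min)
  if (s_min < 1L) stop("s_min must be >= 1")
  if (n == 0L) return(integer(0))
  support <- s_min:as.integer(s_max)
  pmf <- support^(-tau)
  cdf <- cumsum(pmf) / sum(pmf)
  with_seed(seed, {
    u <- runif(n)
    support[findInterval(u, cdf) + 1L]
  })
}

#' Uniform samples on the surface of an ideal solid
#'
#' Area-uniform random points on the surface of a sphere (radius `size`),
#' cube (edge `size`) or regular tetrahedron (edge `size`), centered at the
#' origin. Polyhedron faces are sampled proportionally to their area.
#'
#' @param solid `"sphere"`, `"cube"` or `"tetrahedron"`.
#' @param size radius (sphere) or edge length (cube, tetrahedron),
#'   Angstrom.
#' @param n_points number of samples (>= 4).
#' @param seed integer seed.
#' @return `n_points` x 3 coordinate matrix.
#' @export
sample_solid_surface <- function(solid = c("sphere", "cube", "tetrahedron"),
                                 size, n_points, seed = 1L) {
  solid <- match.arg(solid)
  n <- as.integer(n_points)
  if (n < 4L) stop("need at least 4 points")
  with_seed(seed, {
    if (solid == "sphere") {
      g <- matrix(rnorm(3L * n), n, 3L)
      g <- g / sqrt(rowSums(g^2))
      return(g * size)
    }
    if (solid == "cube") {
      face <- sample.int(6L, n, replace = TRUE)
      uv <- matrix(runif(2L * n) - 0.5, n, 2L) * size
      pts <- matrix(0, n, 3L)
      axis <- (face - 1L) %/% 2L + 1L          # 1=x, 2=y, 3=z
      side <- ifelse(face %% 2L == 1L, 0.5, -0.5) * size
      for (k in seq_len(n)) {
        rest <- setdiff(1:3, axis[k])
        pts[k, axis[k]] <- side[k]
        pts[k, rest] <- uv[k, ]
      }
      return(pts)
    }
    # regular tetrahedron, edge `size`, centroid at origin
    v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
      (size / (2 * sqrt(2)))
    faces <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
    face <- sample.int(4L, n, replace = TRUE)      # equal-area faces
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    a <- v[faces[face, 1], , drop = FALSE]
    b <- v[faces[face, 2], , drop = FALSE]
    c_ <- v[faces[face, 3], , drop = FALSE]
    (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
  })
}
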