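# Alpha-shape volume and surface area from a 3D Delaunay triangulation.
#
# The alpha complex keeps every Delaunay tetrahedron whose circumradius is
# at most the alpha radius (a small relative tolerance absorbs float noise
# for marginal simplices); the shape's volume is the sum of kept tetrahedron
# volumes and its surface area the total area of facets bordering exactly
# one kept tetrahedron. alpha = Inf reduces to the convex hull.

#' Delaunay tetrahedralization of a 3D point set
#'
#' @param points numeric n x 3 matrix, n >= 4, not all coplanar.
#' @return Integer m x 4 matrix of point indices, one tetrahedron per row.
#' @export
delaunay_triangulation <- function(points) {
  points <- as_coord_matrix(points, "input")
  if (nrow(points) < 4L) stop("undefined shape: need at least 4 points")
  .delaunay3d_cpp(points)
}

# circumradii and volumes of tetrahedra, vectorized over rows of `tets`
tet_metrics <- function(points, tets) {
  a <- points[tets[, 1], , drop = FALSE]
  b <- points[tets[, 2], , drop = FALSE] - a
  c_ <- points[tets[, 3], , drop = FALSE] - a
  d <- points[tets[, 4], , drop = FALSE] - a
  cross <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cross(b, c_)
  det <- rowSums(d * bxc)              # 6 * signed volume
  vol <- abs(det) / 6
  # circumcenter relative to a: solves 2 M x = (|b|^2, |c|^2, |d|^2)
  b2 <- rowSums(b^2); c2 <- rowSums(c_^2); d2 <- rowSums(d^2)
  cxd <- cross(c_, d)
  dxb <- cross(d, b)
  # Cramer: x = (b2*cxd + c2*dxb + d2*bxc) / (2*det)
  num <- b2 * cxd + c2 * dxb + d2 * bxc
  denom <- 2 * det
  cc <- num / denom
  r <- sqrt(rowSums(cc^2))
  r[!is.finite(r) | abs(denom) < 1e-300] <- Inf
  list(volume = vol, circumradius = r)
}

#' Alpha-shape volume and surface area
#'
#' Computes the volume and boundary surface area of the alpha complex of a
#' point set at a given alpha radius (oxygen positions only, in cluster
#' use). Degenerate inputs (fewer than 4 points, or all points coplanar)
#' raise an error of class `aquaclust_degenerate_shape`; callers analysing
#' clusters catch it and report missing shape values.
#'
#' @param points numeric n x 3 matrix of positions (Angstrom).
#' @param alpha_radius circumradius threshold (Angstrom); `Inf` gives the
#'   convex hull.
#' @return List with `volume` (Angstrom^3), `area` (Angstrom^2),
#'   `n_tetrahedra` kept, and `alpha_radius`.
#' @examples
#' pts <- sample_solid_surface("cube", 10, 2000, seed = 1)
#' m <- alpha_shape_metrics(pts, alpha_radius = Inf)
#' c(m$volume, m$area)  # close to 1000 and 600
#' @export
alpha_shape_metrics <- function(points, alpha_radius = 3.5) {
  points <- as_coord_matrix(points, "input")
  if (nrow(points) < 4L)
    stop(structure(class = c("aquaclust_degenerate_shape", "error", "condition"),
                   list(message = "undefined shape: need at least 4 points",
                        call = sys.call())))
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2L, ctr))$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    stop(structure(class = c("aquaclust_degenerate_shape", "error", "condition"),
                   list(message = "undefined shape: points are (nearly) coplanar",
                        call = sys.call())))
  if (!is.finite(alpha_radius) && alpha_radius > 0) alpha_radius <- Inf
  if (alpha_radius <= 0) stop("alpha_radius must be positive")

  tets <- .delaunay3d_cpp(points)
  met <- tet_metrics(points, tets)
  keep <- if (is.infinite(alpha_radius)) rep(TRUE, nrow(tets))
          else met$circumradius <= alpha_radius * (1 + 1e-7)
  kept <- tets[keep, , drop = FALSE]
  vol <- sum(met$volume[keep])
  if (!nrow(kept))
    return(list(volume = 0, area = 0, n_tetrahedra = 0L,
                alpha_radius = alpha_radius))
  # boundary facets: those belonging to exactly one kept tetrahedron
  faces <- rbind(kept[, c(1, 2, 3)], kept[, c(1, 2, 4)],
                 kept[, c(1, 3, 4)], kept[, c(2, 3, 4)])
  faces <- t(apply(faces, 1L, sort))
  key <- paste(faces[, 1], faces[, 2], faces[, 3], sep = "-")
  cnt <- table(key)
  boundary <- faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  p1 <- points[boundary[, 1], , drop = FALSE]
  u <- points[boundary[, 2], , drop = FALSE] - p1
  v <- points[boundary[, 3], , drop = FALSE] - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  list(volume = vol, area = area, n_tetrahedra = nrow(kept),
       alpha_radius = alpha_radius)
}
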