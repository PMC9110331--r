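#' Construct a water configuration frame
#'
#' A `water_frame` holds one configuration of rigid water molecules in an
#' orthorhombic periodic box: oxygen positions, hydrogen positions, the
#' hydrogen-to-molecule assignment, the box edge lengths, and time metadata.
#' All lengths are in Angstrom, times in femtoseconds.
#'
#' Coordinates are stored as given (possibly outside the box); periodic
#' wrapping is applied only inside geometry operations, so input fidelity is
#' preserved.
#'
#' @param oxygen numeric matrix (n x 3) of oxygen positions (Angstrom).
#' @param hydrogen numeric matrix (2n x 3) of hydrogen positions (Angstrom).
#' @param h_owner integer vector (length 2n) mapping each hydrogen to the
#'   index of its molecule; every molecule must own exactly two hydrogens.
#' @param box numeric length-3 vector of positive box edge lengths (Angstrom).
#' @param frame_index integer frame number within a trajectory.
#' @param frame_time frame time in femtoseconds.
#' @return An object of class `water_frame`.
#' @examples
#' o <- rbind(c(0, 0, 0), c(2.8, 0, 0))
#' h <- rbind(c(1, 0, 0), c(-0.33, 0.94, 0), c(3.8, 0, 0), c(2.47, 0.94, 0))
#' frame <- water_frame(o, h, c(1L, 1L, 2L, 2L), box = c(20, 20, 20))
#' n_molecules(frame)
#' @export
water_frame <- function(oxygen, hydrogen, h_owner, box,
                        frame_index = 1L, frame_time = 0) {
  oxygen <- as_coord_matrix(oxygen, "oxygen")
  hydrogen <- as_coord_matrix(hydrogen, "hydrogen")
  h_owner <- as.integer(h_owner)
  box <- as.numeric(box)
  n <- nrow(oxygen)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive finite edge lengths")
  if (nrow(hydrogen) != 2L * n)
    stop(sprintf("composition error: %d hydrogens for %d oxygens (need 2 per molecule)",
                 nrow(hydrogen), n))
  if (length(h_owner) != nrow(hydrogen))
    stop("h_owner must map every hydrogen to a molecule")
  counts <- tabulate(h_owner, nbins = n)
  if (any(counts != 2L))
    stop(sprintf("composition error: molecule(s) %s do not own exactly 2 hydrogens",
                 paste(head(which(counts != 2L), 5L), collapse = ", ")))
  structure(
    list(oxygen = oxygen, hydrogen = hydrogen, h_owner = h_owner,
         box = box, frame_index = as.integer(frame_index),
         frame_time = as.numeric(frame_time)),
    class = "water_frame")
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(sprintf("%s coordinates must be n x 3", what))
  if (any(!is.finite(x))) stop(sprintf("non-finite %s coordinates", what))
  dimnames(x) <- NULL
  x
}

#' Number of molecules in a frame
#' @param frame a [water_frame()].
#' @return Integer molecule count.
#' @export
n_molecules <- function(frame) nrow(frame$oxygen)

#' @export
print.water_frame <- function(x, ...) {
  cat(sprintf("water_frame: %d molecules, box %.2f x %.2f x %.2f A, t = %.1f fs (frame %d)\n",
              n_molecules(x), x$box[1], x$box[2], x$box[3],
              x$frame_time, x$frame_index))
  invisible(x)
}

#' Analysis settings for the clustering pipeline
#'
#' Bundles every threshold used along the hierarchy so that a run is fully
#' described by one settings object. Defaults follow the geometric
#' hydrogen-bond criterion (O...H < 2.5 Angstrom), shortest-path rings up to
#' size 8, cage fragments of 3-5 rings, an alpha radius of 3.5 Angstrom for
#' cluster shapes, a 4.6 Angstrom probe sphere for local density, a 3.7
#' Angstrom first-shell cutoff for the local structure index, a 10 Angstrom
#' interaction cutoff for SPC/E pair energies, and a 10 fs frame interval.
#'
#' @param frame_interval time between consecutive frames (fs).
#' @param hb_cutoff hydrogen-bond O...H distance cutoff (Angstrom, strict `<`).
#' @param max_ring_size largest ring size enumerated (>= 3).
#' @param fragment_ring_counts admissible numbers of rings per cage fragment.
#' @param alpha_radius alpha radius for cluster shapes (Angstrom).
#' @param probe_radius probe-sphere radius for local density (Angstrom).
#' @param lsi_shell_cutoff first-shell cutoff for the LSI (Angstrom).
#' @param energy_cutoff pair-interaction truncation distance (Angstrom).
#' @param rng_seed integer seed controlling every stochastic step.
#' @return An object of class `trajectory_settings`.
#' @export
trajectory_settings <- function(frame_interval = 10.0,
                                hb_cutoff = 2.5,
                                max_ring_size = 8L,
                                fragment_ring_counts = c(3L, 4L, 5L),
                                alpha_radius = 3.5,
                                probe_radius = 4.6,
                                lsi_shell_cutoff = 3.7,
                                energy_cutoff = 10.0,
                                rng_seed = 1L) {
  lens <- c(frame_interval, hb_cutoff, alpha_radius, probe_radius,
            lsi_shell_cutoff, energy_cutoff)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths and intervals must be positive and finite")
  max_ring_size <- as.integer(max_ring_size)
  if (max_ring_size < 3L) stop("max_ring_size must be at least 3")
  fragment_ring_counts <- sort(unique(as.integer(fragment_ring_counts)))
  if (any(fragment_ring_counts < 3L))
    stop("cage fragments need at least 3 rings")
  structure(
    list(frame_interval = frame_interval, hb_cutoff = hb_cutoff,
         max_ring_size = max_ring_size,
         fragment_ring_counts = fragment_ring_counts,
         alpha_radius = alpha_radius, probe_radius = probe_radius,
         lsi_shell_cutoff = lsi_shell_cutoff, energy_cutoff = energy_cutoff,
         rng_seed = as.integer(rng_seed)),
    class = "trajectory_settings")
}

#' Minimum-image displacement between points in a periodic box
#'
#' Returns `q - p` with every component wrapped into `[-box/2, box/2)`,
#' i.e. the displacement to the nearest periodic image of `q`.
#'
#' @param p,q numeric 3-vectors or n x 3 matrices (recycled row-wise).
#' @param box numeric length-3 box edge lengths.
#' @return A 3-vector (or n x 3 matrix) of wrapped displacements.
#' @examples
#' minimum_image_displacement(c(1, 0, 0), c(9, 0, 0), c(10, 10, 10)) # -2 0 0
#' @export
minimum_image_displacement <- function(p, q, box) {
  if (any(!is.finite(p)) || any(!is.finite(q)) || any(!is.finite(box)))
    stop("non-finite input to minimum_image_displacement")
  if (any(box <= 0)) stop("box lengths must be positive")
  d <- if (is.matrix(p) || is.matrix(q)) {
    p <- if (is.matrix(p)) p else matrix(p, nrow = 1L)
    q <- if (is.matrix(q)) q else matrix(q, nrow = 1L)
    if (nrow(p) == 1L && nrow(q) > 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
    if (nrow(q) == 1L && nrow(p) > 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
    q - p
  } else q - p
  wrap_displacement(d, box)
}

# wrap displacement components into [-box/2, box/2)
wrap_displacement <- function(d, box) {
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * floor(d[, k] / box[k] + 0.5)
    d
  } else {
    d - box * floor(d / box + 0.5)
  }
}

# minimum-image distances between paired rows of a and b
min_image_dist <- function(a, b, box) {
  d <- minimum_image_displacement(a, b, box)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

# positions wrapped into [0, box)
wrap_positions <- function(x, box) {
  for (k in 1:3) x[, k] <- x[, k] - box[k] * floor(x[, k] / box[k])
  x
}

#' Rigidly translate all coordinates of a frame
#' @param frame a [water_frame()].
#' @param shift numeric 3-vector added to every atom position.
#' @return The translated `water_frame`.
#' @export
translate_frame <- function(frame, shift) {
  shift <- as.numeric(shift)
  frame$oxygen <- sweep(frame$oxygen, 2L, shift, "+")
  frame$hydrogen <- sweep(frame$hydrogen, 2L, shift, "+")
  frame
}
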