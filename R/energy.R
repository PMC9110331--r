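# SPC/E pairwise interaction energies and the cluster energy-size relation.
#
# SPC/E rigid water: point charges q_O = -0.8476 e, q_H = +0.4238 e on the
# three sites plus one Lennard-Jones center on oxygen (sigma = 3.166 A,
# epsilon = 0.650 kJ/mol). Pair energies are plain truncated sums (cutoff on
# the O-O distance, default 10 A) under minimum image; no Ewald or tail
# correction is applied, matching a direct pair-sum definition of cluster
# energy. Energies are in kJ/mol.

spce <- list(
  q_o = -0.8476, q_h = 0.4238,
  sigma = 3.166, epsilon = 0.650,
  coulomb_k = 1389.35458  # kJ mol^-1 A e^-2
)

#' Conversion factor from kJ/mol to eV
#' @format Scalar: 1 kJ/mol in eV (1/96.485).
#' @export
kjmol_per_ev <- 96.48533

# absolute site coordinates of molecule m, reconstructed contiguously around
# its oxygen (hydrogens placed at their minimum image w.r.t. the oxygen)
molecule_sites <- function(frame, m) {
  o <- frame$oxygen[m, ]
  hs <- which(frame$h_owner == m)
  h1 <- o + wrap_displacement(frame$hydrogen[hs[1], ] - o, frame$box)
  h2 <- o + wrap_displacement(frame$hydrogen[hs[2], ] - o, frame$box)
  rbind(o, h1, h2)
}

#' SPC/E interaction energy of a molecule pair
#'
#' Site-site Coulomb energy over all nine charge pairs plus the
#' oxygen-oxygen Lennard-Jones term, under minimum image, truncated to zero
#' when the O-O distance is at or beyond the cutoff.
#'
#' @param frame a [water_frame()].
#' @param i,j molecule indices (distinct).
#' @param cutoff O-O truncation distance (Angstrom, default 10).
#' @return Energy in kJ/mol (0 beyond the cutoff).
#' @export
pair_interaction_energy <- function(frame, i, j, cutoff = 10) {
  if (i == j) stop("need two distinct molecules")
  d_oo <- min_image_dist(frame$oxygen[i, ], frame$oxygen[j, ], frame$box)
  if (d_oo >= cutoff) return(0)
  si <- molecule_sites(frame, i)
  sj <- molecule_sites(frame, j)
  # shift j's sites to the minimum image relative to i's oxygen
  shift <- wrap_displacement(sj[1, ] - si[1, ], frame$box) - (sj[1, ] - si[1, ])
  sj <- sweep(sj, 2L, shift, "+")
  q <- c(spce$q_o, spce$q_h, spce$q_h)
  e <- 0
  for (a in 1:3) {
    for (b in 1:3) {
      r <- sqrt(sum((si[a, ] - sj[b, ])^2))
      if (r < 0.1)
        stop(sprintf("numeric overlap: sites of molecules %d and %d are %.3f A apart",
                     i, j, r))
      e <- e + spce$coulomb_k * q[a] * q[b] / r
    }
  }
  sr6 <- (spce$sigma / d_oo)^6
  e + 4 * spce$epsilon * (sr6^2 - sr6)
}

#' Total interaction energy of a water cluster
#'
#' Sum of [pair_interaction_energy()] over all unordered molecule pairs of
#' the cluster.
#'
#' @param frame a [water_frame()].
#' @param molecules cluster molecule indices (or a cluster object with a
#'   `molecules` element).
#' @param cutoff O-O truncation distance (Angstrom).
#' @return E_S in kJ/mol (0 for singleton clusters).
#' @export
cluster_energy <- function(frame, molecules, cutoff = 10) {
  if (is.list(molecules)) molecules <- molecules$molecules
  molecules <- as.integer(molecules)
  k <- length(molecules)
  if (k < 2L) return(0)
  e <- 0
  for (a in 1:(k - 1L)) {
    for (b in (a + 1L):k) {
      e <- e + pair_interaction_energy(frame, molecules[a], molecules[b],
                                       cutoff)
    }
  }
  e
}

#' Linear fit of cluster energy against cluster size
#'
#' Least-squares fit of `E_S = a * S + b`. Larger clusters then have lower
#' per-molecule energy, `E_S / S = a + b / S`.
#'
#' @param S integer cluster sizes (at least 3 distinct values).
#' @param E_S cluster energies (same length, kJ/mol).
#' @return List with slope `a` (kJ/mol per molecule), intercept `b`
#'   (kJ/mol), their standard errors, and `n`.
#' @export
energy_size_fit <- function(S, E_S) {
  stopifnot(length(S) == length(E_S))
  ok <- is.finite(S) & is.finite(E_S)
  if (length(unique(S[ok])) < 3L)
    stop("fit error: need at least 3 distinct cluster sizes")
  f <- lm(E_S[ok] ~ S[ok])
  se <- sqrt(diag(stats::vcov(f)))
  list(a = unname(coef(f)[2]), b = unname(coef(f)[1]),
       a_se = unname(se[2]), b_se = unname(se[1]), n = sum(ok))
}
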