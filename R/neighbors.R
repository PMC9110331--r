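# Cell-list pair search under periodic minimum image.
#
# pair_search() is the one spatial index everything else leans on: hydrogen
# bond detection, oxygen neighbor lists, probe counting and RDFs. Cells are
# at least `radius` wide, so candidate pairs only need the 27 neighboring
# cells. Boxes too small for 3 cells per dimension fall back to a direct
# all-pairs scan (the cell walk would double-count wrapped neighbors there).

# xa, xb: coordinate matrices; xb = NULL means within-set pairs (i < j).
# Returns data.frame(i, j, d) with minimum-image distance d < radius (strict).
pair_search <- function(xa, xb = NULL, box, radius) {
  stopifnot(is.matrix(xa), length(box) == 3L)
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (radius > min(box) / 2 + 1e-9)
    stop("radius exceeds half the smallest box length; minimum image ambiguous")
  within <- is.null(xb)
  ncell <- pmax(1L, as.integer(floor(box / radius)))
  if (any(ncell < 3L))
    return(pair_search_brute(xa, xb, box, radius))

  cell_size <- box / ncell
  cell_of <- function(x) {
    w <- wrap_positions(x, box)
    cb <- matrix(0L, nrow(x), 3L)
    for (k in 1:3)
      cb[, k] <- pmin(as.integer(floor(w[, k] / cell_size[k])), ncell[k] - 1L)
    cb
  }
  ca <- cell_of(xa)
  cb <- if (within) ca else cell_of(xb)
  nb <- if (within) nrow(xa) else nrow(xb)
  idb <- cb[, 1] + ncell[1] * (cb[, 2] + ncell[2] * cb[, 3])
  bucket <- split(seq_len(nb), idb)

  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ii <- integer(0); jj <- integer(0)
  for (o in seq_len(nrow(offsets))) {
    nc <- ca
    for (k in 1:3) nc[, k] <- (ca[, k] + offsets[o, k]) %% ncell[k]
    nid <- nc[, 1] + ncell[1] * (nc[, 2] + ncell[2] * nc[, 3])
    hit <- bucket[match(as.character(nid), names(bucket))]
    lens <- lengths(hit)
    keep <- lens > 0L
    if (!any(keep)) next
    ii <- c(ii, rep.int(seq_len(nrow(xa))[keep], lens[keep]))
    jj <- c(jj, unlist(hit[keep], use.names = FALSE))
  }
  if (within) {
    sel <- ii < jj
    ii <- ii[sel]; jj <- jj[sel]
  }
  if (!length(ii))
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  pa <- xa[ii, , drop = FALSE]
  pb <- if (within) xa[jj, , drop = FALSE] else xb[jj, , drop = FALSE]
  d <- min_image_dist(pa, pb, box)
  sel <- d < radius
  data.frame(i = ii[sel], j = jj[sel], d = d[sel])
}

pair_search_brute <- function(xa, xb = NULL, box, radius) {
  within <- is.null(xb)
  if (within) xb <- xa
  na <- nrow(xa); nb <- nrow(xb)
  ii <- integer(0); jj <- integer(0); dd <- numeric(0)
  for (i in seq_len(na)) {
    js <- if (within) seq_len(nb)[-seq_len(i)] else seq_len(nb)
    if (!length(js)) next
    d <- min_image_dist(xa[rep(i, length(js)), , drop = FALSE],
                        xb[js, , drop = FALSE], box)
    sel <- d < radius
    if (any(sel)) {
      ii <- c(ii, rep.int(i, sum(sel))); jj <- c(jj, js[sel]); dd <- c(dd, d[sel])
    }
  }
  data.frame(i = ii, j = jj, d = dd)
}

#' Oxygen pairs within a radius under minimum image
#'
#' Cell-list search for all oxygen-oxygen pairs closer than `radius` (strict
#' `<`). The radius must not exceed half the smallest box edge, otherwise the
#' minimum image is ambiguous.
#'
#' @param frame a [water_frame()].
#' @param radius search radius (Angstrom).
#' @return `data.frame(i, j, d)` with `i < j` and minimum-image distance `d`.
#' @export
neighbor_search <- function(frame, radius) {
  pair_search(frame$oxygen, NULL, frame$box, radius)
}
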