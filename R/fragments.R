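# Cage fragments: closed assemblies of 3-5 shortest-path rings.
#
# The topological closure condition is that every hydrogen-bond edge covered
# by the fragment's rings is covered by exactly two of them (a closed
# 2-complex), and that no proper subset of at least 3 rings is itself
# closed. The simplest family is the theta cage: two degree-3 molecules
# joined by three paths, whose three rings pairwise share one path.

#' Detect closed cage fragments among shortest-path rings
#'
#' Enumerates connected sets of rings (rings are adjacent when they share at
#' least one hydrogen-bond edge) of the admissible cardinalities and keeps
#' those in which every covered edge belongs to exactly two member rings and
#' no proper sub-assembly of 3 or more rings is itself closed.
#'
#' @param rings a `ring_set` from [enumerate_sp_rings()].
#' @param graph the `hbond_graph` the rings were enumerated in.
#' @param ring_counts admissible numbers of rings per fragment
#'   (default `c(3, 4, 5)`).
#' @return An object of class `fragment_set`: a list of fragments, each a
#'   list with `rings` (indices into `rings$rings`), `molecules` (sorted
#'   union of members) and `signature` (non-decreasing ring sizes).
#' @examples
#' cage <- build_theta_cage(c(2, 2, 3))
#' g <- detect_hbonds(cage$frame)
#' rs <- enumerate_sp_rings(g)
#' fr <- detect_fragments(rs, g)
#' fr[[1]]$signature  # 4 5 5
#' @export
detect_fragments <- function(rings, graph, ring_counts = c(3L, 4L, 5L)) {
  stopifnot(inherits(rings, "ring_set"))
  ring_counts <- sort(unique(as.integer(ring_counts)))
  if (any(ring_counts < 3L)) stop("fragments need at least 3 rings")
  nr <- length(rings$rings)
  empty <- structure(list(), class = "fragment_set")
  if (nr < min(ring_counts)) return(empty)

  edge_keys <- lapply(rings$rings, ring_edge_keys)
  # ring adjacency: share >= 1 hydrogen-bond edge
  edge_to_rings <- split(rep(seq_len(nr), lengths(edge_keys)),
                         unlist(edge_keys, use.names = FALSE))
  radj <- vector("list", nr)
  for (k in seq_len(nr)) radj[[k]] <- integer(0)
  for (rr in edge_to_rings) {
    if (length(rr) > 1L)
      for (a in rr) radj[[a]] <- union(radj[[a]], setdiff(rr, a))
  }
  radj <- lapply(radj, sort)

  max_k <- max(ring_counts)
  closed <- list()
  # enumerate each connected subset once: root = minimum ring index,
  # extensions restricted to indices > root
  for (root in seq_len(nr)) {
    grow <- function(sub, ext) {
      if (length(sub) >= 3L && length(sub) %in% ring_counts &&
          is_closed_set(sub, edge_keys))
        closed[[length(closed) + 1L]] <<- sort(sub)
      if (length(sub) == max_k || !length(ext)) return(invisible())
      while (length(ext)) {
        w <- ext[1L]
        ext <- ext[-1L]
        new_ext <- union(ext, setdiff(radj[[w]][radj[[w]] > root],
                                      c(sub, w)))
        grow(c(sub, w), new_ext)
      }
    }
    grow(root, radj[[root]][radj[[root]] > root])
  }
  if (!length(closed)) return(empty)
  closed <- unique(closed)
  # minimality: drop sets strictly containing another closed set
  keep <- rep(TRUE, length(closed))
  for (a in seq_along(closed)) {
    for (b in seq_along(closed)) {
      if (a != b && length(closed[[b]]) < length(closed[[a]]) &&
          all(closed[[b]] %in% closed[[a]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  closed <- closed[keep]
  frs <- lapply(closed, function(rr) {
    list(rings = rr,
         molecules = sort(unique(unlist(rings$rings[rr], use.names = FALSE))),
         signature = sort(rings$sizes[rr]))
  })
  structure(frs, class = "fragment_set")
}

# every covered edge in exactly two member rings
is_closed_set <- function(sub, edge_keys) {
  counts <- table(unlist(edge_keys[sub], use.names = FALSE))
  all(counts == 2L)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d cage fragment(s)\n", length(x)))
  if (length(x)) {
    sig <- vapply(x, function(f) signature_label(f$signature), "")
    h <- table(sig)
    for (s in names(h)) cat(sprintf("  %s: %d\n", s, h[[s]]))
  }
  invisible(x)
}

#' Ring-size signature of a fragment
#' @param fragment one element of a `fragment_set`.
#' @return Non-decreasing integer vector of ring sizes, e.g. `c(4, 5, 5)`.
#' @export
fragment_signature <- function(fragment) sort(as.integer(fragment$signature))

signature_label <- function(sig) paste0("(", paste(sig, collapse = ","), ")")

#' Classify rings of a cluster as body or surface rings
#'
#' Within one cluster, a ring shared by two (or more) fragments is a body
#' ring; every other ring of the cluster is a surface ring.
#'
#' @param cluster_fragments a `fragment_set` (or plain list of fragments)
#'   belonging to one cluster.
#' @return `data.frame(ring, role)` with one row per distinct ring.
#' @export
classify_ring_roles <- function(cluster_fragments) {
  rr <- unlist(lapply(cluster_fragments, `[[`, "rings"), use.names = FALSE)
  if (!length(rr))
    return(data.frame(ring = integer(0), role = character(0)))
  counts <- table(rr)
  data.frame(ring = as.integer(names(counts)),
             role = ifelse(as.integer(counts) >= 2L, "body", "surface"))
}

#' Export a fragment table as TSV
#' @param fragments a `fragment_set`.
#' @param path output path.
#' @param frame_index frame label.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(fragments, path, frame_index = 1L) {
  tab <- data.frame(
    frame = frame_index,
    fragment_id = seq_along(fragments),
    signature = vapply(fragments, function(f) signature_label(f$signature), ""),
    ring_ids = vapply(fragments, function(f) paste(f$rings, collapse = ","), ""),
    molecule_ids = vapply(fragments, function(f) paste(f$molecules, collapse = ","), ""))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
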