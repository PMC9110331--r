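# Shortest-path (SP) ring enumeration in the hydrogen-bond graph.
#
# A cycle qualifies as an SP ring when, for every pair of its members, the
# shorter arc along the cycle equals the shortest-path distance in the full
# graph: rings that can be short-cut through a chord or an external path are
# rejected. Enumeration is a bounded depth-first search rooted at the
# minimum-index vertex of each cycle; correctness is defined by the SP
# condition, which is re-checked for every candidate.

#' Enumerate shortest-path rings
#'
#' Finds every cycle of size `3..max_size` in the hydrogen-bond graph whose
#' arcs are graph geodesics (the "shortest-path" ring criterion, applied to
#' all vertex pairs of the cycle against the full graph). Rings are returned
#' in canonical form: lowest member first, lexicographically smaller
#' traversal direction, deduplicated.
#'
#' @param graph an `hbond_graph` (see [detect_hbonds()]).
#' @param max_size largest ring size admitted (default 8).
#' @return An object of class `ring_set`: list with `rings` (list of integer
#'   member vectors in cyclic order), `sizes`, and `n` (molecule count).
#' @examples
#' g <- hbond_graph_from_edges(6, cbind(1:6, c(2:6, 1)))
#' rings <- enumerate_sp_rings(g)
#' rings$sizes  # one 6-ring
#' @export
enumerate_sp_rings <- function(graph, max_size = 8L) {
  stopifnot(inherits(graph, "hbond_graph"))
  max_size <- as.integer(max_size)
  if (max_size < 3L) stop("max_size must be at least 3")
  n <- graph$n
  adj <- adjacency_list(graph)
  adj <- lapply(adj, sort)
  # distances capped at floor(max_size / 2): arcs are never longer than that
  cap <- max_size %/% 2L
  D <- bfs_distance_matrix(adj, n, cap)

  found <- new.env(hash = TRUE, parent = emptyenv())
  rings <- list()

  for (root in seq_len(n)) {
    if (length(adj[[root]]) < 2L) next
    path <- integer(max_size)
    path[1L] <- root
    in_path <- logical(n)
    in_path[root] <- TRUE
    dfs <- function(depth) {
      v <- path[depth]
      for (w in adj[[v]]) {
        if (w == root && depth >= 3L) {
          # close the cycle; dedupe directions via second < last member
          if (path[2L] < path[depth]) {
            cyc <- path[seq_len(depth)]
            if (is_sp_ring(cyc, D, cap)) {
              key <- paste(cyc, collapse = ",")
              if (is.null(found[[key]])) {
                found[[key]] <- TRUE
                rings[[length(rings) + 1L]] <<- cyc
              }
            }
          }
        } else if (w > root && !in_path[w] && depth < max_size) {
          dr <- D[w, root]
          if (!is.na(dr) && depth + dr <= max_size) {
            path[depth + 1L] <<- w
            in_path[w] <<- TRUE
            dfs(depth + 1L)
            in_path[w] <<- FALSE
          }
        }
      }
    }
    dfs(1L)
  }
  rings <- lapply(rings, canonical_ring)
  structure(list(rings = rings,
                 sizes = vapply(rings, length, integer(1)),
                 n = n),
            class = "ring_set")
}

# BFS distances from every vertex, capped at `cap` (NA beyond)
bfs_distance_matrix <- function(adj, n, cap) {
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    d <- 0L
    while (length(frontier) && d < cap) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.na(dist[nxt])]
      d <- d + 1L
      dist[nxt] <- d
      frontier <- nxt
    }
    D[, s] <- dist
  }
  D
}

# all-pairs SP check: shorter arc along the cycle == graph distance
is_sp_ring <- function(cyc, D, cap) {
  k <- length(cyc)
  for (a in 1:(k - 1L)) {
    for (b in (a + 1L):k) {
      arc <- min(b - a, k - (b - a))
      g <- D[cyc[a], cyc[b]]
      if (is.na(g)) g <- cap + 1L
      if (g < arc) return(FALSE)
    }
  }
  TRUE
}

# canonical cyclic form: minimum member first, then the lexicographically
# smaller of the two directions
canonical_ring <- function(members) {
  k <- length(members)
  i0 <- which.min(members)
  fwd <- members[((i0 - 1L + 0:(k - 1L)) %% k) + 1L]
  bwd <- members[((i0 - 1L - 0:(k - 1L)) %% k) + 1L]
  for (p in 2:k) {
    if (fwd[p] < bwd[p]) return(fwd)
    if (bwd[p] < fwd[p]) return(bwd)
  }
  fwd
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("ring_set: %d shortest-path rings", length(x$rings)))
  if (length(x$rings)) {
    h <- table(x$sizes)
    cat(" (", paste(sprintf("%sx size %s", h, names(h)), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Histogram of ring sizes
#' @param rings a `ring_set`.
#' @param max_size largest size reported (defaults to the largest present,
#'   at least 8).
#' @return Named integer vector of counts for sizes `3..max_size`.
#' @export
ring_size_histogram <- function(rings, max_size = NULL) {
  if (is.null(max_size))
    max_size <- max(8L, if (length(rings$sizes)) max(rings$sizes) else 0L)
  counts <- integer(max_size - 2L)
  names(counts) <- as.character(3:max_size)
  if (length(rings$sizes)) {
    h <- table(factor(rings$sizes, levels = 3:max_size))
    counts[] <- as.integer(h)
  }
  counts
}

# edge keys ("a-b" with a < b) covered by a ring
ring_edge_keys <- function(members) {
  k <- length(members)
  nxt <- c(members[-1L], members[1L])
  paste(pmin(members, nxt), pmax(members, nxt), sep = "-")
}

#' Export a ring table as TSV
#' @param rings a `ring_set`.
#' @param path output path.
#' @param frame_index frame label.
#' @return `path`, invisibly.
#' @export
write_ring_table <- function(rings, path, frame_index = 1L) {
  tab <- data.frame(
    frame = frame_index,
    ring_id = seq_along(rings$rings),
    size = rings$sizes,
    member_ids = vapply(rings$rings, paste, "", collapse = ","))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
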