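# Water clusters as Louvain communities of the fragment-sharing network.

#' Build the fragment-sharing network
#'
#' Fragments are nodes; two fragments are joined when they share at least
#' one ring, with edge weight equal to the number of shared rings.
#'
#' @param fragments a `fragment_set` from [detect_fragments()].
#' @return An object of class `fragment_network`: list with `n` (fragment
#'   count), `edges` (`data.frame(a, b, weight)`), and `signatures`.
#' @export
build_fragment_network <- function(fragments) {
  nf <- length(fragments)
  sig <- vapply(fragments, function(f) signature_label(f$signature), "")
  rr <- lapply(fragments, `[[`, "rings")
  ring_to_frag <- split(rep(seq_len(nf), lengths(rr)),
                        unlist(rr, use.names = FALSE))
  pair_count <- new.env(hash = TRUE, parent = emptyenv())
  for (fl in ring_to_frag) {
    if (length(fl) < 2L) next
    fl <- sort(fl)
    for (a in seq_len(length(fl) - 1L)) {
      for (b in (a + 1L):length(fl)) {
        key <- paste(fl[a], fl[b], sep = "-")
        pair_count[[key]] <- (if (is.null(pair_count[[key]])) 0L
                              else pair_count[[key]]) + 1L
      }
    }
  }
  keys <- ls(pair_count)
  if (length(keys)) {
    ab <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
    edges <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                        weight = vapply(keys, function(k) pair_count[[k]],
                                        integer(1), USE.NAMES = FALSE))
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = integer(0), b = integer(0), weight = integer(0))
  }
  structure(list(n = nf, edges = edges, signatures = sig),
            class = "fragment_network")
}

#' @export
print.fragment_network <- function(x, ...) {
  cat(sprintf("fragment_network: %d fragments, %d shared-ring edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' Louvain community partition of a fragment network
#'
#' Runs the Louvain modularity heuristic (weighted by shared-ring counts
#' unless `weighted = FALSE`, resolution 1) on the fragment network. The
#' heuristic's randomness lies in the node traversal order: the run is made
#' deterministic by seeding it, and with `restarts > 1` each restart applies
#' a different seeded node permutation (the first uses the input order) and
#' the best partition (highest modularity) is returned. Isolated fragments
#' form singleton communities.
#'
#' @param network a `fragment_network`.
#' @param seed integer seed.
#' @param weighted use shared-ring counts as edge weights (default TRUE).
#' @param restarts number of seeded restarts (default 1).
#' @return Integer community membership vector of length `network$n`
#'   (1-based, consecutive), with attribute `"modularity"`.
#' @export
louvain_partition <- function(network, seed = 1L, weighted = TRUE,
                              restarts = 1L) {
  stopifnot(inherits(network, "fragment_network"))
  if (network$n == 0L)
    return(structure(integer(0), modularity = NA_real_))
  g <- igraph::make_empty_graph(n = network$n, directed = FALSE)
  w <- NULL
  if (nrow(network$edges)) {
    g <- igraph::add_edges(g, rbind(network$edges$a, network$edges$b))
    w <- if (weighted) as.numeric(network$edges$weight)
         else rep(1, nrow(network$edges))
    igraph::E(g)$weight <- w  # survives vertex permutation
  }
  best <- NULL
  best_q <- -Inf
  for (k in seq_len(max(1L, as.integer(restarts)))) {
    memb <- with_seed(as.integer(seed) + k - 1L, {
      mm <- if (k %% 2L == 1L) {
        # igraph's multilevel run under a permuted node traversal order
        perm <- if (k == 1L) seq_len(network$n) else sample.int(network$n)
        gp <- igraph::permute(g, perm)
        cl <- igraph::cluster_louvain(gp, resolution = 1)
        as.integer(igraph::membership(cl))[perm]  # back to input order
      } else {
        # own multilevel run with a freshly randomized sweep order
        louvain_run(network$n, network$edges$a, network$edges$b,
                    if (is.null(w)) numeric(0) else w)
      }
      # complete the heuristic with a finest-level local-moving sweep:
      # aggregation can lock single vertices into communities that one
      # more pass of phase-1 moves on the original graph would improve
      louvain_refine(network$n, network$edges$a, network$edges$b,
                     if (is.null(w)) numeric(0) else w, mm)
    })
    q <- igraph::modularity(g, memb, weights = w)
    if (q > best_q || is.null(best)) {
      best <- memb
      best_q <- q
    }
  }
  memb <- as.integer(best)
  memb <- match(memb, unique(memb))  # consecutive ids in first-seen order
  structure(memb, modularity = best_q)
}

# Louvain phase-1 local moving, starting from a given membership: sweep
# vertices in random order, moving each to the neighboring community (or a
# fresh singleton) with the largest strictly positive modularity gain,
# until a full sweep makes no move. `sl` carries self-loop weights of
# aggregated vertices; degrees include twice the self-loop weight.
louvain_refine <- function(n, ea, eb, w, memb, sl = numeric(n)) {
  if (!length(ea) && !any(sl > 0)) return(memb)
  if (!length(w)) w <- rep(1, length(ea))
  m <- sum(w) + sum(sl)
  deg <- 2 * sl
  inc <- vector("list", n)  # incident (other endpoint, weight) pairs
  for (k in seq_along(ea)) {
    deg[ea[k]] <- deg[ea[k]] + w[k]
    deg[eb[k]] <- deg[eb[k]] + w[k]
    inc[[ea[k]]] <- rbind(inc[[ea[k]]], c(eb[k], w[k]))
    inc[[eb[k]]] <- rbind(inc[[eb[k]]], c(ea[k], w[k]))
  }
  K <- as.numeric(tapply(deg, factor(memb, levels = seq_len(max(memb))), sum))
  K[is.na(K)] <- 0
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      nb <- inc[[v]]
      if (is.null(nb)) next
      cv <- memb[v]
      wvc <- tapply(nb[, 2], memb[nb[, 1]], sum)
      cand <- as.integer(names(wvc))
      free <- which(K == 0)          # reuse an empty community id
      empty_id <- if (length(free)) free[1] else length(K) + 1L
      cand <- unique(c(cand, empty_id))
      if (length(cand) > 1L) cand <- sample(cand)  # random tie-breaking
      w_self <- if (as.character(cv) %in% names(wvc)) wvc[[as.character(cv)]] else 0
      best_gain <- 0
      best_c <- cv
      for (cc in cand) {
        if (cc == cv) next
        w_to <- if (as.character(cc) %in% names(wvc)) wvc[[as.character(cc)]] else 0
        Kd <- if (cc <= length(K)) K[cc] else 0
        gain <- (w_to - w_self) / m -
          deg[v] * (Kd - (K[cv] - deg[v])) / (2 * m^2)
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_c <- cc
        }
      }
      if (best_c != cv) {
        if (best_c > length(K)) K <- c(K, 0)
        K[cv] <- K[cv] - deg[v]
        K[best_c] <- K[best_c] + deg[v]
        memb[v] <- best_c
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

# Complete multilevel Louvain with randomized sweep order: alternate
# phase-1 local moving (from singletons) and community aggregation until a
# level makes no merge. Used as an additional restart engine alongside
# igraph's implementation; both are the same heuristic with different
# traversal dynamics.
louvain_run <- function(n, ea, eb, w) {
  if (!length(w)) w <- rep(1, length(ea))
  memb_global <- seq_len(n)
  cur_n <- n
  cea <- ea; ceb <- eb; cw <- w
  sl <- numeric(n)
  repeat {
    m1 <- louvain_refine(cur_n, cea, ceb, cw, seq_len(cur_n), sl)
    m1 <- match(m1, unique(m1))
    k <- max(m1)
    memb_global <- m1[memb_global]
    if (k == cur_n) break
    # aggregate: communities become vertices, weights are summed
    new_sl <- as.numeric(tapply(sl, factor(m1, levels = seq_len(k)), sum))
    new_sl[is.na(new_sl)] <- 0
    a2 <- m1[cea]; b2 <- m1[ceb]
    intra <- a2 == b2
    if (any(intra)) {
      add <- tapply(cw[intra], factor(a2[intra], levels = seq_len(k)), sum)
      add[is.na(add)] <- 0
      new_sl <- new_sl + as.numeric(add)
    }
    if (any(!intra)) {
      lo <- pmin(a2[!intra], b2[!intra])
      hi <- pmax(a2[!intra], b2[!intra])
      key <- paste(lo, hi)
      agg <- tapply(cw[!intra], key, sum)
      parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
      cea <- as.integer(parts[, 1])
      ceb <- as.integer(parts[, 2])
      cw <- as.numeric(agg)
    } else {
      cea <- integer(0); ceb <- integer(0); cw <- numeric(0)
    }
    sl <- new_sl
    cur_n <- k
  }
  memb_global
}

#' Materialize water clusters from a community partition
#'
#' One cluster per community: its molecules are the union over member
#' fragments, its rings the union of member rings. Fragments assigned to
#' different communities may still share molecules through shared rings;
#' such molecules belong to both clusters (coverage statistics use the
#' union).
#'
#' @param partition membership vector from [louvain_partition()].
#' @param fragments the `fragment_set` the partition refers to.
#' @return An object of class `water_clusters`: list of clusters, each with
#'   `cluster_id`, `fragments`, `molecules`, `rings` and size `S`.
#' @export
assemble_clusters <- function(partition, fragments) {
  stopifnot(length(partition) == length(fragments))
  out <- lapply(sort(unique(partition)), function(cid) {
    members <- which(partition == cid)
    mols <- sort(unique(unlist(lapply(fragments[members], `[[`, "molecules"),
                               use.names = FALSE)))
    rngs <- sort(unique(unlist(lapply(fragments[members], `[[`, "rings"),
                               use.names = FALSE)))
    list(cluster_id = cid, fragments = members, molecules = mols,
         rings = rngs, S = length(mols))
  })
  structure(out, class = "water_clusters")
}

#' @export
print.water_clusters <- function(x, ...) {
  cat(sprintf("water_clusters: %d cluster(s)", length(x)))
  if (length(x)) {
    s <- vapply(x, `[[`, integer(1), "S")
    cat(sprintf(", sizes %s", paste(sort(s, decreasing = TRUE), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Fraction of molecules covered by water clusters
#' @param clusters a `water_clusters` object.
#' @param frame the `water_frame` the clusters live in.
#' @return Fraction in `[0, 1]`: distinct clustered molecules / all molecules.
#' @export
coverage_fraction <- function(clusters, frame) {
  n <- n_molecules(frame)
  if (n == 0L) return(0)
  covered <- unique(unlist(lapply(clusters, `[[`, "molecules"),
                           use.names = FALSE))
  length(covered) / n
}

#' Signature-pair adjacency frequencies of fragments within clusters
#'
#' Counts, over all clusters with at least two fragments, the
#' fragment-network edges (shared-ring adjacencies) joining fragments of
#' given signature pairs, and row-normalizes the resulting symmetric count
#' matrix into conditional frequencies.
#'
#' @param clusters a `water_clusters` object.
#' @param fragments the underlying `fragment_set`.
#' @return A row-normalized numeric matrix with signature labels as
#'   dimnames; empty (0 x 0) when no cluster has two adjacent fragments.
#' @export
fragment_adjacency_stats <- function(clusters, fragments) {
  sig <- vapply(fragments, function(f) signature_label(f$signature), "")
  pairs <- character(0)
  for (cl in clusters) {
    if (length(cl$fragments) < 2L) next
    sub <- fragments[cl$fragments]
    net <- build_fragment_network(sub)
    if (!nrow(net$edges)) next
    sa <- sig[cl$fragments[net$edges$a]]
    sb <- sig[cl$fragments[net$edges$b]]
    pairs <- c(pairs, paste(pmin(sa, sb), pmax(sa, sb), sep = "|"))
  }
  if (!length(pairs)) return(matrix(numeric(0), 0L, 0L))
  labs <- sort(unique(unlist(strsplit(pairs, "|", fixed = TRUE))))
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (p in pairs) {
    ab <- strsplit(p, "|", fixed = TRUE)[[1]]
    m[ab[1], ab[2]] <- m[ab[1], ab[2]] + 1
    if (ab[1] != ab[2]) m[ab[2], ab[1]] <- m[ab[2], ab[1]] + 1
  }
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  sweep(m, 1L, rs, "/")
}

#' Export the per-frame cluster table as TSV
#'
#' Columns: frame, cluster_id, S, V, A, L, E_S, signature (the multiset of
#' fragment signatures in the cluster). Shape and energy columns may be NA
#' when not computed.
#'
#' @param clusters a `water_clusters` object.
#' @param fragments the underlying `fragment_set`.
#' @param path output path.
#' @param frame_index frame label.
#' @param shapes optional data.frame of per-cluster `V`, `A`, `L`.
#' @param energies optional numeric vector of cluster energies.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, fragments, path, frame_index = 1L,
                                shapes = NULL, energies = NULL) {
  k <- length(clusters)
  tab <- data.frame(
    frame = rep(frame_index, k),
    cluster_id = vapply(clusters, `[[`, integer(1), "cluster_id"),
    S = vapply(clusters, `[[`, integer(1), "S"),
    V = if (is.null(shapes)) NA_real_ else shapes$V,
    A = if (is.null(shapes)) NA_real_ else shapes$A,
    L = if (is.null(shapes)) NA_real_ else shapes$L,
    E_S = if (is.null(energies)) NA_real_ else energies,
    signature = vapply(clusters, function(cl)
      paste(vapply(fragments[cl$fragments],
                   function(f) signature_label(f$signature), ""),
            collapse = "+"), ""))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
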