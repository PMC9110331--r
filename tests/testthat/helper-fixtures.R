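# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# a frame of n molecules at given oxygen positions with hydrogens parked
# close to their oxygen in a fixed non-bonding orientation
frame_from_oxygens <- function(o, box, h_offsets = NULL) {
  o <- as.matrix(o)
  n <- nrow(o)
  if (is.null(h_offsets))
    h_offsets <- list(c(0.55, 0.55, 0.45), c(-0.55, 0.55, -0.45))
  h <- matrix(NA_real_, 2 * n, 3)
  for (m in seq_len(n)) {
    h[2 * m - 1, ] <- o[m, ] + h_offsets[[1]]
    h[2 * m, ] <- o[m, ] + h_offsets[[2]]
  }
  water_frame(o, h, rep(seq_len(n), each = 2L), box)
}

# hydrogen-bonded dimer: donor at origin, acceptor on the +x axis with the
# donating hydrogen on the O-O axis
hb_dimer_frame <- function(d_oo = 2.8, d_oh = 1.0, box = c(20, 20, 20)) {
  o <- rbind(c(5, 5, 5), c(5 + d_oo, 5, 5))
  h <- rbind(c(5 + d_oh, 5, 5),            # donating H, on axis
             c(5 - 0.33, 5 + 0.94, 5),     # spare H of molecule 1
             c(5 + d_oo + 0.33, 5 + 0.94, 5),
             c(5 + d_oo - 0.33, 5 - 0.94, 5))
  water_frame(o, h, c(1L, 1L, 2L, 2L), box)
}

# simple-entity constructors for dynamics tests
ent <- function(type, mols, id = paste0(substr(type, 1, 1), mols[1]))
  list(type = type, molecules = as.integer(mols), id = id)

ents <- function(...) structure(list(...), class = "frame_entities")

cross3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

# a seeded random connected-ish graph with degree <= 4 (hydrogen-bond-like)
random_hb_graph <- function(n, seed, p = 0.35, max_degree = 4L) {
  set.seed(seed)
  edges <- NULL
  deg <- integer(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (runif(1) < p && deg[i] < max_degree && deg[j] < max_degree) {
        edges <- rbind(edges, c(i, j))
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    }
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  hbond_graph_from_edges(n, edges)
}

# random fragment-network-like object
random_network <- function(n, seed, p = 0.4, weighted = TRUE) {
  set.seed(seed)
  A <- matrix(runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  ea <- row(A)[A]; eb <- col(A)[A]
  w <- if (weighted) sample(1:3, length(ea), replace = TRUE)
       else rep(1L, length(ea))
  structure(list(n = n, edges = data.frame(a = ea, b = eb, weight = w),
                 signatures = rep("(4,5,5)", n)),
            class = "fragment_network")
}
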