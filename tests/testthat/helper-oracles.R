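# Independent oracles used to validate the implementation by a second
# route: brute-force geometry, exhaustive enumeration, and (where a second
# in-process implementation would not be independent) python networkx /
# scipy.spatial called through the system interpreter.

# run a python snippet with JSON on stdin, parse its JSON stdout
py_json <- function(code, input) {
  fin <- tempfile(fileext = ".json")
  fpy <- tempfile(fileext = ".py")
  jsonlite::write_json(input, fin, auto_unbox = TRUE, digits = NA)
  writeLines(code, fpy)
  out <- suppressWarnings(
    system2("python", fpy, stdout = TRUE, stderr = FALSE,
            stdin = fin))
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = TRUE)
}

# all simple cycles of length <= maxlen, via networkx (independent of the
# package's DFS enumeration)
nx_simple_cycles <- function(graph, maxlen) {
  if (!nrow(graph$edges)) return(list())
  res <- py_json("
import sys, json, networkx as nx
d = json.load(sys.stdin)
G = nx.Graph()
G.add_nodes_from(range(1, d['n'] + 1))
G.add_edges_from(zip(d['i'], d['j']))
cyc = [list(map(int, c)) for c in nx.simple_cycles(G, length_bound=d['k'])]
print(json.dumps(cyc))
", list(n = graph$n, i = as.list(graph$edges$i), j = as.list(graph$edges$j),
       k = maxlen))
  if (is.matrix(res)) res <- lapply(seq_len(nrow(res)), function(r) res[r, ])
  if (!is.list(res)) res <- if (length(res)) list(res) else list()
  lapply(res, as.integer)
}

# batched variant: one interpreter launch for a whole list of graphs
nx_simple_cycles_batch <- function(graphs, maxlen) {
  payload <- lapply(graphs, function(g)
    list(n = g$n, i = as.list(g$edges$i), j = as.list(g$edges$j)))
  res <- py_json("
import sys, json, networkx as nx
batch = json.load(sys.stdin)
out = []
for d in batch['graphs']:
    G = nx.Graph()
    G.add_nodes_from(range(1, d['n'] + 1))
    G.add_edges_from(zip(d['i'], d['j']))
    out.append([list(map(int, c))
                for c in nx.simple_cycles(G, length_bound=batch['k'])])
print(json.dumps(out))
", list(graphs = payload, k = maxlen))
  lapply(res, function(cyc) {
    if (is.matrix(cyc)) cyc <- lapply(seq_len(nrow(cyc)), function(r) cyc[r, ])
    if (!is.list(cyc)) cyc <- if (length(cyc)) list(cyc) else list()
    lapply(cyc, as.integer)
  })
}

# SP filter applied to pre-enumerated cycles (shared by single and batch)
sp_filter_keys <- function(graph, cycles) {
  cycles <- Filter(function(cc) length(cc) >= 3L, cycles)
  if (!length(cycles)) return(character(0))
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
  D <- igraph::distances(g)
  keep <- vapply(cycles, function(cc) {
    k <- length(cc)
    for (a in 1:(k - 1L)) {
      for (b in (a + 1L):k) {
        arc <- min(b - a, k - (b - a))
        if (D[cc[a], cc[b]] < arc) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  sort(vapply(cycles[keep], oracle_ring_key, ""))
}

# brute-force SP rings: all simple cycles (networkx) filtered by the
# shortest-path condition computed with igraph::distances
oracle_sp_rings <- function(graph, max_size) {
  cycles <- nx_simple_cycles(graph, max_size)
  cycles <- Filter(function(cc) length(cc) >= 3L, cycles)
  if (!length(cycles)) return(character(0))
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
  D <- igraph::distances(g)
  keep <- vapply(cycles, function(cc) {
    k <- length(cc)
    for (a in 1:(k - 1L)) {
      for (b in (a + 1L):k) {
        arc <- min(b - a, k - (b - a))
        if (D[cc[a], cc[b]] < arc) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  sort(vapply(cycles[keep], oracle_ring_key, ""))
}

# order-independent cycle key: the multiset of members plus the multiset of
# cycle edges (identifies a cycle regardless of rotation/direction)
oracle_ring_key <- function(members) {
  k <- length(members)
  nxt <- c(members[-1], members[1])
  ek <- sort(paste(pmin(members, nxt), pmax(members, nxt), sep = "-"))
  paste(paste(sort(members), collapse = ","), paste(ek, collapse = ";"),
        sep = "|")
}

ring_set_keys <- function(rings)
  sort(vapply(rings$rings, oracle_ring_key, ""))

# scipy convex hull volume and area (oracle for alpha = Inf shapes)
scipy_hull <- function(points) {
  res <- py_json("
import sys, json
import numpy as np
from scipy.spatial import ConvexHull
d = json.load(sys.stdin)
h = ConvexHull(np.asarray(d['pts']))
print(json.dumps({'volume': float(h.volume), 'area': float(h.area)}))
", list(pts = unname(as.data.frame(points))))
  res
}

# exhaustive modularity optimum over all set partitions (restricted growth
# strings); modularity computed with our own formula, not igraph's
oracle_best_modularity <- function(network) {
  n <- network$n
  ea <- network$edges$a
  eb <- network$edges$b
  w <- as.numeric(network$edges$weight)
  m <- sum(w)
  deg <- numeric(n)
  for (k in seq_along(ea)) {
    deg[ea[k]] <- deg[ea[k]] + w[k]
    deg[eb[k]] <- deg[eb[k]] + w[k]
  }
  best <- -Inf
  p <- integer(n)
  rec <- function(pos, mx) {
    if (pos > n) {
      q <- sum(w[p[ea] == p[eb]]) / m -
        sum((tapply(deg, p, sum) / (2 * m))^2)
      if (q > best) best <<- q
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) {
      p[pos] <<- v
      rec(pos + 1L, max(mx, v))
    }
  }
  rec(1L, 0L)
  best
}

# minimum-image oracle: explicit minimum over the 27 periodic images
oracle_min_image <- function(p, q, box) {
  imgs <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% diag(box)
  d <- matrix(q - p, 27, 3, byrow = TRUE) + imgs
  d[which.min(rowSums(d^2)), ]
}

# O(N^2) neighbor search oracle: explicit 27-image minimum, no cell list
oracle_pairs <- function(x, box, radius) {
  n <- nrow(x)
  imgs <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% diag(box)
  out_i <- integer(0); out_j <- integer(0)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    dif <- x[js, , drop = FALSE] - matrix(x[i, ], length(js), 3, byrow = TRUE)
    d2min <- rep(Inf, length(js))
    for (k in 1:27) {
      d2 <- rowSums((dif + matrix(imgs[k, ], length(js), 3, byrow = TRUE))^2)
      d2min <- pmin(d2min, d2)
    }
    sel <- sqrt(d2min) < radius
    out_i <- c(out_i, rep.int(i, sum(sel)))
    out_j <- c(out_j, js[sel])
  }
  if (!length(out_i)) return(NULL)
  cbind(out_i, out_j)
}
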