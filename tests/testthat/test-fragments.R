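# fragment detection on topological fixtures; the theta-graph family is
# built directly at the graph level so the geometry stays out of the way

theta_graph <- function(p) {
  # vertices: 1, 2 poles; paths of p[k] edges between them
  n <- 2L
  edges <- NULL
  for (k in 1:3) {
    if (p[k] == 1L) {
      edges <- rbind(edges, c(1L, 2L))
    } else {
      ids <- n + seq_len(p[k] - 1L)
      n <- n + p[k] - 1L
      chain <- c(1L, ids, 2L)
      edges <- rbind(edges, cbind(chain[-length(chain)], chain[-1]))
    }
  }
  hbond_graph_from_edges(n, edges)
}

test_that("theta cages close into single fragments with the expected signature", {
  cases <- list(list(p = c(2, 2, 3), sig = c(4, 5, 5), mols = 6),
                list(p = c(3, 3, 4), sig = c(6, 7, 7), mols = 9),
                list(p = c(2, 2, 6), sig = c(4, 8, 8), mols = 9),
                list(p = c(2, 2, 4), sig = c(4, 6, 6), mols = 7))
  for (cs in cases) {
    g <- theta_graph(cs$p)
    rs <- enumerate_sp_rings(g)
    fr <- detect_fragments(rs, g)
    expect_length(fr, 1L)
    expect_equal(fragment_signature(fr[[1]]), as.integer(cs$sig))
    expect_length(fr[[1]]$molecules, cs$mols)
  }
})

test_that("a single isolated ring cannot close into a fragment", {
  g <- hbond_graph_from_edges(6, cbind(1:6, c(2:6, 1)))
  rs <- enumerate_sp_rings(g)
  expect_length(detect_fragments(rs, g), 0L)
})

test_that("fragment signatures are sorted ring-size tuples", {
  f1 <- list(rings = 1:3, molecules = 1:6, signature = c(5, 4, 5))
  expect_equal(fragment_signature(f1), c(4L, 5L, 5L))
  f2 <- list(rings = 1:4, molecules = 1:10, signature = c(6, 7, 7, 6))
  expect_equal(fragment_signature(f2), c(6L, 6L, 7L, 7L))
  f3 <- list(rings = 1:3, molecules = 1:9, signature = c(8, 6, 8))
  expect_equal(fragment_signature(f3), c(6L, 8L, 8L))
})

test_that("covered edges belong to exactly two member rings (recount)", {
  for (p in list(c(2, 2, 3), c(3, 3, 4), c(2, 2, 6), c(4, 4, 4))) {
    g <- theta_graph(p)
    rs <- enumerate_sp_rings(g)
    fr <- detect_fragments(rs, g)
    expect_length(fr, 1L)
    cover <- table(unlist(lapply(rs$rings[fr[[1]]$rings],
                                 aquaclust:::ring_edge_keys)))
    expect_true(all(cover == 2L))
  }
})

test_that("theta closed-form molecule count 2 + sum(p - 1) holds for every admissible spec", {
  for (p1 in 1:4) for (p2 in p1:6) for (p3 in p2:7) {
    p <- c(p1, p2, p3)
    if (sum(p == 1L) > 1L) next
    sizes <- c(p1 + p2, p1 + p3, p2 + p3)
    if (max(sizes) > 8L || min(sizes) < 3L) next
    g <- theta_graph(p)
    rs <- enumerate_sp_rings(g)
    fr <- detect_fragments(rs, g)
    if (p1 == p2) {
      # all three cycles are geodesic: the cage closes
      expect_length(fr, 1L)
      expect_length(fr[[1]]$molecules, 2L + sum(p - 1L))
      expect_equal(fragment_signature(fr[[1]]), sort(as.integer(sizes)))
    } else {
      # the largest cycle is short-cut through the shortest path and is not
      # an SP ring, so no 3-ring closure exists
      expect_length(fr, 0L)
      expect_length(rs$rings, 2L)
    }
  }
})

test_that("body rings join two fragments of a cluster; the rest are surface", {
  # two theta cages sharing one ring: fuse (2,2,3) cages along the 4-ring
  f1 <- list(rings = c(1L, 2L, 3L), molecules = 1:6, signature = c(4, 5, 5))
  f2 <- list(rings = c(1L, 4L, 5L), molecules = c(1:2, 7:10),
             signature = c(4, 5, 5))
  roles <- classify_ring_roles(list(f1, f2))
  expect_equal(roles$role[roles$ring == 1L], "body")
  expect_equal(sum(roles$role == "surface"), 4L)
  expect_equal(nrow(roles), 5L)
  # single fragment: everything is surface
  roles1 <- classify_ring_roles(list(f1))
  expect_true(all(roles1$role == "surface"))
  # three fragments pairwise sharing rings
  f3 <- list(rings = c(2L, 4L, 6L), molecules = c(3, 4, 7, 8, 11, 12),
             signature = c(4, 4, 4))
  roles3 <- classify_ring_roles(list(f1, f2, f3))
  expect_setequal(roles3$ring[roles3$role == "body"], c(1L, 2L, 4L))
  expect_setequal(roles3$ring[roles3$role == "surface"], c(3L, 5L, 6L))
})

test_that("geometric route reproduces the topological fragments", {
  cage <- build_theta_cage(c(2, 2, 3))
  g <- detect_hbonds(cage$frame)
  rs <- enumerate_sp_rings(g)
  fr <- detect_fragments(rs, g)
  expect_length(fr, 1L)
  expect_equal(fragment_signature(fr[[1]]), c(4L, 5L, 5L))
  expect_equal(fr[[1]]$molecules, 1:6)
})
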