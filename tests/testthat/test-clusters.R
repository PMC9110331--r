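mk_frag <- function(rings, molecules, sig = c(4, 5, 5))
  list(rings = as.integer(rings), molecules = as.integer(molecules),
       signature = sig)

test_that("fragment network edges count shared rings", {
  f1 <- mk_frag(1:3, 1:6)
  f2 <- mk_frag(c(3, 4, 5), 5:10)
  f3 <- mk_frag(7:9, 20:25)
  net <- build_fragment_network(structure(list(f1, f2, f3),
                                          class = "fragment_set"))
  expect_equal(net$n, 3L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$a, 1L)
  expect_equal(net$edges$b, 2L)
  expect_equal(net$edges$weight, 1L)
  # disjoint fragments: no edges
  net2 <- build_fragment_network(structure(list(f1, f3),
                                           class = "fragment_set"))
  expect_equal(nrow(net2$edges), 0L)
  # chain A-B, B-C with two shared rings on one link
  f4 <- mk_frag(c(4, 5, 6), 8:14)
  net3 <- build_fragment_network(structure(list(f1, f2, f4),
                                           class = "fragment_set"))
  expect_equal(nrow(net3$edges), 2L)
  expect_equal(net3$edges$weight[net3$edges$a == 2 & net3$edges$b == 3], 2L)
})

test_that("louvain finds the two cliques joined by a bridge", {
  cl4 <- t(combn(1:4, 2))
  net <- structure(list(
    n = 8L,
    edges = data.frame(a = c(cl4[, 1], cl4[, 1] + 4L, 4L),
                       b = c(cl4[, 2], cl4[, 2] + 4L, 5L),
                       weight = 1L),
    signatures = rep("(4,5,5)", 8)), class = "fragment_network")
  p <- louvain_partition(net, seed = 3)
  expect_length(unique(p), 2L)
  expect_length(unique(p[1:4]), 1L)
  expect_length(unique(p[5:8]), 1L)
  expect_false(p[1] == p[5])
  # exhaustive oracle agrees that this is the optimum
  expect_equal(attr(p, "modularity"), oracle_best_modularity(net),
               tolerance = 1e-12)
})

test_that("louvain is deterministic given a seed and handles edge cases", {
  net <- random_network(9, seed = 13)
  p1 <- louvain_partition(net, seed = 42)
  p2 <- louvain_partition(net, seed = 42)
  expect_identical(as.integer(p1), as.integer(p2))
  # singleton node
  net1 <- structure(list(n = 1L,
                         edges = data.frame(a = integer(0), b = integer(0),
                                            weight = integer(0)),
                         signatures = "(4,5,5)"), class = "fragment_network")
  expect_equal(as.integer(louvain_partition(net1, seed = 1)), 1L)
  # empty network
  net0 <- structure(list(n = 0L,
                         edges = data.frame(a = integer(0), b = integer(0),
                                            weight = integer(0)),
                         signatures = character(0)),
                    class = "fragment_network")
  expect_length(louvain_partition(net0, seed = 1), 0L)
})

test_that("returned partition is never worse than all singletons", {
  for (seed in 1:8) {
    net <- random_network(sample(4:10, 1), seed = seed,
                          weighted = seed %% 2 == 0)
    if (!nrow(net$edges)) next
    p <- louvain_partition(net, seed = seed)
    g <- igraph::make_empty_graph(n = net$n, directed = FALSE)
    g <- igraph::add_edges(g, rbind(net$edges$a, net$edges$b))
    q_single <- igraph::modularity(g, seq_len(net$n),
                                   weights = net$edges$weight)
    expect_gte(attr(p, "modularity"), q_single - 1e-12)
  }
})

test_that("clusters are unions of member fragments; coverage uses the union", {
  f1 <- mk_frag(1:3, 1:6)
  f2 <- mk_frag(c(3, 4, 5), 5:10)
  f3 <- mk_frag(7:9, 20:25)
  frs <- structure(list(f1, f2, f3), class = "fragment_set")
  cl <- assemble_clusters(c(1L, 1L, 2L), frs)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$molecules, 1:10)
  expect_equal(cl[[1]]$S, 10L)
  expect_equal(cl[[2]]$S, 6L)
  expect_gte(sum(vapply(cl, `[[`, integer(1), "S")),
             length(unique(c(1:10, 20:25))))
  # coverage against a 32-molecule frame
  fr <- build_random_box(32, 0.02, seed = 2)
  expect_equal(coverage_fraction(cl, fr), 16 / 32)
  expect_equal(coverage_fraction(list(), fr), 0)
})

test_that("cage fixtures materialize into the expected single cluster", {
  cage <- build_theta_cage(c(2, 2, 3))
  rep1 <- run_pipeline(cage$frame, trajectory_settings(),
                       stages = "shapes")
  cl <- rep1$frames[[1]]$clusters
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$S, 6L)
  expect_equal(rep1$coverage, 1.0)
})

test_that("signature-pair adjacency frequencies match hand counts", {
  f1 <- mk_frag(1:3, 1:6, c(4, 5, 5))
  f2 <- mk_frag(c(3, 4, 5), 5:10, c(4, 5, 5))
  cl <- assemble_clusters(c(1L, 1L), structure(list(f1, f2),
                                               class = "fragment_set"))
  m <- fragment_adjacency_stats(cl, list(f1, f2))
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(m[1, 1], 1.0)
  # no multi-fragment cluster: empty matrix
  cl2 <- assemble_clusters(c(1L, 2L), structure(list(f1, mk_frag(7:9, 20:25)),
                                                class = "fragment_set"))
  expect_equal(dim(fragment_adjacency_stats(cl2, list(f1, mk_frag(7:9, 20:25)))),
               c(0L, 0L))
  # 3-fragment chain with mixed signatures: A(455)-B(455), B-C(667)
  f3 <- mk_frag(c(5, 7, 8), 9:14, c(6, 6, 7))
  cl3 <- assemble_clusters(c(1L, 1L, 1L),
                           structure(list(f1, f2, f3), class = "fragment_set"))
  m3 <- fragment_adjacency_stats(cl3, list(f1, f2, f3))
  expect_equal(m3["(4,5,5)", "(4,5,5)"], 0.5)
  expect_equal(m3["(4,5,5)", "(6,6,7)"], 0.5)
  expect_equal(m3["(6,6,7)", "(4,5,5)"], 1.0)
  expect_equal(unname(rowSums(m3)), c(1, 1))
})
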