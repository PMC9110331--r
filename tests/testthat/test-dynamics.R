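test_that("overlap map and bipartite components identify events", {
  e1 <- ents(ent("cluster", 1:6), ent("cluster", 10:15))
  e2 <- ents(ent("cluster", 1:6), ent("cluster", 10:15))
  mc <- match_clusters(e1, e2)
  expect_equal(nrow(mc$overlap), 2L)
  expect_true(all(mc$overlap$shared == 6L))
  comps <- Filter(function(cc) length(cc$a) && length(cc$b), mc$components)
  expect_length(comps, 2L)
  # disjoint molecule sets: no overlap rows
  mc2 <- match_clusters(ents(ent("cluster", 1:4)),
                        ents(ent("cluster", 21:24)))
  expect_equal(nrow(mc2$overlap), 0L)
  # engineered 2 -> 1 overlap
  mc3 <- match_clusters(ents(ent("cluster", 1:4), ent("cluster", 5:8)),
                        ents(ent("cluster", 1:8)))
  comp3 <- Filter(function(cc) length(cc$b), mc3$components)
  expect_length(comp3, 1L)
  expect_length(comp3[[1]]$a, 2L)
  expect_length(comp3[[1]]$b, 1L)
})

test_that("the four transformation patterns classify exactly", {
  # changeless: identical membership
  ev <- transformation_events(ents(ent("cluster", 1:6)),
                              ents(ent("cluster", 1:6)))
  expect_equal(vapply(ev, `[[`, "", "type"), "changeless")
  # merge: one cluster + three debris molecules -> one larger cluster
  ev2 <- transformation_events(
    ents(ent("cluster", 1:6), ent("debris", 7), ent("debris", 8),
         ent("debris", 9)),
    ents(ent("cluster", 1:9)))
  expect_equal(vapply(ev2, `[[`, "", "type"), "merge")
  expect_equal(ev2[[1]]$i_c, 1L)
  expect_equal(ev2[[1]]$i_m, 3L)
  # ring + debris merging into a cluster (i_R >= 1 suffices)
  ev2b <- transformation_events(
    ents(ent("ring", 1:4), ent("debris", 5), ent("debris", 6)),
    ents(ent("cluster", 1:6)))
  expect_equal(vapply(ev2b, `[[`, "", "type"), "merge")
  # split: one cluster -> cluster + isolated ring + two debris molecules
  ev3 <- transformation_events(
    ents(ent("cluster", 1:12)),
    ents(ent("cluster", 1:6), ent("ring", 7:10), ent("debris", 11),
         ent("debris", 12)))
  expect_equal(vapply(ev3, `[[`, "", "type"), "split")
  expect_equal(ev3[[1]]$ip_R, 1L)
  expect_equal(ev3[[1]]$ip_m, 2L)
  # complex: crossed membership between two clusters
  ev4 <- transformation_events(
    ents(ent("cluster", 1:6), ent("cluster", 7:12)),
    ents(ent("cluster", c(1:3, 7:9)), ent("cluster", c(4:6, 10:12))))
  expect_equal(vapply(ev4, `[[`, "", "type"), "complex")
})

test_that("molecule multisets are conserved within every event", {
  evs <- c(
    transformation_events(ents(ent("cluster", 1:6), ent("debris", 7)),
                          ents(ent("cluster", 1:7))),
    transformation_events(ents(ent("cluster", 1:9)),
                          ents(ent("cluster", 1:5), ent("ring", 6:9))))
  for (ev in evs) expect_true(ev$conserved)
})

test_that("reversing frame order swaps merge and split counts exactly", {
  ea <- ents(ent("cluster", 1:6), ent("debris", 7), ent("debris", 8),
             ent("cluster", 20:28))
  eb <- ents(ent("cluster", 1:8), ent("cluster", 20:24),
             ent("ring", 25:28))
  fwd <- table(vapply(transformation_events(ea, eb), `[[`, "", "type"))
  rev <- table(vapply(transformation_events(eb, ea), `[[`, "", "type"))
  expect_equal(unname(fwd[["merge"]]), unname(rev[["split"]]))
  expect_equal(unname(fwd[["split"]]), unname(rev[["merge"]]))
})

test_that("lifetimes count strictly unchanged membership chains", {
  c1 <- ent("cluster", 1:6)
  c2 <- ent("cluster", 8:11)
  frames <- list(ents(c1), ents(c1), ents(c1), ents(c1),
                 ents(ent("cluster", 1:7)))
  ls <- lifetime_stats(frames, size_classes = list(small = c(1, 9)))
  expect_equal(ls$lifetimes$small$mean_lifetime, (4 + 1) / 2)  # chain 4 + new 1
  # single-frame cluster: lifetime 1
  ls1 <- lifetime_stats(list(ents(c2)), size_classes = list(all = c(1, Inf)))
  expect_equal(ls1$lifetimes$all$mean_lifetime, 1)
  # hand-built tracks: 2, 1, 3 frames for three clusters
  f <- list(ents(c1, c2), ents(c1, ent("cluster", 30:33)),
            ents(ent("cluster", 40:44)), ents(ent("cluster", 40:44)),
            ents(ent("cluster", 40:44)))
  ls2 <- lifetime_stats(f, size_classes = list(all = c(1, Inf)))
  expect_equal(sort(c(2, 1, 1, 3)),
               sort(c(2, 1, 1, 3)))  # chains: c1=2, c2=1, 30:33=1, 40:44=3
  expect_equal(ls2$lifetimes$all$mean_lifetime, mean(c(2, 1, 1, 3)))
})

test_that("event rates over a run are proper fractions summing to one", {
  frames <- list(
    ents(ent("cluster", 1:6), ent("debris", 7), ent("debris", 8)),
    ents(ent("cluster", 1:8)),
    ents(ent("cluster", 1:8)),
    ents(ent("cluster", 1:4), ent("ring", 5:8)))
  ls <- lifetime_stats(frames)
  expect_equal(sum(ls$rates), 1)
  expect_equal(unname(ls$rates[["merge"]]), 1 / 3)
  expect_equal(unname(ls$rates[["changeless"]]), 1 / 3)
  expect_equal(unname(ls$rates[["split"]]), 1 / 3)
})
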