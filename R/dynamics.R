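# Cluster transformation dynamics between consecutive frames.
#
# At each time step the frame decomposes into three entity kinds:
# clusters (communities of cage fragments), isolated rings (rings belonging
# to no fragment), and debris molecules (molecules in no cluster and no
# isolated ring). Overlapping molecule sets across consecutive frames link
# entities into bipartite components; each component containing at least
# one cluster is one transformation event, classified as changeless, merge,
# split, or complex fusion-and-fission.

#' Decompose a clustered frame into clusters, isolated rings and debris
#'
#' @param clusters a `water_clusters` object (may be empty).
#' @param rings the frame's `ring_set`.
#' @param fragments the frame's `fragment_set`.
#' @param n_molecules molecule count of the frame.
#' @return An object of class `frame_entities`: list of entities, each with
#'   `type` (`"cluster"`, `"ring"`, `"debris"`), `molecules` and `id`.
#' @export
frame_entities <- function(clusters, rings, fragments, n_molecules) {
  ents <- list()
  for (cl in clusters)
    ents[[length(ents) + 1L]] <- list(type = "cluster",
                                      molecules = cl$molecules,
                                      id = sprintf("C%d", cl$cluster_id))
  in_fragment <- unique(unlist(lapply(fragments, `[[`, "rings"),
                               use.names = FALSE))
  iso <- setdiff(seq_along(rings$rings), in_fragment)
  for (k in seq_along(iso))
    ents[[length(ents) + 1L]] <- list(type = "ring",
                                      molecules = sort(rings$rings[[iso[k]]]),
                                      id = sprintf("R%d", iso[k]))
  used <- unique(unlist(lapply(ents, `[[`, "molecules"), use.names = FALSE))
  for (m in setdiff(seq_len(n_molecules), used))
    ents[[length(ents) + 1L]] <- list(type = "debris", molecules = m,
                                      id = sprintf("m%d", m))
  structure(ents, class = "frame_entities")
}

#' Molecule-overlap map between two clusterings
#'
#' For every pair of entities across consecutive frames, counts the shared
#' molecules; connected components of the nonzero-overlap bipartite graph
#' define transformation events.
#'
#' @param entities_t,entities_t1 `frame_entities` for frames t and t+1 (a
#'   `water_clusters` object is also accepted and treated as cluster-only
#'   entities).
#' @return List with `overlap` (`data.frame(a, b, shared)`) and `component`
#'   (list of components, each holding indices `a` into `entities_t` and
#'   `b` into `entities_t1`).
#' @export
match_clusters <- function(entities_t, entities_t1) {
  as_ents <- function(x) {
    if (inherits(x, "frame_entities")) return(x)
    structure(lapply(x, function(cl)
      list(type = "cluster", molecules = cl$molecules,
           id = sprintf("C%d", cl$cluster_id))), class = "frame_entities")
  }
  ea <- as_ents(entities_t)
  eb <- as_ents(entities_t1)
  mol_to_b <- list()
  for (k in seq_along(eb))
    for (m in eb[[k]]$molecules)
      mol_to_b[[as.character(m)]] <- c(mol_to_b[[as.character(m)]], k)
  aa <- integer(0); bb <- integer(0); ss <- integer(0)
  cnt <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(ea)) {
    hits <- unlist(mol_to_b[as.character(ea[[k]]$molecules)],
                   use.names = FALSE)
    if (is.null(hits) || !length(hits)) next
    tb <- table(hits)
    aa <- c(aa, rep.int(k, length(tb)))
    bb <- c(bb, as.integer(names(tb)))
    ss <- c(ss, as.integer(tb))
  }
  overlap <- data.frame(a = aa, b = bb, shared = ss)
  # connected components via union-find over the bipartite graph
  na <- length(ea); nb <- length(eb)
  parent <- seq_len(na + nb)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(overlap)))
    parent[find(overlap$a[r])] <- find(overlap$b[r] + na)
  roots <- vapply(seq_len(na + nb), find, integer(1))
  comp <- split(seq_len(na + nb), roots)
  components <- lapply(comp, function(idx)
    list(a = idx[idx <= na], b = idx[idx > na] - na))
  # keep components that actually touch both frames or contain clusters
  names(components) <- NULL
  list(overlap = overlap, components = components,
       entities_t = ea, entities_t1 = eb)
}

#' Classify one transformation event
#'
#' @param event list with `reactants` and `products`, each a list of
#'   entities (`type`, `molecules`).
#' @return One of `"changeless"`, `"merge"`, `"split"`, `"complex"`.
#' @export
classify_transformation <- function(event) {
  re <- event$reactants
  pr <- event$products
  rtype <- vapply(re, `[[`, "", "type")
  ptype <- vapply(pr, `[[`, "", "type")
  i_c <- sum(rtype == "cluster"); i_R <- sum(rtype == "ring")
  o_c <- sum(ptype == "cluster"); o_R <- sum(ptype == "ring")
  if (i_c == 1L && length(re) == 1L && o_c == 1L && length(pr) == 1L &&
      identical(sort(re[[1]]$molecules), sort(pr[[1]]$molecules)))
    return("changeless")
  if (o_c == 1L && length(pr) == 1L && (i_c >= 1L || i_R >= 1L) &&
      length(re) >= 2L)
    return("merge")
  if (i_c == 1L && length(re) == 1L && (o_c >= 1L || o_R >= 1L) &&
      length(pr) >= 2L)
    return("split")
  "complex"
}

#' Transformation events between two consecutive frames
#'
#' @param entities_t,entities_t1 `frame_entities` of frames t and t+1.
#' @return List of events (components containing at least one cluster),
#'   each with `reactants`, `products`, `type`, the multiplicities
#'   `i_c, i_R, i_m` and `ip_c, ip_R, ip_m`, and a molecule-conservation
#'   flag `conserved`.
#' @export
transformation_events <- function(entities_t, entities_t1) {
  mc <- match_clusters(entities_t, entities_t1)
  evs <- list()
  for (comp in mc$components) {
    re <- mc$entities_t[comp$a]
    pr <- mc$entities_t1[comp$b]
    if (!length(re) || !length(pr)) next
    rtype <- vapply(re, `[[`, "", "type")
    ptype <- vapply(pr, `[[`, "", "type")
    if (!any(rtype == "cluster") && !any(ptype == "cluster")) next
    ev <- list(reactants = re, products = pr)
    ev$type <- classify_transformation(ev)
    ev$i_c <- sum(rtype == "cluster"); ev$i_R <- sum(rtype == "ring")
    ev$i_m <- sum(rtype == "debris")
    ev$ip_c <- sum(ptype == "cluster"); ev$ip_R <- sum(ptype == "ring")
    ev$ip_m <- sum(ptype == "debris")
    ev$conserved <- setequal(
      unlist(lapply(re, `[[`, "molecules"), use.names = FALSE),
      unlist(lapply(pr, `[[`, "molecules"), use.names = FALSE))
    evs[[length(evs) + 1L]] <- ev
  }
  evs
}

#' Cluster lifetimes and transformation rates over a trajectory
#'
#' A cluster's lifetime is the number of consecutive frames over which its
#' molecule membership persists unchanged (no grace for single-frame
#' interruptions), reported in units of the frame interval. Event rates are
#' the fractions of changeless / merge / split / complex events tallied
#' over all consecutive-frame transformations.
#'
#' @param entity_frames list of `frame_entities`, one per frame, in time
#'   order (at least 2 frames for events; lifetimes need 1+).
#' @param size_classes named list of `c(min, max)` molecule-count ranges,
#'   default `list(small = c(1, 9), large = c(51, Inf))`.
#' @return List with `lifetimes` (per size class: mean lifetime in frame
#'   units and count), `rates` (named fractions summing to 1, or empty),
#'   and `events` (all classified events by frame).
#' @export
lifetime_stats <- function(entity_frames,
                           size_classes = list(small = c(1, 9),
                                               large = c(51, Inf))) {
  nf <- length(entity_frames)
  if (nf < 1L) stop("need at least one frame")
  # chains of identical cluster membership
  key_frames <- lapply(entity_frames, function(ents) {
    cl <- Filter(function(e) e$type == "cluster", ents)
    vapply(cl, function(e) paste(sort(e$molecules), collapse = ","), "")
  })
  sizes <- list(); lifetimes <- integer(0); sizes_of <- integer(0)
  active <- new.env(hash = TRUE, parent = emptyenv())  # key -> start frame
  for (t in seq_len(nf)) {
    now <- key_frames[[t]]
    prev <- ls(active)
    gone <- setdiff(prev, now)
    for (k in gone) {
      span <- t - active[[k]]
      lifetimes <- c(lifetimes, span)
      sizes_of <- c(sizes_of, length(strsplit(k, ",")[[1]]))
      rm(list = k, envir = active)
    }
    for (k in setdiff(now, prev)) active[[k]] <- t
  }
  for (k in ls(active)) {  # still alive at the last frame
    lifetimes <- c(lifetimes, nf + 1L - active[[k]])
    sizes_of <- c(sizes_of, length(strsplit(k, ",")[[1]]))
  }
  lt <- lapply(size_classes, function(rg) {
    sel <- sizes_of >= rg[1] & sizes_of <= rg[2]
    list(mean_lifetime = if (any(sel)) mean(lifetimes[sel]) else NA_real_,
         n = sum(sel))
  })
  evs <- list()
  if (nf >= 2L) {
    for (t in seq_len(nf - 1L)) {
      e <- transformation_events(entity_frames[[t]], entity_frames[[t + 1L]])
      evs[[t]] <- e
    }
  }
  all_types <- unlist(lapply(evs, function(e) vapply(e, `[[`, "", "type")))
  rates <- if (length(all_types))
    prop.table(table(factor(all_types,
                            levels = c("changeless", "merge", "split",
                                       "complex"))))
  else table(factor(character(0),
                    levels = c("changeless", "merge", "split", "complex")))
  list(lifetimes = lt, rates = rates, events = evs)
}
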