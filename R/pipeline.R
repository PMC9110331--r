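# Full analysis pipeline over a trajectory: hydrogen bonds -> rings ->
# fragments -> fragment network -> Louvain clusters -> morphology, energy,
# descriptors -> cross-frame dynamics.

#' Run the hierarchical clustering pipeline over a trajectory
#'
#' Processes each frame independently through the hierarchy (hydrogen-bond
#' detection, shortest-path ring enumeration, cage-fragment detection,
#' fragment network, Louvain communities, cluster assembly), then computes
#' the requested per-cluster quantities and, when several frames are given,
#' the transformation dynamics between consecutive frames. Deterministic
#' for a fixed `rng_seed` (each frame's Louvain run is seeded by
#' `rng_seed + frame position`).
#'
#' @param frames a `water_frame` or list of them, in time order.
#' @param settings a [trajectory_settings()] object.
#' @param stages character vector of optional stages to run after
#'   clustering: any of `"shapes"`, `"energy"`, `"lsi"`, `"dynamics"`.
#' @return An object of class `aquaclust_report`: list with per-frame
#'   results (`frames`: graph, rings, fragments, clusters, coverage,
#'   cluster table), pooled `cluster_table`, `counts`, `rates`/`lifetimes`
#'   (when dynamics ran) and the `settings` used.
#' @export
run_pipeline <- function(frames, settings = trajectory_settings(),
                         stages = c("shapes", "energy", "lsi", "dynamics")) {
  if (inherits(frames, "water_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L, inherits(settings, "trajectory_settings"))
  stages <- match.arg(stages, several.ok = TRUE)
  per_frame <- vector("list", length(frames))
  entity_frames <- vector("list", length(frames))

  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    graph <- detect_hbonds(fr, settings$hb_cutoff)
    rings <- enumerate_sp_rings(graph, settings$max_ring_size)
    fragments <- detect_fragments(rings, graph,
                                  settings$fragment_ring_counts)
    network <- build_fragment_network(fragments)
    partition <- louvain_partition(network, seed = settings$rng_seed + t)
    clusters <- assemble_clusters(partition, fragments)
    cov <- coverage_fraction(clusters, fr)

    tab <- data.frame(
      frame = rep(t, length(clusters)),
      cluster_id = vapply(clusters, `[[`, integer(1), "cluster_id"),
      S = vapply(clusters, `[[`, integer(1), "S"))
    if ("shapes" %in% stages && length(clusters)) {
      sh <- cluster_shapes(clusters, fr, graph, settings$alpha_radius)
      tab$V <- sh$V; tab$A <- sh$A; tab$L <- sh$L; tab$r <- sh$r
    }
    if ("energy" %in% stages && length(clusters)) {
      tab$E_S <- vapply(clusters, function(cl)
        cluster_energy(fr, cl, settings$energy_cutoff), numeric(1))
    }
    lsi_vals <- NULL
    if ("lsi" %in% stages)
      lsi_vals <- lsi_profile(fr, shell_cutoff = settings$lsi_shell_cutoff)

    per_frame[[t]] <- list(
      graph = graph, rings = rings, fragments = fragments,
      network = network, partition = partition, clusters = clusters,
      coverage = cov, cluster_table = tab, lsi = lsi_vals,
      counts = c(molecules = n_molecules(fr),
                 hbonds = nrow(graph$edges),
                 rings = length(rings$rings),
                 fragments = length(fragments),
                 clusters = length(clusters)))
    entity_frames[[t]] <- frame_entities(clusters, rings, fragments,
                                         n_molecules(fr))
  }

  report <- list(
    frames = per_frame,
    cluster_table = do.call(rbind, lapply(per_frame, `[[`, "cluster_table")),
    counts = do.call(rbind, lapply(per_frame, `[[`, "counts")),
    coverage = vapply(per_frame, `[[`, numeric(1), "coverage"),
    settings = settings)

  if ("dynamics" %in% stages && length(frames) >= 2L) {
    dyn <- lifetime_stats(entity_frames)
    report$rates <- dyn$rates
    report$lifetimes <- dyn$lifetimes
    report$events <- dyn$events
  }
  class(report) <- "aquaclust_report"
  report
}

#' @export
print.aquaclust_report <- function(x, ...) {
  nf <- length(x$frames)
  cat(sprintf("aquaclust_report: %d frame(s)\n", nf))
  tot <- as.integer(colSums(x$counts))
  names(tot) <- colnames(x$counts)
  cat(sprintf("  totals: %d molecules, %d H-bonds, %d rings, %d fragments, %d clusters\n",
              tot["molecules"], tot["hbonds"], tot["rings"],
              tot["fragments"], tot["clusters"]))
  cat(sprintf("  mean molecule coverage by clusters: %.3f\n", mean(x$coverage)))
  if (!is.null(x$rates)) {
    r <- x$rates
    cat(sprintf("  event rates: changeless %.2f, merge %.2f, split %.2f, complex %.2f\n",
                r[["changeless"]], r[["merge"]], r[["split"]], r[["complex"]]))
  }
  invisible(x)
}

#' Write a pipeline report to an output directory
#'
#' Emits the pooled cluster table (TSV), per-frame stage counts (TSV) and a
#' JSON summary with settings, coverage and (when available) event rates.
#'
#' @param report an `aquaclust_report`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$cluster_table, file.path(outdir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(frame = seq_len(nrow(report$counts)), report$counts),
              file.path(outdir, "counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(settings = unclass(report$settings),
               coverage = report$coverage)
  if (!is.null(report$rates)) meta$rates <- as.list(report$rates)
  if (!is.null(report$lifetimes)) meta$lifetimes <- report$lifetimes
  jsonlite::write_json(meta, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
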