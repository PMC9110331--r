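#' Detect hydrogen bonds with the geometric distance criterion
#'
#' Two molecules are hydrogen bonded when a hydrogen of one lies strictly
#' closer than `cutoff` (default 2.5 Angstrom) to the oxygen of the other,
#' under the minimum-image convention. The criterion is purely geometric: no
#' donor-hydrogen-acceptor angle term is applied, and equality at the cutoff
#' is excluded. Several H...O contacts between the same pair collapse to a
#' single undirected edge; the donor annotation of the shortest contact is
#' kept, and all contacts are retained in the `contacts` table (so
#' bifurcated bonds, one hydrogen bonding two acceptors, contribute one edge
#' per acceptor).
#'
#' @param frame a [water_frame()].
#' @param cutoff O...H distance cutoff in Angstrom (strict `<`).
#' @return An object of class `hbond_graph`: a list with
#'   \describe{
#'     \item{n}{molecule count,}
#'     \item{edges}{`data.frame(i, j, donor, hydrogen, d_oh)` with `i < j`,
#'       the donor molecule, the donating hydrogen row index and the O...H
#'       distance of the closest contact,}
#'     \item{contacts}{every individual H...O contact below the cutoff.}
#'   }
#' @examples
#' frame <- build_theta_cage(c(2, 2, 3))$frame
#' g <- detect_hbonds(frame)
#' nrow(g$edges)  # 7 hydrogen bonds in the (4,5,5) theta cage
#' @export
detect_hbonds <- function(frame, cutoff = 2.5) {
  stopifnot(inherits(frame, "water_frame"))
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  hits <- pair_search(frame$hydrogen, frame$oxygen, frame$box, cutoff)
  donor <- frame$h_owner[hits$i]
  keep <- donor != hits$j  # drop intramolecular contacts
  contacts <- data.frame(donor = donor[keep], acceptor = hits$j[keep],
                         hydrogen = hits$i[keep], d_oh = hits$d[keep])
  if (nrow(contacts)) {
    a <- pmin(contacts$donor, contacts$acceptor)
    b <- pmax(contacts$donor, contacts$acceptor)
    ord <- order(a, b, contacts$d_oh)
    a <- a[ord]; b <- b[ord]; cc <- contacts[ord, ]
    first <- !duplicated(cbind(a, b))
    edges <- data.frame(i = a[first], j = b[first],
                        donor = cc$donor[first], hydrogen = cc$hydrogen[first],
                        d_oh = cc$d_oh[first])
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), donor = integer(0),
                        hydrogen = integer(0), d_oh = numeric(0))
  }
  structure(list(n = n_molecules(frame), edges = edges, contacts = contacts),
            class = "hbond_graph")
}

#' @export
print.hbond_graph <- function(x, ...) {
  cat(sprintf("hbond_graph: %d molecules, %d hydrogen bonds\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

# construct an hbond_graph directly from an edge list (used by tests and
# synthetic builders that work at the topology level)
hbond_graph_from_edges <- function(n, edges) {
  edges <- as.data.frame(edges)
  if (!nrow(edges)) {
    edges <- data.frame(i = integer(0), j = integer(0))
  } else {
    a <- pmin(edges[[1]], edges[[2]])
    b <- pmax(edges[[1]], edges[[2]])
    if (any(a == b)) stop("self-edges are not allowed")
    keep <- !duplicated(cbind(a, b))
    edges <- data.frame(i = a[keep], j = b[keep])
  }
  structure(list(n = as.integer(n), edges = edges,
                 contacts = data.frame()), class = "hbond_graph")
}

# adjacency list representation (list of integer vectors, length n)
adjacency_list <- function(graph) {
  e <- graph$edges
  src <- c(e$i, e$j)
  dst <- c(e$j, e$i)
  unname(lapply(split(as.integer(dst), factor(src, levels = seq_len(graph$n))),
                as.integer))
}

as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
  g
}

#' Export a hydrogen-bond edge list as TSV
#' @param graph an `hbond_graph`.
#' @param path output path.
#' @param frame_index frame label written in the first column.
#' @return `path`, invisibly.
#' @export
write_hbond_table <- function(graph, path, frame_index = 1L) {
  e <- graph$edges
  tab <- data.frame(frame = frame_index, donor_mol = e$donor,
                    acceptor_mol = ifelse(e$donor == e$i, e$j, e$i),
                    O..H_distance_A = e$d_oh)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
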