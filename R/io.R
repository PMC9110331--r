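# Trajectory readers and writers.
#
# Three plain-text dialects are supported: XYZ (element x y z, box stored on
# the comment line), GROMACS GRO (fixed width, nm; converted to Angstrom),
# and LAMMPS dump ("ITEM: ATOMS id type x y z" with a type -> element map).
# Only orthorhombic boxes are accepted. Hydrogens are reassigned to their
# nearest oxygen under minimum image on read, because not every format
# groups atoms by molecule.

#' Read water coordinate frames from a trajectory file
#'
#' @param path file path.
#' @param format one of `"xyz"`, `"gro"`, `"lammps-dump"`.
#' @param box optional length-3 box override (Angstrom); required for XYZ
#'   files whose comment line does not carry three box lengths.
#' @param type_map named character vector mapping LAMMPS atom types to
#'   elements, e.g. `c("1" = "O", "2" = "H")` (the default).
#' @return A list of [water_frame()] objects in file order.
#' @export
read_frames <- function(path, format = c("xyz", "gro", "lammps-dump"),
                        box = NULL, type_map = c("1" = "O", "2" = "H")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  raw <- switch(format,
                "xyz" = parse_xyz(lines, box),
                "gro" = parse_gro(lines),
                "lammps-dump" = parse_dump(lines, type_map))
  lapply(seq_along(raw), function(k) {
    fr <- raw[[k]]
    assemble_frame(fr$element, fr$xyz, fr$box, frame_index = k,
                   frame_time = fr$time)
  })
}

#' Write water frames to a trajectory file
#'
#' @param frames a `water_frame` or list of them.
#' @param path output file path.
#' @param format `"xyz"`, `"gro"` or `"lammps-dump"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, format = c("xyz", "gro", "lammps-dump")) {
  format <- match.arg(format)
  if (inherits(frames, "water_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    el <- c(rep("O", n_molecules(fr)), rep("H", nrow(fr$hydrogen)))
    xyz <- rbind(fr$oxygen, fr$hydrogen)
    switch(format,
      "xyz" = {
        writeLines(as.character(nrow(xyz)), con)
        writeLines(sprintf("box %.8f %.8f %.8f t= %.3f",
                           fr$box[1], fr$box[2], fr$box[3], fr$frame_time), con)
        writeLines(sprintf("%-2s %14.8f %14.8f %14.8f",
                           el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
      },
      "gro" = {
        # interleave atoms per molecule: OW, HW1, HW2
        writeLines(sprintf("water frame t= %.3f", fr$frame_time), con)
        n <- n_molecules(fr)
        writeLines(as.character(3L * n), con)
        at <- 0L
        for (m in seq_len(n)) {
          hs <- which(fr$h_owner == m)
          pos <- rbind(fr$oxygen[m, ], fr$hydrogen[hs[1], ], fr$hydrogen[hs[2], ]) / 10
          nm <- c("OW", "HW1", "HW2")
          for (a in 1:3) {
            at <- at + 1L
            writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                               m %% 100000L, "SOL", nm[a], at %% 100000L,
                               pos[a, 1], pos[a, 2], pos[a, 3]), con)
          }
        }
        writeLines(sprintf("%10.5f%10.5f%10.5f",
                           fr$box[1] / 10, fr$box[2] / 10, fr$box[3] / 10), con)
      },
      "lammps-dump" = {
        writeLines("ITEM: TIMESTEP", con)
        writeLines(as.character(fr$frame_index), con)
        writeLines("ITEM: NUMBER OF ATOMS", con)
        writeLines(as.character(nrow(xyz)), con)
        writeLines("ITEM: BOX BOUNDS pp pp pp", con)
        writeLines(sprintf("0.0 %.8f", fr$box), con)
        writeLines("ITEM: ATOMS id type x y z", con)
        ty <- ifelse(el == "O", 1L, 2L)
        writeLines(sprintf("%d %d %.8f %.8f %.8f",
                           seq_len(nrow(xyz)), ty, xyz[, 1], xyz[, 2], xyz[, 3]),
                   con)
      })
  }
  invisible(path)
}

parse_xyz <- function(lines, box = NULL) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L)
      stop(sprintf("parse error at line %d: expected atom count, got '%s'",
                   i, lines[i]))
    if (i + 1L + nat > length(lines))
      stop(sprintf("parse error at line %d: truncated frame", i))
    comment <- lines[i + 1L]
    nums <- suppressWarnings(as.numeric(
      regmatches(comment, gregexpr("-?[0-9]+\\.?[0-9]*(e[-+]?[0-9]+)?",
                                   comment, ignore.case = TRUE))[[1]]))
    fbox <- box
    if (is.null(fbox)) {
      if (length(nums) >= 3L) fbox <- nums[1:3]
      else stop(sprintf("parse error at line %d: no box lengths on comment line and no box= argument",
                        i + 1L))
    }
    tm <- if (grepl("t=", comment) && length(nums) >= 4L) nums[length(nums)] else 0
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad))
      stop(sprintf("parse error at line %d: malformed atom record", i + 1L + bad[1]))
    el <- toupper(substr(vapply(toks, `[[`, "", 1L), 1L, 1L))
    xyz <- matrix(as.numeric(vapply(toks, function(t) t[2:4], character(3))),
                  ncol = 3L, byrow = TRUE)
    if (any(!is.finite(xyz)))
      stop(sprintf("parse error near line %d: non-numeric coordinate", i + 2L))
    frames[[length(frames) + 1L]] <- list(element = el, xyz = xyz,
                                          box = fbox, time = tm)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("parse error: no frames found")
  frames
}

parse_gro <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat))
      stop(sprintf("parse error at line %d: expected atom count", i + 1L))
    if (i + 2L + nat > length(lines))
      stop(sprintf("parse error at line %d: truncated frame", i))
    body <- lines[(i + 2L):(i + 1L + nat)]
    name <- trimws(substr(body, 11L, 15L))
    el <- toupper(substr(name, 1L, 1L))
    x <- as.numeric(substr(body, 21L, 28L))
    y <- as.numeric(substr(body, 29L, 36L))
    z <- as.numeric(substr(body, 37L, 44L))
    if (any(!is.finite(c(x, y, z))))
      stop(sprintf("parse error in frame starting line %d: bad coordinate field", i))
    boxline <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[i + 2L + nat]), "[[:space:]]+")[[1]]))
    if (length(boxline) < 3L || any(!is.finite(boxline[1:3])))
      stop(sprintf("parse error at line %d: bad box line", i + 2L + nat))
    if (length(boxline) > 3L && any(abs(boxline[-(1:3)]) > 1e-12))
      stop("triclinic boxes are not supported (off-diagonal box components present)")
    tm <- 0
    if (grepl("t=", title)) {
      tv <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", title)))
      if (is.finite(tv)) tm <- tv
    }
    frames[[length(frames) + 1L]] <- list(
      element = el, xyz = cbind(x, y, z) * 10, box = boxline[1:3] * 10, time = tm)
    i <- i + 3L + nat
  }
  if (!length(frames)) stop("parse error: no frames found")
  frames
}

parse_dump <- function(lines, type_map) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!grepl("^ITEM: TIMESTEP", lines[i]))
      stop(sprintf("parse error at line %d: expected ITEM: TIMESTEP", i))
    step <- as.numeric(trimws(lines[i + 1L]))
    if (!grepl("^ITEM: NUMBER OF ATOMS", lines[i + 2L]))
      stop(sprintf("parse error at line %d: expected ITEM: NUMBER OF ATOMS", i + 2L))
    nat <- as.integer(trimws(lines[i + 3L]))
    if (!grepl("^ITEM: BOX BOUNDS", lines[i + 4L]))
      stop(sprintf("parse error at line %d: expected ITEM: BOX BOUNDS", i + 4L))
    if (grepl("xy|xz|yz", lines[i + 4L]))
      stop("triclinic boxes are not supported")
    bounds <- t(vapply(lines[(i + 5L):(i + 7L)], function(l)
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]][1:2]), numeric(2)))
    box <- bounds[, 2] - bounds[, 1]
    hdr <- lines[i + 8L]
    if (!grepl("^ITEM: ATOMS", hdr))
      stop(sprintf("parse error at line %d: expected ITEM: ATOMS", i + 8L))
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", hdr), "[[:space:]]+")[[1]]
    need <- c("type", "x", "y", "z")
    if (!all(need %in% cols))
      stop(sprintf("parse error at line %d: dump must provide columns type x y z",
                   i + 8L))
    body <- lines[(i + 9L):(i + 8L + nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(toks) < length(cols))
    if (length(bad))
      stop(sprintf("parse error at line %d: malformed atom record", i + 8L + bad[1]))
    tab <- matrix(unlist(toks, use.names = FALSE), ncol = length(cols),
                  byrow = TRUE)
    colnames(tab) <- cols
    ty <- tab[, "type"]
    el <- unname(type_map[ty])
    if (any(is.na(el)))
      stop(sprintf("unknown atom type '%s' (extend type_map)",
                   ty[which(is.na(el))[1]]))
    xyz <- cbind(as.numeric(tab[, "x"]), as.numeric(tab[, "y"]),
                 as.numeric(tab[, "z"]))
    frames[[length(frames) + 1L]] <- list(element = toupper(el), xyz = xyz,
                                          box = box, time = step)
    i <- i + 9L + nat
  }
  if (!length(frames)) stop("parse error: no frames found")
  frames
}

# Build a water_frame from element labels + coordinates: split O/H and
# assign each hydrogen to its nearest oxygen under minimum image.
assemble_frame <- function(element, xyz, box, frame_index = 1L, frame_time = 0) {
  is_o <- element == "O"
  is_h <- element == "H"
  if (!all(is_o | is_h))
    stop(sprintf("composition error: unknown element '%s'",
                 element[which(!(is_o | is_h))[1]]))
  o <- xyz[is_o, , drop = FALSE]
  h <- xyz[is_h, , drop = FALSE]
  if (nrow(h) != 2L * nrow(o))
    stop(sprintf("composition error: %d hydrogens for %d oxygens",
                 nrow(h), nrow(o)))
  owner <- assign_hydrogens(o, h, box)
  water_frame(o, h, owner, box, frame_index = frame_index,
              frame_time = frame_time)
}

# nearest-oxygen covalent assignment, with ambiguity detection
assign_hydrogens <- function(o, h, box) {
  nh <- nrow(h)
  owner <- integer(nh)
  d1 <- rep(Inf, nh)  # nearest oxygen distance
  d2 <- rep(Inf, nh)  # second nearest (for ambiguity check)
  r <- min(1.5, min(box) / 2)
  repeat {
    pairs <- pair_search(h, o, box, r)
    if (nrow(pairs)) {
      ord <- order(pairs$i, pairs$d)
      pi <- pairs$i[ord]; pj <- pairs$j[ord]; pd <- pairs$d[ord]
      rank_in_group <- sequence(rle(pi)$lengths)
      first <- rank_in_group == 1L
      second <- rank_in_group == 2L
      owner[pi[first]] <- pj[first]
      d1[pi[first]] <- pd[first]
      d2[pi] <- Inf
      d2[pi[second]] <- pd[second]
    }
    if (all(owner > 0L) || r >= min(box) / 2 - 1e-12) break
    r <- min(r * 1.8, min(box) / 2)
  }
  if (any(owner == 0L)) {
    # direct scan fallback for stragglers (e.g. stretched geometries)
    for (k in which(owner == 0L)) {
      d <- min_image_dist(h[rep(k, nrow(o)), , drop = FALSE], o, box)
      ord <- order(d)
      owner[k] <- ord[1]
      d1[k] <- d[ord[1]]
      if (length(d) > 1L) d2[k] <- d[ord[2]]
    }
  }
  amb <- which(is.finite(d2) & (d2 - d1) < 1e-6)
  if (length(amb))
    stop(sprintf("assignment error: hydrogen %d equidistant between two oxygens",
                 amb[1]))
  owner
}
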