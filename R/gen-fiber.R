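#' Define an aromatic ring on a structure
#'
#' A ring is an ordered set of at least five atom indices belonging to one
#' molecule; its centroid and unit plane normal are computed from coordinates
#' when contacts are detected.
#'
#' @param molecule_id molecule the ring belongs to.
#' @param atom_idx ordered atom indices (>= 5).
#' @return an object of class `fa_ring`.
#' @export
ring_spec <- function(molecule_id, atom_idx) {
  if (length(atom_idx) < 5L)
    fa_stop("fa_validation_error", "a ring needs at least 5 atoms, got %d", length(atom_idx))
  structure(list(molecule_id = as.character(molecule_id),
                 atom_idx = as.integer(atom_idx)), class = "fa_ring")
}

#' Construct a static structure object
#'
#' A single-frame structure: coordinates in Angstrom, per-atom tags, unit
#' masses unless given, and an optional list of [ring_spec()] definitions.
#'
#' @param coords atoms x 3 matrix, Angstrom.
#' @param atoms data.frame with `molecule_id` and `group` per atom.
#' @param rings list of [ring_spec()] objects.
#' @param masses per-atom masses; default unit masses.
#' @return an object of class `fa_structure`.
#' @export
structure3d <- function(coords, atoms, rings = list(), masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) fa_stop("fa_validation_error", "coords must be atoms x 3")
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) != nrow(coords))
    fa_stop("fa_validation_error", "atoms must describe every coordinate row")
  masses <- masses %||% rep(1, nrow(coords))
  for (r in rings)
    if (any(r$atom_idx > nrow(coords)))
      fa_stop("fa_validation_error", "ring refers to atoms outside the structure")
  structure(list(coords = coords, atoms = atoms, rings = rings,
                 masses = as.numeric(masses)), class = "fa_structure")
}

#' @export
print.fa_structure <- function(x, ...) {
  cat(sprintf("<fa_structure> %d atoms, %d molecules, %d rings\n",
              nrow(x$coords), length(unique(x$atoms$molecule_id)), length(x$rings)))
  invisible(x)
}

# Orthonormal in-plane basis for a unit normal.
plane_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  cbind(e1, e2)
}

#' Generate an idealised pi-stacked ring fiber
#'
#' Builds `n_units` planar hexagonal rings (C-C radius 1.4 A, unit masses)
#' stacked along the z axis with the given rise and per-unit twist — the
#' primary (linear) fiber structure. Each branch point attaches a sub-stack of
#' parallel rings growing along a direction tilted 25 degrees off the main
#' axis (azimuths of successive branches separated by the golden angle), so a
#' branch ring pi-stacks with its anchor ring and produces the degree-3 node
#' that defines secondary (branched) structure. With `with_glycoside`, each
#' ring carries a 5-atom cluster 2.5 A radially outside the ring plane edge,
#' mimicking the outward-facing sugar backbone.
#'
#' The construction is deterministic (no RNG). The expected assembly ground
#' truth is attached as attribute `truth`: total ring count and topology class
#' (`SINGLETON` for one ring, `SECONDARY` if any branch, else `PRIMARY`).
#'
#' @param spec a [fiber_spec()].
#' @return an [structure3d()] with one molecule per ring and ring definitions.
#' @export
gen_ring_fiber <- function(spec) {
  if (!inherits(spec, "fa_fiber_spec"))
    fa_stop("fa_validation_error", "spec must be created by fiber_spec()")
  radius <- 1.4
  tilt <- 25 * pi / 180
  centroids <- list(); normals <- list(); twists <- numeric(0)
  for (k in seq_len(spec$n_units)) {
    centroids[[k]] <- c(0, 0, (k - 1) * spec$rise)
    normals[[k]] <- c(0, 0, 1)
    twists[k] <- (k - 1) * spec$twist
  }
  for (b in seq_along(spec$branch_points)) {
    bp <- spec$branch_points[[b]]
    phi <- (b - 1) * 137.5 * pi / 180
    dir <- c(sin(tilt) * cos(phi), sin(tilt) * sin(phi), cos(tilt))
    anchor <- centroids[[bp[1]]]
    for (j in seq_len(bp[2])) {
      centroids[[length(centroids) + 1L]] <- anchor + j * spec$rise * dir
      normals[[length(normals) + 1L]] <- dir
      twists <- c(twists, (j - 1) * spec$twist)
    }
  }
  n_rings <- length(centroids)
  coords <- NULL; mol <- character(0); grp <- character(0); rings <- list()
  for (r in seq_len(n_rings)) {
    basis <- plane_basis(normals[[r]])
    ang <- (0:5) * 60 * pi / 180 + twists[r] * pi / 180
    ring_xyz <- t(vapply(ang, function(a)
      centroids[[r]] + radius * (cos(a) * basis[, 1] + sin(a) * basis[, 2]),
      numeric(3)))
    idx0 <- if (is.null(coords)) 0L else nrow(coords)
    coords <- rbind(coords, ring_xyz)
    id <- sprintf("M%03d", r)
    mol <- c(mol, rep(id, 6)); grp <- c(grp, rep("flavonoid_core", 6))
    rings[[r]] <- ring_spec(id, idx0 + 1:6)
    if (spec$with_glycoside) {
      out <- (radius + 2.5) * basis[, 1]
      gly <- t(vapply(1:5, function(j)
        centroids[[r]] + out + 0.5 * switch(j, c(0, 0, 0),
                                            basis[, 1], -basis[, 1],
                                            basis[, 2], -basis[, 2]),
        numeric(3)))
      coords <- rbind(coords, gly)
      mol <- c(mol, rep(id, 5)); grp <- c(grp, rep("glycoside", 5))
    }
  }
  out <- structure3d(coords, data.frame(molecule_id = mol, group = grp), rings)
  # Analytic stacking adjacency implied by the construction: consecutive
  # main-stack rings; each branch chains internally and its first ring stacks
  # with both its anchor and, when one exists, the anchor's +1 neighbour
  # (interior junctions are crowded at pi-stacking distances). Classifying
  # this combinatorial graph gives the ground truth the geometric detector
  # must reproduce.
  edges <- if (spec$n_units > 1L)
    cbind(seq_len(spec$n_units - 1L), seq_len(spec$n_units - 1L) + 1L)
  else matrix(integer(0), 0, 2)
  nxt <- spec$n_units
  for (bp in spec$branch_points) {
    first <- nxt + 1L
    edges <- rbind(edges, c(bp[1], first))
    if (bp[1] < spec$n_units) edges <- rbind(edges, c(bp[1] + 1L, first))
    if (bp[2] > 1L)
      edges <- rbind(edges, cbind(first:(first + bp[2] - 2L),
                                  (first + 1L):(first + bp[2] - 1L)))
    nxt <- nxt + bp[2]
  }
  g <- igraph::make_empty_graph(n_rings, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  attr(out, "truth") <- list(n_rings = n_rings, edges = edges,
                             class = classify_assembly(g))
  out
}
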