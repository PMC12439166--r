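# Geometric pi-stacking detection and molecule-level assembly graphs.
# A stacking contact between two aromatic rings requires (i) centroid
# distance, (ii) interplanar angle (between plane normals, folded to [0, 90]
# degrees) and (iii) lateral (parallel-displacement) offset all within
# thresholds. Components of the molecule graph are classified as SINGLETON,
# PRIMARY (simple path), SECONDARY (branched: any degree >= 3) or CYCLIC.

# Centroid, unit normal (smallest principal axis) and max out-of-plane
# deviation of a ring's atoms.
ring_geometry <- function(coords, ring) {
  xyz <- coords[ring$atom_idx, , drop = FALSE]
  ctr <- colMeans(xyz)
  dev <- sweep(xyz, 2L, ctr)
  sv <- svd(dev)
  nrm <- sv$v[, 3]
  list(centroid = ctr, normal = nrm / sqrt(sum(nrm^2)),
       out_of_plane = max(abs(dev %*% nrm)))
}

#' Detect pi-stacking contacts between rings
#'
#' Evaluates every ring pair geometrically. The interplanar angle is
#' `acos(|n_i . n_j|)` (folded into \[0, 90\] degrees). The lateral offset is
#' the larger of the two parallel-displacement components: for each ring, the
#' centroid-centroid vector minus its projection on that ring's normal.
#' A parallel stacking contact requires centroid distance <= `max_dist`,
#' angle <= `max_angle`, and offset <= `max_offset` (defaults 4.5 A, 30 deg,
#' 2.0 A — standard parallel pi-stacking geometry). Optionally, T-shaped
#' (edge-to-face) contacts with angle inside `t_angle_window` and centroid
#' distance within `max_dist + 1.5` A are also reported (the offset criterion
#' does not apply to perpendicular geometry).
#'
#' @param x an [structure3d()] (rings taken from it) or an atoms x 3
#'   coordinate matrix in Angstrom.
#' @param rings list of [ring_spec()]; defaults to `x$rings`.
#' @param max_dist,max_angle,max_offset parallel-stacking thresholds
#'   (Angstrom, degrees, Angstrom).
#' @param t_shaped include T-shaped contacts (default FALSE).
#' @param t_angle_window angle window for T-shaped contacts, degrees.
#' @return data.frame with `ring_i`, `ring_j`, `molecule_i`, `molecule_j`,
#'   `centroid_distance`, `interplanar_angle`, `lateral_offset`, `type`.
#' @export
detect_stacking_contacts <- function(x, rings = NULL, max_dist = 4.5,
                                     max_angle = 30, max_offset = 2.0,
                                     t_shaped = FALSE, t_angle_window = c(60, 90)) {
  if (inherits(x, "fa_structure")) {
    coords <- x$coords
    rings <- rings %||% x$rings
  } else coords <- as.matrix(x)
  if (is.null(rings) || length(rings) == 0L)
    fa_stop("fa_validation_error", "no rings defined")
  for (r in rings) {
    if (!inherits(r, "fa_ring")) fa_stop("fa_validation_error", "rings must be ring_spec objects")
    if (any(r$atom_idx > nrow(coords)))
      fa_stop("fa_validation_error", "ring atoms missing from the frame")
  }
  geo <- lapply(rings, ring_geometry, coords = coords)
  nr <- length(rings)
  out <- list()
  for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
    d <- geo[[j]]$centroid - geo[[i]]$centroid
    dist <- sqrt(sum(d * d))
    if (dist > max_dist + 1.5) next
    cosang <- min(1, abs(sum(geo[[i]]$normal * geo[[j]]$normal)))
    ang <- acos(cosang) * 180 / pi
    off_i <- sqrt(max(0, sum(d * d) - sum(d * geo[[i]]$normal)^2))
    off_j <- sqrt(max(0, sum(d * d) - sum(d * geo[[j]]$normal)^2))
    off <- max(off_i, off_j)
    type <- NA_character_
    if (dist <= max_dist && ang <= max_angle && off <= max_offset) type <- "parallel"
    else if (t_shaped && ang >= t_angle_window[1] && ang <= t_angle_window[2] &&
             dist <= max_dist + 1.5) type <- "t_shaped"
    if (!is.na(type))
      out[[length(out) + 1L]] <- data.frame(
        ring_i = i, ring_j = j,
        molecule_i = rings[[i]]$molecule_id, molecule_j = rings[[j]]$molecule_id,
        centroid_distance = dist, interplanar_angle = ang,
        lateral_offset = off, type = type)
  }
  if (length(out) == 0L)
    return(data.frame(ring_i = integer(0), ring_j = integer(0),
                      molecule_i = character(0), molecule_j = character(0),
                      centroid_distance = numeric(0), interplanar_angle = numeric(0),
                      lateral_offset = numeric(0), type = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the topology of an assembly component
#'
#' @param g an [igraph] graph representing one connected component.
#' @return `"SINGLETON"` (one node), `"SECONDARY"` (any node of degree >= 3,
#'   i.e. branching), `"CYCLIC"` (a cycle with no branching), or `"PRIMARY"`
#'   (a simple path: acyclic, all degrees <= 2).
#' @export
classify_assembly <- function(g) {
  nv <- igraph::vcount(g)
  if (nv == 1L) return("SINGLETON")
  if (max(igraph::degree(g)) >= 3) return("SECONDARY")
  if (igraph::ecount(g) >= nv) return("CYCLIC")
  "PRIMARY"
}

#' Build the molecule-level assembly graph
#'
#' Collapses ring-level stacking contacts to one undirected molecule-level
#' edge per molecule pair (intramolecular contacts are dropped), computes
#' connected components, and classifies each with [classify_assembly()].
#'
#' @param contacts output of [detect_stacking_contacts()].
#' @param molecules character vector of all molecule ids (so molecules with
#'   no contacts appear as singletons); defaults to the ids present in
#'   `contacts`.
#' @return an object of class `fa_assembly`: list with `graph` (igraph),
#'   `membership` (component id per molecule) and `components` (data.frame
#'   `component`, `size`, `class`).
#' @export
build_assembly_graph <- function(contacts, molecules = NULL) {
  molecules <- as.character(molecules %||%
    sort(unique(c(contacts$molecule_i, contacts$molecule_j))))
  bad <- setdiff(c(contacts$molecule_i, contacts$molecule_j), molecules)
  if (length(bad))
    fa_stop("fa_validation_error", "contacts reference unknown molecule(s): %s",
            paste(unique(bad), collapse = ", "))
  edges <- unique(contacts[contacts$molecule_i != contacts$molecule_j,
                           c("molecule_i", "molecule_j")])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = molecules))
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  cls <- vapply(seq_len(comp$no), function(k) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == k))
    classify_assembly(sub)
  }, character(1))
  out <- list(graph = g,
              membership = stats::setNames(comp$membership, molecules),
              components = data.frame(component = seq_len(comp$no),
                                      size = as.integer(comp$csize),
                                      class = cls))
  class(out) <- "fa_assembly"
  out
}

#' @export
print.fa_assembly <- function(x, ...) {
  cat(sprintf("<fa_assembly> %d molecules, %d contacts, %d component(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              nrow(x$components)))
  print.data.frame(x$components)
  invisible(x)
}
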