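#' Construct a trajectory object
#'
#' The in-memory trajectory container: coordinates in nm as a
#' frames x atoms x 3 array, per-atom masses (amu), strictly increasing frame
#' times (ns), and per-atom tags (molecule id and chemical group).
#'
#' @param coords numeric array, frames x atoms x 3, nm; all finite.
#' @param masses per-atom masses, amu, positive.
#' @param times frame times in ns, strictly increasing.
#' @param tags data.frame with columns `molecule_id` and `group`; groups are
#'   free-form but `protein`, `flavonoid_core`, `glycoside` and `other` are the
#'   conventional values used by selections.
#' @return an object of class `fa_trajectory`.
#' @export
trajectory <- function(coords, masses, times, tags) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    fa_stop("fa_validation_error", "coords must be a frames x atoms x 3 array")
  if (!all(is.finite(coords)))
    fa_stop("fa_validation_error", "coordinates must be finite")
  n_atoms <- dim(coords)[2]
  if (length(masses) != n_atoms || any(masses <= 0))
    fa_stop("fa_validation_error", "masses must be positive, one per atom")
  if (length(times) != dim(coords)[1])
    fa_stop("fa_validation_error", "times must have one entry per frame")
  if (length(times) > 1 && is.unsorted(times, strictly = TRUE))
    fa_stop("fa_validation_error", "frame_times must be strictly increasing")
  tags <- as.data.frame(tags)
  if (!all(c("molecule_id", "group") %in% names(tags)) || nrow(tags) != n_atoms)
    fa_stop("fa_validation_error", "tags must have molecule_id and group for every atom")
  structure(list(coords = coords, masses = as.numeric(masses),
                 times = as.numeric(times), tags = tags),
            class = "fa_trajectory")
}

#' @export
print.fa_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<fa_trajectory> %d frames x %d atoms, t = %.3g..%.3g ns\n",
              d[1], d[2], x$times[1], x$times[d[1]]))
  cat("  groups:", paste(sprintf("%s (%d)", names(table(x$tags$group)),
                                 table(x$tags$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic self-assembly collapse trajectory
#'
#' Places `n_molecules` rigid molecules uniformly at random in the box
#' (rejection sampling against a minimum center separation, at most 10^4
#' attempts per molecule), then contracts the configuration: at frame time t
#' every mean molecule position has relaxed toward the ensemble centroid by
#' the factor `exp(-collapse_rate * t)`, and each frame adds fresh isotropic
#' Gaussian thermal jitter of sd `thermal_sd` about that mean (a stationary
#' fluctuation about the collapse path, not an accumulating walk). Atoms ride
#' rigidly on their molecule centers; all masses are 12 amu (carbon-like).
#' With `collapse_rate = 0` the series fluctuates with no systematic trend;
#' with a positive rate the ensemble radius of gyration contracts toward a
#' jitter-limited plateau, emulating self-assembly compaction.
#'
#' RNG stream (fixed for reproducibility): (1) placement draws, three uniforms
#' per attempt, molecules in order; (2) intramolecular offsets, one Gaussian
#' block; (3) per-frame jitter, one Gaussian block in frame-major order.
#'
#' @param spec a [collapse_traj_spec()].
#' @return an [trajectory()] object; molecule tags are `flavonoid_core`.
#' @export
gen_collapse_trajectory <- function(spec) {
  if (!inherits(spec, "fa_collapse_spec"))
    fa_stop("fa_validation_error", "spec must be created by collapse_traj_spec()")
  n_mol <- spec$n_molecules; apm <- spec$atoms_per_molecule
  n_atoms <- n_mol * apm
  with_seed(spec$seed, {
    centers <- matrix(NA_real_, n_mol, 3)
    for (m in seq_len(n_mol)) {
      placed <- FALSE
      for (try in seq_len(10000L)) {
        cand <- stats::runif(3, 0, spec$box_edge)
        if (m == 1L || all(sqrt(rowSums(sweep(centers[seq_len(m - 1L), , drop = FALSE],
                                              2L, cand)^2)) >= spec$min_separation)) {
          centers[m, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed)
        fa_stop("fa_placement_error",
                "could not place molecule %d without overlap (box too small?)", m)
    }
    offsets <- matrix(stats::rnorm(n_atoms * 3, 0, spec$atom_spread), n_atoms, 3)
    jitter <- array(stats::rnorm((spec$n_frames - 1L) * n_mol * 3, 0, spec$thermal_sd),
                    c(spec$n_frames - 1L, n_mol, 3))
    mol_of <- rep(seq_len(n_mol), each = apm)
    coords <- array(NA_real_, c(spec$n_frames, n_atoms, 3))
    centroid <- colMeans(centers)
    dev0 <- sweep(centers, 2L, centroid)
    for (f in seq_len(spec$n_frames)) {
      t_f <- (f - 1L) * spec$dt
      mean_pos <- sweep(dev0 * exp(-spec$collapse_rate * t_f), 2L, centroid, `+`)
      pos <- if (f == 1L) mean_pos else mean_pos + jitter[f - 1L, , ]
      coords[f, , ] <- pos[mol_of, ] + offsets
    }
    trajectory(coords, masses = rep(12, n_atoms),
               times = (seq_len(spec$n_frames) - 1L) * spec$dt,
               tags = data.frame(molecule_id = sprintf("M%03d", mol_of),
                                 group = "flavonoid_core"))
  })
}
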