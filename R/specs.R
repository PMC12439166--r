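# Specification objects for the synthetic-data generators. Each constructor
# validates its invariants and returns a classed list; generators accept only
# these objects so downstream errors name the offending field.

#' Specification for a synthetic inhibition screening panel
#'
#' Describes a compound x enzyme dose-response screen: true IC50s (molar; `NA`
#' entries mean the compound shows no true inhibition of that enzyme and reads
#' out at baseline), Hill slopes, Gaussian readout noise on the
#' percent-inhibition scale, the shared concentration series, and the number of
#' technical replicates.
#'
#' @param true_ic50 numeric matrix (compounds x enzymes) of true IC50s in molar,
#'   with dimnames; `NA` marks an absent effect.
#' @param hill Hill slope, a scalar or a matrix conformable with `true_ic50`.
#' @param noise_sd standard deviation of the additive Gaussian readout noise,
#'   in percent-inhibition units. Responses are deliberately not clipped to
#'   \[0, 100\]: real assay readouts can exceed those bounds.
#' @param concentrations assayed concentrations in molar, strictly increasing.
#'   Default: 10 points log-spaced over 5 nM to 100 uM.
#' @param n_replicates technical replicates per concentration.
#' @param seed integer root seed for the generator.
#' @return an object of class `fa_panel_spec`.
#' @seealso [gen_inhibition_panel()], [default_panel_spec()]
#' @export
panel_spec <- function(true_ic50, hill = 1, noise_sd = 5,
                       concentrations = 10^seq(log10(5e-9), log10(1e-4), length.out = 10),
                       n_replicates = 2, seed = 1L) {
  true_ic50 <- as.matrix(true_ic50)
  check_field(!is.null(rownames(true_ic50)) && !is.null(colnames(true_ic50)),
              "true_ic50", "must have compound rownames and enzyme colnames")
  check_field(all(is.na(true_ic50) | true_ic50 > 0), "true_ic50",
              "entries must be positive molar values or NA (absent)")
  if (length(hill) == 1L) hill <- matrix(hill, nrow(true_ic50), ncol(true_ic50),
                                         dimnames = dimnames(true_ic50))
  hill <- as.matrix(hill)
  check_field(all(dim(hill) == dim(true_ic50)), "hill", "must be scalar or conformable with true_ic50")
  check_field(all(hill > 0), "hill", "slopes must be positive")
  check_field(is.numeric(noise_sd) && length(noise_sd) == 1L && noise_sd >= 0,
              "noise_sd", "must be a single value >= 0")
  check_field(all(concentrations > 0) && !is.unsorted(concentrations, strictly = TRUE),
              "concentrations", "must be positive and strictly increasing")
  check_field(length(concentrations) >= 1L, "concentrations", "must be non-empty")
  check_field(n_replicates >= 1, "n_replicates", "must be >= 1")
  structure(list(true_ic50 = true_ic50, hill = hill, noise_sd = noise_sd,
                 concentrations = as.numeric(concentrations),
                 n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
            class = "fa_panel_spec")
}

#' Default study-design screening panel
#'
#' A 58-compound x 7-enzyme panel (the enzymes: ARG1, KDM4C, Lysozyme, MARK4,
#' NSD2, PTP1B, SIRT3), measured at 10 concentrations spanning 5 nM to 100 uM
#' with two technical replicates. The composition of the true-IC50 matrix
#' matches the screen's reported fit-category split: of the 406 pairs, 106
#' (26.1%) have an IC50 inside the assayed range, 49 (12.1%) have an IC50 just
#' above it (so the 50% crossing must be extrapolated), and 251 (61.8%) show no
#' inhibition (baseline readouts). In-range truths are drawn log-uniformly over
#' 2e-8 to 3e-5 M; above-range truths over 1.5e-4 to 2.5e-4 M, a window in
#' which a unit-slope curve still rises visibly above baseline within the
#' assayed range.
#'
#' @param seed integer seed controlling which pairs fall in which category and
#'   their true IC50s.
#' @param noise_sd readout noise (percent); the generator's own default, 5, is
#'   a typical biochemical-assay scale.
#' @param n_compounds,n_replicates panel dimensions, defaulting to the study
#'   design.
#' @return an `fa_panel_spec`.
#' @export
default_panel_spec <- function(seed = 1L, noise_sd = 5, n_compounds = 58L, n_replicates = 2L) {
  enzymes <- c("ARG1", "KDM4C", "Lysozyme", "MARK4", "NSD2", "PTP1B", "SIRT3")
  compounds <- sprintf("FLV%02d", seq_len(n_compounds))
  n_pair <- n_compounds * length(enzymes)
  counts <- round(n_pair * c(in_range = 106, extrapolated = 49, absent = 251) / 406)
  counts["absent"] <- n_pair - counts["in_range"] - counts["extrapolated"]
  truth <- with_seed(seed, {
    status <- sample(rep(names(counts), counts))
    u <- stats::runif(n_pair)
    ic <- rep(NA_real_, n_pair)
    ic[status == "in_range"] <- 10^(log10(2e-8) +
      u[status == "in_range"] * (log10(3e-5) - log10(2e-8)))
    ic[status == "extrapolated"] <- 10^(log10(1.5e-4) +
      u[status == "extrapolated"] * (log10(2.5e-4) - log10(1.5e-4)))
    matrix(ic, n_compounds, length(enzymes), dimnames = list(compounds, enzymes))
  })
  panel_spec(truth, hill = 1, noise_sd = noise_sd, n_replicates = n_replicates,
             seed = seed)
}

#' Specification for a synthetic self-assembly collapse trajectory
#'
#' Rigid molecules placed uniformly at random in a cubic box whose centers
#' drift toward the ensemble centroid (rate `collapse_rate`) under Gaussian
#' thermal jitter, emulating the compaction that accompanies supramolecular
#' self-assembly. With the defaults (10 molecules in a 3 nm box) the initial
#' ensemble radius of gyration is about 1.5 nm, the typical pre-assembly
#' starting point.
#'
#' @param n_molecules number of rigid molecules.
#' @param atoms_per_molecule atoms per molecule (rigid about the center).
#' @param box_edge cubic box edge, nm.
#' @param collapse_rate drift rate toward the ensemble centroid, 1/ns; 0 gives
#'   pure jitter with no systematic compaction.
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing, ns.
#' @param thermal_sd per-frame Gaussian jitter of molecule centers, nm.
#' @param min_separation minimum center-center distance at placement, nm.
#' @param atom_spread sd of the fixed intramolecular atom offsets, nm.
#' @param seed integer root seed.
#' @return an object of class `fa_collapse_spec`.
#' @seealso [gen_collapse_trajectory()]
#' @export
collapse_traj_spec <- function(n_molecules = 10L, atoms_per_molecule = 5L,
                               box_edge = 3, collapse_rate = 0.2, n_frames = 200L,
                               dt = 0.1, thermal_sd = 0.02, min_separation = 0.2,
                               atom_spread = 0.05, seed = 1L) {
  check_field(n_molecules >= 1, "n_molecules", "must be >= 1")
  check_field(atoms_per_molecule >= 1, "atoms_per_molecule", "must be >= 1")
  check_field(box_edge > 0, "box_edge", "must be > 0")
  check_field(collapse_rate >= 0, "collapse_rate", "must be >= 0")
  check_field(n_frames >= 2, "n_frames", "must be >= 2")
  check_field(dt > 0, "dt", "must be > 0")
  check_field(thermal_sd >= 0, "thermal_sd", "must be >= 0")
  check_field(min_separation >= 0, "min_separation", "must be >= 0")
  structure(list(n_molecules = as.integer(n_molecules),
                 atoms_per_molecule = as.integer(atoms_per_molecule),
                 box_edge = box_edge, collapse_rate = collapse_rate,
                 n_frames = as.integer(n_frames), dt = dt,
                 thermal_sd = thermal_sd, min_separation = min_separation,
                 atom_spread = atom_spread, seed = as.integer(seed)),
            class = "fa_collapse_spec")
}

#' Specification for an idealised pi-stacked ring fiber
#'
#' A linear stack of planar hexagonal rings (unit masses) with a fixed rise
#' between consecutive ring centroids and an in-plane twist per unit — the
#' primary fiber structure. Branch points spawn tilted sub-stacks growing away
#' from the main axis, producing the branched secondary structure. Optionally
#' each ring carries an off-ring "glycoside" atom cluster positioned radially
#' outward, mimicking the sugar backbone of glycosylated flavonoids.
#'
#' @param n_units rings in the main stack (>= 1).
#' @param rise distance between consecutive ring centroids, Angstrom.
#' @param twist in-plane rotation per unit, degrees.
#' @param branch_points list of `c(unit, length)` pairs: a sub-stack of
#'   `length` rings attached at main-stack ring `unit`.
#' @param with_glycoside add a 5-atom off-ring cluster per ring.
#' @return an object of class `fa_fiber_spec`.
#' @seealso [gen_ring_fiber()]
#' @export
fiber_spec <- function(n_units, rise = 3.5, twist = 30, branch_points = list(),
                       with_glycoside = FALSE) {
  check_field(n_units >= 1, "n_units", "must be >= 1")
  check_field(rise > 0, "rise", "must be > 0")
  if (length(branch_points) && !is.list(branch_points)) branch_points <- list(branch_points)
  for (bp in branch_points) {
    check_field(length(bp) == 2L, "branch_points", "each entry must be c(unit, length)")
    check_field(bp[1] >= 1 && bp[1] <= n_units, "branch_points",
                sprintf("branch unit %d outside [1, %d]", bp[1], n_units))
    check_field(bp[2] >= 1, "branch_points", "branch length must be >= 1")
  }
  structure(list(n_units = as.integer(n_units), rise = rise, twist = twist,
                 branch_points = lapply(branch_points, as.integer),
                 with_glycoside = isTRUE(with_glycoside)),
            class = "fa_fiber_spec")
}

#' Specification for the double-well toy propagator
#'
#' Overdamped Langevin dynamics on the quartic double well
#' \eqn{U(x) = B ((x/a)^2 - 1)^2}, with barrier height `B` (in kT units when
#' `kT = 1`) and minima at \eqn{x = \pm a}. Serves as the desk-scale dynamics
#' driving the weighted-ensemble engine.
#'
#' @param barrier barrier height, energy units of `kT`.
#' @param well_half_separation `a`, position of the minima.
#' @param diffusion diffusion coefficient, units^2/time.
#' @param dt Euler-Maruyama time step.
#' @param kT thermal energy scale.
#' @param seed integer seed used when the propagator is run standalone.
#' @return an object of class `fa_doublewell_spec`.
#' @seealso [make_double_well_propagator()]
#' @export
double_well_spec <- function(barrier = 3, well_half_separation = 1, diffusion = 1,
                             dt = 1e-3, kT = 1, seed = 1L) {
  check_field(barrier >= 0, "barrier", "must be >= 0")
  check_field(well_half_separation > 0, "well_half_separation", "must be > 0")
  check_field(diffusion > 0, "diffusion", "must be > 0")
  check_field(dt > 0, "dt", "must be > 0")
  check_field(kT > 0, "kT", "must be > 0")
  structure(list(barrier = barrier, well_half_separation = well_half_separation,
                 diffusion = diffusion, dt = dt, kT = kT, seed = as.integer(seed)),
            class = "fa_doublewell_spec")
}
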