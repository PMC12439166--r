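#' Generate a synthetic inhibition screening table
#'
#' Evaluates the four-parameter logistic curve (bottom 0, top 100) implied by
#' each pair's true IC50 and Hill slope at every assayed concentration, and
#' adds zero-mean Gaussian readout noise of sd `noise_sd`. Pairs whose true
#' IC50 is absent (`NA`) read out at baseline: noise around 0%.
#'
#' Reproducibility: the generator seeds a private RNG stream from
#' `spec$seed` and draws a single Gaussian vector in table row order
#' (compounds outermost, then enzymes, then concentrations, then replicates),
#' so output is bit-identical across calls and releases for a fixed spec.
#'
#' @param spec an [panel_spec()] object.
#' @return a data.frame of class `fa_inhibition_table` with columns
#'   `compound_id`, `enzyme_id`, `concentration` (molar), `replicate`,
#'   `percent_inhibition`.
#' @examples
#' spec <- panel_spec(matrix(1e-6, 1, 1, dimnames = list("A", "E1")), noise_sd = 0)
#' gen_inhibition_panel(spec)
#' @export
gen_inhibition_panel <- function(spec) {
  if (!inherits(spec, "fa_panel_spec"))
    fa_stop("fa_validation_error", "spec must be created by panel_spec()")
  compounds <- rownames(spec$true_ic50)
  enzymes <- colnames(spec$true_ic50)
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      concentration = spec$concentrations,
                      enzyme_id = enzymes, compound_id = compounds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("compound_id", "enzyme_id", "concentration", "replicate")]
  ic <- spec$true_ic50[cbind(grid$compound_id, grid$enzyme_id)]
  hl <- spec$hill[cbind(grid$compound_id, grid$enzyme_id)]
  mu <- ifelse(is.na(ic), 0,
               logistic4(log10(grid$concentration), 0, 100, hl, log10(ic)))
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, stats::rnorm(nrow(grid), 0, spec$noise_sd))
  else 0
  grid$percent_inhibition <- mu + noise
  rownames(grid) <- NULL
  class(grid) <- c("fa_inhibition_table", "data.frame")
  attr(grid, "true_ic50") <- spec$true_ic50
  grid
}
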