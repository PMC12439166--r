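# Weighted Z-score efficacy ranking across an enzyme panel. For each enzyme,
# compounds with a successful IC50 readout are standardised on the log10 IC50
# scale; compounds with no readout are imputed z = 2 (worse than one sd above
# the panel mean, so unmeasurable/very weak inhibitors still rank). Per
# compound the z-scores are combined as a readout-count-weighted mean divided
# by the panel size, and compounds are ranked ascending (low score = high
# efficacy).

#' Per-enzyme Z-scores of log10 IC50
#'
#' For one enzyme, standardises each successful readout as
#' \eqn{z_i = (\log_{10} IC50_i - \bar X) / s} where \eqn{\bar X} and \eqn{s}
#' are the mean and standard deviation of all successful log10 IC50s for that
#' enzyme; compounds without a readout (`NA`) receive the imputed value
#' `impute_z` and are flagged.
#'
#' @param log10_ic50 named numeric vector of log10 IC50 (molar) per compound;
#'   `NA` = no readout.
#' @param impute_z z assigned to missing readouts (default 2).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param enzyme_id optional label carried into the result.
#' @return list with `enzyme_id`, `mean_log_ic50`, `sd_log_ic50`, `n_success`,
#'   `z` (named, imputations included) and logical `imputed`.
#' @examples
#' enzyme_zscores(c(A = -6, B = -5, C = -4, D = NA))$z  # -1, 0, 1, 2
#' @export
enzyme_zscores <- function(log10_ic50, impute_z = 2, sd_type = c("sample", "population"),
                           enzyme_id = NA_character_) {
  sd_type <- match.arg(sd_type)
  ok <- is.finite(log10_ic50)
  n <- sum(ok)
  if (n < 2L)
    fa_stop("fa_degenerate_scale",
            "enzyme %s has %d successful readouts; need >= 2 to define a scale",
            enzyme_id, n)
  xbar <- mean(log10_ic50[ok])
  s <- stats::sd(log10_ic50[ok])
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (s == 0)
    fa_stop("fa_degenerate_scale", "enzyme %s has zero spread in log10 IC50", enzyme_id)
  z <- (log10_ic50 - xbar) / s
  z[!ok] <- impute_z
  list(enzyme_id = enzyme_id, mean_log_ic50 = xbar, sd_log_ic50 = s,
       n_success = n, z = z, imputed = !ok)
}

#' Readout-count weights over the enzyme panel
#'
#' \eqn{w_i = N_i / \sum_i N_i} with \eqn{N_i} the number of successful
#' readouts for enzyme i.
#'
#' @param n_success named integer vector of successful readouts per enzyme.
#' @return named weights summing to 1.
#' @export
compute_weights <- function(n_success) {
  if (sum(n_success) <= 0)
    fa_stop("fa_validation_error", "all enzymes have zero successful readouts")
  n_success / sum(n_success)
}

#' Weighted mean z-score of a compound
#'
#' \eqn{\bar z = (\sum_i w_i z_i) / n_{panel}}. The division by the panel size
#' (7 in the study design) is applied on top of the already-normalised
#' weights, exactly as the ranking procedure defines it; it is a
#' rank-preserving constant rescaling.
#'
#' @param z named z-scores per enzyme (imputations included).
#' @param w named weights per enzyme (see [compute_weights()]).
#' @param panel_size the panel-size constant (default `length(w)`).
#' @return scalar weighted score.
#' @export
compound_score <- function(z, w, panel_size = length(w)) {
  if (!is.null(names(z)) && !is.null(names(w))) {
    if (!setequal(names(z), names(w)))
      fa_stop("fa_validation_error", "z and w cover different enzyme sets")
    w <- w[names(z)]
  } else if (length(z) != length(w)) {
    fa_stop("fa_validation_error", "z and w must align over the same enzymes")
  }
  sum(w * z) / panel_size
}

#' Rank compounds by weighted Z-score efficacy
#'
#' Runs the full ranking over a table of dose-response fits: successful
#' readouts (categories IN_RANGE and, by default, EXTRAPOLATED with a finite
#' extrapolated IC50) are standardised per enzyme with [enzyme_zscores()],
#' missing readouts are imputed `z = impute_z`, weights follow
#' [compute_weights()], and per-compound scores are weighted means divided by
#' `panel_size`. Compounds screened repeatedly (a `repeat_id` column) are
#' scored per repeat and their scores averaged. Ranking is ascending in the
#' score — low scores mean potent, broad inhibition; ties are broken
#' lexicographically by compound id and flagged.
#'
#' Enzymes with fewer than two successful readouts define no z-scale and are
#' dropped from the panel (with a warning) before scoring.
#'
#' @param fits an `fa_drfits` data.frame (needs `compound_id`, `enzyme_id`,
#'   `log10_ic50`, `category`; optional `repeat_id`).
#' @param panel_size the constant divisor; default the number of distinct
#'   enzymes in `fits`.
#' @param impute_z imputed z for missing readouts.
#' @param include_extrapolated count finite extrapolated IC50s as successful
#'   readouts (default TRUE); if FALSE only IN_RANGE fits enter.
#' @param sd_type passed to [enzyme_zscores()].
#' @return an object of class `fa_ranking`: a data.frame with `compound_id`,
#'   `zbar`, `rank`, `n_repeats_averaged`, `tied`; per-enzyme `z`, `imputed`,
#'   `weights`, `n_success` and `panel_size` are attached as attributes.
#' @export
rank_compounds <- function(fits, panel_size = NULL, impute_z = 2,
                           include_extrapolated = TRUE,
                           sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.null(fits) || nrow(fits) == 0L)
    fa_stop("fa_validation_error", "empty panel: no fits to rank")
  enzymes <- sort(unique(fits$enzyme_id))
  panel_size <- panel_size %||% length(enzymes)
  rep_id <- fits$repeat_id %||% rep(1L, nrow(fits))
  unit <- paste(fits$compound_id, rep_id, sep = "\r")
  units <- unique(unit)
  ok <- fits$category == "IN_RANGE" |
    (include_extrapolated & fits$category == "EXTRAPOLATED" & is.finite(fits$log10_ic50))
  mat <- matrix(NA_real_, length(units), length(enzymes),
                dimnames = list(units, enzymes))
  mat[cbind(match(unit[ok], units), match(fits$enzyme_id[ok], enzymes))] <-
    fits$log10_ic50[ok]
  n_success <- colSums(is.finite(mat))
  usable <- n_success >= 2L
  if (!any(usable))
    fa_stop("fa_degenerate_scale", "no enzyme has >= 2 successful readouts")
  if (!all(usable))
    warning(sprintf("dropping enzyme(s) with < 2 successful readouts: %s",
                    paste(enzymes[!usable], collapse = ", ")), call. = FALSE)
  mat <- mat[, usable, drop = FALSE]
  zs <- lapply(colnames(mat), function(e)
    enzyme_zscores(mat[, e], impute_z, sd_type, enzyme_id = e))
  zmat <- do.call(cbind, lapply(zs, `[[`, "z"))
  imput <- do.call(cbind, lapply(zs, `[[`, "imputed"))
  unit_labels <- sub("\r.*$", "", units)
  if (anyDuplicated(unit_labels))
    unit_labels <- sub("\r", "#", units, fixed = TRUE)
  dimnames(zmat) <- dimnames(imput) <- list(unit_labels, colnames(mat))
  w <- compute_weights(vapply(zs, `[[`, numeric(1), "n_success"))
  names(w) <- colnames(mat)
  zbar_unit <- as.vector(zmat %*% w) / panel_size
  comp_of_unit <- sub("\r.*$", "", units)
  zbar <- tapply(zbar_unit, comp_of_unit, mean)
  n_rep <- tapply(zbar_unit, comp_of_unit, length)
  ord <- order(zbar, names(zbar))
  out <- data.frame(compound_id = names(zbar)[ord],
                    zbar = as.numeric(zbar[ord]),
                    rank = seq_along(ord),
                    n_repeats_averaged = as.integer(n_rep[ord]),
                    tied = duplicated(zbar[ord]) | duplicated(zbar[ord], fromLast = TRUE))
  rownames(out) <- NULL
  class(out) <- c("fa_ranking", "data.frame")
  attr(out, "z") <- zmat
  attr(out, "imputed") <- imput
  attr(out, "weights") <- w
  attr(out, "n_success") <- n_success[usable]
  attr(out, "panel_size") <- panel_size
  out
}

#' @export
print.fa_ranking <- function(x, ...) {
  cat(sprintf("<fa_ranking> %d compounds over %d enzymes (panel size %d)\n",
              nrow(x), length(attr(x, "weights")), attr(x, "panel_size")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
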