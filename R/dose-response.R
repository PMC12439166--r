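# Sigmoidal dose-response fitting for an inhibition screen: bounded
# four-parameter logistic least squares on the log10-concentration axis, IC50
# read off at the 50% inhibition crossing, and a deterministic three-way fit
# categorisation replacing manual curve review.

# top's lower bound sits below the baseline threshold on purpose: series with
# no real signal must be free to fit a near-flat curve (plateau < threshold)
# instead of being forced to place a >= 30% rise somewhere inside the range.
.fa_default_bounds <- list(lower = c(bottom = -20, top = 5, hill = 0.2, logx0 = -12),
                           upper = c(bottom = 30, top = 120, hill = 5, logx0 = 0))

#' Categorise a fitted dose-response curve
#'
#' Given 4PL parameters, locates the 50%-inhibition crossing of the fitted
#' curve and assigns one of the screen's three fit categories:
#' \describe{
#'   \item{IN_RANGE}{the crossing lies at or below the top of the assayed
#'     range (`assay_range[2]`); the IC50 is the crossing concentration.}
#'   \item{EXTRAPOLATED}{the fitted curve rises clearly above baseline inside
#'     the assayed range but only crosses 50% beyond its upper end; the IC50 is
#'     the extrapolated crossing (or `Inf` when the fitted top never reaches
#'     50%).}
#'   \item{BASELINE}{the fitted maximum response within the assayed range
#'     stays below `baseline_threshold`, or the fit failed; no IC50.}
#' }
#'
#' @param pars named list or vector with `bottom`, `top`, `hill`, `logx0`
#'   (inflection, log10 molar); `NULL` or `fit_failed = TRUE` means the
#'   optimiser did not converge.
#' @param assay_range c(min, max) assayed concentrations, molar.
#' @param baseline_threshold percent inhibition below which a fitted plateau
#'   counts as baseline (default 25).
#' @param fit_failed logical optimiser-failure flag.
#' @return list with `category` (one of `"IN_RANGE"`, `"EXTRAPOLATED"`,
#'   `"BASELINE"`), `ic50` (molar; `NA` for baseline, may be `Inf`), and
#'   `log10_ic50`.
#' @export
categorize_fit <- function(pars, assay_range, baseline_threshold = 25,
                           fit_failed = FALSE) {
  if (isTRUE(fit_failed) || is.null(pars))
    return(list(category = "BASELINE", ic50 = NA_real_, log10_ic50 = NA_real_))
  pars <- as.list(pars)
  max_resp <- logistic4(log10(assay_range[2]), pars$bottom, pars$top,
                        pars$hill, pars$logx0)
  if (max_resp < baseline_threshold)
    return(list(category = "BASELINE", ic50 = NA_real_, log10_ic50 = NA_real_))
  if (pars$top > 50 && pars$bottom < 50) {
    x50 <- pars$logx0 - log10((pars$top - 50) / (50 - pars$bottom)) / pars$hill
    ic50 <- 10^x50
    cat <- if (ic50 > assay_range[2]) "EXTRAPOLATED" else "IN_RANGE"
    return(list(category = cat, ic50 = ic50, log10_ic50 = x50))
  }
  # plateau above threshold but the curve never reaches 50% anywhere
  list(category = "EXTRAPOLATED", ic50 = Inf, log10_ic50 = Inf)
}

#' Fit a four-parameter logistic inhibition curve
#'
#' Least-squares 4PL fit of percent inhibition against log10(concentration in
#' M) for one compound x enzyme series, via bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM]). Replicates enter the loss jointly (not averaged
#' first). The IC50 is the concentration where the fitted curve crosses 50%
#' inhibition, and the fit is categorised by [categorize_fit()].
#'
#' Parameter bounds: bottom in \[-20, 30\]%, top in \[30, 120\]%, Hill slope in
#' \[0.2, 5\]. Starting values are bottom 0, top 100, hill 1, and inflection at
#' the concentration whose mean response is nearest 50%; on non-convergence
#' three preset alternative starts are tried before the series is declared a
#' failed fit (category BASELINE with `fit_failed = TRUE`).
#'
#' @param series data.frame with columns `concentration` (molar) and
#'   `percent_inhibition` (replicate rows allowed), or a list/data.frame
#'   carrying those columns.
#' @param assay_range c(min, max) assayed concentrations; defaults to the
#'   range of `series$concentration`.
#' @param baseline_threshold see [categorize_fit()].
#' @param compound_id,enzyme_id identifiers carried into the result.
#' @return an object of class `fa_drfit`: a list with the fitted `bottom`,
#'   `top`, `hill`, `logx0`, the crossing `log10_ic50` and `ic50`, `category`,
#'   `rmse`, `n_points`, and `fit_failed`.
#' @examples
#' conc <- 10^seq(-8.3, -4, length.out = 10)
#' y <- logistic4(log10(conc), 0, 100, 1, -6)
#' fit <- fit_dose_response(data.frame(concentration = conc, percent_inhibition = y))
#' fit$ic50          # ~1e-6
#' fit$category      # "IN_RANGE"
#' @export
fit_dose_response <- function(series, assay_range = NULL, baseline_threshold = 25,
                              compound_id = NA_character_, enzyme_id = NA_character_) {
  conc <- series$concentration
  y <- series$percent_inhibition
  if (is.null(conc) || is.null(y))
    fa_stop("fa_schema_error", "series must have 'concentration' and 'percent_inhibition'")
  if (length(unique(conc)) < 4L)
    fa_stop("fa_insufficient_data",
            "need >= 4 distinct concentrations, got %d", length(unique(conc)))
  assay_range <- assay_range %||% range(conc)
  x <- log10(conc)
  mean_by_x <- tapply(y, x, mean)
  start0 <- as.numeric(names(mean_by_x))[which.min(abs(mean_by_x - 50))]
  starts <- list(c(bottom = 0, top = 100, hill = 1, logx0 = start0),
                 c(bottom = 0, top = 100, hill = 0.5, logx0 = start0 + 1),
                 c(bottom = 0, top = 100, hill = 2, logx0 = start0 - 1),
                 c(bottom = 10, top = 80, hill = 1, logx0 = mean(log10(assay_range))))
  dat <- data.frame(x = x, y = y)
  fit <- NULL; best_rmse <- Inf
  for (st in starts) {
    st <- pmin(pmax(st, .fa_default_bounds$lower), .fa_default_bounds$upper)
    cand <- tryCatch(
      minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + 10^(hill * (logx0 - x))),
                        data = dat, start = as.list(st),
                        lower = .fa_default_bounds$lower,
                        upper = .fa_default_bounds$upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(cand)) {
      r <- sqrt(mean(stats::resid(cand)^2))
      if (r < best_rmse) { fit <- cand; best_rmse <- r }
      if (best_rmse < 1e-6) break   # essentially exact; no better start exists
    }
  }
  if (is.null(fit)) {
    out <- list(compound_id = compound_id, enzyme_id = enzyme_id,
                bottom = NA_real_, top = NA_real_, hill = NA_real_, logx0 = NA_real_,
                log10_ic50 = NA_real_, ic50 = NA_real_, category = "BASELINE",
                rmse = NA_real_, n_points = length(y), fit_failed = TRUE,
                assay_range = assay_range)
    class(out) <- "fa_drfit"
    return(out)
  }
  pars <- as.list(stats::coef(fit))
  cl <- categorize_fit(pars, assay_range, baseline_threshold)
  out <- c(list(compound_id = compound_id, enzyme_id = enzyme_id), pars,
           list(log10_ic50 = cl$log10_ic50, ic50 = cl$ic50, category = cl$category,
                rmse = sqrt(mean(stats::resid(fit)^2)), n_points = length(y),
                fit_failed = FALSE, assay_range = assay_range))
  class(out) <- "fa_drfit"
  out
}

#' @export
print.fa_drfit <- function(x, ...) {
  cat(sprintf("<fa_drfit> %s x %s: %s", x$compound_id, x$enzyme_id, x$category))
  if (!is.na(x$ic50)) cat(sprintf(", IC50 = %.3g M", x$ic50))
  cat(sprintf(" (rmse %.2f%%, n = %d)\n", x$rmse, x$n_points))
  invisible(x)
}

#' Fit every compound x enzyme series of an inhibition table
#'
#' @param tbl an inhibition table (see [read_inhibition_table()] or
#'   [gen_inhibition_panel()]).
#' @param assay_range defaults to the range of concentrations in `tbl`.
#' @inheritParams fit_dose_response
#' @return a data.frame of class `fa_drfits`, one row per pair, with the
#'   fitted parameters, `log10_ic50`, `ic50`, `category`, `rmse`, `n_points`
#'   and `fit_failed`.
#' @export
fit_panel <- function(tbl, assay_range = NULL, baseline_threshold = 25) {
  assay_range <- assay_range %||% range(tbl$concentration)
  keys <- unique(tbl[, c("compound_id", "enzyme_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tbl[tbl$compound_id == keys$compound_id[i] &
               tbl$enzyme_id == keys$enzyme_id[i], ]
    f <- fit_dose_response(sub, assay_range, baseline_threshold,
                           keys$compound_id[i], keys$enzyme_id[i])
    data.frame(compound_id = f$compound_id, enzyme_id = f$enzyme_id,
               bottom = f$bottom, top = f$top, hill = f$hill,
               log10_ic50 = f$log10_ic50, ic50 = f$ic50, category = f$category,
               rmse = f$rmse, n_points = f$n_points, fit_failed = f$fit_failed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fa_drfits", "data.frame")
  attr(out, "assay_range") <- assay_range
  out
}

#' Fraction of fits per category
#'
#' @param fits an `fa_drfits` data.frame (or anything with a `category`
#'   column/field).
#' @return named numeric percentages over `IN_RANGE`, `EXTRAPOLATED`,
#'   `BASELINE`, summing to 100 within rounding.
#' @export
summarize_categories <- function(fits) {
  cats <- if (is.data.frame(fits)) fits$category else
    vapply(fits, function(f) f$category, character(1))
  if (length(cats) == 0L) fa_stop("fa_validation_error", "no fits to summarise")
  lv <- c("IN_RANGE", "EXTRAPOLATED", "BASELINE")
  out <- 100 * as.vector(table(factor(cats, levels = lv))) / length(cats)
  names(out) <- lv
  out
}
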