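# Radius-of-gyration time series over trajectories, windowed distribution
# summaries, and variance-heterogeneity testing across pooled replicate
# windows (Levene / Brown-Forsythe).

# Resolve a selection against trajectory tags: NULL = all atoms, an
# integer/logical index, or a list(group =, molecule_id =) tag filter.
resolve_selection <- function(traj, selection) {
  n <- dim(traj$coords)[2]
  if (is.null(selection)) return(seq_len(n))
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) return(as.integer(selection))
  keep <- rep(TRUE, n)
  if (!is.null(selection$group)) keep <- keep & traj$tags$group %in% selection$group
  if (!is.null(selection$molecule_id))
    keep <- keep & traj$tags$molecule_id %in% selection$molecule_id
  which(keep)
}

#' Radius-of-gyration time series of a trajectory
#'
#' Per frame, \eqn{R_g = \sqrt{\sum_k m_k |r_k - \bar r|^2 / \sum_k m_k}} over
#' the selected atoms, with \eqn{\bar r} the mass-weighted centroid.
#' Mass weighting is the default (the convention of standard
#' trajectory-analysis tooling); `mass_weighted = FALSE` uses unit masses.
#'
#' @param traj an [trajectory()].
#' @param selection `NULL` for all atoms, an atom index vector, or a
#'   `list(group =, molecule_id =)` tag filter (e.g.
#'   `list(group = "protein")`).
#' @param mass_weighted logical.
#' @return a data.frame of class `fa_rgyr` with columns `time_ns`, `rgyr_nm`.
#' @export
radius_of_gyration <- function(traj, selection = NULL, mass_weighted = TRUE) {
  idx <- resolve_selection(traj, selection)
  if (length(idx) == 0L) fa_stop("fa_validation_error", "selection matches no atoms")
  m <- if (mass_weighted) traj$masses[idx] else rep(1, length(idx))
  w <- m / sum(m)
  vals <- vapply(seq_len(dim(traj$coords)[1]), function(f) {
    xyz <- traj$coords[f, idx, , drop = FALSE]
    dim(xyz) <- c(length(idx), 3L)
    ctr <- colSums(xyz * w)
    dev <- sweep(xyz, 2L, ctr)
    sqrt(sum(w * rowSums(dev * dev)))
  }, numeric(1))
  out <- data.frame(time_ns = traj$times, rgyr_nm = vals)
  class(out) <- c("fa_rgyr", "data.frame")
  attr(out, "selection") <- selection
  attr(out, "mass_weighted") <- mass_weighted
  out
}

#' Values of a series inside a time window
#'
#' Window bounds are inclusive on both ends, times in ns.
#'
#' @param series an `fa_rgyr` data.frame (or any with `time_ns` and a value
#'   column as the second column).
#' @param window c(t0, t1) in ns.
#' @return numeric vector of the windowed values.
#' @export
window_values <- function(series, window) {
  keep <- series$time_ns >= window[1] & series$time_ns <= window[2]
  if (!any(keep))
    fa_stop("fa_validation_error", "window [%g, %g] contains no frames",
            window[1], window[2])
  series[[2]][keep]
}

#' Quartile summary of a windowed series
#'
#' @inheritParams window_values
#' @param window c(t0, t1) ns; default the full series.
#' @return list with `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
distribution_summary <- function(series, window = range(series$time_ns)) {
  v <- window_values(series, window)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(v), min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v))
}

#' Levene / Brown-Forsythe variance-homogeneity test
#'
#' Tests equality of variances across two or more groups of pooled values
#' (e.g. the radius-of-gyration samples of duplicate simulations over the
#' equilibrated window, concatenated per condition). The statistic is the
#' one-way ANOVA F on absolute deviations from the group center: the mean
#' (Levene's original test, the default) or the median (the Brown-Forsythe
#' variant, more robust to heavy tails).
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @param center `"mean"` or `"median"`.
#' @return list with `levene_W`, `p_value`, `df` (c(k-1, N-k)), `n` per group,
#'   `center`, `group_labels`. Identical (or zero-deviation) groups give
#'   `W = 0`, `p = 1`.
#' @examples
#' variance_comparison(list(ctrl = rnorm(50), flav = rnorm(50, sd = 2)))
#' @export
variance_comparison <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(groups) < 2L) fa_stop("fa_validation_error", "need >= 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) fa_stop("fa_validation_error", "every group needs n >= 2")
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, n), levels = labels)
  res <- car::leveneTest(y, g, center = if (center == "mean") mean else stats::median)
  W <- res$`F value`[1]
  p <- res$`Pr(>F)`[1]
  if (!is.finite(W)) { W <- 0; p <- 1 }   # zero within-group deviation spread
  list(levene_W = W, p_value = p, df = c(res$Df[1], res$Df[2]),
       n = stats::setNames(as.integer(n), labels), center = center,
       group_labels = labels)
}
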