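# Internal helpers: condition constructors, seeded evaluation, shared numerics.

fa_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "fa_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' @noRd
check_field <- function(ok, field, what) {
  if (!isTRUE(ok)) fa_stop("fa_validation_error", "invalid spec field '%s': %s", field, what)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Four-parameter logistic response
#'
#' Percent response of the 4PL model on the log10-concentration axis,
#' \code{bottom + (top - bottom) / (1 + 10^(hill * (logx0 - x)))}, where
#' \code{logx0} is the inflection point (log10 molar) and \code{x} is
#' log10(concentration in M). Increasing in \code{x} for \code{hill > 0}.
#'
#' @param x log10 concentration (molar).
#' @param bottom,top lower/upper plateaus, percent inhibition.
#' @param hill Hill slope (dimensionless).
#' @param logx0 inflection point, log10 molar.
#' @return numeric vector of responses (percent).
#' @export
logistic4 <- function(x, bottom, top, hill, logx0) {
  bottom + (top - bottom) / (1 + 10^(hill * (logx0 - x)))
}

# Radius of gyration of one configuration.
#' Radius of gyration of a point configuration
#'
#' \eqn{R_g = \sqrt{\sum_k m_k |r_k - \bar r|^2 / \sum_k m_k}} with \eqn{\bar r}
#' the (mass-weighted) centroid. Units follow the coordinates.
#'
#' @param coords numeric matrix, n_atoms x 3.
#' @param masses atomic masses; \code{NULL} for unweighted.
#' @return scalar radius of gyration.
#' @export
rgyr_points <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) fa_stop("fa_validation_error", "coords must be an n x 3 matrix")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (length(masses) != nrow(coords))
    fa_stop("fa_validation_error", "length(masses) must equal nrow(coords)")
  if (any(masses <= 0)) fa_stop("fa_validation_error", "masses must be positive")
  w <- masses / sum(masses)
  ctr <- colSums(coords * w)
  dev <- sweep(coords, 2L, ctr)
  sqrt(sum(w * rowSums(dev * dev)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
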