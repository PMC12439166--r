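# Desk-scale weighted-ensemble engine. An ensemble of weighted walkers is
# alternately propagated and resampled; the resampler clones walkers in
# poorly covered regions of a progress coordinate and merges near-duplicates,
# keeping the walker count constant and conserving total probability weight
# exactly. The resampling objective is the REVO-style "variation"
# V = sum_ij (d_ij / d0)^alpha over all walker pairs (novelty terms fixed at
# 1): cloning a distant walker raises V, merging two close walkers barely
# lowers it, and proposals are accepted greedily while V strictly increases.

#' Resampler parameters
#'
#' The study's resampler settings are the defaults: 50 walkers, merge
#' distance 0.25, characteristic distance `d0` = 0.1, distance exponent
#' `alpha` = 4, maximum walker weight 0.5, minimum 1e-12.
#'
#' @param n_walkers walkers in the ensemble (>= 2).
#' @param merge_dist maximum distance between merge partners (progress
#'   coordinate units, nm for a radius-of-gyration coordinate).
#' @param char_dist characteristic distance `d0` normalising pair distances in
#'   the variation objective `(d_ij/d0)^alpha`.
#' @param dist_exp exponent `alpha` of the variation objective.
#' @param pmax,pmin weight bounds: merges must not create weight above
#'   `pmax`; clones must not create weight below `pmin`.
#' @param steps_per_cycle propagator steps between resamplings.
#' @param n_cycles number of propagate/resample cycles.
#' @return an object of class `fa_revo_params`.
#' @export
revo_params <- function(n_walkers = 50L, merge_dist = 0.25, char_dist = 0.1,
                        dist_exp = 4, pmax = 0.5, pmin = 1e-12,
                        steps_per_cycle = 10L, n_cycles = 1000L) {
  check_field(n_walkers >= 2, "n_walkers", "must be >= 2")
  check_field(merge_dist > 0, "merge_dist", "must be > 0")
  check_field(char_dist > 0, "char_dist", "must be > 0")
  check_field(dist_exp > 0, "dist_exp", "must be > 0")
  check_field(pmin > 0 && pmin < pmax && pmax <= 1, "pmax/pmin",
              "need 0 < pmin < pmax <= 1")
  check_field(steps_per_cycle >= 0, "steps_per_cycle", "must be >= 0")
  check_field(n_cycles >= 0, "n_cycles", "must be >= 0")
  structure(list(n_walkers = as.integer(n_walkers), merge_dist = merge_dist,
                 char_dist = char_dist, dist_exp = dist_exp, pmax = pmax,
                 pmin = pmin, steps_per_cycle = as.integer(steps_per_cycle),
                 n_cycles = as.integer(n_cycles)),
            class = "fa_revo_params")
}

#' Radius-of-gyration distance between walker states
#'
#' `|Rg(a) - Rg(b)|` for coordinate states (matrices, optionally with masses);
#' scalar states are compared directly as `|a - b|` (the state already being
#' the progress coordinate). Non-negative, symmetric, zero iff the radii of
#' gyration agree.
#'
#' @param a,b walker states: scalars or n x 3 coordinate matrices.
#' @param masses optional masses for coordinate states.
#' @return non-negative distance.
#' @export
rgyr_distance <- function(a, b, masses = NULL) {
  va <- if (is.matrix(a)) rgyr_points(a, masses) else as.numeric(a)
  vb <- if (is.matrix(b)) rgyr_points(b, masses) else as.numeric(b)
  if (length(va) != 1L || length(vb) != 1L)
    fa_stop("fa_validation_error", "states must reduce to one progress value each")
  abs(va - vb)
}

# Variation objective for a slot->walker assignment given the pair matrix
# M = (d/d0)^alpha over original walkers.
.variation <- function(M, orig) sum(M[orig, orig])

#' REVO-style variation-maximising resampling
#'
#' One resampling step: greedily (a) clone the walker with the largest
#' marginal contribution to the variation `V = sum_ij (d_ij/d0)^alpha`
#' (eligible if its half-weight stays >= `pmin`), and (b) merge the closest
#' eligible pair (distance <= `merge_dist`, combined weight <= `pmax`,
#' neither being the cloned walker), the survivor drawn with probability
#' proportional to weight. Each clone+merge pair is accepted only if it
#' strictly increases V (relative tolerance 1e-9), so when all pairwise
#' distances vanish — or the distance exponent degenerates towards zero — the
#' ensemble is returned unchanged. Walker count and total weight are
#' conserved exactly; all output weights lie in `[pmin, pmax]` provided the
#' input weights do.
#'
#' @param states walker states: a numeric vector of progress values, or a
#'   list of coordinate states.
#' @param weights walker weights summing to 1 (tolerance 1e-9).
#' @param params an [revo_params()].
#' @param distance pairwise distance function; default [rgyr_distance()].
#' @return list with `states`, `weights`, `parent` (input index each output
#'   slot descends from) and `record` (`clones`: parent indices;
#'   `merges`: data.frame of absorbed/survivor input indices).
#' @export
resample_revo <- function(states, weights, params, distance = rgyr_distance) {
  n <- if (is.list(states)) length(states) else length(states)
  if (length(weights) != n)
    fa_stop("fa_validation_error", "states and weights lengths differ")
  if (abs(sum(weights) - 1) > 1e-9)
    fa_stop("fa_validation_error", "weights must sum to 1 (got %.3g)", sum(weights))
  get_state <- function(i) if (is.list(states)) states[[i]] else states[i]
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    dmat[i, j] <- dmat[j, i] <- distance(get_state(i), get_state(j))
  M <- (dmat / params$char_dist)^params$dist_exp
  orig <- seq_len(n)           # slot -> original walker index
  w <- as.numeric(weights)
  clones <- integer(0)
  merges <- data.frame(absorbed = integer(0), survivor = integer(0))
  V <- .variation(M, orig)
  eps <- 1e-9 * max(1, V)
  for (iter in seq_len(2L * n)) {
    gains <- 2 * rowSums(M[orig, orig, drop = FALSE])
    clone_ok <- which(w / 2 >= params$pmin)
    if (length(clone_ok) == 0L) break
    clone_ord <- clone_ok[order(-gains[clone_ok], clone_ok)]
    dsub <- dmat[orig, orig, drop = FALSE]
    wsum <- outer(w, w, `+`)
    eligible <- dsub <= params$merge_dist & wsum <= params$pmax &
      upper.tri(dsub)
    accepted <- FALSE
    for (cl in clone_ord) {
      elig <- eligible
      elig[cl, ] <- FALSE; elig[, cl] <- FALSE
      if (!any(elig)) next
      cand <- which(elig, arr.ind = TRUE)
      best <- cand[order(dsub[cand], cand[, 1], cand[, 2])[1], ]
      a <- best[1]; b <- best[2]
      surv <- if (stats::runif(1) < w[a] / (w[a] + w[b])) a else b
      abso <- if (surv == a) b else a
      orig_new <- c(orig[-abso], orig[cl])
      V_new <- .variation(M, orig_new)
      if (V_new > V + eps) {
        # apply: merge weight into survivor, split clone weight
        w[surv] <- w[surv] + w[abso]
        merges <- rbind(merges, data.frame(absorbed = orig[abso],
                                           survivor = orig[surv]))
        clones <- c(clones, orig[cl])
        half <- w[cl] / 2
        orig <- c(orig[-abso], orig[cl])
        w <- c(w[-abso], half)
        # the retained clone slot keeps the other half
        cl_slot <- if (cl > abso) cl - 1L else cl
        w[cl_slot] <- half
        V <- .variation(M, orig)
        accepted <- TRUE
      }
      break   # evaluate only the closest pair for the best feasible clone
    }
    if (!accepted) break
  }
  out_states <- if (is.list(states)) states[orig] else states[orig]
  list(states = out_states, weights = w, parent = orig,
       record = list(clones = clones, merges = merges))
}

#' Run a weighted-ensemble simulation
#'
#' `n_cycles` iterations of propagate-then-resample over an ensemble of
#' equally initialised weights (1/n each). After each propagation the walkers'
#' progress values (the radius of gyration for coordinate states, the state
#' itself for scalars) are recorded together with the weights carried during
#' that propagation; resampling then clones/merges via [resample_revo()].
#' Fully reproducible from `seed`.
#'
#' @param propagator a propagator `function(states, n_steps)`; for numeric
#'   scalar walkers it is called once with the full state vector (vectorised
#'   propagation), for list states once per walker.
#' @param init initial states: numeric vector of length `params$n_walkers`,
#'   or a list of coordinate states.
#' @param params an [revo_params()].
#' @param seed integer seed covering propagation noise and merge-survivor
#'   draws.
#' @param value_fn maps a state to its progress value; default: identity for
#'   scalars, [rgyr_points()] for matrices.
#' @param distance pairwise distance on states; default [rgyr_distance()].
#' @return an object of class `fa_weresult`: list with `values` and `weights`
#'   ((n_cycles+1) x n matrices; row c+1 holds cycle c post-propagation
#'   values and the weights carried during that propagation), `post_weights`
#'   (weights after each resampling), `parent` (n_cycles x n ancestry map),
#'   `records`, `params`, `seed`, and — when the propagator exposes a `dt` —
#'   the per-walker and aggregate simulated times.
#' @export
run_weighted_ensemble <- function(propagator, init, params, seed = 1L,
                                  value_fn = NULL, distance = rgyr_distance) {
  n <- params$n_walkers
  list_mode <- is.list(init)
  if ((list_mode && length(init) != n) || (!list_mode && length(init) != n))
    fa_stop("fa_validation_error", "init must provide %d walker states", n)
  value_fn <- value_fn %||% function(s) if (is.matrix(s)) rgyr_points(s) else as.numeric(s)
  val_of <- function(states) {
    if (list_mode) vapply(states, value_fn, numeric(1)) else
      vapply(seq_len(n), function(i) value_fn(states[i]), numeric(1))
  }
  states <- init
  w <- rep(1 / n, n)
  values <- matrix(NA_real_, params$n_cycles + 1L, n)
  weights <- matrix(NA_real_, params$n_cycles + 1L, n)
  post_weights <- matrix(NA_real_, params$n_cycles, n)
  parent <- matrix(NA_integer_, params$n_cycles, n)
  records <- vector("list", params$n_cycles)
  values[1L, ] <- val_of(states)
  weights[1L, ] <- w
  with_seed(seed, {
    for (cyc in seq_len(params$n_cycles)) {
      states <- if (list_mode)
        lapply(states, propagator, n_steps = params$steps_per_cycle)
      else propagator(states, params$steps_per_cycle)
      values[cyc + 1L, ] <- val_of(states)
      weights[cyc + 1L, ] <- w
      rs <- resample_revo(if (list_mode) states else as.numeric(states),
                          w, params, distance)
      states <- rs$states
      w <- rs$weights
      post_weights[cyc, ] <- w
      parent[cyc, ] <- rs$parent
      records[[cyc]] <- rs$record
    }
  })
  out <- list(values = values, weights = weights, post_weights = post_weights,
              parent = parent, records = records, params = params, seed = seed,
              final_states = states, final_weights = w)
  dt <- attr(propagator, "dt")
  if (!is.null(dt)) {
    out$time_per_walker <- params$n_cycles * params$steps_per_cycle * dt
    out$time_aggregate <- n * out$time_per_walker
  }
  class(out) <- "fa_weresult"
  out
}

#' @export
print.fa_weresult <- function(x, ...) {
  cat(sprintf("<fa_weresult> %d walkers x %d cycles", x$params$n_walkers,
              x$params$n_cycles))
  if (!is.null(x$time_per_walker))
    cat(sprintf(" (%.4g time units/walker, %.4g aggregate)",
                x$time_per_walker, x$time_aggregate))
  cat(sprintf("\n  final weight sum deviation: %.2e\n",
              abs(sum(x$final_weights) - 1)))
  invisible(x)
}

#' Trace a walker lineage back to its initial ancestor
#'
#' Follows the resampling ancestry map from a final walker slot back through
#' every cycle, yielding the continuous progress-value and weight series of
#' that lineage.
#'
#' @param result an `fa_weresult`.
#' @param walker final walker slot index.
#' @return data.frame with `cycle` (0 = initialisation), `value`, `weight`.
#' @export
trace_lineage <- function(result, walker) {
  n <- result$params$n_walkers
  nc <- result$params$n_cycles
  if (walker < 1 || walker > n)
    fa_stop("fa_validation_error", "walker index out of range")
  value <- numeric(nc + 1L); weight <- numeric(nc + 1L)
  idx <- as.integer(walker)
  for (cyc in rev(seq_len(nc))) {
    pre <- result$parent[cyc, idx]
    if (is.na(pre) || pre < 1L || pre > n)
      fa_stop("fa_integrity_error", "broken resampling record at cycle %d", cyc)
    value[cyc + 1L] <- result$values[cyc + 1L, pre]
    weight[cyc + 1L] <- result$weights[cyc + 1L, pre]
    idx <- pre
  }
  value[1L] <- result$values[1L, idx]
  weight[1L] <- result$weights[1L, idx]
  data.frame(cycle = 0:nc, value = value, weight = weight)
}

#' Free-energy-like profile from weighted samples
#'
#' Pools progress values and weights (over post-burn-in cycles for a
#' weighted-ensemble result), normalises the weighted histogram to a
#' probability distribution over occupied bins, and transforms it as
#' \eqn{F = -\ln \hat p} (kT units up to an additive constant). Empty bins
#' are omitted.
#'
#' @param x an `fa_weresult`, or a numeric vector of values.
#' @param weights sample weights when `x` is a vector (default uniform).
#' @param bins number of uniform bins over the value range, or an explicit
#'   vector of bin edges.
#' @param burn_in fraction of initial cycles discarded when `x` is a
#'   weighted-ensemble result (default 0.2).
#' @param range optional c(lo, hi) histogram range; samples outside are
#'   dropped (an error if none remain).
#' @return a data.frame of class `fa_feprofile` with `bin_lower`,
#'   `bin_upper`, `bin_mid`, `p`, `F`; occupied bins only, `sum(p) == 1`.
#' @export
free_energy_profile <- function(x, weights = NULL, bins = 50, burn_in = 0.2,
                                range = NULL) {
  if (inherits(x, "fa_weresult")) {
    nc <- x$params$n_cycles
    if (nc == 0L) {
      vals <- x$values[1L, ]; wts <- x$weights[1L, ]
    } else {
      first <- min(floor(burn_in * nc) + 1L, nc)
      rows <- (first:nc) + 1L
      vals <- as.vector(x$values[rows, , drop = FALSE])
      wts <- as.vector(x$weights[rows, , drop = FALSE])
    }
  } else {
    vals <- as.numeric(x)
    wts <- weights %||% rep(1, length(vals))
  }
  if (length(vals) == 0L) fa_stop("fa_validation_error", "no samples after burn-in")
  if (!is.null(range)) {
    keep <- vals >= range[1] & vals <= range[2]
    if (!any(keep)) fa_stop("fa_validation_error", "all samples outside bin range")
    vals <- vals[keep]; wts <- wts[keep]
  }
  if (length(bins) == 1L) {
    lo <- min(vals); hi <- max(vals)
    if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
    edges <- seq(lo, hi, length.out = bins + 1L)
  } else edges <- sort(bins)
  bin <- findInterval(vals, edges, rightmost.closed = TRUE, all.inside = FALSE)
  ok <- bin >= 1L & bin <= length(edges) - 1L
  if (!any(ok)) fa_stop("fa_validation_error", "all samples outside bin range")
  bin <- bin[ok]; wts2 <- wts[ok]
  mass <- tapply(wts2, factor(bin, levels = seq_len(length(edges) - 1L)), sum)
  mass[is.na(mass)] <- 0
  p <- as.numeric(mass) / sum(wts2)
  occ <- which(p > 0)
  out <- data.frame(bin_lower = edges[occ], bin_upper = edges[occ + 1L],
                    bin_mid = (edges[occ] + edges[occ + 1L]) / 2,
                    p = p[occ], F = -log(p[occ]))
  class(out) <- c("fa_feprofile", "data.frame")
  attr(out, "n_samples") <- length(bin)
  out
}
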