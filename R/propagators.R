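# Toy stochastic propagators for the weighted-ensemble engine. These are
# overdamped (Brownian) dynamics on one-dimensional potentials, vectorised
# over walkers; they stand in for the molecular propagation step so that the
# resampling machinery can be exercised and validated at desk scale.

#' Build an overdamped Langevin propagator on a 1-D potential
#'
#' Euler-Maruyama integration of
#' \deqn{dx = -(D/kT)\, U'(x)\, dt + \sqrt{2 D\, dt}\, dW}
#' with diffusion coefficient `D`. The returned function has signature
#' `function(x, n_steps)` and is vectorised over walkers: `x` may be a numeric
#' vector and every step advances all walkers simultaneously from the ambient
#' RNG stream, so results are deterministic given the stream. `n_steps = 0`
#' returns `x` unchanged.
#'
#' @param grad_u gradient of the potential, a vectorised function of `x`.
#' @param diffusion diffusion coefficient, units^2/time.
#' @param dt time step.
#' @param kT thermal energy scale.
#' @return a propagator function with class `fa_propagator`; the time step is
#'   attached as attribute `dt`.
#' @export
make_langevin_propagator <- function(grad_u, diffusion, dt, kT = 1) {
  if (diffusion <= 0) fa_stop("fa_validation_error", "invalid spec field 'diffusion': must be > 0")
  if (dt <= 0) fa_stop("fa_validation_error", "invalid spec field 'dt': must be > 0")
  mob_dt <- diffusion / kT * dt
  noise_sd <- sqrt(2 * diffusion * dt)
  f <- function(x, n_steps) {
    n_steps <- as.integer(n_steps)
    if (n_steps < 0L) fa_stop("fa_validation_error", "n_steps must be >= 0")
    for (s in seq_len(n_steps))
      x <- x - mob_dt * grad_u(x) + stats::rnorm(length(x), 0, noise_sd)
    x
  }
  structure(f, class = c("fa_propagator", "function"), dt = dt, kT = kT,
            diffusion = diffusion)
}

#' Double-well potential and its propagator
#'
#' `double_well_potential()` evaluates \eqn{U(x) = B((x/a)^2 - 1)^2};
#' `make_double_well_propagator()` returns the overdamped Langevin propagator
#' on that potential (see [make_langevin_propagator()] for the contract). The
#' two minima sit at \eqn{x = \pm a} and the barrier at the origin has height
#' `B`; for `B` of a few tens of kT, well-to-well crossings become Kramers-rare
#' on short runs.
#'
#' @param x position(s).
#' @param spec a [double_well_spec()].
#' @return for `double_well_potential`, potential values; for
#'   `make_double_well_propagator`, an `fa_propagator` (the spec is attached
#'   as attribute `spec`).
#' @export
double_well_potential <- function(x, spec) {
  spec$barrier * ((x / spec$well_half_separation)^2 - 1)^2
}

#' @rdname double_well_potential
#' @export
make_double_well_propagator <- function(spec) {
  if (!inherits(spec, "fa_doublewell_spec"))
    fa_stop("fa_validation_error", "spec must be created by double_well_spec()")
  a2 <- spec$well_half_separation^2
  grad <- function(x) 4 * spec$barrier * x * (x^2 / a2 - 1) / a2
  p <- make_langevin_propagator(grad, spec$diffusion, spec$dt, spec$kT)
  attr(p, "spec") <- spec
  p
}
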