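#' Mechanical parameters of the vertex model
#'
#' Bundles the mechanical constants of the tissue energy and of the Brownian
#' overdamped dynamics. All quantities are dimensionless: lengths are in
#' units of `sqrt(A0)` of a reference cell, energies in units of
#' `K_A * A0^2`, and time in units of the natural time
#' `tau = 1 / (mu * K_A * A0)`, which corresponds to `tau_min` minutes of
#' developmental time.
#'
#' @param K_A Area spring constant (reference scale, default 1).
#' @param K_P Perimeter spring constant.
#' @param mu Inverse friction coefficient of the overdamped dynamics.
#' @param temperature Brownian noise strength `T`; the per-component variance
#'   of the random vertex displacement per step is `2 * mu * T * dt`.
#' @param dt Integration step in units of tau (default 0.01).
#' @param tau_min Minutes of developmental time per simulation time unit
#'   (default 0.1 min).
#' @param q Target shape index; preferred perimeters are set as
#'   `P0 = q * sqrt(A0)` for every cell type (default 3.4).
#'
#' @return An object of class `me_params`.
#' @export
#' @examples
#' p <- me_params()
#' p$temperature
me_params <- function(K_A = 1, K_P = 1, mu = 1, temperature = 0.010,
                      dt = 0.01, tau_min = 0.1, q = 3.4) {
  stopifnot(K_A >= 0, K_P >= 0, mu > 0, temperature >= 0, dt > 0,
            tau_min > 0, q > 0)
  structure(list(K_A = K_A, K_P = K_P, mu = mu, temperature = temperature,
                 dt = dt, tau_min = tau_min, q = q),
            class = "me_params")
}

#' @export
print.me_params <- function(x, ...) {
  cat("Vertex-model mechanical parameters\n")
  cat(sprintf("  K_A = %g, K_P = %g, mu = %g, T = %g\n",
              x$K_A, x$K_P, x$mu, x$temperature))
  cat(sprintf("  dt = %g tau, tau = %g min, target shape index q = %g\n",
              x$dt, x$tau_min, x$q))
  invisible(x)
}

# steps per simulated minute at the given parameters
steps_per_minute <- function(params) {
  round(1 / (params$tau_min * params$dt))
}
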