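# Kelvin-Voigt analysis of post-ablation recoil curves.
#
# A severed junction modelled as a spring (elastic coefficient E) and
# dashpot (viscosity mu) in parallel relaxes, after the load sigma0 is
# released, as an exponential approach to a retraction plateau:
#   L(t) = L0 + D (1 - exp(-t / tau))
# with D = sigma0 / E (stress-to-elasticity ratio, the asymptotic
# retraction amplitude) and tau = mu / E (viscosity-to-elasticity ratio,
# the relaxation time). The initial recoil velocity, proportional to the
# junctional tension, is the t = 0 derivative v0 = D / tau.

#' Kelvin-Voigt recoil model
#'
#' @param t Time since ablation (seconds; vectorized).
#' @param L0 Distance between the junction ends at t = 0 (um).
#' @param D Asymptotic retraction amplitude (um), the stress-to-elasticity
#'   ratio.
#' @param tau_relax Relaxation time (s), the viscosity-to-elasticity ratio.
#' @return Predicted end-to-end distance L(t) in um.
#' @export
kv_model <- function(t, L0, D, tau_relax) {
  stopifnot(tau_relax > 0, D >= 0)
  L0 + D * (1 - exp(-t / tau_relax))
}

#' Fit the Kelvin-Voigt model to a recoil series
#'
#' Nonlinear least squares of [kv_model()] against a post-ablation
#' distance-vs-time series. Initialization: `D` from the observed rise,
#' `tau` from the time to half of it; bounds keep `D >= 0` and `tau`
#' between 0.1 s and ten observation windows. The initial recoil velocity
#' is reported as `v0 = D / tau_relax`.
#'
#' @param series data.frame with columns `t` (s, non-negative, increasing)
#'   and `L` (um); at least 4 samples.
#' @param L0 Optional prior for the t = 0 length (e.g. from the pre-cut
#'   frame); by default estimated freely.
#' @return Object of class `kv_fit`: list with `D`, `tau_relax`, `L0`,
#'   `v0`, `sigma` (residual SD), `cov` (parameter covariance),
#'   `converged`, and the fitted `nls` model.
#' @export
fit_recoil <- function(series, L0 = NULL) {
  t <- series$t; L <- series$L
  stopifnot(length(t) >= 4, all(diff(t) > 0), all(t >= 0), all(L > 0))
  if (diff(range(L)) < 1e-8 * max(abs(L))) {
    # flat series: no retraction; the relaxation time is unidentifiable
    return(structure(list(D = 0, tau_relax = 0.1, L0 = mean(L), v0 = 0,
                          sigma = 0, cov = NULL, converged = TRUE,
                          model = NULL),
                     class = "kv_fit"))
  }
  rise <- max(L[length(L)] - L[1], 1e-6)
  half_t <- stats::approx(L - L[1], t, xout = rise / 2, ties = "ordered")$y
  if (!is.finite(half_t) || half_t <= 0) half_t <- diff(range(t)) / 4
  start <- list(L0 = if (is.null(L0)) L[1] else L0,
                D = rise, tau_relax = half_t / log(2))
  lower <- c(L0 = 0, D = 0, tau_relax = 0.1)
  upper <- c(L0 = Inf, D = Inf, tau_relax = 10 * diff(range(t)) + 1)
  fit <- try(minpack.lm::nlsLM(
    L ~ L0 + D * (1 - exp(-t / tau_relax)),
    data = data.frame(t = t, L = L), start = start,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(D = NA_real_, tau_relax = NA_real_,
                          L0 = NA_real_, v0 = NA_real_, sigma = NA_real_,
                          cov = NULL, converged = FALSE, model = NULL),
                     class = "kv_fit"))
  }
  cf <- coef(fit)
  covm <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(covm, "try-error")) covm <- NULL
  res <- structure(list(D = unname(cf["D"]),
                        tau_relax = unname(cf["tau_relax"]),
                        L0 = unname(cf["L0"]),
                        v0 = unname(cf["D"] / cf["tau_relax"]),
                        sigma = summary(fit)$sigma, cov = covm,
                        converged = TRUE, model = fit),
                   class = "kv_fit")
  # flag gross monotonicity violations beyond the fitted noise level
  drop <- min(diff(L))
  if (is.finite(res$sigma) && drop < -6 * max(res$sigma, 1e-12))
    warning("recoil series decreases beyond the noise level")
  res
}

#' @export
print.kv_fit <- function(x, ...) {
  if (!x$converged) { cat("kv_fit: did not converge\n"); return(invisible(x)) }
  cat(sprintf(
    "Kelvin-Voigt fit: D = %.3g um, tau = %.3g s, v0 = D/tau = %.3g um/s\n",
    x$D, x$tau_relax, x$v0))
  invisible(x)
}

#' Empirical (secant) initial recoil velocity
#'
#' `(L(t1) - L(t0)) / (t1 - t0)` over the first post-ablation interval;
#' reported alongside the model-based `v0` as a model-free cross-check. For
#' a noiseless Kelvin-Voigt curve the secant under-estimates the tangent.
#'
#' @param series data.frame with columns `t`, `L` (at least 2 samples).
#' @return Velocity in um/s.
#' @export
recoil_velocity_empirical <- function(series) {
  stopifnot(nrow(series) >= 2)
  (series$L[2] - series$L[1]) / (series$t[2] - series$t[1])
}

#' Fit a set of recoil series from a long-format table
#'
#' @param data data.frame with columns `series_id`, `t`, `L` and optional
#'   `group`.
#' @return data.frame with one row per series: the fitted `D`, `tau_relax`,
#'   `v0`, the empirical velocity, and the group label when present.
#' @export
fit_recoil_set <- function(data) {
  ids <- unique(data$series_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- data[data$series_id == id, ]
    sub <- sub[order(sub$t), ]
    f <- fit_recoil(sub[, c("t", "L")])
    data.frame(series_id = id,
               group = if ("group" %in% names(sub)) sub$group[1] else NA,
               D = f$D, tau_relax = f$tau_relax, v0 = f$v0,
               v_empirical = recoil_velocity_empirical(sub),
               converged = f$converged)
  }))
  rownames(out) <- NULL
  out
}
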