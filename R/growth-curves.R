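#' Von Bertalanffy growth curves across life stages
#'
#' Deterministic length-at-age relationships used throughout the model:
#' the classical von Bertalanffy growth equation (VBGE) for the aquatic
#' larval stage, its evaluation at the latent age at metamorphosis, and a
#' Fabens-style reparameterisation for the terrestrial adult stage that is
#' anchored at the length attained at metamorphosis rather than at age zero.
#' All functions are pure, vectorised, and return the analytic value of the
#' curve unclamped: for ages below `t0` the larval curve is negative, which
#' is a property of the curve, not an error. Clamping (if any) is the
#' responsibility of the observation layer.
#'
#' Units: lengths in mm (snout-vent length, SVL), ages and times in years,
#' growth rates per year.
#'
#' @param t Age in years.
#' @param L_inf Asymptotic length in mm; must be positive.
#' @param k_L Larval growth-rate coefficient (per year); must be positive.
#' @param t0 Theoretical age (years) at which length is zero.
#' @return Length in mm (`larval_length`, `length_at_metamorphosis`,
#'   `adult_length`, `adult_length_at_recapture`) or age in years
#'   (`age_at_length_larval`).
#' @examples
#' larval_length(1.0, L_inf = 59.0, k_L = 1.77, t0 = 0)
#' age_at_length_larval(35, L_inf = 59.0, k_L = 1.77, t0 = 0)
#' @name growth_curves
NULL

.check_finite <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (!all(is.finite(args[[nm]]))) {
      stop("non-finite value for '", nm, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @rdname growth_curves
#' @export
larval_length <- function(t, L_inf, k_L, t0) {
  .check_finite(t = t, L_inf = L_inf, k_L = k_L, t0 = t0)
  stopifnot(all(L_inf > 0), all(k_L > 0))
  L_inf * (1 - exp(-k_L * (t - t0)))
}

#' @rdname growth_curves
#' @param t_m Age at metamorphosis in years.
#' @export
length_at_metamorphosis <- function(t_m, L_inf, k_L, t0) {
  larval_length(t_m, L_inf, k_L, t0)
}

#' @rdname growth_curves
#' @param L_tm Length at metamorphosis in mm; must satisfy
#'   `0 <= L_tm <= L_inf`.
#' @param k_A Adult growth-rate coefficient (per year); must be positive.
#' @export
adult_length <- function(t, t_m, L_tm, L_inf, k_A, t0) {
  .check_finite(t = t, t_m = t_m, L_tm = L_tm, L_inf = L_inf,
                k_A = k_A, t0 = t0)
  stopifnot(all(k_A > 0), all(L_inf >= L_tm), all(L_tm >= 0))
  L_inf - (L_inf - L_tm) * exp(-k_A * (t - (t_m + t0)))
}

#' @rdname growth_curves
#' @param dt Elapsed time since first capture in years; must be >= 0.
#' @export
adult_length_at_recapture <- function(t, dt, t_m, L_tm, L_inf, k_A, t0) {
  stopifnot(all(dt >= 0))
  adult_length(t + dt, t_m, L_tm, L_inf, k_A, t0)
}

#' @rdname growth_curves
#' @param L Target length in mm; must satisfy `0 <= L < L_inf`.
#' @export
age_at_length_larval <- function(L, L_inf, k_L, t0) {
  .check_finite(L = L, L_inf = L_inf, k_L = k_L, t0 = t0)
  stopifnot(all(L_inf > 0), all(k_L > 0), all(L >= 0))
  if (any(L >= L_inf)) {
    stop("no finite age reaches L >= L_inf", call. = FALSE)
  }
  t0 - log(1 - L / L_inf) / k_L
}

#' Weeks per year used when reporting ages in weeks
#'
#' The model works in years internally; weeks appear only in reports.
#' @export
WEEKS_PER_YEAR <- 52.18
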