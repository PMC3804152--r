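#' Inertia profile: cubic CM rotational radius l(theta)
#'
#' The inertia-variable (telescopic) inverted pendulum represents multi-joint
#' influence through an angle-dependent CM rotational radius
#' `l(theta) = a0*theta^3 + a1*theta^2 + a3*theta + a4` (coefficient names
#' keep the a0, a1, a3, a4 convention: there is no coefficient named a2).
#' The rotational inertia is `I(theta) = mass * l(theta)^2` and its angle
#' derivative `dI/dtheta = 2 * mass * l * l'`, both derived exactly from the
#' stored cubic. A constant profile (`a0 = a1 = a3 = 0`) reduces every
#' derived quantity to the simple inverted pendulum with length `a4`.
#'
#' `theta` is the CM angle measured from the anterior horizontal axis
#' (theta = pi/2 when the CM is directly above the ankle; theta > pi/2 when
#' posterior of the ankle).
#'
#' @param a0,a1,a3,a4 Cubic radius coefficients, m (per rad^3, rad^2, rad, 1).
#' @param theta_range Length-2 numeric: the angle domain (rad) over which the
#'   profile is valid; `l(theta)` must be positive throughout.
#' @param mass Body mass, kg.
#' @return An object of class `sts_inertia_profile`.
#' @examples
#' p <- constant_inertia_profile(l = 0.93, mass = 70)
#' radius(p, pi / 2)
#' @export
inertia_profile <- function(a0, a1, a3, a4, theta_range, mass) {
  stopifnot(length(theta_range) == 2L, theta_range[1] < theta_range[2],
            mass > 0)
  p <- structure(
    list(a0 = a0, a1 = a1, a3 = a3, a4 = a4,
         theta_range = as.numeric(theta_range), mass = mass),
    class = "sts_inertia_profile")
  th <- seq(theta_range[1], theta_range[2], length.out = 513L)
  if (any(radius(p, th) <= 0))
    stop("inertia profile has l(theta) <= 0 inside theta_range")
  p
}

#' @param l Constant pendulum length, m.
#' @rdname inertia_profile
#' @export
constant_inertia_profile <- function(l, mass, theta_range = c(0.1, 3.0)) {
  inertia_profile(0, 0, 0, l, theta_range = theta_range, mass = mass)
}

#' Is a profile constant (simple-model twin)?
#' @param profile An `sts_inertia_profile`.
#' @return Logical.
#' @export
is_constant_profile <- function(profile) {
  profile$a0 == 0 && profile$a1 == 0 && profile$a3 == 0
}

#' Evaluate the rotational radius and its derivatives
#'
#' `radius()` returns l(theta); `radius_d1()` and `radius_d2()` its first and
#' second angle derivatives; `inertia()` returns I(theta) = m l^2 and
#' `inertia_d1()` returns dI/dtheta = 2 m l l'. All are vectorised over
#' `theta`.
#'
#' @param profile An `sts_inertia_profile`.
#' @param theta CM angle(s), rad.
#' @return Numeric vector.
#' @export
radius <- function(profile, theta) {
  ((profile$a0 * theta + profile$a1) * theta + profile$a3) * theta + profile$a4
}

#' @rdname radius
#' @export
radius_d1 <- function(profile, theta) {
  (3 * profile$a0 * theta + 2 * profile$a1) * theta + profile$a3
}

#' @rdname radius
#' @export
radius_d2 <- function(profile, theta) {
  6 * profile$a0 * theta + 2 * profile$a1
}

#' @rdname radius
#' @export
inertia <- function(profile, theta) {
  profile$mass * radius(profile, theta)^2
}

#' @rdname radius
#' @export
inertia_d1 <- function(profile, theta) {
  2 * profile$mass * radius(profile, theta) * radius_d1(profile, theta)
}

#' @export
print.sts_inertia_profile <- function(x, ...) {
  cat("<sts_inertia_profile>\n")
  cat(sprintf("  l(theta) = %.5g th^3 + %.5g th^2 + %.5g th + %.5g  [m]\n",
              x$a0, x$a1, x$a3, x$a4))
  cat(sprintf("  theta in [%.3f, %.3f] rad, mass %.1f kg%s\n",
              x$theta_range[1], x$theta_range[2], x$mass,
              if (is_constant_profile(x)) " (constant: simple-model twin)" else ""))
  invisible(x)
}

#' Fit a cubic inertia profile from measured (theta, l) samples
#'
#' Ordinary least squares fit of the cubic rotational radius to pooled
#' (theta, l) samples from one or more natural sit-to-stand trials, as
#' produced by [kinematics_to_polar()]. The fitted angle domain is the
#' observed theta range. The fit is rejected when the theta span is too small
#' to identify a cubic.
#'
#' @param polar A data.frame with columns `theta` (rad) and `l` (m), or a
#'   list of such data.frames (trials are pooled).
#' @param mass Body mass, kg.
#' @param min_span Minimum acceptable theta span, rad.
#' @return An `sts_inertia_profile` with attributes `rms` (residual RMS, m)
#'   and `se` (coefficient standard errors, named a0, a1, a3, a4).
#' @export
fit_inertia_profile <- function(polar, mass, min_span = 0.15) {
  if (is.data.frame(polar)) polar <- list(polar)
  th <- unlist(lapply(polar, function(d) d$theta), use.names = FALSE)
  l <- unlist(lapply(polar, function(d) d$l), use.names = FALSE)
  ok <- is.finite(th) & is.finite(l)
  th <- th[ok]; l <- l[ok]
  if (length(th) < 8L) stop("too few (theta, l) samples to fit a cubic")
  if (diff(range(th)) < min_span)
    stop("theta span ", format(diff(range(th)), digits = 3),
         " rad is too small to identify a cubic radius (need >= ",
         min_span, ")")
  fit <- stats::lm(l ~ I(th^3) + I(th^2) + th)
  cf <- stats::coef(fit)
  # summary.lm warns on an essentially perfect fit (noiseless samples)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  # lm order: (Intercept)=a4, th^3=a0, th^2=a1, th=a3
  prof <- inertia_profile(a0 = cf[["I(th^3)"]], a1 = cf[["I(th^2)"]],
                          a3 = cf[["th"]], a4 = cf[["(Intercept)"]],
                          theta_range = range(th), mass = mass)
  attr(prof, "rms") <- sqrt(mean(stats::residuals(fit)^2))
  attr(prof, "se") <- c(a0 = se[["I(th^3)"]], a1 = se[["I(th^2)"]],
                        a3 = se[["th"]], a4 = se[["(Intercept)"]])
  prof
}

#' Extend an inertia profile's angle domain
#'
#' Returns the same cubic on the union of the current and requested
#' domains. A profile fitted from natural sit-to-stand trials only covers
#' the observed angle range, which never includes the toe-hold terminal of
#' a balance map; computing a map therefore extrapolates the fitted cubic.
#' The extension re-validates positivity of l(theta), so an extrapolation
#' that leaves the physically plausible family is rejected.
#'
#' @param profile An `sts_inertia_profile`.
#' @param theta_range Length-2 numeric target domain, rad.
#' @return An `sts_inertia_profile` on the widened domain.
#' @export
extend_profile <- function(profile, theta_range) {
  inertia_profile(profile$a0, profile$a1, profile$a3, profile$a4,
                  theta_range = range(c(profile$theta_range, theta_range)),
                  mass = profile$mass)
}

#' Read / write an inertia profile (JSON)
#' @param path Path to a JSON file.
#' @return `read_profile_json()` returns an `sts_inertia_profile`.
#' @export
read_profile_json <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  raw <- jsonlite::fromJSON(path)
  for (f in c("a0", "a1", "a3", "a4", "theta_range", "mass"))
    if (is.null(raw[[f]])) stop("profile field '", f, "' missing in ", path)
  inertia_profile(raw$a0, raw$a1, raw$a3, raw$a4,
                  theta_range = raw$theta_range, mass = raw$mass)
}

#' @param profile An `sts_inertia_profile`.
#' @rdname read_profile_json
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(
    list(a0 = profile$a0, a1 = profile$a1, a3 = profile$a3, a4 = profile$a4,
         theta_range = profile$theta_range, mass = profile$mass),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
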