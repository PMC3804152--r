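# Balance feasibility maps: stability boundaries, the zero-torque
# trajectory, state classification, and between-map similarity.
#
# Map coordinates: x = posterior CM distance from the toe in foot lengths
# (0 = toe, 1 = heel); v = anterior CM velocity normalised to body height
# (heights/s).

#' Convert pendulum states to normalised map coordinates (and back)
#'
#' `state_to_map()` maps (theta, omega) to (x, v): `x = (d_toe - l cos
#' theta) / foot_length`, `v = d/dt(l cos theta) / height`. `map_to_state()`
#' inverts the conversion, solving `l(theta) cos(theta) = d_toe - x *
#' foot_length` for theta within the profile domain (the CM horizontal
#' position must be monotone in theta over the domain, which
#' [make_inertia_profile()] guarantees).
#'
#' @param theta,omega Pendulum state (vectorised).
#' @param x,v Map coordinates (vectorised).
#' @param subject An `sts_subject`.
#' @param profile An `sts_inertia_profile`.
#' @return A data.frame with columns `x`, `v` (or `theta`, `omega`).
#' @export
state_to_map <- function(theta, omega, subject, profile) {
  pp <- .pend_pack(subject, profile)
  as.data.frame(.state_to_map_pp(pp, theta, omega))
}

#' @rdname state_to_map
#' @export
map_to_state <- function(x, v, subject, profile) {
  pp <- .pend_pack(subject, profile)
  theta <- vapply(x, function(xi) .map_to_theta(pp, xi), numeric(1))
  l <- radius(profile, theta)
  l1 <- radius_d1(profile, theta)
  bu <- l1 * cos(theta) - l * sin(theta)
  if (any(abs(bu) < 1e-9))
    stop("CM horizontal velocity is insensitive to omega at this angle")
  data.frame(theta = theta, omega = v * pp$height / bu)
}

# Solve l(theta) cos(theta) = d_toe - x * foot_length for theta.
.map_to_theta <- function(pp, x) {
  u <- pp$dT - x * pp$foot_length
  f <- function(th)
    (((pp$a0 * th + pp$a1) * th + pp$a3) * th + pp$a4) * cos(th) - u
  flo <- f(pp$th_min); fhi <- f(pp$th_max)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("x = ", format(x, digits = 4),
         " maps outside the profile's theta domain")
  stats::uniroot(f, c(pp$th_min, pp$th_max), tol = 1e-13)$root
}

# ---------------------------------------------------------------------------
# Boundary construction.
#
# Each boundary is the backward-in-time extremal trajectory ending at the
# most anterior (upper, max plantarflexion) or most posterior (lower, max
# dorsiflexion) statically holdable CM position. That terminal state is a
# saddle of the extremal-torque dynamics; the curve is its stable manifold,
# recovered by integrating backward from a small offset along the stable
# eigendirection. The zero-torque trajectory is the stable manifold of the
# upright (CM above ankle) equilibrium of the tau = 0 dynamics.

# Smallest v >= v_from at which the admissible torque set is empty at map
# abscissa x (NA when x is outside the theta domain or already infeasible
# at v_from).
.frontier_v <- function(pp, x, v_from = 0, v_cap = 3) {
  th <- tryCatch(.map_to_theta(pp, x), error = function(e) NA_real_)
  if (is.na(th)) return(NA_real_)
  l <- (((pp$a0 * th + pp$a1) * th + pp$a3) * th + pp$a4)
  l1 <- (3 * pp$a0 * th + 2 * pp$a1) * th + pp$a3
  bu <- l1 * cos(th) - l * sin(th)
  if (abs(bu) < 1e-9) return(NA_real_)
  feas <- function(v) .torque_range(th, v * pp$height / bu, pp)[3] > 0
  if (!feas(v_from)) return(NA_real_)
  hi <- v_from + 0.5
  while (feas(hi) && hi < v_cap) hi <- hi + 0.5
  if (hi >= v_cap) return(NA_real_)
  lo <- v_from
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (feas(mid)) lo <- mid else hi <- mid
  }
  lo
}

# Continue the upper boundary along the feasibility frontier past the end
# of the extremal trajectory, until the stable region closes on the lower
# boundary (or the grid/domain ends).
.extend_upper_frontier <- function(pp, upper, lower, xg) {
  x_end <- max(upper$x)
  if (x_end >= xg[length(xg)] - 1e-9) return(upper)
  lo_v <- function(x) {
    o <- order(lower$x)
    stats::approx(lower$x[o], lower$v[o], xout = x, rule = 1)$y
  }
  xs <- xg[xg > x_end]
  rows <- list(); k <- 0L
  for (x in xs) {
    vf <- .frontier_v(pp, x)
    if (is.na(vf)) break
    lv <- lo_v(x)
    k <- k + 1L
    rows[[k]] <- data.frame(theta = NA_real_, omega = NA_real_, x = x, v = vf)
    if (!is.na(lv) && vf <= lv) break  # region closed
  }
  if (k == 0L) return(upper)
  out <- rbind(upper, do.call(rbind, rows))
  attr(out, "terminal") <- attr(upper, "terminal")
  out
}

# Terminal equilibrium angle for a curve family.
.terminal_theta <- function(pp, family) {
  u_star <- switch(family,
    upper = min(pp$dT, pp$tpf / (pp$m * pp$g)),
    lower = -min(pp$dH, pp$tdf / (pp$m * pp$g)),
    zero = 0)
  f <- function(th)
    ((((pp$a0 * th + pp$a1) * th + pp$a3) * th + pp$a4) * cos(th)) - u_star
  stats::uniroot(f, c(pp$th_min, pp$th_max), tol = 1e-13)$root
}

# Extremal (or zero) torque at a state; NA if the admissible set is empty.
.curve_tau <- function(pp, th, w, family) {
  if (family == "zero") return(0)
  r <- .torque_range(th, w, pp)
  if (r[3] == 0) return(NA_real_)
  if (family == "upper") r[2] else r[1]
}

# Backward integration of one stable-manifold branch.
# branch +1: posterior side (theta > theta_e), -1: anterior side.
.manifold_branch <- function(pp, family, branch, dt, eps, x_range, t_max) {
  th_e <- .terminal_theta(pp, family)
  f_acc <- function(th, w) {
    tau <- .curve_tau(pp, th, w, family)
    if (is.na(tau)) return(NA_real_)
    .alpha_pp(pp, th, w, tau)
  }
  # local Jacobian of the extremal dynamics by central differences
  d <- 1e-6
  A <- (f_acc(th_e + d, 0) - f_acc(th_e - d, 0)) / (2 * d)
  B <- (f_acc(th_e, d) - f_acc(th_e, -d)) / (2 * d)
  if (!is.finite(A) || !is.finite(B) || A <= 0)
    stop("terminal state of the '", family,
         "' curve is not a saddle of the extremal dynamics")
  lam <- (B - sqrt(B^2 + 4 * A)) / 2  # stable eigenvalue (< 0)
  th <- th_e + branch * eps
  w <- branch * eps * lam
  nmax <- ceiling(t_max / dt)
  TH <- numeric(nmax + 1L); W <- numeric(nmax + 1L)
  TH[1] <- th; W[1] <- w
  i <- 1L
  x_ext <- if (branch > 0) -Inf else Inf
  tau_fun <- function(a, b) .curve_tau(pp, a, b, family)
  while (i <= nmax) {
    tau_here <- tau_fun(th, w)
    if (is.na(tau_here)) break
    st <- tryCatch(.rk4_step(pp, th, w, dt, tau_fun, dir = -1),
                   error = function(e) NULL)
    if (is.null(st) || any(!is.finite(st))) break
    th <- st[1]; w <- st[2]
    if (th <= pp$th_min || th >= pp$th_max) break
    xi <- (pp$dT - ((((pp$a0 * th + pp$a1) * th + pp$a3) * th + pp$a4) *
                      cos(th))) / pp$foot_length
    if (branch > 0) {
      if (xi > x_range[2] + 0.05) { i <- i + 1L; TH[i] <- th; W[i] <- w; break }
      if (xi < x_ext - 0.02) break  # fold: keep the outermost sweep
      x_ext <- max(x_ext, xi)
    } else {
      if (xi < x_range[1] - 0.05) { i <- i + 1L; TH[i] <- th; W[i] <- w; break }
      if (xi > x_ext + 0.02) break
      x_ext <- min(x_ext, xi)
    }
    i <- i + 1L
    TH[i] <- th; W[i] <- w
  }
  idx <- seq_len(i)
  mc <- .state_to_map_pp(pp, TH[idx], W[idx])
  data.frame(theta = TH[idx], omega = W[idx], x = mc$x, v = mc$v)
}

# Full curve: anterior branch + exact terminal point + posterior branch,
# ordered by increasing x.
.manifold_curve <- function(pp, family, dt, eps, x_range, t_max) {
  th_e <- .terminal_theta(pp, family)
  mc_e <- .state_to_map_pp(pp, th_e, 0)
  term <- data.frame(theta = th_e, omega = 0, x = mc_e$x, v = mc_e$v)
  post <- .manifold_branch(pp, family, +1, dt, eps, x_range, t_max)
  ant <- .manifold_branch(pp, family, -1, dt, eps, x_range, t_max)
  curve <- rbind(ant[rev(seq_len(nrow(ant))), ], term, post)
  rownames(curve) <- NULL
  attr(curve, "terminal") <- term
  curve
}

#' Compute a balance feasibility map
#'
#' Computes, for one subject and inertia profile, the three curves that
#' define sit-to-stand balance controllability in normalised CM
#' velocity-position coordinates:
#' \describe{
#'   \item{upper boundary}{the trajectory that stops the CM just over the
#'     toe using the maximal admissible plantarflexion-side torque at every
#'     instant; states above it fall forward.}
#'   \item{lower boundary}{the trajectory that takes the CM just over the
#'     heel using the maximal admissible dorsiflexion; states below it fall
#'     backward.}
#'   \item{zero-torque curve}{the trajectory that reaches upright static
#'     balance with zero ankle torque: the most energy-efficient successful
#'     strategy.}
#' }
#' Curves are obtained by backward-in-time RK4 integration from the
#' corresponding terminal equilibrium (a saddle of the extremal dynamics),
#' then sampled onto a uniform x grid by monotone piecewise-linear
#' interpolation.
#'
#' @param subject An `sts_subject`.
#' @param profile An `sts_inertia_profile`; with `model = "simple"` it must
#'   be constant.
#' @param model `"variable"` or `"simple"`.
#' @param x_range Map x extent, foot lengths.
#' @param n Number of grid samples.
#' @param dt Integration step, s.
#' @param eps Initial offset from the terminal saddle, rad.
#' @param t_max Maximum backward-integration time per branch, s.
#' @return An object of class `sts_balance_map` with elements `grid`
#'   (data.frame `x`, `v_upper`, `v_lower`, `v_zero`; NA where a curve is
#'   not defined), `curves` (raw integration samples per curve), `model`,
#'   `subject`, `profile` and `params`.
#' @export
balance_map <- function(subject, profile, model = c("variable", "simple"),
                        x_range = c(-0.2, 3.0), n = 400, dt = 5e-4,
                        eps = 1e-6, t_max = 20) {
  model <- match.arg(model)
  validate_subject(subject)
  if (model == "simple" && !is_constant_profile(profile))
    stop("model 'simple' requires a constant inertia profile")
  pp <- .pend_pack(subject, profile)
  curves <- list(
    upper = .manifold_curve(pp, "upper", dt, eps, x_range, t_max),
    lower = .manifold_curve(pp, "lower", dt, eps, x_range, t_max),
    zero = .manifold_curve(pp, "zero", dt, eps, x_range, t_max))
  xg <- seq(x_range[1], x_range[2], length.out = n)
  # Where the extremal braking trajectory runs into the feasibility
  # frontier (the admissible torque interval pinches shut, typically at the
  # no-slip limit in fast crouched postures), the forward-fall boundary
  # continues along that frontier until it meets the backward-fall
  # boundary and the stable region closes.
  curves$upper <- .extend_upper_frontier(pp, curves$upper, curves$lower, xg)
  interp <- function(curve) {
    o <- order(curve$x)
    cx <- curve$x[o]; cv <- curve$v[o]
    keep <- c(TRUE, diff(cx) > 1e-12)
    stats::approx(cx[keep], cv[keep], xout = xg, rule = 1)$y
  }
  grid <- data.frame(x = xg,
                     v_upper = interp(curves$upper),
                     v_lower = interp(curves$lower),
                     v_zero = interp(curves$zero))
  structure(
    list(grid = grid, curves = curves,
         terminals = lapply(curves, attr, "terminal"),
         model = model, subject = subject, profile = profile,
         params = list(x_range = x_range, n = n, dt = dt, eps = eps,
                       t_max = t_max)),
    class = "sts_balance_map")
}

#' Individual map curves
#'
#' Convenience wrappers returning the raw integration samples of a single
#' curve (columns `theta`, `omega`, `x`, `v`).
#'
#' @inheritParams balance_map
#' @return A data.frame of curve samples ordered by increasing x.
#' @export
upper_boundary <- function(subject, profile, model = c("variable", "simple"),
                           ...) {
  balance_map(subject, profile, model, ...)$curves$upper
}

#' @rdname upper_boundary
#' @export
lower_boundary <- function(subject, profile, model = c("variable", "simple"),
                           ...) {
  balance_map(subject, profile, model, ...)$curves$lower
}

#' @rdname upper_boundary
#' @export
zero_torque_curve <- function(subject, profile,
                              model = c("variable", "simple"), ...) {
  balance_map(subject, profile, model, ...)$curves$zero
}

#' @export
print.sts_balance_map <- function(x, ...) {
  g <- x$grid
  cat("<sts_balance_map> model:", x$model, "\n")
  cat(sprintf("  x in [%.2f, %.2f] foot lengths, %d samples\n",
              x$params$x_range[1], x$params$x_range[2], x$params$n))
  for (nm in c("v_upper", "v_lower", "v_zero")) {
    ok <- which(!is.na(g[[nm]]))
    if (length(ok) > 0)
      cat(sprintf("  %s defined on x in [%.2f, %.2f], v up to %.3f heights/s\n",
                  nm, g$x[ok[1]], g$x[ok[length(ok)]],
                  max(g[[nm]][ok])))
  }
  invisible(x)
}

# Interpolated boundary value at x (NA outside the sampled support).
.map_v_at <- function(map, which, x) {
  g <- map$grid
  y <- g[[which]]
  ok <- !is.na(y)
  stats::approx(g$x[ok], y[ok], xout = x, rule = 1)$y
}

#' Classify a CM state against a balance map
#'
#' A state is `"stable"` iff the whole horizontal error bar
#' `[x - dx, x + dx]` (and its centre) lies strictly between the lower and
#' upper boundaries (linear interpolation between map samples); a point on a
#' boundary is unstable. Queries outside the sampled support are an error,
#' never an extrapolation.
#'
#' @param map An `sts_balance_map`.
#' @param x,v State in map coordinates.
#' @param dx Horizontal half-width of the CM position uncertainty, foot
#'   lengths.
#' @return `"stable"` or `"unstable"`.
#' @export
classify_state <- function(map, x, v, dx = 0) {
  xs <- unique(c(x - dx, x, x + dx))
  xr <- map$params$x_range
  if (min(xs) < xr[1] || max(xs) > xr[2])
    stop("query x in [", format(min(xs), digits = 4), ", ",
         format(max(xs), digits = 4),
         "] is outside the sampled map range [", xr[1], ", ", xr[2], "]")
  up <- .map_v_at(map, "v_upper", xs)
  lo <- .map_v_at(map, "v_lower", xs)
  # inside the map extent but past the region apex (no stable band there)
  if (any(is.na(up)) || any(is.na(lo))) return("unstable")
  if (all(v > lo) && all(v < up)) "stable" else "unstable"
}

#' Signed stability margin of a state
#'
#' Smallest vertical distance from `v` to either boundary over the error
#' bar; positive inside the stable region.
#'
#' @inheritParams classify_state
#' @return Numeric margin, heights/s.
#' @export
stability_margin <- function(map, x, v, dx = 0) {
  xs <- unique(c(x - dx, x, x + dx))
  up <- .map_v_at(map, "v_upper", xs)
  lo <- .map_v_at(map, "v_lower", xs)
  if (any(is.na(up)) || any(is.na(lo))) return(NA_real_)
  min(c(up - v, v - lo))
}

#' Stable-region area of a map
#'
#' Area (foot lengths x heights/s) between the boundaries, summed over grid
#' cells where both are defined.
#'
#' @param map An `sts_balance_map`.
#' @return Numeric area.
#' @export
stable_region_area <- function(map) {
  g <- map$grid
  wdt <- pmax(0, g$v_upper - g$v_lower)
  wdt[is.na(wdt)] <- 0
  sum(wdt) * (g$x[2] - g$x[1])
}

# Invert a boundary curve: x on the posterior (v >= 0, x >= terminal x)
# limb at velocity v. Non-monotone samples are reduced to the innermost
# (conservative) crossing by cumulative max/min.
.invert_boundary <- function(map, which, v) {
  curve <- map$curves[[if (which == "upper") "upper" else "lower"]]
  term <- map$terminals[[if (which == "upper") "upper" else "lower"]]
  post <- curve[curve$x >= term$x - 1e-12 & curve$v >= -1e-12, ]
  post <- post[order(post$x), ]
  # keep the rising limb only (up to the curve's velocity maximum): the
  # position control tolerance at velocity v is measured between the
  # anterior-most crossings of the two boundaries
  post <- post[seq_len(which.max(post$v)), ]
  o <- order(post$v)
  cv <- post$v[o]; cx <- post$x[o]
  # enforce x nondecreasing in v, taking the conservative (innermost)
  # envelope: larger x for the upper boundary, smaller x for the lower
  cx <- if (which == "upper") cummax(cx) else rev(cummin(rev(cx)))
  keep <- c(TRUE, diff(cv) > 1e-12)
  stats::approx(cv[keep], cx[keep], xout = v, rule = 1)$y
}

#' Position control tolerance of a map
#'
#' The horizontal width of the stable region at CM velocity `v`:
#' `W(v) = x_lower(v) - x_upper(v)`, obtained by inverting the posterior
#' limbs of the boundary curves.
#'
#' @param map An `sts_balance_map`.
#' @param v Velocities, heights/s (vectorised).
#' @return Numeric widths, foot lengths (NA where undefined).
#' @export
tolerance_width <- function(map, v) {
  .invert_boundary(map, "lower", v) - .invert_boundary(map, "upper", v)
}

#' Between-map similarity at a velocity
#'
#' Compares the position control tolerance of a candidate map against a
#' reference map (normally the inertia-variable one):
#' `similarity(v) = 1 - |W_a(v) - W_b(v)| / W_b(v)`. Velocities where the
#' reference tolerance is undefined or non-positive yield NA.
#'
#' @param map_a Candidate `sts_balance_map`.
#' @param map_b Reference `sts_balance_map`.
#' @param v Velocities, heights/s (vectorised).
#' @return Numeric similarities.
#' @export
map_similarity <- function(map_a, map_b, v) {
  wa <- tolerance_width(map_a, v)
  wb <- tolerance_width(map_b, v)
  out <- 1 - abs(wa - wb) / wb
  out[!is.finite(out) | wb <= 0] <- NA_real_
  out
}

#' Largest velocity up to which two maps stay similar
#'
#' `validity_velocity` is the largest `v*` in `v_grid` such that
#' `map_similarity(v) >= threshold` for every grid velocity `v <= v*`.
#'
#' @inheritParams map_similarity
#' @param threshold Similarity threshold (e.g. 0.85).
#' @param v_grid Velocity grid to scan, heights/s.
#' @return The validity velocity (heights/s); 0 if similarity fails at the
#'   smallest grid velocity.
#' @export
validity_velocity <- function(map_a, map_b, threshold = 0.85,
                              v_grid = seq(0.02, 1.0, by = 0.02)) {
  sims <- map_similarity(map_a, map_b, v_grid)
  bad <- which(is.na(sims) | sims < threshold)
  if (length(bad) == 0) return(v_grid[length(v_grid)])
  if (bad[1] == 1L) return(0)
  v_grid[bad[1] - 1L]
}

#' Write / read a balance map (CSV + JSON sidecar)
#'
#' The CSV holds the grid with unit-suffixed headers (`x_footlen`,
#' `v_upper`, `v_lower`, `v_zero`, all velocities in heights/s); the JSON
#' sidecar (`<path>.json`) records subject parameters, profile
#' coefficients, model kind, resolution and curve terminals so the map can
#' be reloaded and queried.
#'
#' @param map An `sts_balance_map`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `read_balance_map()` returns an `sts_balance_map` (grid-backed:
#'   raw curve samples are rebuilt from the grid).
#' @export
write_balance_map <- function(map, path) {
  g <- map$grid
  out <- data.frame(x_footlen = g$x, v_upper = g$v_upper,
                    v_lower = g$v_lower, v_zero = g$v_zero)
  utils::write.csv(out, path, row.names = FALSE)
  side <- list(
    model = map$model,
    subject = unclass(map$subject)[c("mass", "height", "foot_length",
                                     "d_toe", "d_heel", "ankle_height",
                                     "mu", "tau_pf_max", "tau_df_max")],
    profile = map$profile[c("a0", "a1", "a3", "a4", "theta_range", "mass")],
    params = map$params,
    terminals = lapply(map$terminals, function(t)
      list(x = t$x, theta = t$theta)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_balance_map
#' @export
read_balance_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  g <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("map sidecar not found: ", side_path)
  side <- jsonlite::fromJSON(side_path)
  grid <- data.frame(x = g$x_footlen, v_upper = g$v_upper,
                     v_lower = g$v_lower, v_zero = g$v_zero)
  subj <- do.call(subject_model,
                  c(side$subject[c("mass", "height", "foot_length", "d_toe",
                                   "d_heel", "ankle_height", "mu",
                                   "tau_pf_max", "tau_df_max")]))
  prof <- inertia_profile(side$profile$a0, side$profile$a1, side$profile$a3,
                          side$profile$a4,
                          theta_range = side$profile$theta_range,
                          mass = side$profile$mass)
  curves <- list()
  terminals <- list()
  for (nm in c("upper", "lower", "zero")) {
    col <- paste0("v_", nm)
    ok <- !is.na(grid[[col]])
    curves[[nm]] <- data.frame(theta = NA_real_, omega = NA_real_,
                               x = grid$x[ok], v = grid[[col]][ok])
    terminals[[nm]] <- data.frame(theta = side$terminals[[nm]]$theta,
                                  omega = 0, x = side$terminals[[nm]]$x,
                                  v = 0)
  }
  structure(list(grid = grid, curves = curves, terminals = terminals,
                 model = side$model, subject = subj, profile = prof,
                 params = side$params),
            class = "sts_balance_map")
}
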