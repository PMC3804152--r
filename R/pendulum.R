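# Pendulum dynamics core: angular acceleration, ground reaction forces, and
# the admissible ankle-torque range under the no-foot-motion constraints.
#
# Conventions (fixed throughout): anterior = +x, up = +z, ankle at the
# origin; theta is the CM angle from the anterior horizontal axis (pi/2 =
# upright); positive ankle torque is counterclockwise on the body
# (plantarflexion side, braking anterior CM motion); gravity torque about
# the ankle is -m g l(theta) cos(theta).

GRAVITY <- 9.81

# Pack subject + profile into a flat parameter list for the hot loops.
.pend_pack <- function(subject, profile) {
  list(m = profile$mass, g = GRAVITY,
       a0 = profile$a0, a1 = profile$a1, a3 = profile$a3, a4 = profile$a4,
       th_min = profile$theta_range[1], th_max = profile$theta_range[2],
       hA = subject$ankle_height, dT = subject$d_toe, dH = subject$d_heel,
       mu = subject$mu, tpf = subject$tau_pf_max, tdf = subject$tau_df_max,
       height = subject$height, foot_length = subject$foot_length)
}

# l, l', l'' at theta from packed parameters (scalar, hot path).
.radius3 <- function(pp, th) {
  c(((pp$a0 * th + pp$a1) * th + pp$a3) * th + pp$a4,
    (3 * pp$a0 * th + 2 * pp$a1) * th + pp$a3,
    6 * pp$a0 * th + 2 * pp$a1)
}

#' Angular acceleration of the pendulum
#'
#' For the simple model (constant radius l): `alpha = (tau - m g l cos(theta))
#' / (m l^2)`. For the inertia-variable model the angular-momentum balance
#' about the ankle gives `alpha = (tau - m g l(theta) cos(theta) -
#' dI/dtheta * omega^2) / I(theta)` with `I = m l^2` and
#' `dI/dtheta = 2 m l l'`. With a constant profile the two are identical.
#'
#' @param theta CM angle, rad.
#' @param omega CM angular velocity, rad/s.
#' @param tau Ankle torque on the body, N·m (positive = plantarflexion side).
#' @param profile An `sts_inertia_profile`.
#' @param model `"variable"` or `"simple"`; `"simple"` requires a constant
#'   profile.
#' @return Angular acceleration, rad/s^2 (vectorised over theta/omega/tau).
#' @export
angular_acceleration <- function(theta, omega, tau, profile,
                                 model = c("variable", "simple")) {
  model <- match.arg(model)
  m <- profile$mass
  l <- radius(profile, theta)
  if (any(l == 0)) stop("degenerate geometry: l(theta) = 0")
  if (model == "simple") {
    if (!is_constant_profile(profile))
      stop("model 'simple' requires a constant inertia profile")
    return((tau - m * GRAVITY * l * cos(theta)) / (m * l^2))
  }
  l1 <- radius_d1(profile, theta)
  (tau - m * GRAVITY * l * cos(theta) - 2 * m * l * l1 * omega^2) /
    (m * l^2)
}

#' Ground reaction forces transmitted to the body
#'
#' Differentiates the CM position `u = l(theta) cos(theta)`,
#' `h = l(theta) sin(theta)` twice along the motion and applies Newton's
#' second law: the horizontal ground reaction (friction) is `Fx = m * u_dd`
#' and the vertical reaction `Fz = m * (h_dd + g)`.
#'
#' @inheritParams angular_acceleration
#' @param alpha Angular acceleration, rad/s^2.
#' @return A list with numeric components `Fx` and `Fz` (N).
#' @export
reaction_forces <- function(theta, omega, alpha, profile) {
  m <- profile$mass
  l <- radius(profile, theta)
  l1 <- radius_d1(profile, theta)
  l2 <- radius_d2(profile, theta)
  cs <- cos(theta); sn <- sin(theta)
  u_dd <- (l2 * cs - 2 * l1 * sn - l * cs) * omega^2 + (l1 * cs - l * sn) * alpha
  h_dd <- (l2 * sn + 2 * l1 * cs - l * sn) * omega^2 + (l1 * sn + l * cs) * alpha
  list(Fx = m * u_dd, Fz = m * (h_dd + GRAVITY))
}

# Admissible torque interval at (th, w); returns c(lo, hi, feasible 0/1).
# All constraints are affine in tau:
#   alpha(tau) = (tau - k)/I,  k = m g l cos + 2 m l l' w^2
#   Fx = fx0 + fx1 tau, Fz = fz0 + fz1 tau
#   (a) Fz > 0
#   (b) |Fx| <= mu Fz
#   (c) CoP within foot: -dH Fz <= tau - hA Fx <= dT Fz
#       (massless foot moment balance about the ankle: u_p Fz + hA Fx = tau)
#   (d) -tdf <= tau <= tpf
.torque_range <- function(th, w, pp) {
  r <- .radius3(pp, th)
  l <- r[1]; l1 <- r[2]; l2 <- r[3]
  m <- pp$m; g <- pp$g
  cs <- cos(th); sn <- sin(th)
  I <- m * l * l
  k <- m * g * l * cs + 2 * m * l * l1 * w * w
  bu <- l1 * cs - l * sn
  bh <- l1 * sn + l * cs
  w2 <- w * w
  cu <- (l2 * cs - 2 * l1 * sn - l * cs) * w2
  ch <- (l2 * sn + 2 * l1 * cs - l * sn) * w2
  fx1 <- m * bu / I
  fx0 <- m * cu - fx1 * k
  fz1 <- m * bh / I
  fz0 <- m * (ch + g) - fz1 * k
  lo <- -pp$tdf
  hi <- pp$tpf
  # inequalities a*tau <= b
  epsz <- 1e-9 * m * g
  a <- c(-fz1,
         fx1 - pp$mu * fz1,
         -fx1 - pp$mu * fz1,
         1 - pp$hA * fx1 - pp$dT * fz1,
         -1 + pp$hA * fx1 - pp$dH * fz1)
  b <- c(fz0 - epsz,
         -(fx0 - pp$mu * fz0),
         fx0 + pp$mu * fz0,
         pp$dT * fz0 + pp$hA * fx0,
         pp$dH * fz0 - pp$hA * fx0)
  for (i in 1:5) {
    ai <- a[i]
    if (ai > 1e-12) {
      v <- b[i] / ai
      if (v < hi) hi <- v
    } else if (ai < -1e-12) {
      v <- b[i] / ai
      if (v > lo) lo <- v
    } else if (b[i] < 0) {
      return(c(0, 0, 0))
    }
  }
  c(lo, hi, as.numeric(lo <= hi + 1e-12))
}

#' Admissible ankle-torque range at a state
#'
#' Intersects, in the ankle torque tau, the physical constraints that keep
#' the support foot motionless: positive vertical ground reaction
#' (`Fz > 0`), the friction cone (`|Fx| <= mu * Fz`), the centre of pressure
#' within the foot (`-d_heel <= u_p <= d_toe`, from the massless-foot moment
#' balance `u_p * Fz + ankle_height * Fx = tau`), and the physiological
#' torque limits (`-tau_df_max <= tau <= tau_pf_max`). Each constraint is
#' affine in tau, so the intersection is an interval (possibly empty: the
#' state is then uncontrollable without foot motion, reported with
#' `feasible = FALSE`, not an error).
#'
#' @inheritParams angular_acceleration
#' @param subject An `sts_subject`.
#' @return A list with `tau_lo`, `tau_hi` (N·m) and `feasible` (logical).
#' @export
admissible_torque_range <- function(theta, omega, profile, subject,
                                    model = c("variable", "simple")) {
  model <- match.arg(model)
  if (model == "simple" && !is_constant_profile(profile))
    stop("model 'simple' requires a constant inertia profile")
  pp <- .pend_pack(subject, profile)
  r <- .torque_range(theta, omega, pp)
  list(tau_lo = r[1], tau_hi = r[2], feasible = r[3] > 0)
}

# Diagnose why no admissible torque exists at (th, w): drop constraint
# families one at a time and see which removal restores feasibility.
.failure_mode <- function(th, w, pp) {
  relax <- function(field, value) {
    q <- pp; q[[field]] <- value; q
  }
  if (.torque_range(th, w, relax("mu", 1e9))[3] > 0) return("slip")
  q <- pp; q$dT <- 1e6; q$dH <- 1e6
  if (.torque_range(th, w, q)[3] > 0) return("tip")
  q <- pp; q$tpf <- 1e9; q$tdf <- 1e9
  if (.torque_range(th, w, q)[3] > 0) return("torque-limit")
  "infeasible"
}

# Angular acceleration from packed params (hot path).
.alpha_pp <- function(pp, th, w, tau) {
  r <- .radius3(pp, th)
  l <- r[1]; l1 <- r[2]
  (tau - pp$m * pp$g * l * cos(th) - 2 * pp$m * l * l1 * w * w) /
    (pp$m * l * l)
}

# One fixed-step RK4 step of (theta, omega) under torque tau_fun(th, w);
# tau_fun must be cheap and deterministic. dir = +1 forward, -1 backward.
.rk4_step <- function(pp, th, w, dt, tau_fun, dir = 1) {
  f <- function(th, w) {
    tau <- tau_fun(th, w)
    c(dir * w, dir * .alpha_pp(pp, th, w, tau))
  }
  k1 <- f(th, w)
  k2 <- f(th + dt / 2 * k1[1], w + dt / 2 * k1[2])
  k3 <- f(th + dt / 2 * k2[1], w + dt / 2 * k2[2])
  k4 <- f(th + dt * k3[1], w + dt * k3[2])
  c(th + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]),
    w + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]))
}

#' Advance the pendulum one time step
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of the pendulum
#' ODE under a torque policy. The policy's torque is clamped to the
#' admissible range at the current state (a clamp is recorded via the
#' `clamped` attribute); if no torque is admissible the step fails with the
#' diagnosed failure mode.
#'
#' @param theta,omega Current state.
#' @param tau_policy Function `(theta, omega, tau_lo, tau_hi) -> tau`.
#' @param profile An `sts_inertia_profile`.
#' @param subject An `sts_subject`.
#' @param dt Time step, s (> 0).
#' @return Numeric `c(theta, omega)`; attribute `tau` holds the applied
#'   torque. If the state is infeasible, returns `NULL` with a warning-free
#'   signalling via attribute is avoided: use [simulate_pendulum()] for
#'   trajectories with failure handling.
#' @export
pendulum_step <- function(theta, omega, tau_policy, profile, subject, dt) {
  stopifnot(dt > 0)
  pp <- .pend_pack(subject, profile)
  r <- .torque_range(theta, omega, pp)
  if (r[3] == 0) stop("no admissible torque at this state (",
                      .failure_mode(theta, omega, pp), ")")
  tau <- tau_policy(theta, omega, r[1], r[2])
  clamped <- FALSE
  if (tau < r[1]) { tau <- r[1]; clamped <- TRUE }
  if (tau > r[2]) { tau <- r[2]; clamped <- TRUE }
  out <- .rk4_step(pp, theta, omega, dt, function(th, w) tau)
  attr(out, "tau") <- tau
  attr(out, "clamped") <- clamped
  out
}

#' Simulate a pendulum trajectory under a torque policy
#'
#' Fixed-step RK4 forward simulation from a seat-off state. The policy is
#' re-evaluated every step and clamped to the admissible torque range; the
#' simulation terminates when the stop condition is met, when the state
#' leaves the profile's angle domain, when no admissible torque exists
#' (labelled `slip`, `tip`, `torque-limit`), or at `t_max`.
#'
#' @param theta0,omega0 Initial state.
#' @param tau_policy Function `(theta, omega, tau_lo, tau_hi) -> tau`.
#' @param profile,subject Model objects.
#' @param dt Time step, s.
#' @param t_max Maximum simulated time, s.
#' @param stop_fun Optional function `(theta, omega) -> logical`; when TRUE
#'   the run terminates with `termination = "stopped"`.
#' @return A list: `trajectory` data.frame (`t`, `theta`, `omega`, `tau`,
#'   `x`, `v`), `termination` label, final `theta`/`omega`.
#' @export
simulate_pendulum <- function(theta0, omega0, tau_policy, profile, subject,
                              dt = 1e-3, t_max = 5, stop_fun = NULL) {
  pp <- .pend_pack(subject, profile)
  n <- ceiling(t_max / dt) + 1L
  TH <- numeric(n); W <- numeric(n); TAU <- numeric(n)
  TH[1] <- theta0; W[1] <- omega0
  termination <- "time-limit"
  i <- 1L
  while (i < n) {
    th <- TH[i]; w <- W[i]
    if (th < pp$th_min || th > pp$th_max) {
      termination <- "domain-exit"; break
    }
    r <- .torque_range(th, w, pp)
    if (r[3] == 0) {
      termination <- .failure_mode(th, w, pp); break
    }
    tau <- tau_policy(th, w, r[1], r[2])
    if (tau < r[1]) tau <- r[1]
    if (tau > r[2]) tau <- r[2]
    TAU[i] <- tau
    st <- .rk4_step(pp, th, w, dt, function(a, b) tau)
    TH[i + 1L] <- st[1]; W[i + 1L] <- st[2]
    i <- i + 1L
    if (!is.null(stop_fun) && isTRUE(stop_fun(st[1], st[2]))) {
      termination <- "stopped"; break
    }
  }
  idx <- seq_len(i)
  mc <- .state_to_map_pp(pp, TH[idx], W[idx])
  list(trajectory = data.frame(t = (idx - 1L) * dt, theta = TH[idx],
                               omega = W[idx], tau = TAU[idx],
                               x = mc$x, v = mc$v),
       termination = termination, theta = TH[i], omega = W[i])
}

# Map-coordinate conversion from packed params (vectorised).
.state_to_map_pp <- function(pp, theta, omega) {
  l <- ((pp$a0 * theta + pp$a1) * theta + pp$a3) * theta + pp$a4
  l1 <- (3 * pp$a0 * theta + 2 * pp$a1) * theta + pp$a3
  u <- l * cos(theta)
  udot <- (l1 * cos(theta) - l * sin(theta)) * omega
  list(x = (pp$dT - u) / pp$foot_length, v = udot / pp$height)
}
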