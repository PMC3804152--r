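# Synthetic data generation: subjects, inertia profiles, marker-level
# sit-to-stand trials (5-segment kinematic chain whose whole-body CM follows
# a forward-simulated pendulum trajectory exactly), and an exhaustive-control
# labelling oracle, so every analysis module is testable without motion
# capture data.

#' Specification for a synthetic cohort
#'
#' Defaults emulate a small healthy-adult cohort: heights 1.65-1.85 m,
#' masses 60-85 kg, CM radius variation of 15% scale between seated and
#' upright postures, 120 Hz marker sampling with 2 mm additive noise.
#'
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param n_subjects Number of subjects.
#' @param height_range,mass_range Uniform anthropometry ranges (m, kg).
#' @param variation Relative amplitude of the l(theta) variation (see
#'   [make_inertia_profile()]).
#' @param marker_noise_sd Additive marker noise SD, m.
#' @param rate Marker sampling rate, Hz.
#' @return A list of class `sts_synth_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_subjects = 6,
                           height_range = c(1.65, 1.85),
                           mass_range = c(60, 85),
                           variation = 0.15,
                           marker_noise_sd = 0.002,
                           rate = 120) {
  stopifnot(seed == round(seed), n_subjects >= 1,
            all(height_range > 0), all(mass_range > 0),
            variation >= 0, marker_noise_sd >= 0, rate > 0)
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 height_range = height_range, mass_range = mass_range,
                 variation = variation, marker_noise_sd = marker_noise_sd,
                 rate = rate),
            class = "sts_synth_spec")
}

#' Draw a synthetic subject
#'
#' Deterministic given `(spec$seed, index)`: anthropometry is drawn
#' uniformly from the spec's ranges; foot geometry, friction and torque
#' limits follow the [subject_model()] defaults.
#'
#' @param spec An `sts_synth_spec`.
#' @param index Subject index (1-based).
#' @return An `sts_subject`.
#' @export
make_subject <- function(spec, index = 1) {
  stopifnot(index >= 1)
  with_seed(spec$seed + 7919L * as.integer(index), {
    height <- stats::runif(1, spec$height_range[1], spec$height_range[2])
    mass <- stats::runif(1, spec$mass_range[1], spec$mass_range[2])
    subject_model(mass = mass, height = height)
  })
}

#' Generate a subject's inertia profile
#'
#' Builds a cubic rotational-radius function
#' `l(theta) = l_up * (1 - variation * (d^2 + 0.3 d^3))`, `d = theta - pi/2`,
#' with upright radius `l_up = 0.52 * height`: the radius shortens towards
#' seated (posterior, crouched) postures and is longest near upright,
#' emulating the multi-joint CM radius change of a sit-to-stand. The
#' profile must satisfy `l(theta) > 0` and a CM horizontal position
#' monotone in theta over the domain; otherwise the variation is damped by
#' 20% and the construction retried.
#'
#' @param subject An `sts_subject`.
#' @param variation Non-negative variation amplitude; 0 gives the constant
#'   simple-model twin.
#' @param theta_range Profile angle domain, rad.
#' @return An `sts_inertia_profile`.
#' @export
make_inertia_profile <- function(subject, variation = 0.15,
                                 theta_range = c(0.5, 2.45)) {
  stopifnot(variation >= 0)
  # CM rotational radius when the CM passes over the ankle mid-rise: the
  # body is still partially flexed there, so the radius sits below the
  # fully erect CM height (~0.53 * height above the ankle)
  l_up <- 0.48 * subject$height
  b <- pi / 2
  # l = l_up - l_up*A*(d^2 + 0.3 d^3), d = theta - b, expanded in theta
  A <- variation
  # d^2 = th^2 - 2b th + b^2 ; d^3 = th^3 - 3b th^2 + 3b^2 th - b^3
  a0 <- -l_up * A * 0.3
  a1 <- -l_up * A * (1 - 0.9 * b)
  a3 <- -l_up * A * (-2 * b + 0.9 * b^2)
  a4 <- l_up - l_up * A * (b^2 - 0.3 * b^3)
  prof <- tryCatch(
    inertia_profile(a0, a1, a3, a4, theta_range = theta_range,
                    mass = subject$mass),
    error = function(e) NULL)
  if (!is.null(prof)) {
    th <- seq(theta_range[1], theta_range[2], length.out = 257)
    du <- radius_d1(prof, th) * cos(th) - radius(prof, th) * sin(th)
    if (any(du >= -1e-6)) prof <- NULL  # CM x not monotone in theta
  }
  if (is.null(prof)) {
    if (variation < 1e-6)
      stop("cannot build an admissible inertia profile for this subject")
    return(make_inertia_profile(subject, 0.8 * variation, theta_range))
  }
  prof
}

# ---------------------------------------------------------------------------
# Five-segment kinematic chain (sagittal): foot static; shank, thigh,
# trunk(+head) posed so that the whole-body CM (default segment table)
# coincides exactly with the pendulum CM (l(theta), theta).

.chain_geometry <- function(subject) {
  h <- subject$height
  list(Ls = 0.25 * h,    # ankle -> knee
       Lt = 0.25 * h,    # knee -> hip
       Ltr = 0.30 * h,   # hip -> C7
       Lh = 0.15 * h,    # C7 -> vertex
       half_width = 0.09,
       marker_floor = 0.02)
}

# Whole-body CM (relative to ankle) for joint angles q = c(q1 shank, q2
# thigh, q3 trunk), angles from vertical, anterior positive.
.chain_cm <- function(subject, geo, q) {
  st <- subject$segment_table
  f <- st$fraction[match(c("head", "trunk", "thigh", "shank", "foot"),
                         st$segment)]
  e1 <- c(sin(q[1]), cos(q[1]))
  e2 <- c(sin(q[2]), cos(q[2]))
  e3 <- c(sin(q[3]), cos(q[3]))
  knee <- geo$Ls * e1
  hip <- knee + geo$Lt * e2
  cm_shank <- geo$Ls / 2 * e1
  cm_thigh <- knee + geo$Lt / 2 * e2
  cm_trunk <- hip + geo$Ltr / 2 * e3
  cm_head <- hip + (geo$Ltr + geo$Lh / 2) * e3
  cm_foot <- c((subject$d_toe - subject$d_heel) / 2,
               geo$marker_floor - subject$ankle_height)
  f[1] * cm_head + f[2] * cm_trunk + f[3] * cm_thigh + f[4] * cm_shank +
    f[5] * cm_foot
}

# Solve thigh and trunk angles so the chain CM hits the target (u, h)
# exactly, shank angle fixed by a posture template.
.posture_solve <- function(subject, geo, theta, l_tgt, guess = NULL) {
  target <- c(l_tgt * cos(theta), l_tgt * sin(theta))
  q1 <- 0.05 - 0.2 * (theta - pi / 2)
  if (is.null(guess))
    guess <- c(-1.9 * (theta - pi / 2), 0.9 * (theta - pi / 2))
  q23 <- guess
  for (it in 1:80) {
    g <- .chain_cm(subject, geo, c(q1, q23)) - target
    if (max(abs(g)) < 1e-13) break
    d <- 1e-7
    g2 <- .chain_cm(subject, geo, c(q1, q23[1] + d, q23[2])) - target
    g3 <- .chain_cm(subject, geo, c(q1, q23[1], q23[2] + d)) - target
    J <- cbind((g2 - g) / d, (g3 - g) / d)
    step <- tryCatch(solve(J, g), error = function(e) NULL)
    if (is.null(step)) break
    # damp large steps for robustness far from the solution
    sn <- sqrt(sum(step^2))
    if (sn > 0.5) step <- step * (0.5 / sn)
    q23 <- q23 - step
  }
  g <- .chain_cm(subject, geo, c(q1, q23)) - target
  if (max(abs(g)) > 1e-10)
    stop("posture solver did not converge at theta = ",
         format(theta, digits = 4))
  c(q1, q23)
}

# Marker positions (x anterior, z vertical, lab frame with the floor at
# z = 0 and the ankle at x = 0) for one posture.
.posture_markers <- function(subject, geo, q) {
  hA <- subject$ankle_height
  e1 <- c(sin(q[1]), cos(q[1]))
  e2 <- c(sin(q[2]), cos(q[2]))
  e3 <- c(sin(q[3]), cos(q[3]))
  ankle <- c(0, hA)
  knee <- ankle + geo$Ls * e1
  hip <- knee + geo$Lt * e2
  c7 <- hip + geo$Ltr * e3
  vertex <- c7 + geo$Lh * e3
  sternum <- hip + 0.75 * geo$Ltr * e3
  shoulder <- hip + 0.95 * geo$Ltr * e3
  heel <- c(-subject$d_heel, geo$marker_floor)
  toe <- c(subject$d_toe, geo$marker_floor)
  list(vertex = vertex, c7 = c7, sternum = sternum,
       shoulder_l = shoulder, shoulder_r = shoulder,
       hip_l = hip, hip_r = hip, knee_l = knee, knee_r = knee,
       ankle_l = ankle, ankle_r = ankle, heel_l = heel, heel_r = heel,
       toe_l = toe, toe_r = toe)
}

# Velocity-tracking "natural" sit-to-stand policy: follow a braking target
# velocity profile that stays above the minimum-energy requirement, then
# stop over the base of support.
.natural_policy <- function(pp, x0, v0, x_stop = 0.45, kp = 8) {
  function(th, w, lo, hi) {
    mc <- .state_to_map_pp(pp, th, w)
    s <- (mc$x - x_stop) / max(x0 - x_stop, 1e-6)
    v_des <- if (s <= 0) 0 else v0 * sqrt(min(s, 1.2))
    udd_des <- kp * (v_des - mc$v) * pp$height
    r <- .radius3(pp, th)
    l <- r[1]; l1 <- r[2]; l2 <- r[3]
    cs <- cos(th); sn <- sin(th)
    bu <- l1 * cs - l * sn
    cu <- (l2 * cs - 2 * l1 * sn - l * cs) * w * w
    alpha_des <- (udd_des - cu) / bu
    pp$m * l * l * alpha_des + pp$m * pp$g * l * cs +
      2 * pp$m * l * l1 * w * w
  }
}

#' Generate a marker-level synthetic sit-to-stand trial
#'
#' Forward-simulates the inertia-variable pendulum from a seat-off state
#' under a velocity-tracking "natural" control policy (clamped to the
#' admissible torque range), then emits 15-marker frames at the spec's
#' sampling rate from a 5-segment kinematic chain posed so that the
#' whole-body CM of the default segment table coincides with the pendulum
#' CM at every frame (noiseless round-trip through [estimate_cm()] is exact
#' to solver tolerance). Gaussian marker noise is added when
#' `noise_sd > 0`.
#'
#' @param subject An `sts_subject` (must use the default segment table's
#'   marker names).
#' @param profile An `sts_inertia_profile`.
#' @param seatoff Numeric `c(x, v)`: seat-off state in map coordinates.
#' @param noise_sd Marker noise SD, m.
#' @param seed Integer seed for the noise.
#' @param rate Sampling rate, Hz.
#' @param t_max Maximum simulated duration, s.
#' @return A list: `frames` (marker data.frame), `cm_true` (noiseless
#'   ground-truth CM series), `polar_true`, `trajectory` (map
#'   coordinates), `outcome` (`"success"`/`"failure"`), `failure_mode`,
#'   `seatoff`.
#' @export
make_marker_trial <- function(subject, profile, seatoff = c(1.3, 0.30),
                              noise_sd = 0, seed = 1, rate = 120,
                              t_max = 4) {
  validate_subject(subject)
  pp <- .pend_pack(subject, profile)
  st0 <- map_to_state(seatoff[1], seatoff[2], subject, profile)
  dt <- 1 / (10 * rate)
  pol <- .natural_policy(pp, x0 = seatoff[1], v0 = seatoff[2])
  sim <- simulate_pendulum(st0$theta, st0$omega, pol, profile, subject,
                           dt = dt, t_max = t_max,
                           stop_fun = function(th, w) {
                             mc <- .state_to_map_pp(pp, th, w)
                             abs(mc$v) <= 0.005 && mc$x >= 0.05 &&
                               mc$x <= 0.95
                           })
  outcome <- if (sim$termination %in% c("stopped", "time-limit"))
    "success" else "failure"
  if (sim$termination == "time-limit") {
    mcf <- .state_to_map_pp(pp, sim$theta, sim$omega)
    if (!(abs(mcf$v) <= 0.05 && mcf$x >= 0 && mcf$x <= 1))
      outcome <- "failure"
  }
  traj <- sim$trajectory
  frame_idx <- seq(1, nrow(traj), by = 10L)
  geo <- .chain_geometry(subject)
  th_f <- traj$theta[frame_idx]
  t_f <- traj$t[frame_idx]
  names_all <- canonical_marker_set()
  M <- matrix(NA_real_, length(frame_idx), 3 * length(names_all))
  colnames(M) <- paste0(rep(names_all, each = 3), c("_x", "_y", "_z"))
  guess <- NULL
  for (i in seq_along(frame_idx)) {
    q <- .posture_solve(subject, geo, th_f[i], radius(profile, th_f[i]),
                        guess = guess)
    guess <- q[2:3]
    mk <- .posture_markers(subject, geo, q)
    for (nm in names_all) {
      y <- if (endsWith(nm, "_l")) geo$half_width else
        if (endsWith(nm, "_r")) -geo$half_width else 0
      M[i, paste0(nm, c("_x", "_y", "_z"))] <- c(mk[[nm]][1], y, mk[[nm]][2])
    }
  }
  frames <- data.frame(time = t_f, M, check.names = FALSE)
  cm_true <- estimate_cm(frames, subject)
  if (noise_sd > 0) {
    with_seed(seed, {
      noise <- matrix(stats::rnorm(length(M), sd = noise_sd), nrow(M))
      frames[, -1] <- M + noise
    })
  }
  list(frames = frames, cm_true = cm_true,
       polar_true = data.frame(time = t_f, theta = th_f,
                               omega = traj$omega[frame_idx],
                               l = radius(profile, th_f)),
       trajectory = traj[, c("t", "x", "v")],
       outcome = outcome,
       failure_mode = if (outcome == "failure") sim$termination else NA_character_,
       seatoff = seatoff)
}

# ---------------------------------------------------------------------------
# Exhaustive-control labelling oracle.

#' Exhaustive-control outcome oracle for a seat-off state
#'
#' Searches over piecewise-constant admissible torque sequences (depth
#' `depth`, `levels` levels spanning the admissible range at each segment
#' start, clamped to the instantaneous admissible range during the segment)
#' for a control that stops the CM over the base of support without
#' violating any constraint. Returns `"success"` if one exists,
#' `"failure"` if the search space is exhausted, and `NA` (indeterminate)
#' if the node budget runs out first.
#'
#' Hard pruning uses two exact facts: a CM posterior of the heel with
#' non-anterior velocity cannot be recovered (the CoP cannot move behind
#' the heel), and a CM anterior of the toe with non-posterior velocity
#' cannot be recovered.
#'
#' @param x,v Seat-off state in map coordinates.
#' @param subject,profile Model objects.
#' @param depth Number of piecewise-constant segments.
#' @param levels Torque levels per segment.
#' @param seg_dt Segment duration, s.
#' @param dt Integration substep, s.
#' @param budget Maximum number of simulated segments.
#' @return `"success"`, `"failure"` or `NA_character_`.
#' @export
oracle_label <- function(x, v, subject, profile, depth = 8, levels = 5,
                         seg_dt = 0.15, dt = 5e-3, budget = 6000) {
  pp <- .pend_pack(subject, profile)
  st0 <- map_to_state(x, v, subject, profile)
  nsub <- max(1L, round(seg_dt / dt))
  used <- 0L
  exhausted <- FALSE

  is_success <- function(xi, vi) xi >= 0.01 && xi <= 0.99 && abs(vi) <= 0.015
  is_lost <- function(xi, vi) (xi > 1 + 1e-9 && vi <= 0) ||
    (xi < -1e-9 && vi >= 0) || xi > 3.5 || xi < -0.5

  # simulate one segment at clamped nominal torque; returns list(status,
  # th, w): status 1 success, -1 lost/infeasible, 0 continue.
  seg <- function(th, w, tau_nom) {
    for (k in seq_len(nsub)) {
      r <- .torque_range(th, w, pp)
      if (r[3] == 0) return(list(status = -1L))
      tau <- min(max(tau_nom, r[1]), r[2])
      st <- .rk4_step(pp, th, w, dt, function(a, b) tau)
      th <- st[1]; w <- st[2]
      if (th <= pp$th_min || th >= pp$th_max) return(list(status = -1L))
      mc <- .state_to_map_pp(pp, th, w)
      if (is_success(mc$x, mc$v)) return(list(status = 1L))
      if (is_lost(mc$x, mc$v)) return(list(status = -1L))
    }
    list(status = 0L, th = th, w = w)
  }

  rec <- function(th, w, d) {
    if (d == 0L) return(FALSE)
    r <- .torque_range(th, w, pp)
    if (r[3] == 0) return(FALSE)
    taus <- seq(r[1], r[2], length.out = levels)
    # extremes first: braking and driving policies resolve most states fast
    ord <- order(-abs(taus - mean(taus)))
    for (tau_nom in taus[ord]) {
      if (used >= budget) { exhausted <<- TRUE; return(FALSE) }
      used <<- used + 1L
      res <- seg(th, w, tau_nom)
      if (res$status == 1L) return(TRUE)
      if (res$status == 0L && rec(res$th, res$w, d - 1L)) return(TRUE)
    }
    FALSE
  }

  mc0 <- .state_to_map_pp(pp, st0$theta, st0$omega)
  if (is_success(mc0$x, mc0$v)) return("success")
  if (is_lost(mc0$x, mc0$v)) return("failure")
  ok <- rec(st0$theta, st0$omega, as.integer(depth))
  if (ok) return("success")
  if (exhausted) return(NA_character_)
  "failure"
}

#' Generate an oracle-labelled cohort of seat-off states
#'
#' Lays a grid over the map region, keeps states at least `margin` (in grid
#' cells of the cohort grid) away from the reference map's boundaries,
#' labels each state with [oracle_label()], and returns a trials table
#' ready for [classify_trials()]. Indeterminate oracle states are dropped.
#'
#' @param subject,profile Model objects.
#' @param map Reference `sts_balance_map` (used for the margin filter).
#' @param x_grid,v_grid Cohort grid, map coordinates.
#' @param margin_cells Minimum distance from a boundary, in cohort grid
#'   cells.
#' @param condition_threshold Seat-off distance splitting normal from
#'   demanding trials, foot lengths.
#' @param ... Passed to [oracle_label()].
#' @return Trials data.frame (`trial_id`, `x_footlen`, `v_heights_per_s`,
#'   `outcome`, `condition`).
#' @export
make_cohort <- function(subject, profile, map,
                        x_grid = seq(0.7, 2.7, length.out = 17),
                        v_grid = seq(0.05, 1.0, length.out = 15),
                        margin_cells = 1, condition_threshold = 2.48, ...) {
  dx <- if (length(x_grid) > 1) diff(x_grid[1:2]) else 0.1
  dv <- if (length(v_grid) > 1) diff(v_grid[1:2]) else 0.1
  bnd <- rbind(map$curves$upper[, c("x", "v")], map$curves$lower[, c("x", "v")])
  bnd <- bnd[bnd$x >= min(x_grid) - 2 * dx & bnd$x <= max(x_grid) + 2 * dx, ]
  rows <- list()
  id <- 0L
  for (xi in x_grid) for (vi in v_grid) {
    if (xi < map$params$x_range[1] || xi > map$params$x_range[2]) next
    # Chebyshev distance (in cohort grid cells) to the nearest boundary
    # sample; states closer than margin_cells are dropped
    dmin <- min(pmax(abs(bnd$x - xi) / dx, abs(bnd$v - vi) / dv))
    if (dmin < margin_cells) next
    lab <- tryCatch(oracle_label(xi, vi, subject, profile, ...),
                    error = function(e) NA_character_)
    if (is.na(lab)) next
    id <- id + 1L
    rows[[id]] <- data.frame(trial_id = id, x_footlen = xi,
                             v_heights_per_s = vi, outcome = lab)
  }
  if (id == 0L) stop("cohort grid produced no usable states")
  assign_condition(do.call(rbind, rows), condition_threshold)
}

#' Materialise a full synthetic cohort directory
#'
#' Writes, for each subject: the subject JSON, two natural marker-trial
#' TSVs (for inertia-function fitting), and an oracle-labelled trials CSV.
#'
#' @param spec An `sts_synth_spec`.
#' @param dir Output directory (created if needed).
#' @param n_trials_grid Grid size per axis for the labelled cohort.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(spec, dir, n_trials_grid = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(spec$n_subjects)) {
    subj <- make_subject(spec, i)
    prof <- make_inertia_profile(subj, spec$variation)
    tag <- sprintf("subject%02d", i)
    write_subject_json(subj, file.path(dir, paste0(tag, ".json")))
    seatoffs <- list(c(1.4, 0.35), c(1.9, 0.56))
    for (k in 1:2) {
      tr <- make_marker_trial(subj, prof, seatoff = seatoffs[[k]],
                              noise_sd = spec$marker_noise_sd,
                              seed = spec$seed + 131L * i + k, rate = spec$rate)
      write_marker_tsv(tr$frames,
                       file.path(dir, sprintf("%s_natural%d.tsv", tag, k)))
    }
    map <- balance_map(subj, prof, "variable")
    trials <- make_cohort(subj, prof, map,
                          x_grid = seq(1.0, 2.8, length.out = n_trials_grid),
                          v_grid = seq(0.05, 0.95, length.out = n_trials_grid))
    write_trials_csv(trials, file.path(dir, paste0(tag, "_trials.csv")))
  }
  invisible(dir)
}
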