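test_that("gravity-balancing torque gives zero angular acceleration", {
  p <- fx_profile_const()
  l <- p$a4
  for (th in c(1.0, pi / 2, 2.0)) {
    tau_eq <- 70 * 9.81 * l * cos(th)
    expect_equal(angular_acceleration(th, 0, tau_eq, p, "simple"), 0,
                 tolerance = 1e-12)
  }
})

test_that("variable model with constant radius reduces to the simple model", {
  p <- fx_profile_const()
  states <- expand.grid(th = c(0.8, 1.4, 2.0, 2.6), w = c(-2, 0, 1.5),
                        tau = c(-40, 0, 90))
  a_simple <- angular_acceleration(states$th, states$w, states$tau, p,
                                   "simple")
  a_var <- angular_acceleration(states$th, states$w, states$tau, p,
                                "variable")
  expect_equal(a_var, a_simple, tolerance = 1e-10)
})

test_that("angular momentum bookkeeping holds along a telescopic trajectory", {
  # profile with linearly varying radius, checked against finite
  # differences of I(theta) * omega along an integrated trajectory
  p <- inertia_profile(0, 0, 0.1, 0.9, c(0.5, 2.5), mass = 70)
  s <- fx_subject()
  tau0 <- 30
  th <- 1.9; w <- -0.4; dt <- 1e-4
  TH <- numeric(2001); W <- numeric(2001)
  for (i in 1:2001) {
    TH[i] <- th; W[i] <- w
    st <- pendulum_step(th, w, function(a, b, lo, hi) tau0, p, s, dt)
    th <- st[1]; w <- st[2]
  }
  L <- inertia(p, TH) * W
  dLdt <- (L[3:2001] - L[1:1999]) / (2 * dt)
  rhs <- tau0 - 70 * 9.81 * radius(p, TH[2:2000]) * cos(TH[2:2000])
  expect_lt(max(abs(dLdt - rhs)), 1e-4 * max(abs(rhs)))
})

test_that("reaction forces reduce to statics and circular motion", {
  p <- fx_profile_const()
  m <- 70; g <- 9.81; l <- p$a4
  fr <- reaction_forces(pi / 2, 0, 0, p)
  expect_equal(fr$Fx, 0, tolerance = 1e-10)
  expect_equal(fr$Fz, m * g, tolerance = 1e-10)
  # omega = 0, constant l: point-mass tangential acceleration only
  th <- 1.2; al <- 2.5
  fr <- reaction_forces(th, 0, al, p)
  expect_equal(fr$Fx, -m * l * sin(th) * al, tolerance = 1e-10)
  expect_equal(fr$Fz, m * (g + l * cos(th) * al), tolerance = 1e-10)
})

test_that("impulse-momentum: integral of Fx equals the CM momentum change", {
  p <- fx_profile_var()
  s <- fx_subject()
  tau0 <- 20
  sim <- simulate_pendulum(1.9, -0.3, function(a, b, lo, hi) tau0, p, s,
                           dt = 1e-4, t_max = 0.4)
  tr <- sim$trajectory
  al <- angular_acceleration(tr$theta, tr$omega, tr$tau, p, "variable")
  Fx <- reaction_forces(tr$theta, tr$omega, al, p)$Fx
  # trapezoid rule over the trajectory
  dtv <- diff(tr$t)
  imp <- sum((Fx[-1] + Fx[-length(Fx)]) / 2 * dtv)
  udot <- function(i) {
    l <- radius(p, tr$theta[i]); l1 <- radius_d1(p, tr$theta[i])
    (l1 * cos(tr$theta[i]) - l * sin(tr$theta[i])) * tr$omega[i]
  }
  expect_equal(imp, 70 * (udot(nrow(tr)) - udot(1)), tolerance = 1e-4)
})

test_that("admissible torque range matches a brute-force constraint scan", {
  s <- fx_subject()
  s_mu0 <- subject_model(70, 1.75, mu = 0)
  p <- fx_profile_var()
  pc <- fx_profile_const()
  cases <- list(
    list(s, p, 1.6, -0.5), list(s, p, 1.2, -1.5), list(s, p, 2.1, -1.0),
    list(s, p, 2.3, 0.5), list(s, pc, 1.9, -0.8), list(s_mu0, pc, 1.4, -0.6))
  for (cs in cases) {
    subj <- cs[[1]]; prof <- cs[[2]]; th <- cs[[3]]; w <- cs[[4]]
    r <- admissible_torque_range(th, w, prof, subj)
    taus <- seq(-subj$tau_df_max, subj$tau_pf_max, length.out = 10001)
    m <- prof$mass; g <- 9.81
    al <- angular_acceleration(th, w, taus, prof, "variable")
    fr <- reaction_forces(th, w, al, prof)
    up <- (taus - subj$ankle_height * fr$Fx) / fr$Fz
    ok <- fr$Fz > 0 & abs(fr$Fx) <= subj$mu * fr$Fz &
      up >= -subj$d_heel & up <= subj$d_toe
    step <- taus[2] - taus[1]
    if (!any(ok)) {
      # the analytic interval, if any, must be narrower than one scan step
      expect_true(!r$feasible || (r$tau_hi - r$tau_lo) < 2 * step)
    } else {
      expect_true(r$feasible)
      expect_equal(r$tau_lo, min(taus[ok]), tolerance = 2 * step)
      expect_equal(r$tau_hi, max(taus[ok]), tolerance = 2 * step)
    }
  }
})

test_that("zero torque limits leave at most the zero torque", {
  s <- subject_model(70, 1.75, tau_pf_max = 0, tau_df_max = 0)
  p <- fx_profile_const()
  r <- admissible_torque_range(1.8, -0.5, p, s)
  if (r$feasible) {
    expect_gte(r$tau_lo, 0)
    expect_lte(r$tau_hi, 0)
  } else {
    succeed()
  }
})

test_that("enlarging mu or torque limits never shrinks the torque interval", {
  p <- fx_profile_var()
  states <- list(c(1.4, -0.8), c(1.9, -0.5), c(2.2, -1.2))
  mus <- c(0.2, 0.5, 0.9)
  for (st in states) {
    prev <- NULL
    for (mu in mus) {
      s <- subject_model(70, 1.75, mu = mu)
      r <- admissible_torque_range(st[1], st[2], p, s)
      if (!is.null(prev) && prev$feasible && r$feasible) {
        expect_gte(r$tau_hi, prev$tau_hi - 1e-9)
        expect_lte(r$tau_lo, prev$tau_lo + 1e-9)
      }
      prev <- r
    }
    prev <- NULL
    for (k in c(0.5, 1, 2)) {
      s <- subject_model(70, 1.75, tau_pf_max = 2.2 * 70 * k,
                         tau_df_max = 0.7 * 70 * k)
      r <- admissible_torque_range(st[1], st[2], p, s)
      if (!is.null(prev) && prev$feasible && r$feasible) {
        expect_gte(r$tau_hi, prev$tau_hi - 1e-9)
        expect_lte(r$tau_lo, prev$tau_lo + 1e-9)
      }
      prev <- r
    }
  }
})

test_that("infeasible states are reported, not silently integrated", {
  p <- fx_profile_var()
  s <- fx_subject()
  r <- admissible_torque_range(2.3, -6, p, s)
  expect_false(r$feasible)
  expect_error(pendulum_step(2.3, -6, function(a, b, lo, hi) 0, p, s, 1e-3),
               "no admissible torque")
  sim <- simulate_pendulum(2.3, -6, function(a, b, lo, hi) 0, p, s)
  expect_true(sim$termination %in% c("slip", "tip", "torque-limit",
                                     "infeasible"))
})

test_that("zero-torque energy is conserved by the integrator", {
  p <- fx_profile_const()
  # relaxed constraints so the coasting pendulum stays admissible and the
  # check isolates the integrator
  s <- subject_model(70, 1.75, mu = 5, tau_pf_max = 1e5, tau_df_max = 1e5,
                     foot_length = 4, d_toe = 2, d_heel = 2)
  l <- p$a4; g <- 9.81
  th <- 1.60; w <- 0
  E0 <- 0.5 * l^2 * w^2 + g * l * sin(th)
  dt <- 1e-4
  for (i in 1:10000) {
    st <- pendulum_step(th, w, function(a, b, lo, hi) 0, p, s, dt)
    th <- st[1]; w <- st[2]
  }
  E1 <- 0.5 * l^2 * w^2 + g * l * sin(th)
  expect_lt(abs(E1 - E0) / abs(E0), 1e-8)
})

test_that("gravity-balancing policy holds the state constant", {
  p <- fx_profile_const()
  s <- fx_subject()
  th0 <- 1.45
  tau_eq <- 70 * 9.81 * p$a4 * cos(th0)
  sim <- simulate_pendulum(th0, 0, function(a, b, lo, hi) tau_eq, p, s,
                           dt = 1e-3, t_max = 1)
  expect_lt(max(abs(sim$trajectory$theta - th0)), 1e-9)
  expect_lt(max(abs(sim$trajectory$omega)), 1e-9)
})

test_that("the integrator converges at fourth order", {
  p <- fx_profile_var()
  s <- fx_subject()
  run <- function(dt) {
    th <- 1.9; w <- -0.4
    for (i in seq_len(round(0.4 / dt)))  {
      st <- pendulum_step(th, w, function(a, b, lo, hi) 10, p, s, dt)
      th <- st[1]; w <- st[2]
    }
    c(th, w)
  }
  e1 <- max(abs(run(2e-3) - run(1e-3)))
  e2 <- max(abs(run(1e-3) - run(5e-4)))
  expect_gt(e1 / e2, 8)   # ~16 for a 4th-order scheme
  expect_lt(e1 / e2, 40)
})
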