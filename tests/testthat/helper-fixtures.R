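# Shared fixtures. Balance maps are expensive (seconds each), so they are
# built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

fx_subject <- function() subject_model(mass = 70, height = 1.75)

fx_profile_var <- function() {
  fixture("profile_var", function() make_inertia_profile(fx_subject(), 0.15))
}

fx_profile_const <- function() {
  fixture("profile_const", function()
    constant_inertia_profile(l = 0.48 * 1.75, mass = 70,
                             theta_range = c(0.1, 3.0)))
}

fx_map_var <- function() {
  fixture("map_var", function()
    balance_map(fx_subject(), fx_profile_var(), "variable"))
}

fx_map_const_simple <- function() {
  fixture("map_const_simple", function()
    balance_map(fx_subject(), fx_profile_const(), "simple"))
}

fx_map_const_variable <- function() {
  fixture("map_const_variable", function()
    balance_map(fx_subject(), fx_profile_const(), "variable"))
}

# one-segment subject for marker-level unit tests (arbitrary marker names)
one_segment_subject <- function(sd = 0) {
  subject_model(
    mass = 70, height = 1.75,
    segment_table = data.frame(
      segment = "body", fraction = 1, fraction_sd = sd,
      proximal = "p1", distal = "d1", stringsAsFactors = FALSE))
}

# frames builder: positions is a named list of n x 3 matrices (x, y, z)
make_frames <- function(time, positions) {
  out <- data.frame(time = time)
  for (nm in names(positions)) {
    m <- positions[[nm]]
    out[[paste0(nm, "_x")]] <- m[, 1]
    out[[paste0(nm, "_y")]] <- m[, 2]
    out[[paste0(nm, "_z")]] <- m[, 3]
  }
  out
}

# closed-form simple-model zero-torque curve (energy conservation to the
# upright equilibrium of Eq. tau = 0): independent oracle, kept separate
# from the package's backward-integration path.
zero_torque_closed_form <- function(theta, l, height) {
  g <- 9.81
  omega <- -sqrt(pmax(0, 2 * g * (1 - sin(theta)) / l))
  -l * sin(theta) * omega / height
}
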