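#' Default five-segment mass-fraction table
#'
#' Sagittal-plane segment table used for centre-of-mass (CM) estimation from
#' marker data: head(+neck), trunk, thigh, shank and foot, with the arm
#' segments excluded and the remaining whole-body mass fractions renormalised
#' to sum to one. Fractions are standard anthropometric-table values; the
#' standard deviations express the between-subject uncertainty of the mass
#' distribution and drive [cm_position_error()]. Left/right lower-limb markers
#' are averaged into one sagittal-plane segment each, so marker columns hold
#' comma-separated marker names that are averaged before use.
#'
#' All values are configurable defaults: supply your own table (same columns)
#' to [subject_model()] to override them.
#'
#' @return A `data.frame` with columns `segment`, `fraction`, `fraction_sd`,
#'   `proximal`, `distal`.
#' @export
default_segment_table <- function() {
  data.frame(
    segment = c("head", "trunk", "thigh", "shank", "foot"),
    # whole-body fractions 0.081/0.497/0.200/0.093/0.029 renormalised by the
    # no-arm total 0.900
    fraction = c(0.081, 0.497, 0.200, 0.093, 0.029) / 0.9,
    fraction_sd = c(0.012, 0.042, 0.030, 0.014, 0.006),
    proximal = c("vertex", "c7", "hip_l,hip_r", "knee_l,knee_r",
                 "heel_l,heel_r"),
    distal = c("c7", "hip_l,hip_r", "knee_l,knee_r", "ankle_l,ankle_r",
               "toe_l,toe_r"),
    stringsAsFactors = FALSE
  )
}

#' Canonical synthetic marker set
#'
#' The 15-marker layout written by the synthetic generator: head vertex, C7,
#' sternum, and bilateral shoulder, hip, knee, ankle, heel and toe markers.
#' Sternum and shoulders are emitted for realism but not used by the default
#' segment table.
#'
#' @return Character vector of marker names.
#' @export
canonical_marker_set <- function() {
  c("vertex", "c7", "sternum",
    "shoulder_l", "shoulder_r", "hip_l", "hip_r", "knee_l", "knee_r",
    "ankle_l", "ankle_r", "heel_l", "heel_r", "toe_l", "toe_r")
}

#' Subject model: anthropometry and balance constraint parameters
#'
#' Bundles everything the pendulum models need to know about a subject: body
#' mass and height, foot geometry (horizontal ankle-to-toe and ankle-to-heel
#' distances, ankle height above the sole), the shoe-floor friction
#' coefficient, physiological ankle torque limits, and the segment
#' mass-fraction table used for CM estimation.
#'
#' Geometry defaults are standard anthropometric scalings of height
#' (foot length 0.152·height, ankle 25% of foot length from the heel, ankle
#' height 0.039·height). Torque-limit defaults are mass-scaled maxima for
#' healthy adults (plantarflexion 2.2 N·m/kg, dorsiflexion 0.7 N·m/kg); they
#' are chosen so that a static hold with the centre of pressure at the toe or
#' heel is within the limits, which anchors the feasibility-map boundaries at
#' the toe and heel.
#'
#' Sign conventions (used throughout the package): anterior = +x, up = +z,
#' ankle joint at the origin; positive ankle torque acts counterclockwise on
#' the body, i.e. the plantarflexion (braking) side; `d_toe` is anterior
#' positive, `d_heel` posterior positive.
#'
#' @param mass Body mass, kg.
#' @param height Body height, m.
#' @param foot_length Foot length, m.
#' @param d_toe Horizontal ankle-to-toe distance, m (anterior positive).
#' @param d_heel Horizontal ankle-to-heel distance, m (posterior positive);
#'   must satisfy `foot_length == d_toe + d_heel`.
#' @param ankle_height Ankle joint height above the sole, m.
#' @param mu Friction coefficient (dimensionless, >= 0).
#' @param tau_pf_max Maximum plantarflexion torque magnitude, N·m.
#' @param tau_df_max Maximum dorsiflexion torque magnitude, N·m.
#' @param segment_table Segment mass-fraction table, see
#'   [default_segment_table()].
#' @return An object of class `sts_subject`.
#' @examples
#' s <- subject_model(mass = 70, height = 1.75)
#' s$foot_length
#' @export
subject_model <- function(mass, height,
                          foot_length = 0.152 * height,
                          d_toe = 0.75 * foot_length,
                          d_heel = foot_length - d_toe,
                          ankle_height = 0.039 * height,
                          mu = 0.8,
                          tau_pf_max = 2.2 * mass,
                          tau_df_max = 0.7 * mass,
                          segment_table = default_segment_table()) {
  subject <- structure(
    list(mass = mass, height = height, foot_length = foot_length,
         d_toe = d_toe, d_heel = d_heel, ankle_height = ankle_height,
         mu = mu, tau_pf_max = tau_pf_max, tau_df_max = tau_df_max,
         segment_table = segment_table),
    class = "sts_subject")
  validate_subject(subject)
  subject
}

#' Validate a subject model
#'
#' Checks all `sts_subject` invariants and stops with an error naming the
#' offending field: positive mass/height, non-negative friction and torque
#' limits, foot-geometry consistency (`foot_length == d_toe + d_heel` within
#' 1e-9 m), and a segment table whose mass fractions sum to 1 within 1e-6.
#'
#' @param subject An `sts_subject` (or plain list with the same fields).
#' @return The subject, invisibly, if valid.
#' @export
validate_subject <- function(subject) {
  need <- c("mass", "height", "foot_length", "d_toe", "d_heel",
            "ankle_height", "mu", "tau_pf_max", "tau_df_max", "segment_table")
  miss <- setdiff(need, names(subject))
  if (length(miss) > 0L)
    stop("subject is missing field(s): ", paste(miss, collapse = ", "))
  num1 <- function(field) {
    v <- subject[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("subject field '", field, "' must be a single finite number")
    v
  }
  if (num1("mass") <= 0) stop("subject field 'mass' must be > 0")
  if (num1("height") <= 0) stop("subject field 'height' must be > 0")
  if (num1("mu") < 0) stop("subject field 'mu' must be >= 0")
  if (num1("tau_pf_max") < 0) stop("subject field 'tau_pf_max' must be >= 0")
  if (num1("tau_df_max") < 0) stop("subject field 'tau_df_max' must be >= 0")
  if (num1("ankle_height") < 0) stop("subject field 'ankle_height' must be >= 0")
  fl <- num1("foot_length")
  if (fl <= 0) stop("subject field 'foot_length' must be > 0")
  if (abs(fl - (num1("d_toe") + num1("d_heel"))) > 1e-9)
    stop("subject field 'foot_length' must equal d_toe + d_heel (within 1e-9 m)")
  st <- subject$segment_table
  cols <- c("segment", "fraction", "fraction_sd", "proximal", "distal")
  if (!is.data.frame(st) || !all(cols %in% names(st)))
    stop("subject field 'segment_table' must be a data.frame with columns ",
         paste(cols, collapse = ", "))
  if (abs(sum(st$fraction) - 1) > 1e-6)
    stop("subject field 'segment_table': mass fractions must sum to 1 within 1e-6 (got ",
         format(sum(st$fraction), digits = 10), ")")
  if (any(st$fraction <= 0))
    stop("subject field 'segment_table': fractions must be > 0")
  if (any(st$fraction_sd < 0))
    stop("subject field 'segment_table': fraction_sd must be >= 0")
  invisible(subject)
}

#' @export
print.sts_subject <- function(x, ...) {
  cat("<sts_subject>\n")
  cat(sprintf("  mass %.1f kg, height %.2f m, foot %.3f m (toe %.3f / heel %.3f)\n",
              x$mass, x$height, x$foot_length, x$d_toe, x$d_heel))
  cat(sprintf("  ankle height %.3f m, mu %.2f, tau_pf_max %.1f N.m, tau_df_max %.1f N.m\n",
              x$ankle_height, x$mu, x$tau_pf_max, x$tau_df_max))
  cat(sprintf("  %d segments: %s\n", nrow(x$segment_table),
              paste(x$segment_table$segment, collapse = ", ")))
  invisible(x)
}

#' Read / write a subject configuration (JSON)
#'
#' The JSON file carries the scalar `sts_subject` fields plus the segment
#' table as an array of records. Validation errors name the offending field.
#'
#' @param path Path to a JSON file.
#' @return `read_subject_json()` returns an `sts_subject`.
#' @export
read_subject_json <- function(path) {
  if (!file.exists(path)) stop("subject file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  st <- if (is.null(raw$segment_table)) default_segment_table() else
    as.data.frame(raw$segment_table, stringsAsFactors = FALSE)
  if (is.null(raw$mass)) stop("subject field 'mass' missing in ", path)
  if (is.null(raw$height)) stop("subject field 'height' missing in ", path)
  args <- list(mass = raw$mass, height = raw$height, segment_table = st)
  for (f in c("foot_length", "d_toe", "d_heel", "ankle_height", "mu",
              "tau_pf_max", "tau_df_max"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(subject_model, args)
}

#' @param subject An `sts_subject`.
#' @rdname read_subject_json
#' @export
write_subject_json <- function(subject, path) {
  validate_subject(subject)
  x <- unclass(subject)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

# Evaluate with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
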