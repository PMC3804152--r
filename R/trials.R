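# Trial-level analysis: classification of measured/synthetic sit-to-stand
# trials against a balance map, confusion statistics, and the
# energy-strategy comparison against the zero-torque trajectory.

#' Classify sit-to-stand trials against a balance map
#'
#' Applies [classify_state()] to every trial's seat-off state, using the
#' horizontal CM uncertainty `dx` as the error-bar half-width (a trial is
#' predicted stable only if the whole error bar is inside the boundaries).
#'
#' The positive class is a *successful* trial predicted *stable*:
#' sensitivity = stable-predicted successes / all successes, specificity =
#' unstable-predicted failures / all failures (set `positive = "failure"`
#' to swap the orientation). An empty class yields an `NA` statistic
#' (reported as undefined, never NaN-propagated).
#'
#' @param trials Data.frame with columns `trial_id`, `x_footlen`,
#'   `v_heights_per_s`, `outcome` (`"success"`/`"failure"`) and optionally
#'   `condition`.
#' @param map An `sts_balance_map`.
#' @param dx Error-bar half-width in foot lengths (scalar); use
#'   `dx_m / subject$foot_length` to convert from metres.
#' @param positive Which outcome is the positive class for sensitivity.
#' @return A list: `trials` (input plus `prediction` and `margin` columns),
#'   `confusion` (TP/FN/TN/FP counts), `sensitivity`, `specificity`
#'   (fractions in [0, 1] or NA).
#' @examples
#' # TP=10 FN=0 TN=14 FP=3 gives sensitivity 1, specificity 14/17
#' @export
classify_trials <- function(trials, map, dx = 0,
                            positive = c("success", "failure")) {
  positive <- match.arg(positive)
  need <- c("trial_id", "x_footlen", "v_heights_per_s", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0)
    stop("trials table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(trials$outcome %in% c("success", "failure")))
    stop("trials column 'outcome' must be 'success' or 'failure'")
  pred <- character(nrow(trials))
  marg <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    pred[i] <- classify_state(map, trials$x_footlen[i],
                              trials$v_heights_per_s[i], dx)
    marg[i] <- stability_margin(map, trials$x_footlen[i],
                                trials$v_heights_per_s[i], dx)
  }
  out <- trials
  out$prediction <- pred
  out$margin <- marg
  pos <- positive
  neg <- setdiff(c("success", "failure"), pos)
  pos_pred <- if (pos == "success") "stable" else "unstable"
  neg_pred <- setdiff(c("stable", "unstable"), pos_pred)
  tp <- sum(out$outcome == pos & pred == pos_pred)
  fn <- sum(out$outcome == pos & pred != pos_pred)
  tn <- sum(out$outcome == neg & pred == neg_pred)
  fp <- sum(out$outcome == neg & pred != neg_pred)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  list(trials = out,
       confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
       sensitivity = sens, specificity = spec)
}

#' Assign normal / demanding condition labels
#'
#' Splits trials at a threshold on the seat-off BOS-CM horizontal distance
#' (foot lengths). The often-quoted 2.48 foot lengths is an empirical value
#' from one cohort, not a constant of the method, hence configurable.
#'
#' @param trials Trials data.frame (see [classify_trials()]).
#' @param threshold Distance threshold, foot lengths.
#' @return The trials with a `condition` column (`"normal"`/`"demanding"`).
#' @export
assign_condition <- function(trials, threshold = 2.48) {
  trials$condition <- ifelse(trials$x_footlen >= threshold,
                             "demanding", "normal")
  trials
}

#' Energy-strategy classification of a CM trajectory
#'
#' Compares a post-seat-off CM trajectory, in map coordinates, with the
#' map's zero-torque curve: `"extra_energy"` if the trajectory stays more
#' than `delta` above the curve throughout, `"crossing"` if the sign of
#' `v - v_zero` changes, `"on_curve"` if `|v - v_zero| <= delta`
#' throughout.
#'
#' @param traj Data.frame with columns `x` and `v` (map coordinates).
#' @param map An `sts_balance_map`.
#' @param delta Tolerance band, heights/s.
#' @return One of `"extra_energy"`, `"crossing"`, `"on_curve"`.
#' @export
energy_strategy <- function(traj, map, delta = 0.01) {
  vz <- .map_v_at(map, "v_zero", traj$x)
  if (any(is.na(vz)))
    stop("trajectory extends outside the map's zero-torque curve range")
  d <- traj$v - vz
  if (all(abs(d) <= delta)) return("on_curve")
  above <- any(d > delta)
  below <- any(d < -delta)
  if (above && !below) return("extra_energy")
  # a dip below the efficiency curve (with or without excursions above it)
  # means the trajectory crosses / undershoots the zero-torque condition
  "crossing"
}

#' Read / write trial tables (CSV)
#'
#' Columns: `trial_id, x_footlen, v_heights_per_s, outcome, condition`;
#' classification results add `prediction, margin`.
#'
#' @param path CSV path.
#' @return `read_trials_csv()` returns the trials data.frame.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop("trials file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "x_footlen", "v_heights_per_s", "outcome")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("trials file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  d
}

#' @param trials Trials data.frame.
#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
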