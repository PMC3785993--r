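#' Read a tri-axial gait recording
#'
#' Reads a CSV with columns `time, x, y, z` (time in seconds, acceleration
#' in the unit declared by a leading comment line `# unit=g` or
#' `# unit=m/s2`; `g` assumed when absent). The sampling rate is inferred
#' from the median time step when not declared.
#'
#' @param path CSV file path.
#' @return A tibble of class `gait_recording` with columns `time`, `x`,
#'   `y`, `z` and attributes `sampling_rate` (Hz) and `unit`.
#' @export
read_gait_recording <- function(path) {
  if (!file.exists(path)) io_error(paste0("recording not found: ", path))
  head_lines <- readLines(path, n = 5)
  unit <- "g"
  m <- regmatches(head_lines, regexpr("^#\\s*unit=(\\S+)", head_lines))
  if (length(m)) unit <- sub("^#\\s*unit=", "", m[1])
  df <- readr::read_csv(path, comment = "#",
                        col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  miss <- setdiff(c("time", "x", "y", "z"), names(df))
  if (length(miss))
    data_error(paste0("recording lacks columns: ", paste(miss, collapse = ", ")))
  new_recording(df[c("time", "x", "y", "z")], unit = unit)
}

#' @rdname read_gait_recording
#' @param rec A `gait_recording`.
#' @export
write_gait_recording <- function(rec, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# unit=", attr(rec, "unit")), con)
  writeLines("time,x,y,z", con)
  writeLines(sprintf("%s,%s,%s,%s", fmt_num(rec$time), fmt_num(rec$x),
                     fmt_num(rec$y), fmt_num(rec$z)), con)
  invisible(path)
}

new_recording <- function(df, sampling_rate = NULL, unit = "g") {
  df <- as_tibble(df)
  if (nrow(df) < 2) data_error("a gait recording needs at least 2 samples")
  if (any(diff(df$time) <= 0))
    data_error("recording time column must be strictly increasing")
  rate <- sampling_rate %||% (1 / stats::median(diff(df$time)))
  structure(df, sampling_rate = rate, unit = unit,
            class = c("gait_recording", class(df)))
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %d samples @ %.6g Hz [%s]\n",
              nrow(x), attr(x, "sampling_rate"), attr(x, "unit")))
  NextMethod()
}

#' Filter and segment a gait recording
#'
#' Smooths each axis with a centered moving average of odd `window` samples
#' (the `(window - 1) / 2` edge samples without a full window are dropped)
#' and then trims `trim_seconds` from each end of the record, discarding
#' the unsteady start and stop of the walk.
#'
#' @param rec A `gait_recording`.
#' @param window Odd moving-average window length in samples
#'   (1 disables smoothing).
#' @param trim_seconds Duration removed from each end (0 disables
#'   trimming).
#' @return The preprocessed `gait_recording`.
#' @export
preprocess_recording <- function(rec, window = 5, trim_seconds = 1) {
  if (window < 1 || window %% 2 != 1)
    usage_error("smoothing window must be a positive odd integer")
  df <- as_tibble(rec)[c("time", "x", "y", "z")]
  if (window > 1) {
    half <- (window - 1) / 2
    sm <- function(v) as.numeric(stats::filter(v, rep(1 / window, window),
                                               sides = 2))
    df$x <- sm(df$x); df$y <- sm(df$y); df$z <- sm(df$z)
    keep <- seq_len(nrow(df)) > half & seq_len(nrow(df)) <= nrow(df) - half
    df <- df[keep, ]
  }
  if (trim_seconds > 0 && nrow(df)) {
    t0 <- min(df$time); t1 <- max(df$time)
    df <- df[df$time >= t0 + trim_seconds & df$time <= t1 - trim_seconds, ]
  }
  if (nrow(df) < 2)
    data_error("preprocessing left fewer than 2 samples; shorten the trim or the window")
  new_recording(df, sampling_rate = attr(rec, "sampling_rate"),
                unit = attr(rec, "unit"))
}

#' Gait dispersion measures from a tri-axial recording
#'
#' The 20 dispersion variables of the frailty schema, computed from a
#' preprocessed recording. Per axis (x, y, z): arithmetic mean; sample
#' standard deviation (n - 1); absolute mean difference (the mean absolute
#' deviation about the axis mean); variance (sd squared); amplitude
#' (max - min); and Pearson coefficient of variation `sd / |mean|`. From
#' the acceleration magnitude \eqn{m_t = \sqrt{x_t^2 + y_t^2 + z_t^2}}: its
#' mean (`acceleration_mean`) and sample sd (`acceleration_sd`). An axis
#' whose mean is exactly 0 has an undefined coefficient of variation,
#' reported as `NA` with a warning rather than an error.
#'
#' @param rec A preprocessed `gait_recording` with at least 2 samples.
#' @return A one-row tibble with the 20 dispersion variables, named as in
#'   the schema's dispersion group.
#' @examples
#' rec <- simulate_gait_signal(duration = 10, rate = 50, seed = 1)
#' dispersion_measures(preprocess_recording(rec))
#' @export
dispersion_measures <- function(rec) {
  df <- as_tibble(rec)
  if (nrow(df) < 2) data_error("dispersion measures need at least 2 samples")
  per_axis <- function(v, axis) {
    mu <- mean(v)
    sdv <- stats::sd(v)
    cv <- if (mu == 0) {
      warn(paste0("axis ", axis, " mean is exactly 0; Pearson CV undefined"))
      NA_real_
    } else sdv / abs(mu)
    stats::setNames(
      c(mu, sdv, mean(abs(v - mu)), sdv^2, max(v) - min(v), cv),
      paste0(axis, "_", c("arithmetic_mean", "standard_deviation",
                          "absolute_mean_difference", "variance",
                          "amplitude", "pearson_cv")))
  }
  m <- sqrt(df$x^2 + df$y^2 + df$z^2)
  vals <- c(per_axis(df$x, "x"), per_axis(df$y, "y"), per_axis(df$z, "z"),
            acceleration_mean = mean(m), acceleration_sd = stats::sd(m))
  as_tibble(as.list(vals[dispersion_variable_names()]))
}

#' Attach dispersion measures to a patient instance
#'
#' Sets the 20 dispersion variables of the given instance to `present`
#' with the supplied values; every other variable is untouched. Re-attaching
#' overwrites. A measure that is `NA` (an undefined Pearson CV) is stored
#' as `missing`.
#'
#' @param stack A `frailty_stack`.
#' @param instance_id Instance to update.
#' @param dm One-row tibble from [dispersion_measures()].
#' @return The updated `frailty_stack`.
#' @export
attach_dispersion <- function(stack, instance_id, dm) {
  if (!instance_id %in% stack$instance_id)
    data_error(paste0("instance ", instance_id, " not in stack"))
  vals <- unlist(dm[1, dispersion_variable_names()])
  rows <- stack$instance_id == instance_id &
    stack$variable %in% dispersion_variable_names()
  ord <- match(stack$variable[rows], dispersion_variable_names())
  stack$value_num[rows] <- unname(vals[ord])
  stack$value_chr[rows] <- NA_character_
  stack$state[rows] <- ifelse(is.na(vals[ord]), "missing", "present")
  stack
}
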