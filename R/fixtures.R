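#' Synthetic cohort specification
#'
#' Defaults emulate the study cohort: 20 nursing-home residents, 10 women
#' (age mean 85.43, sd 3.22 years) and 10 men (age mean 81.80, sd 4.74
#' years), each assessed over 3 iterations. Ages are *moment-matched*: a
#' seeded normal draw is affinely rescaled so the per-sex sample mean and
#' sample sd equal the spec exactly.
#'
#' @param n_male,n_female Patient counts per sex.
#' @param male_age_mean,male_age_sd,female_age_mean,female_age_sd Years.
#' @param iterations Assessments per patient.
#' @param seed Integer RNG seed; the generated stack is a pure function of
#'   the spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 10, n_female = 10,
                        male_age_mean = 81.80, male_age_sd = 4.74,
                        female_age_mean = 85.43, female_age_sd = 3.22,
                        iterations = 3, seed = 1L) {
  if (n_male < 0 || n_female < 0) usage_error("counts must be >= 0")
  if (male_age_sd < 0 || female_age_sd < 0) usage_error("age sds must be >= 0")
  if ((n_male < 2 && male_age_sd > 0 && n_male > 0) ||
      (n_female < 2 && female_age_sd > 0 && n_female > 0))
    usage_error("need at least 2 patients per sex to match a positive age sd")
  structure(list(n_male = n_male, n_female = n_female,
                 male_age_mean = male_age_mean, male_age_sd = male_age_sd,
                 female_age_mean = female_age_mean, female_age_sd = female_age_sd,
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Builds a fully valid `frailty_stack` under the given [cohort_spec()]:
#' per-sex ages moment-matched to the spec, quantitative baseline values
#' drawn uniformly within each variable's schema range, qualitative values
#' uniformly over the declared categories, binary syndrome flags with
#' prevalence 0.3. Later iterations evolve each patient's quantitative
#' values as `previous + shift + noise` (`noise` Gaussian with sd
#' `noise_frac` of the variable's schema range), which makes per-stage
#' mean shifts recoverable; qualitative and binary values are carried
#' unchanged.
#'
#' @param spec A [cohort_spec()].
#' @param stage_shift Named numeric: per-iteration additive shift applied
#'   to the named quantitative variables (e.g. `c(weight = -5)` makes mean
#'   weight drop 5 kg per stage). Unnamed variables shift 0.
#' @param noise_frac Within-subject iteration-to-iteration noise sd, as a
#'   fraction of each variable's schema range.
#' @param missing_rate Probability that a non-demographic value is missing.
#' @return A `frailty_stack`.
#' @examples
#' stk <- generate_cohort(cohort_spec(seed = 42))
#' mean(stack_instances(stk)$age[stack_instances(stk)$sex == "F" &
#'                               stack_instances(stk)$iteration == 1])
#' @export
generate_cohort <- function(spec = cohort_spec(), stage_shift = numeric(),
                            noise_frac = 0.05, missing_rate = 0) {
  schema <- frailty_schema()
  with_seed(spec$seed, {
    ages_m <- moment_matched(spec$n_male, spec$male_age_mean, spec$male_age_sd)
    ages_f <- moment_matched(spec$n_female, spec$female_age_mean, spec$female_age_sd)
    patients <- tibble(
      patient_id = sprintf("P%02d", seq_len(spec$n_male + spec$n_female)),
      sex = c(rep("M", spec$n_male), rep("F", spec$n_female)),
      age = c(ages_m, ages_f))
    n_pat <- nrow(patients)

    shift <- stats::setNames(rep(0, nrow(schema)), schema$name)
    if (length(stage_shift)) shift[names(stage_shift)] <- stage_shift
    rng <- ifelse(is.na(schema$hi - schema$lo), 1, schema$hi - schema$lo)

    rows <- vector("list", spec$iterations)
    base <- NULL
    for (it in seq_len(spec$iterations)) {
      vals <- vector("list", n_pat)
      for (p in seq_len(n_pat)) {
        if (it == 1) {
          v_num <- rep(NA_real_, nrow(schema))
          qn <- schema$kind == "quantitative"
          v_num[qn] <- stats::runif(sum(qn), schema$lo[qn], schema$hi[qn])
          v_chr <- vapply(schema$categories, function(cs)
            if (is.null(cs)) NA_character_ else sample(cs, 1), character(1))
          v_chr[schema$kind == "binary"] <-
            ifelse(stats::runif(sum(schema$kind == "binary")) < 0.3, "true", "false")
        } else {
          v_num <- base[[p]]$value_num + shift +
            stats::rnorm(nrow(schema), 0, noise_frac * rng)
          v_chr <- base[[p]]$value_chr
        }
        v_num[schema$kind != "quantitative"] <- NA_real_
        v_chr[schema$kind == "quantitative"] <- NA_character_
        # demographics mirror the instance metadata
        v_chr[schema$name == "gender"] <- patients$sex[p]
        v_num[schema$name == "age_years"] <- patients$age[p]
        state <- rep("present", nrow(schema))
        if (missing_rate > 0) {
          drop <- stats::runif(nrow(schema)) < missing_rate &
            !schema$name %in% c("gender", "age_years")
          state[drop] <- "missing"
          v_num[drop] <- NA_real_; v_chr[drop] <- NA_character_
        }
        # missingness persists across iterations: no value, no state
        gone <- (schema$kind == "quantitative" & is.na(v_num)) |
          (schema$kind != "quantitative" & is.na(v_chr))
        state[gone] <- "missing"
        v_num <- unname(v_num); v_chr <- unname(v_chr)
        vals[[p]] <- tibble(
          patient_id = patients$patient_id[p],
          instance_id = (it - 1L) * n_pat + p,
          iteration = it, sex = patients$sex[p], age = patients$age[p],
          variable = schema$name, state = state,
          value_num = v_num, value_chr = v_chr)
      }
      base <- vals  # carried forward as the next iteration's baseline
      rows[[it]] <- bind_rows(vals)
    }
    frailty_stack(bind_rows(rows), schema)
  })
}

# Affine rescaling of a normal draw to hit the sample mean and sd exactly.
moment_matched <- function(n, mean, sd) {
  if (n == 0) return(numeric())
  if (n == 1) return(mean)
  z <- stats::rnorm(n)
  if (sd == 0) return(rep(mean, n))
  mean + sd * (z - base::mean(z)) / stats::sd(z)
}

# Per-patient / per-iteration / per-group state pattern transcribed from the
# study's instance tables. Entries: integer = number of present values
# (the first n variables of the group), "k" = whole group carried forward,
# NA = the patient has no instance at that iteration.
table_pattern <- function() {
  sex <- c(rep("M", 5), rep("F", 10), rep("M", 5))
  list(
    sex = sex,
    anthropometric = list(
      it1 = c(9, 9, 9, 9, 8, 9, 8, 8, 9, 8, 9, 9, 9, 2, 9, 9, 9, 9, 9, 9),
      it2 = rep(8, 20),
      it3 = c(rep(8, 5), NA, rep(8, 7), NA, rep(8, 6))),
    functional = list(
      it1 = c(4, 5, 4, 5, 4, 4, 5, 4, 4, 5, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4),
      it2 = rep("k", 20),
      it3 = c(rep(0, 5), NA, rep(0, 7), NA, rep(0, 6))),
    nutritional = list(
      it1 = c(11, 11, 0, 12, 11, 11, 12, 12, 12, 12, 11, 11, 11, 10, 11, 12, 12, 12, 12, 11),
      it2 = c(9, 8, 7, 8, 8, 10, 7, 9, 8, 8, 10, 10, 9, 10, 12, 10, 10, 9, 9, 9),
      it3 = c(8, 8, 0, 8, 9, NA, 8, 8, 8, 8, 9, 9, 9, NA, 10, 10, 9, 10, 9, 9)),
    cognitive = list(
      it1 = c(2, 1, 0, 1, 0, 1, 1, 1, 0, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1),
      it2 = rep(0, 20),
      it3 = c(rep(0, 5), NA, rep(0, 7), NA, rep(0, 6))),
    geriatric_syndromes = list(
      it1 = rep(11, 20),
      it2 = rep("k", 20),   # patient 6's shifted row read as it2 = kept
      it3 = c(rep("k", 5), NA, rep("k", 7), NA, rep("k", 6))),
    dispersion = list(
      it1 = rep(17, 20),
      it2 = rep(0, 20),
      it3 = c(rep(20, 5), NA, rep(20, 7), NA, rep(20, 6)))
  )
}

#' The packaged study-pattern fixture stack
#'
#' A synthetic 20-patient stack whose present / kept / missing states
#' reproduce, patient by patient and group by group, the per-iteration
#' existing-value pattern of the study's instance tables: iteration-1
#' instances are numbered 1-20, iteration-2 instances 22-41, iteration-3
#' instances 47-64, and patients 6 and 14 have no third instance. Values
#' are synthetic (drawn under a fixed packaged seed); only the structure,
#' counts and demographics emulate the study. Under this pattern the
#' iteration-1 existing-value total is 1057 and the iteration-2 total
#' (counting resolvable kept values, see [count_existing_values()]) is 644.
#'
#' @return A `frailty_stack` of 58 instances.
#' @export
table_pattern_fixture <- function() {
  schema <- frailty_schema()
  pat <- table_pattern()
  groups <- schema_groups
  base <- generate_cohort(cohort_spec(seed = 20130904))
  # reuse the moment-matched demographic draw but override ids/states
  meta1 <- stack_instances(base) |> filter(.data$iteration == 1)
  # patients 1-5 and 16-20 are male, 6-15 female, to match the study rows
  males <- meta1$patient_id[meta1$sex == "M"]
  females <- meta1$patient_id[meta1$sex == "F"]
  patient_order <- c(males[1:5], females, males[6:10])

  it3_ids <- integer(20); it3_ids[] <- NA_integer_
  have3 <- setdiff(1:20, c(6, 14))
  it3_ids[have3] <- 46L + seq_along(have3)
  inst_id <- function(p, it) switch(it, p, 21L + p, it3_ids[p])

  rows <- list()
  for (p in 1:20) {
    pid <- patient_order[p]
    pmeta <- meta1[meta1$patient_id == pid, ]
    for (it in 1:3) {
      id <- inst_id(p, it)
      if (is.na(id)) next
      states <- character(0); vars <- character(0)
      for (g in groups) {
        gv <- schema$name[schema$group == g]
        cell <- pat[[g]][[paste0("it", it)]][p]
        st <- if (identical(cell, "k")) rep("kept", length(gv)) else {
          k <- as.integer(cell)
          c(rep("present", k), rep("missing", length(gv) - k))
        }
        states <- c(states, st); vars <- c(vars, gv)
      }
      sub <- as_tibble(base) |>
        filter(.data$patient_id == pid, .data$iteration == it) |>
        mutate(instance_id = as.integer(id))
      ord <- match(vars, sub$variable)
      sub$state <- "missing"
      sub$state[ord] <- states
      sub$value_num[sub$state != "present"] <- NA_real_
      sub$value_chr[sub$state != "present"] <- NA_character_
      rows[[length(rows) + 1]] <- sub
    }
  }
  frailty_stack(bind_rows(rows), schema)
}

#' Simulate a tri-axial gait signal
#'
#' A deterministic test signal: per-axis sinusoids at the step frequency
#' (the z axis carries a 1 g gravity offset and a double-frequency
#' component, as a waist-worn sensor shows) plus seeded Gaussian noise.
#'
#' @param duration Seconds.
#' @param rate Sampling rate, Hz.
#' @param step_frequency Step frequency, Hz.
#' @param amplitude Sinusoid amplitude, g.
#' @param noise_sd Gaussian noise sd, g.
#' @param seed Integer RNG seed.
#' @return A `gait_recording`.
#' @export
simulate_gait_signal <- function(duration = 10, rate = 50, step_frequency = 1.8,
                                 amplitude = 0.3, noise_sd = 0.02, seed = 1L) {
  if (rate <= 0) usage_error("sampling rate must be positive")
  n <- floor(duration * rate)
  if (n < 2) usage_error("duration * rate must be at least 2 samples")
  t <- (seq_len(n) - 1) / rate
  with_seed(seed, {
    w <- 2 * pi * step_frequency
    df <- tibble(
      time = t,
      x = amplitude * sin(w * t) + stats::rnorm(n, 0, noise_sd),
      y = 0.6 * amplitude * sin(w * t + pi / 2) + stats::rnorm(n, 0, noise_sd),
      z = 1 + 0.8 * amplitude * sin(2 * w * t) + stats::rnorm(n, 0, noise_sd))
    new_recording(df, sampling_rate = rate, unit = "g")
  })
}
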