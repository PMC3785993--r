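# Independent reference implementations and small stack builders used
# across the suite. The oracles deliberately share no code with the
# package's vectorised paths: plain loops, two-pass formulas.

# Build a small schema from a kind specification, e.g.
# mini_schema(q = c("a", "b"), c = "col", b = "flag").
mini_schema <- function(q = character(), c = character(), b = character(),
                        categories = list()) {
  rows <- list()
  groups <- c("anthropometric", "functional", "nutritional",
              "cognitive", "geriatric_syndromes", "dispersion")
  gi <- 0
  nxt <- function() { gi <<- gi %% length(groups) + 1; groups[gi] }
  for (v in q) rows[[length(rows) + 1]] <- tibble::tibble(
    name = v, group = nxt(), kind = "quantitative", unit = "kg",
    default_weight = 1, categories = list(NULL), lo = 0, hi = 10)
  for (v in c) rows[[length(rows) + 1]] <- tibble::tibble(
    name = v, group = nxt(), kind = "qualitative", unit = "",
    default_weight = 1,
    categories = list(categories[[v]] %||% c("red", "green", "blue")),
    lo = NA_real_, hi = NA_real_)
  for (v in b) rows[[length(rows) + 1]] <- tibble::tibble(
    name = v, group = nxt(), kind = "binary", unit = "",
    default_weight = 1, categories = list(NULL), lo = NA_real_, hi = NA_real_)
  sch <- dplyr::bind_rows(rows)
  class(sch) <- c("frailty_schema", class(sch))
  sch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a stack from a wide list: values[[instance_id]] is a named list of
# variable values (NA = missing; "k" not supported here). All instances are
# iteration 1 of distinct patients unless meta overrides.
mini_stack <- function(values, schema, meta = NULL) {
  rows <- list()
  ids <- as.integer(names(values))
  for (q in seq_along(values)) {
    id <- ids[q]
    m <- if (is.null(meta)) list(patient_id = paste0("P", id), iteration = 1L,
                                 sex = "M", age = 80)
         else meta[[q]]
    for (v in schema$name) {
      val <- values[[q]][[v]]
      is_miss <- is.null(val) || (length(val) == 1 && is.na(val))
      kind <- schema$kind[schema$name == v]
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = m$patient_id, instance_id = id,
        iteration = m$iteration, sex = m$sex, age = m$age, variable = v,
        state = if (is_miss) "missing" else "present",
        value_num = if (!is_miss && kind == "quantitative") as.numeric(val)
                    else NA_real_,
        value_chr = if (!is_miss && kind != "quantitative") as.character(val)
                    else NA_character_)
    }
  }
  frailty_stack(dplyr::bind_rows(rows), schema)
}

# Term-by-term Gower oracle: direct evaluation of the weighted sum with
# explicit per-variable loops; missing handling and binary modes per the
# same contract as the package, but via scalar logic.
gower_oracle <- function(stack, i, j, weights, binary_mode = "symmetric") {
  schema <- stack_schema(stack)
  w <- stats::setNames(rep(0, nrow(schema)), schema$name)
  w[weights$variable] <- weights$weight
  num <- 0; den <- 0
  for (k in seq_len(nrow(schema))) {
    v <- schema$name[k]
    ri <- stack[stack$instance_id == i & stack$variable == v, ]
    rj <- stack[stack$instance_id == j & stack$variable == v, ]
    if (ri$state != "present" || rj$state != "present") next
    if (schema$kind[k] == "quantitative") {
      all_v <- stack$value_num[stack$variable == v & stack$state == "present"]
      R <- max(all_v) - min(all_v)
      s <- if (R == 0) 1 else 1 - abs(ri$value_num - rj$value_num) / R
      delta <- 1
    } else if (schema$kind[k] == "binary" && binary_mode == "asymmetric") {
      if (ri$value_chr == "false" && rj$value_chr == "false") next
      s <- as.numeric(ri$value_chr == rj$value_chr)
      delta <- 1
    } else {
      s <- as.numeric(ri$value_chr == rj$value_chr)
      delta <- 1
    }
    num <- num + w[[v]] * delta * s
    den <- den + w[[v]] * delta
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Two-pass reference statistics for one axis of a recording.
reference_axis_stats <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  ss <- sum((v - mu)^2)
  sdv <- sqrt(ss / (n - 1))
  list(mean = mu, sd = sdv, amd = sum(abs(v - mu)) / n, var = ss / (n - 1),
       amplitude = max(v) - min(v),
       cv = if (mu == 0) NA_real_ else sdv / abs(mu))
}

# A random mixed-type stack of n instances over <= 8 variables with
# missingness, for oracle comparison.
random_small_stack <- function(seed, n = 5, miss_p = 0.2) {
  set.seed(seed)
  sch <- mini_schema(q = c("wt", "ht", "lab"), c = c("col"), b = c("fl", "fr"))
  vals <- lapply(seq_len(n), function(i) {
    v <- list(wt = runif(1, 0, 10), ht = runif(1, 0, 10),
              lab = runif(1, 0, 10),
              col = sample(c("red", "green", "blue"), 1),
              fl = sample(c("true", "false"), 1),
              fr = sample(c("true", "false"), 1))
    for (nm in names(v)) if (runif(1) < miss_p) v[[nm]] <- NA
    v
  })
  names(vals) <- seq_len(n)
  mini_stack(vals, sch)
}

new_recording_for_test <- function(x, y, z, rate) {
  n <- length(x)
  frailmap:::new_recording(
    tibble::tibble(time = (seq_len(n) - 1) / rate, x = x, y = y, z = z),
    sampling_rate = rate)
}

random_weights <- function(schema, seed) {
  set.seed(seed)
  tibble::tibble(variable = schema$name,
                 weight = round(runif(nrow(schema)), 2))
}
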