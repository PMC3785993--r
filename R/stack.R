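#' Build a patient stack from a long value table
#'
#' A patient stack is the stored collection of patient instances against
#' which a studied patient is compared. Internally it is a *long* tibble:
#' one row per instance x schema variable, with an explicit `state` column
#' (`"present"`, `"missing"` or `"kept"`). Quantitative values live in
#' `value_num`, qualitative and binary values in `value_chr` (binary as
#' `"true"`/`"false"`). An optional `unit` column tags quantitative values
#' measured in a non-canonical unit (see [normalize_units()]).
#'
#' Missing instance x variable combinations are completed with state
#' `"missing"`, so a valid stack is always dense: `nrow(stack)` equals
#' `n_instances * nrow(schema)`.
#'
#' @param values Data frame with columns `patient_id`, `instance_id`,
#'   `iteration`, `sex`, `age`, `variable`, `state`, and `value_num`,
#'   `value_chr` (either may be omitted if unused).
#' @param schema A [frailty_schema()] tibble.
#' @return A tibble of class `frailty_stack` with the schema attached as the
#'   `"schema"` attribute.
#' @export
frailty_stack <- function(values, schema = frailty_schema()) {
  values <- as_tibble(values)
  if (!"value_num" %in% names(values)) values$value_num <- NA_real_
  if (!"value_chr" %in% names(values)) values$value_chr <- NA_character_
  if (!"unit" %in% names(values)) values$unit <- NA_character_
  required <- c("patient_id", "instance_id", "iteration", "sex", "age",
                "variable", "state")
  miss <- setdiff(required, names(values))
  if (length(miss))
    data_error(paste0("stack is missing columns: ", paste(miss, collapse = ", ")))
  unknown <- setdiff(unique(values$variable), schema$name)
  if (length(unknown))
    data_error(paste0("unknown variables not in schema: ",
                      paste(unknown, collapse = ", ")))

  meta <- distinct(values, .data$patient_id, .data$instance_id,
                   .data$iteration, .data$sex, .data$age)
  if (anyDuplicated(meta$instance_id))
    data_error("duplicate instance_id in stack")

  # densify: every instance carries a row for every schema variable
  grid <- tidyr::expand_grid(meta, variable = schema$name)
  out <- grid |>
    left_join(values, by = c("patient_id", "instance_id", "iteration",
                             "sex", "age", "variable")) |>
    mutate(state = ifelse(is.na(.data$state), "missing", .data$state)) |>
    mutate(variable = factor(.data$variable, levels = schema$name)) |>
    arrange(.data$instance_id, .data$variable) |>
    mutate(variable = as.character(.data$variable))
  out <- out[, c(required, "value_num", "value_chr", "unit")]
  out$value_num <- unname(out$value_num)
  out$value_chr <- unname(out$value_chr)
  new_stack(out, schema)
}

new_stack <- function(values, schema) {
  attr(values, "schema") <- schema
  class(values) <- unique(c("frailty_stack", class(values)))
  values
}

#' @export
print.frailty_stack <- function(x, ...) {
  meta <- stack_instances(x)
  cat(sprintf("<frailty_stack> %d instances, %d patients, %d variables\n",
              nrow(meta), length(unique(meta$patient_id)),
              nrow(stack_schema(x))))
  NextMethod()
}

#' Schema and instance metadata of a stack
#'
#' @param stack A `frailty_stack`.
#' @return `stack_schema()` returns the attached `frailty_schema`;
#'   `stack_instances()` one metadata row per instance.
#' @export
stack_schema <- function(stack) attr(stack, "schema")

#' @rdname stack_schema
#' @export
stack_instances <- function(stack) {
  distinct(as_tibble(stack), .data$patient_id, .data$instance_id,
           .data$iteration, .data$sex, .data$age)
}

#' Read and write a patient stack as CSV
#'
#' The CSV dialect is wide: header `patient_id, instance_id, iteration, sex,
#' age`, then the schema variables in schema order. An empty cell is a
#' missing value; the literal `k` marks a value kept (carried forward) from
#' the patient's previous instance, legal only for iterations greater
#' than 1; binary cells are `true`/`false`; the decimal separator is `.`.
#'
#' @param path CSV file path.
#' @param schema A [frailty_schema()] tibble.
#' @return `read_stack()` returns a `frailty_stack`; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path, schema = frailty_schema()) {
  if (!file.exists(path)) io_error(paste0("stack file not found: ", path))
  wide <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  id_cols <- c("patient_id", "instance_id", "iteration", "sex", "age")
  miss <- setdiff(id_cols, names(wide))
  if (length(miss))
    data_error(paste0("stack CSV lacks id columns: ", paste(miss, collapse = ", ")))
  vars <- setdiff(names(wide), id_cols)
  unknown <- setdiff(vars, schema$name)
  if (length(unknown))
    data_error(paste0("unknown variables not in schema: ",
                      paste(unknown, collapse = ", ")))
  if (anyDuplicated(wide$instance_id))
    data_error("duplicate instance_id in stack file")

  long <- wide |>
    pivot_longer(all_of(vars), names_to = "variable", values_to = "cell") |>
    mutate(instance_id = as.integer(.data$instance_id),
           iteration = as.integer(.data$iteration),
           age = as.numeric(.data$age))

  kind <- stats::setNames(schema$kind, schema$name)
  parsed <- parse_cells(long$cell, kind[long$variable], long$iteration,
                        long$instance_id, long$variable)
  out <- long |>
    mutate(state = parsed$state, value_num = parsed$value_num,
           value_chr = parsed$value_chr) |>
    select(-"cell")
  frailty_stack(out, schema)
}

# Vectorised cell parser for the wide CSV dialect.
parse_cells <- function(cell, kind, iteration, instance_id, variable) {
  cell <- ifelse(is.na(cell), "", trimws(cell))
  state <- rep("present", length(cell))
  state[cell == ""] <- "missing"
  state[cell == "k"] <- "kept"
  bad_kept <- state == "kept" & iteration <= 1L
  if (any(bad_kept)) {
    i <- which(bad_kept)[1]
    data_error(sprintf(
      "kept marker 'k' in an iteration-1 row (instance %s, variable %s): no earlier value to keep",
      instance_id[i], variable[i]))
  }
  value_num <- rep(NA_real_, length(cell))
  value_chr <- rep(NA_character_, length(cell))
  pres <- state == "present"

  qn <- pres & kind == "quantitative"
  suppressWarnings(value_num[qn] <- as.numeric(cell[qn]))
  bad <- qn & is.na(value_num)
  if (any(bad)) {
    i <- which(bad)[1]
    data_error(sprintf("malformed numeric cell '%s' (instance %s, variable %s)",
                       cell[i], instance_id[i], variable[i]))
  }

  bn <- pres & kind == "binary"
  bl <- tolower(cell)
  bad <- bn & !bl %in% c("true", "false")
  if (any(bad)) {
    i <- which(bad)[1]
    data_error(sprintf("malformed binary cell '%s' (instance %s, variable %s): expected true/false",
                       cell[i], instance_id[i], variable[i]))
  }
  value_chr[bn] <- bl[bn]

  ql <- pres & kind == "qualitative"
  value_chr[ql] <- cell[ql]
  list(state = state, value_num = value_num, value_chr = value_chr)
}

#' @rdname read_stack
#' @param stack A `frailty_stack`.
#' @export
write_stack <- function(stack, path) {
  schema <- stack_schema(stack)
  kind <- stats::setNames(schema$kind, schema$name)
  cells <- dplyr::case_when(
    stack$state == "missing" ~ "",
    stack$state == "kept" ~ "k",
    kind[stack$variable] == "quantitative" ~ fmt_num(stack$value_num),
    TRUE ~ stack$value_chr
  )
  wide <- as_tibble(stack) |>
    mutate(cell = cells) |>
    select("patient_id", "instance_id", "iteration", "sex", "age",
           "variable", "cell") |>
    mutate(variable = factor(.data$variable, levels = schema$name)) |>
    pivot_wider(names_from = "variable", values_from = "cell") |>
    arrange(.data$instance_id)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Resolve carried-forward ("kept") values
#'
#' Replaces every `kept` value by the same patient's most recent *present*
#' value of that variable from an earlier iteration; a kept value with no
#' such antecedent becomes `missing`. The operation is idempotent and the
#' resolved stack contains no `kept` states.
#'
#' @param stack A `frailty_stack`.
#' @return The resolved `frailty_stack`.
#' @export
resolve_kept <- function(stack) {
  schema <- stack_schema(stack)
  df <- as_tibble(stack) |>
    group_by(.data$patient_id, .data$variable) |>
    arrange(.data$iteration, .by_group = TRUE) |>
    mutate(
      # last present row at-or-before each row; a kept row is never present,
      # so for kept rows this is strictly earlier
      prev = cummax(ifelse(.data$state == "present", dplyr::row_number(), 0L)),
      value_num = ifelse(.data$state == "kept" & .data$prev > 0,
                         .data$value_num[pmax(.data$prev, 1L)], .data$value_num),
      value_chr = ifelse(.data$state == "kept" & .data$prev > 0,
                         .data$value_chr[pmax(.data$prev, 1L)], .data$value_chr),
      state = ifelse(.data$state == "kept",
                     ifelse(.data$prev > 0, "present", "missing"), .data$state)
    ) |>
    ungroup() |>
    select(-"prev") |>
    arrange(.data$instance_id, factor(.data$variable, levels = schema$name))
  new_stack(df, schema)
}

#' Count existing values in one iteration
#'
#' The number of variables carrying a value across all instances of the
#' given iteration. With `count_kept = TRUE`, kept values that resolve to an
#' earlier present value (see [resolve_kept()]) are counted as well, which
#' is the accounting under which the study's iteration totals are
#' reproduced.
#'
#' @param stack A `frailty_stack`.
#' @param iteration Iteration number.
#' @param count_kept Also count resolvable kept values?
#' @return Integer count.
#' @export
count_existing_values <- function(stack, iteration, count_kept = FALSE) {
  it <- iteration
  n_present <- sum(stack$state == "present" & stack$iteration == it)
  if (!count_kept) return(n_present)
  res <- resolve_kept(stack)
  was_kept <- stack$state == "kept" & stack$iteration == it
  key <- paste(stack$instance_id, stack$variable)
  rkey <- paste(res$instance_id, res$variable)
  resolved_present <- res$state[match(key[was_kept], rkey)] == "present"
  n_present + sum(resolved_present)
}

#' Validate a patient stack
#'
#' Report-based validation: every invariant violation yields one finding
#' row; an empty report means the stack is valid.
#'
#' @param stack A `frailty_stack`.
#' @return A tibble with columns `finding`, `instance_id`, `variable`,
#'   `message` (zero rows when valid).
#' @export
validate_stack <- function(stack) {
  schema <- stack_schema(stack)
  findings <- list()
  add <- function(finding, instance_id, variable, message) {
    findings[[length(findings) + 1]] <<- tibble(
      finding = finding, instance_id = as.integer(instance_id),
      variable = as.character(variable), message = message)
  }

  meta <- distinct(as_tibble(stack), .data$patient_id, .data$instance_id,
                   .data$iteration, .data$sex, .data$age)
  dup <- meta$instance_id[duplicated(meta$instance_id)]
  for (id in unique(dup)) add("integrity", id, NA, "duplicate instance_id")

  unknown <- setdiff(unique(stack$variable), schema$name)
  for (v in unknown) add("schema", NA, v, "variable not in schema")

  bad_sex <- meta[!meta$sex %in% c("M", "F"), ]
  for (i in seq_len(nrow(bad_sex)))
    add("range", bad_sex$instance_id[i], NA,
        paste0("sex must be M or F, got ", bad_sex$sex[i]))
  bad_age <- meta[!is.na(meta$age) & (meta$age < 0 | meta$age > 130), ]
  for (i in seq_len(nrow(bad_age)))
    add("range", bad_age$instance_id[i], NA,
        paste0("implausible age ", bad_age$age[i]))

  kind <- stats::setNames(schema$kind, schema$name)
  cats <- stats::setNames(schema$categories, schema$name)
  known <- stack$variable %in% schema$name
  pres <- stack$state == "present" & known
  k <- kind[stack$variable]

  bad_type <- pres & k == "quantitative" & is.na(stack$value_num)
  bad_type <- bad_type | (pres & k != "quantitative" & is.na(stack$value_chr))
  for (i in which(bad_type))
    add("type", stack$instance_id[i], stack$variable[i],
        "present value of the wrong kind for this variable")

  bad_bin <- pres & k == "binary" & !is.na(stack$value_chr) &
    !stack$value_chr %in% c("true", "false")
  for (i in which(bad_bin))
    add("type", stack$instance_id[i], stack$variable[i],
        paste0("binary value must be true/false, got ", stack$value_chr[i]))

  qual <- which(pres & k == "qualitative" & !is.na(stack$value_chr))
  for (i in qual) {
    cs <- cats[[stack$variable[i]]]
    if (!is.null(cs) && !stack$value_chr[i] %in% cs)
      add("type", stack$instance_id[i], stack$variable[i],
          paste0("category '", stack$value_chr[i], "' not in declared set"))
  }

  bad_kept <- stack$state == "kept" & stack$iteration <= 1
  for (i in which(bad_kept))
    add("integrity", stack$instance_id[i], stack$variable[i],
        "kept marker in an iteration-1 instance")

  if (length(findings)) bind_rows(findings)
  else tibble(finding = character(), instance_id = integer(),
              variable = character(), message = character())
}
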