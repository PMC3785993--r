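# Unit normalization: every quantitative value must be expressed in its
# variable's canonical unit before similarity ranges are computed.

# Multiplicative conversion registry, keyed "from->to". Only conversions a
# clinical record plausibly needs; anything else is an error, not a guess.
unit_factors <- c(
  "kg->kg" = 1, "g->kg" = 1e-3, "lb->kg" = 0.45359237,
  "cm->cm" = 1, "m->cm" = 100, "mm->cm" = 0.1,
  "g/dl->g/dl" = 1, "g/l->g/dl" = 0.1, "mg/dl->g/dl" = 1e-3,
  "mg/dl->mg/dl" = 1, "g/l->mg/dl" = 100,
  "ug/dl->ug/dl" = 1, "ng/ml->ng/ml" = 1, "pg/ml->pg/ml" = 1,
  "thousand/mcl->thousand/mcl" = 1, "million/l->thousand/mcl" = 1e-3,
  "%->%" = 1, "years->years" = 1, "months->years" = 1 / 12,
  "score->score" = 1, "kg/m2->kg/m2" = 1,
  "g->g" = 1, "m/s2->g" = 1 / 9.80665, "g2->g2" = 1
)

#' Convert all quantitative values to their canonical units
#'
#' Values whose `unit` column names a unit other than the schema's canonical
#' unit for that variable are converted (multiplicatively) and re-tagged;
#' values with no unit tag are assumed canonical. Non-quantitative values
#' are untouched.
#'
#' @param stack A `frailty_stack`.
#' @return The normalized `frailty_stack` (all unit tags canonical).
#' @export
normalize_units <- function(stack) {
  schema <- stack_schema(stack)
  canon <- stats::setNames(schema$unit, schema$name)
  kind <- stats::setNames(schema$kind, schema$name)
  need <- which(!is.na(stack$unit) & stack$state == "present" &
                  kind[stack$variable] == "quantitative" &
                  stack$unit != canon[stack$variable])
  if (length(need)) {
    key <- paste0(stack$unit[need], "->", canon[stack$variable[need]])
    f <- unit_factors[key]
    if (anyNA(f)) {
      i <- need[which(is.na(f))[1]]
      data_error(sprintf(
        "cannot convert variable '%s' from unit '%s' to canonical '%s'",
        stack$variable[i], stack$unit[i], canon[stack$variable[i]]))
    }
    stack$value_num[need] <- stack$value_num[need] * unname(f)
  }
  stack$unit <- unname(canon[stack$variable])
  stack
}

#' Weight profiles
#'
#' A weight profile assigns each schema variable an importance in `[0, 1]`
#' used by the Gower coefficient. `default_weights()` takes every variable's
#' schema default (1, full importance). `read_weight_profile()` reads a JSON
#' object mapping variable names to weights, with an optional `"groups"`
#' object mapping a group name to a weight that is applied uniformly to each
#' of its member variables; explicit per-variable entries override group
#' entries, and unmentioned variables get `fill`.
#'
#' @param schema A [frailty_schema()] tibble.
#' @return A tibble with columns `variable`, `weight`.
#' @export
default_weights <- function(schema = frailty_schema()) {
  tibble(variable = schema$name, weight = schema$default_weight)
}

#' @rdname default_weights
#' @param path JSON file path.
#' @param fill Weight for variables not named in the file.
#' @export
read_weight_profile <- function(path, schema = frailty_schema(), fill = 0) {
  if (!file.exists(path)) io_error(paste0("weight profile not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  w <- stats::setNames(rep(fill, nrow(schema)), schema$name)
  if (!is.null(raw$groups)) {
    for (g in names(raw$groups)) {
      if (!g %in% schema$group)
        data_error(paste0("unknown group in weight profile: ", g))
      w[schema$name[schema$group == g]] <- as.numeric(raw$groups[[g]])
    }
    raw$groups <- NULL
  }
  for (v in names(raw)) {
    if (!v %in% schema$name)
      data_error(paste0("unknown variable in weight profile: ", v))
    w[v] <- as.numeric(raw[[v]])
  }
  check_weights(tibble(variable = schema$name, weight = unname(w)))
}

check_weights <- function(weights) {
  if (any(weights$weight < 0 | weights$weight > 1))
    data_error("weights must lie in [0, 1]")
  if (!any(weights$weight > 0))
    data_error("a usable weight profile needs at least one positive weight")
  weights
}
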