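#' The canonical 61-variable frailty schema
#'
#' Returns the fixed schema of frailty variables used throughout the package:
#' one row per variable with its domain group, data kind, canonical unit,
#' default weight, the closed category set for qualitative variables, and a
#' plausible clinical value range (`lo`, `hi`) used only by the synthetic-data
#' generators.
#'
#' The 61 variables are partitioned across six groups: anthropometric (9),
#' functional (6), nutritional (13), cognitive (2), geriatric syndromes
#' (11, all binary) and gait dispersion measures (20, derived from a
#' tri-axial accelerometer recording). Group membership follows the standard
#' frailty-record factor list; the "drug number" item is covered by the
#' geriatric polypharmacy flag, and the independence-in-daily-living level is
#' a functional variable, so that the printed group sizes 9/6/13/2/11/20 are
#' met exactly.
#'
#' @return A tibble of class `frailty_schema` with columns `name`, `group`,
#'   `kind` (`"quantitative"`, `"qualitative"` or `"binary"`), `unit`,
#'   `default_weight`, `categories` (list column), `lo`, `hi`.
#' @examples
#' sch <- frailty_schema()
#' nrow(sch)                    # 61
#' dplyr::count(sch, group)
#' @export
frailty_schema <- function() {
  q <- function(name, group, unit, lo, hi) {
    tibble(name = name, group = group, kind = "quantitative", unit = unit,
           default_weight = 1, categories = list(NULL), lo = lo, hi = hi)
  }
  qual <- function(name, group, categories) {
    tibble(name = name, group = group, kind = "qualitative", unit = "",
           default_weight = 1, categories = list(categories),
           lo = NA_real_, hi = NA_real_)
  }
  bin <- function(name, group) {
    tibble(name = name, group = group, kind = "binary", unit = "",
           default_weight = 1, categories = list(NULL),
           lo = NA_real_, hi = NA_real_)
  }

  adl_levels <- c("independent", "mild_dependent", "moderate_dependent",
                  "great_dependent", "serious_dependent")

  sch <- bind_rows(
    # anthropometric and general data (9)
    qual("gender", "anthropometric", c("M", "F")),
    q("age_years",       "anthropometric", "years", 65, 100),
    q("size",            "anthropometric", "cm",    140, 190),
    q("weight",          "anthropometric", "kg",    40, 100),
    q("body_mass_index", "anthropometric", "kg/m2", 15, 40),
    q("body_mass",       "anthropometric", "kg",    30, 80),
    q("lean_mass",       "anthropometric", "kg",    25, 60),
    q("fat_mass",        "anthropometric", "%",     10, 50),
    q("total_water",     "anthropometric", "kg",    20, 50),
    # functional assessment (6)
    q("tinetti_gait_balance", "functional", "score", 0, 28),
    q("barthel_index",        "functional", "score", 0, 100),
    q("lawton_brody",         "functional", "score", 0, 8),
    q("get_up_and_go",        "functional", "score", 1, 5),
    bin("needs_help_physical", "functional"),
    qual("adl_independence", "functional", adl_levels),
    # nutritional assessment: lab panel (13)
    q("total_protein",    "nutritional", "g/dl",         5, 8.5),
    q("serum_albumin",    "nutritional", "g/dl",         2.5, 5),
    q("cholesterol",      "nutritional", "mg/dl",        120, 280),
    q("triglycerides",    "nutritional", "mg/dl",        50, 250),
    q("blood_iron",       "nutritional", "ug/dl",        30, 160),
    q("ferritin",         "nutritional", "ng/ml",        15, 300),
    q("vitamin_b12",      "nutritional", "pg/ml",        180, 900),
    q("serum_folic_acid", "nutritional", "ng/ml",        2, 20),
    q("serum_transferrin","nutritional", "mg/dl",        180, 380),
    q("leukocytes",       "nutritional", "thousand/mcl", 3.5, 11),
    q("lymphocytes",      "nutritional", "thousand/mcl", 0.8, 4),
    q("hemoglobin",       "nutritional", "g/dl",         10, 17),
    q("calcium",          "nutritional", "mg/dl",        8, 11),
    # cognitive assessment (2)
    q("mini_mental_status", "cognitive", "score", 0, 30),
    q("cruz_roja_mental",   "cognitive", "score", 0, 5),
    # geriatric syndromes (11, binary flags)
    bin("dementia",           "geriatric_syndromes"),
    bin("depression",         "geriatric_syndromes"),
    bin("incontinence",       "geriatric_syndromes"),
    bin("immobility",         "geriatric_syndromes"),
    bin("recurrent_falls",    "geriatric_syndromes"),
    bin("polypharmacy",       "geriatric_syndromes"),
    bin("comorbidity",        "geriatric_syndromes"),
    bin("sensory_deprivation","geriatric_syndromes"),
    bin("pressure_ulcers",    "geriatric_syndromes"),
    bin("malnutrition",       "geriatric_syndromes"),
    bin("terminal_illness",   "geriatric_syndromes"),
    # gait dispersion measures (20)
    dispersion_specs()
  )
  class(sch) <- c("frailty_schema", class(sch))
  sch
}

# The 20 dispersion-measure variable specs: six statistics per axis plus two
# statistics of the acceleration magnitude sqrt(x^2 + y^2 + z^2).
dispersion_specs <- function() {
  per_axis <- function(axis) {
    tibble(
      name = paste0(axis, "_", c("arithmetic_mean", "standard_deviation",
                                 "absolute_mean_difference", "variance",
                                 "amplitude", "pearson_cv")),
      group = "dispersion", kind = "quantitative",
      unit = c("g", "g", "g", "g2", "g", ""),
      default_weight = 1, categories = list(NULL),
      lo = c(-1, 0, 0, 0, 0, 0), hi = c(1, 0.5, 0.5, 0.25, 2, 3)
    )
  }
  bind_rows(
    per_axis("x"), per_axis("y"), per_axis("z"),
    tibble(name = c("acceleration_mean", "acceleration_sd"),
           group = "dispersion", kind = "quantitative", unit = "g",
           default_weight = 1, categories = list(NULL),
           lo = c(0.5, 0), hi = c(1.5, 0.5))
  )
}

#' Names of the dispersion-measure variables
#'
#' @return Character vector of the 20 dispersion variable names, in schema
#'   order.
#' @export
dispersion_variable_names <- function() dispersion_specs()$name

#' Read / write a schema as JSON
#'
#' The on-disk form is an array of objects
#' `{name, group, kind, unit, default_weight, categories?}`; the synthesis
#' ranges `lo`/`hi` are carried when present and default to `NA` otherwise.
#'
#' @param path File path.
#' @return `read_schema_json()` returns a `frailty_schema` tibble;
#'   `write_schema_json()` returns `path` invisibly.
#' @export
read_schema_json <- function(path) {
  if (!file.exists(path)) io_error(paste0("schema file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  sch <- bind_rows(lapply(raw, function(v) {
    tibble(name = v$name, group = v$group, kind = v$kind,
           unit = v$unit %||% "",
           default_weight = v$default_weight %||% 1,
           categories = list(if (is.null(v$categories)) NULL
                             else unlist(v$categories)),
           lo = v$lo %||% NA_real_, hi = v$hi %||% NA_real_)
  }))
  validate_schema(sch)
  class(sch) <- c("frailty_schema", class(sch))
  sch
}

#' @rdname read_schema_json
#' @param schema A `frailty_schema` tibble.
#' @export
write_schema_json <- function(schema, path) {
  validate_schema(schema)
  objs <- lapply(seq_len(nrow(schema)), function(i) {
    v <- list(name = schema$name[i], group = schema$group[i],
              kind = schema$kind[i], unit = schema$unit[i],
              default_weight = schema$default_weight[i])
    if (!is.null(schema$categories[[i]])) v$categories <- schema$categories[[i]]
    if (!is.na(schema$lo[i])) { v$lo <- schema$lo[i]; v$hi <- schema$hi[i] }
    v
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

schema_groups <- c("anthropometric", "functional", "nutritional",
                   "cognitive", "geriatric_syndromes", "dispersion")

validate_schema <- function(schema) {
  if (anyDuplicated(schema$name))
    data_error("schema variable names must be unique")
  if (!all(schema$kind %in% c("quantitative", "qualitative", "binary")))
    data_error("unknown variable kind in schema")
  if (!all(schema$group %in% schema_groups))
    data_error("unknown variable group in schema")
  bad_unit <- schema$kind == "quantitative" & is.na(schema$unit)
  if (any(bad_unit))
    data_error(paste0("quantitative variables must carry a unit: ",
                      paste(schema$name[bad_unit], collapse = ", ")))
  invisible(schema)
}
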