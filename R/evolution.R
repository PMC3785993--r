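# Longitudinal nutritional-evolution analysis: per-sex stage means of a
# selected variable subset, inter-stage deltas, and trend labels.

#' Stage labels
#'
#' Assessment stages map to iterations: `initial` = 1, `spontaneous` = 2
#' (the unassisted evolution after the first assessment),
#' `post_supplementation` = 3 (after a period of protein supplementation).
#' @keywords internal
stage_levels <- c(initial = 1L, spontaneous = 2L, post_supplementation = 3L)

as_stage_iteration <- function(stage) {
  if (is.numeric(stage)) return(as.integer(stage))
  if (!stage %in% names(stage_levels))
    usage_error(paste0("unknown stage '", stage, "'; use ",
                       paste(names(stage_levels), collapse = ", "),
                       " or an iteration number"))
  stage_levels[[stage]]
}

stage_name <- function(iteration) {
  nm <- names(stage_levels)[match(iteration, stage_levels)]
  ifelse(is.na(nm), paste0("iteration_", iteration), nm)
}

#' The nutritional/anthropometric weight profile
#'
#' Weights the nine variables of the nutritional evolution analysis at 1
#' (full importance) — weight, body mass index, fat mass, lean mass, total
#' water, total protein, hemoglobin, serum albumin, lymphocytes — and every
#' other variable at 0, so the Gower coefficient and all stage summaries
#' depend on these nine alone.
#'
#' @param schema A [frailty_schema()] tibble.
#' @return Weight profile tibble (`variable`, `weight`).
#' @export
nutritional_weight_profile <- function(schema = frailty_schema()) {
  selected <- c("weight", "body_mass_index", "fat_mass", "lean_mass",
                "total_water", "total_protein", "hemoglobin",
                "serum_albumin", "lymphocytes")
  absent <- setdiff(selected, schema$name)
  if (length(absent))
    data_error(paste0("schema lacks selected variables: ",
                      paste(absent, collapse = ", ")))
  tibble(variable = schema$name,
         weight = as.numeric(schema$name %in% selected))
}

#' Per-sex stage means of the selected variables
#'
#' Arithmetic mean over the *present* values of each positively weighted
#' variable, for one sex and one stage (iteration). A mean based on fewer
#' than `min_n` contributing values is suppressed and flagged `no_data`,
#' mirroring the study's "not enough data to calculate the average" rule.
#'
#' @param stack A kept-resolved, unit-normalized `frailty_stack`.
#' @param profile Weight profile; variables with weight > 0 are summarised.
#' @param sex `"M"`, `"F"`, or a vector of both.
#' @param stage Stage name (`"initial"`, `"spontaneous"`,
#'   `"post_supplementation"`) or iteration number.
#' @param min_n Minimum contributing values for a reportable mean.
#' @return Tibble with columns `stage`, `sex`, `variable`, `mean`
#'   (`NA` when suppressed), `n`, `no_data`.
#' @export
stage_means <- function(stack, profile = nutritional_weight_profile(stack_schema(stack)),
                        sex = c("M", "F"), stage = "initial", min_n = 3) {
  it <- as_stage_iteration(stage)
  selected <- profile$variable[profile$weight > 0]
  df <- as_tibble(stack) |>
    filter(.data$iteration == it, .data$sex %in% !!sex,
           .data$variable %in% selected)
  out <- df |>
    group_by(sex = .data$sex, variable = .data$variable) |>
    summarise(mean = if (sum(.data$state == "present") >= min_n)
                       base::mean(.data$value_num[.data$state == "present"])
                     else NA_real_,
              n = sum(.data$state == "present"), .groups = "drop") |>
    mutate(stage = stage_name(it), no_data = .data$n < min_n,
           variable = factor(.data$variable, levels = selected)) |>
    arrange(.data$sex, .data$variable) |>
    mutate(variable = as.character(.data$variable)) |>
    select("stage", "sex", "variable", "mean", "n", "no_data")
  out
}

#' Signed differences between two stage summaries
#'
#' Per sex and variable, `delta = mean(s2) - mean(s1)` where both means are
#' reportable; the trend label is `declined` if `delta < -epsilon`,
#' `improved` if `delta > epsilon`, else `maintained`. Swapping the stages
#' negates the deltas and swaps declined and improved.
#'
#' @param s1,s2 Stage summaries from [stage_means()] over the same sexes
#'   and variables.
#' @param epsilon Half-width of the `maintained` band, in the variable's
#'   unit.
#' @return Tibble: `sex`, `variable`, `from`, `to`, `mean_from`,
#'   `mean_to`, `delta` (`NA` when either side is suppressed), `trend`.
#' @export
stage_delta <- function(s1, s2, epsilon = 0) {
  if (!setequal(paste(s1$sex, s1$variable), paste(s2$sex, s2$variable)))
    usage_error("stage summaries cover different sex/variable sets")
  j <- inner_join(s1, s2, by = c("sex", "variable"), suffix = c("_from", "_to"))
  j |>
    mutate(delta = ifelse(.data$no_data_from | .data$no_data_to, NA_real_,
                          .data$mean_to - .data$mean_from),
           trend = dplyr::case_when(
             is.na(.data$delta) ~ NA_character_,
             .data$delta < -epsilon ~ "declined",
             .data$delta > epsilon ~ "improved",
             TRUE ~ "maintained")) |>
    select(sex = "sex", variable = "variable",
           from = "stage_from", to = "stage_to",
           mean_from = "mean_from", mean_to = "mean_to",
           delta = "delta", trend = "trend")
}

#' Full longitudinal evolution report
#'
#' Stage means for the three assessment stages and both sexes, plus the
#' consecutive-stage deltas (initial to spontaneous, spontaneous to
#' post-supplementation).
#'
#' @inheritParams stage_means
#' @param epsilon Passed to [stage_delta()].
#' @param stages Stages to summarise, in order.
#' @return A list of class `evolution_report` with elements `summaries`
#'   (one tibble, all stages) and `deltas` (one tibble, consecutive
#'   pairs).
#' @export
evolution_report <- function(stack, profile = nutritional_weight_profile(stack_schema(stack)),
                             sex = c("M", "F"), stages = names(stage_levels),
                             min_n = 3, epsilon = 0) {
  sums <- lapply(stages, function(s)
    stage_means(stack, profile, sex = sex, stage = s, min_n = min_n))
  deltas <- list()
  if (length(sums) > 1) {
    deltas <- lapply(seq_len(length(sums) - 1), function(q)
      stage_delta(sums[[q]], sums[[q + 1]], epsilon = epsilon))
  }
  structure(list(summaries = bind_rows(sums), deltas = bind_rows(deltas)),
            class = "evolution_report")
}

#' @export
print.evolution_report <- function(x, ...) {
  cat("<evolution_report>\n")
  print(tidy(x))
  invisible(x)
}

#' Write an evolution report as CSV
#'
#' A wide table mirroring the study's layout — one row per stage and sex,
#' one column per selected variable (suppressed means printed as
#' `no_data`) — followed by the delta rows with trend labels. Output is
#' byte-deterministic.
#'
#' @param report An [evolution_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evolution_report <- function(report, path) {
  s <- report$summaries |>
    mutate(cell = ifelse(.data$no_data, "no_data", fmt_num(.data$mean))) |>
    select("stage", "sex", "variable", "cell") |>
    pivot_wider(names_from = "variable", values_from = "cell")
  d <- report$deltas |>
    mutate(cell = ifelse(is.na(.data$delta), "no_data",
                         paste0(fmt_num(.data$delta), " (", .data$trend, ")")),
           stage = paste0(.data$from, "->", .data$to)) |>
    select("stage", "sex", "variable", "cell") |>
    pivot_wider(names_from = "variable", values_from = "cell")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(readr::format_csv(bind_rows(s, d)), con, sep = "")
  invisible(path)
}
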