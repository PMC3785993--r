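# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a similarity matrix
#'
#' @param x A `frailty_simmat`.
#' @param ... Unused.
#' @return One row per unordered instance pair: `i`, `j`, `coefficient`,
#'   `effective_weight` (`coefficient` is `NA` for incomparable pairs).
#' @method tidy frailty_simmat
#' @export
tidy.frailty_simmat <- function(x, ...) {
  ids <- as.integer(rownames(x))
  ut <- which(upper.tri(x), arr.ind = TRUE)
  D <- attr(x, "effective_weight")
  tibble(i = ids[ut[, 1]], j = ids[ut[, 2]],
         coefficient = x[ut], effective_weight = D[ut])
}

#' @rdname tidy.frailty_simmat
#' @return `glance()`: a one-row tibble with `n_instances`, `n_pairs`,
#'   `mean_coefficient`, `min_coefficient`, `max_coefficient`,
#'   `n_incomparable`.
#' @method glance frailty_simmat
#' @export
glance.frailty_simmat <- function(x, ...) {
  p <- tidy(x)
  tibble(n_instances = nrow(x), n_pairs = nrow(p),
         mean_coefficient = mean(p$coefficient, na.rm = TRUE),
         min_coefficient = min(p$coefficient, na.rm = TRUE),
         max_coefficient = max(p$coefficient, na.rm = TRUE),
         n_incomparable = sum(is.na(p$coefficient)))
}

#' Tidy a similarity treemap
#'
#' @param x A `frailty_treemap`.
#' @param ... Unused.
#' @return One row per node, in breadth-first order: `parent_instance_id`,
#'   `instance_id`, `age`, `similarity_coefficient`, `depth`.
#' @method tidy frailty_treemap
#' @export
tidy.frailty_treemap <- function(x, ...) {
  rows <- list()
  queue <- list(list(node = unclass(x), depth = 1L))
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    nd <- cur$node
    rows[[length(rows) + 1]] <- tibble(
      parent_instance_id = nd$parent_instance_id,
      instance_id = nd$instance_id, age = nd$age,
      similarity_coefficient = nd$similarity_coefficient,
      depth = cur$depth)
    for (ch in nd$children)
      queue[[length(queue) + 1]] <- list(node = ch, depth = cur$depth + 1L)
  }
  bind_rows(rows)
}

#' @rdname tidy.frailty_treemap
#' @return `glance()`: one row with `root_instance_id`, `n_nodes`,
#'   `depth`, `max_children`, `n_ranked_lists`.
#' @method glance frailty_treemap
#' @export
glance.frailty_treemap <- function(x, ...) {
  nodes <- tidy(x)
  kid_counts <- nodes |>
    filter(!is.na(.data$parent_instance_id)) |>
    count(.data$parent_instance_id)
  tibble(root_instance_id = x$instance_id, n_nodes = nrow(nodes),
         depth = max(nodes$depth),
         max_children = if (nrow(kid_counts)) max(kid_counts$n) else 0L,
         n_ranked_lists = attr(x, "n_ranked_lists") %||% NA_integer_)
}

#' Tidy an evolution report
#'
#' @param x An `evolution_report`.
#' @param ... Unused.
#' @return The stage-summary tibble (`stage`, `sex`, `variable`, `mean`,
#'   `n`, `no_data`).
#' @method tidy evolution_report
#' @export
tidy.evolution_report <- function(x, ...) x$summaries

#' @rdname tidy.evolution_report
#' @return `glance()`: one row with counts of stages, variables, suppressed
#'   cells, and the trend tallies across consecutive-stage deltas.
#' @method glance evolution_report
#' @export
glance.evolution_report <- function(x, ...) {
  tibble(n_stages = length(unique(x$summaries$stage)),
         n_variables = length(unique(x$summaries$variable)),
         n_suppressed = sum(x$summaries$no_data),
         n_declined = sum(x$deltas$trend == "declined", na.rm = TRUE),
         n_maintained = sum(x$deltas$trend == "maintained", na.rm = TRUE),
         n_improved = sum(x$deltas$trend == "improved", na.rm = TRUE))
}

#' Plot an evolution report
#'
#' Per-variable stage trajectories of the group means, one line per sex;
#' suppressed (`no_data`) cells are simply absent.
#'
#' @param object An `evolution_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evolution_report
#' @export
autoplot.evolution_report <- function(object, ...) {
  s <- object$summaries |> filter(!.data$no_data)
  s$stage <- factor(s$stage, levels = unique(object$summaries$stage))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$stage, y = .data$mean,
                                  color = .data$sex, group = .data$sex)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean", color = "sex") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heatmap of a similarity matrix
#'
#' @param object A `frailty_simmat`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frailty_simmat
#' @export
autoplot.frailty_simmat <- function(object, ...) {
  ids <- rownames(object)
  df <- as_tibble(as.data.frame(as.table(unclass(object))))
  names(df) <- c("i", "j", "coefficient")
  df$i <- factor(df$i, levels = ids); df$j <- factor(df$j, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#DEEBF7", high = "#08519C",
                                 limits = c(0, 1), na.value = "grey80",
                                 name = "similarity") +
    ggplot2::labs(x = "instance", y = "instance") +
    ggplot2::theme_minimal()
}
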