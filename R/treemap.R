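#' Treemap construction options
#'
#' Structural limits of the similarity treemap: depth at most `max_depth`
#' levels counting the root (default 3) and at most `max_children` child
#' nodes per parent (default 3). `exclusion_policy = "placed_nodes"`
#' (default) bars every node already placed anywhere in the tree from later
#' candidate lists, so no instance appears twice; `"path_only"` only bars a
#' node's own ancestors. `same_patient_rule = "exclude"` additionally bars
#' other instances of the root's patient.
#'
#' @param max_depth Maximum tree depth, counting the root as level 1.
#' @param max_children Maximum children per node.
#' @param exclusion_policy `"placed_nodes"` or `"path_only"`.
#' @param same_patient_rule `"allow"` or `"exclude"`.
#' @return A list of class `treemap_config`.
#' @export
treemap_config <- function(max_depth = 3, max_children = 3,
                           exclusion_policy = c("placed_nodes", "path_only"),
                           same_patient_rule = c("allow", "exclude")) {
  if (max_depth < 1) usage_error("max_depth must be >= 1")
  if (max_children < 1) usage_error("max_children must be >= 1")
  structure(list(max_depth = as.integer(max_depth),
                 max_children = as.integer(max_children),
                 exclusion_policy = match.arg(exclusion_policy),
                 same_patient_rule = match.arg(same_patient_rule)),
            class = "treemap_config")
}

#' Build the similarity treemap for a studied instance
#'
#' The studied (root) instance sits at level 1 with similarity 1. Its
#' children are its top `max_children` neighbors by Gower similarity;
#' breadth-first, each level-2 node's children are *its* top neighbors
#' (similarity computed against that node, not the root) among instances
#' not yet placed. With the default limits on a sufficiently large stack,
#' exactly `1 + max_children` ranked neighbor lists are computed: one for
#' the root and one per level-2 child.
#'
#' @param stack A kept-resolved, unit-normalized `frailty_stack`.
#' @param root Instance id of the studied instance.
#' @param weights Weight profile tibble (`variable`, `weight`).
#' @param sim_config A [similarity_config()].
#' @param tm_config A [treemap_config()].
#' @return A nested node structure of class `frailty_treemap`; each node
#'   has `parent_instance_id` (`NA` for the root), `instance_id`, `age`,
#'   `similarity_coefficient` and `children` (ordered by descending
#'   similarity). The attribute `"n_ranked_lists"` records how many ranked
#'   neighbor lists were computed.
#' @examples
#' stk <- generate_cohort(cohort_spec(seed = 7))
#' tm <- build_treemap(stk, root = 1)
#' glance(tm)
#' @export
build_treemap <- function(stack, root,
                          weights = default_weights(stack_schema(stack)),
                          sim_config = similarity_config(),
                          tm_config = treemap_config()) {
  meta <- stack_instances(stack)
  if (!root %in% meta$instance_id)
    data_error(paste0("root instance ", root, " not in stack"))
  age_of <- stats::setNames(meta$age, meta$instance_id)

  base_exclude <- integer()
  if (tm_config$same_patient_rule == "exclude") {
    root_patient <- meta$patient_id[meta$instance_id == root]
    base_exclude <- setdiff(meta$instance_id[meta$patient_id == root_patient], root)
  }

  prep_weights <- check_weights(weights)
  n_lists <- 0L
  placed <- root

  # flat node table built breadth-first, nested into a tree afterwards
  nodes <- tibble(row = 1L, parent_row = NA_integer_,
                  parent_id = NA_integer_, id = as.integer(root),
                  sim = 1, depth = 1L)
  ancestors <- function(row) {
    path <- integer()
    while (!is.na(row)) {
      path <- c(path, nodes$id[row])
      row <- nodes$parent_row[row]
    }
    path
  }

  depth <- 1L
  while (depth < tm_config$max_depth) {
    frontier <- which(nodes$depth == depth)
    if (!length(frontier)) break
    for (fr in frontier) {
      excl <- if (tm_config$exclusion_policy == "placed_nodes") placed
              else ancestors(fr)
      ranked <- rank_neighbors(stack, nodes$id[fr], weights = prep_weights,
                               config = sim_config,
                               exclude = union(excl, base_exclude))
      n_lists <- n_lists + 1L
      top <- utils::head(ranked, tm_config$max_children)
      if (nrow(top)) {
        nodes <- bind_rows(nodes, tibble(
          row = nrow(nodes) + seq_len(nrow(top)),
          parent_row = fr, parent_id = nodes$id[fr],
          id = as.integer(top$j), sim = top$coefficient,
          depth = depth + 1L))
        placed <- union(placed, top$j)
      }
    }
    depth <- depth + 1L
  }

  nest <- function(row) {
    kid_rows <- nodes$row[!is.na(nodes$parent_row) & nodes$parent_row == row]
    list(parent_instance_id = nodes$parent_id[row],
         instance_id = nodes$id[row],
         age = unname(age_of[as.character(nodes$id[row])]),
         similarity_coefficient = nodes$sim[row],
         children = lapply(kid_rows, nest))
  }
  structure(nest(1L), class = "frailty_treemap", n_ranked_lists = n_lists)
}

#' @export
print.frailty_treemap <- function(x, ...) {
  nodes <- tidy(x)
  cat(sprintf("<frailty_treemap> root instance %d, %d nodes, depth %d\n",
              x$instance_id, nrow(nodes), max(nodes$depth)))
  walk <- function(nd, indent) {
    cat(strrep("  ", indent),
        sprintf("%d (sim %.3f, age %s)\n", nd$instance_id,
                nd$similarity_coefficient, format(nd$age)), sep = "")
    for (ch in nd$children) walk(ch, indent + 1)
  }
  walk(unclass(x), 0)
  invisible(x)
}

#' Serialize a treemap to JSON and back
#'
#' The JSON form is the nested object
#' `{parent_instance_id, instance_id, age, similarity_coefficient,
#' children: [...]}` — exactly the four node attributes plus the ordered
#' children; re-parsing reproduces the tree.
#'
#' @param tree A `frailty_treemap`.
#' @return `treemap_to_json()` returns a JSON string; with `path` given it
#'   also writes the file. `treemap_from_json()` returns the
#'   `frailty_treemap`.
#' @param path Optional file path to write to / read from.
#' @export
treemap_to_json <- function(tree, path = NULL) {
  # numbers are written with %.17g so that re-parsing is bit-exact
  node_json <- function(nd, indent) {
    pad <- strrep("  ", indent)
    kids <- if (!length(nd$children)) "[]" else paste0(
      "[\n", paste(vapply(nd$children, node_json, character(1), indent + 1),
                   collapse = ",\n"), "\n", pad, "]")
    paste0(
      pad, "{\n",
      pad, sprintf('  "parent_instance_id": %s,\n',
                   if (is.na(nd$parent_instance_id)) "null"
                   else sprintf("%d", nd$parent_instance_id)),
      pad, sprintf('  "instance_id": %d,\n', nd$instance_id),
      pad, sprintf('  "age": %s,\n', fmt_num(nd$age)),
      pad, sprintf('  "similarity_coefficient": %s,\n',
                   fmt_num(nd$similarity_coefficient)),
      pad, sprintf('  "children": %s\n', kids),
      pad, "}")
  }
  js <- node_json(unclass(tree), 0)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(js, con, sep = "\n")
  }
  invisible_if_path(js, path)
}

invisible_if_path <- function(x, path) if (is.null(path)) x else invisible(x)

#' @rdname treemap_to_json
#' @param json JSON string (ignored when `path` is given).
#' @export
treemap_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path), collapse = "\n")
  raw <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  from_list <- function(v) {
    list(parent_instance_id = if (is.null(v$parent_instance_id)) NA_integer_
                              else as.integer(v$parent_instance_id),
         instance_id = as.integer(v$instance_id),
         age = as.numeric(v$age),
         similarity_coefficient = as.numeric(v$similarity_coefficient),
         children = lapply(v$children, from_list))
  }
  structure(from_list(raw), class = "frailty_treemap")
}

#' Slice-and-dice treemap layout
#'
#' Tiles the unit canvas with nested rectangles: each node's children
#' partition the node's rectangle, alternating split direction per level,
#' with sibling areas proportional to their similarity coefficients. The
#' fill color is a linear interpolation between `low` and `high` over the
#' coefficient in `[0, 1]`.
#'
#' @param tree A `frailty_treemap`.
#' @param width,height Canvas size in normalized units (default unit square).
#' @param low,high Hex color endpoints of the similarity ramp.
#' @return Tibble of class `treemap_layout` with one row per node:
#'   `instance_id`, `parent_instance_id`, `depth`, `x`, `y`, `w`, `h`,
#'   `similarity_coefficient`, `age`, `color`, `label`.
#' @export
layout_treemap <- function(tree, width = 1, height = 1,
                           low = "#DEEBF7", high = "#08519C") {
  if (width <= 0 || height <= 0) usage_error("canvas must have positive area")
  rows <- list()
  place <- function(nd, x, y, w, h, depth) {
    rows[[length(rows) + 1]] <<- tibble(
      instance_id = nd$instance_id,
      parent_instance_id = nd$parent_instance_id,
      depth = depth, x = x, y = y, w = w, h = h,
      similarity_coefficient = nd$similarity_coefficient,
      age = nd$age)
    kids <- nd$children
    if (!length(kids)) return(invisible())
    sims <- vapply(kids, function(k) k$similarity_coefficient, numeric(1))
    frac <- if (sum(sims) > 0) sims / sum(sims) else rep(1 / length(sims), length(sims))
    horizontal <- depth %% 2 == 1   # odd depth: children side by side
    off <- 0
    for (q in seq_along(kids)) {
      if (horizontal) place(kids[[q]], x + off * w, y, w * frac[q], h, depth + 1)
      else place(kids[[q]], x, y + off * h, w, h * frac[q], depth + 1)
      off <- off + frac[q]
    }
  }
  place(unclass(tree), 0, 0, width, height, 1L)
  out <- bind_rows(rows) |>
    mutate(color = ramp_hex(.data$similarity_coefficient, low, high),
           label = sprintf("%d (%.3f)", .data$instance_id,
                           .data$similarity_coefficient))
  class(out) <- c("treemap_layout", class(out))
  out
}

# Linear RGB interpolation between two hex endpoints; byte-stable output.
ramp_hex <- function(t, low, high) {
  t <- pmin(pmax(t, 0), 1)
  lo <- grDevices::col2rgb(low); hi <- grDevices::col2rgb(high)
  rgb <- round(lo %*% t(1 - t) + hi %*% t(t))
  sprintf("#%02X%02X%02X", rgb[1, ], rgb[2, ], rgb[3, ])
}

#' Write a treemap layout as a standalone SVG
#'
#' One `<rect>` per node (parents first, children drawn on top), filled by
#' the similarity color ramp, labelled `instance_id (coefficient)`. Output
#' is byte-deterministic for identical layouts.
#'
#' @param layout A `treemap_layout` tibble from [layout_treemap()].
#' @param path Output file path.
#' @param width,height Pixel size of the SVG canvas.
#' @return `path`, invisibly.
#' @export
write_treemap_svg <- function(layout, path, width = 640, height = 480) {
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) io_error(paste0("cannot write SVG, no such directory: ", dirname(path)))
  l <- arrange(layout, .data$depth, dplyr::row_number())
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height))
  sx <- width / max(l$x + l$w); sy <- height / max(l$y + l$h)
  for (r in seq_len(nrow(l))) {
    lines <- c(lines, sprintf(
      '  <rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s" stroke="#FFFFFF" stroke-width="1"/>',
      l$x[r] * sx, l$y[r] * sy, l$w[r] * sx, l$h[r] * sy, l$color[r]))
    lines <- c(lines, sprintf(
      '  <text x="%.2f" y="%.2f" font-family="sans-serif" font-size="10" fill="#000000">%s</text>',
      l$x[r] * sx + 3, l$y[r] * sy + 12, l$label[r]))
  }
  lines <- c(lines, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Plot a treemap with ggplot2
#'
#' @param object A `frailty_treemap`.
#' @param ... Passed to [layout_treemap()].
#' @return A ggplot object.
#' @method autoplot frailty_treemap
#' @export
autoplot.frailty_treemap <- function(object, ...) {
  l <- layout_treemap(object, ...)
  ggplot2::ggplot(l, ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                                  ymin = .data$y, ymax = .data$y + .data$h)) +
    ggplot2::geom_rect(ggplot2::aes(fill = .data$similarity_coefficient),
                       color = "white", linewidth = 0.6) +
    ggplot2::geom_text(ggplot2::aes(x = .data$x + .data$w / 2,
                                    y = .data$y + .data$h / 2,
                                    label = .data$label),
                       size = 3,
                       data = l[!l$instance_id %in% l$parent_instance_id, ]) +
    ggplot2::scale_fill_gradient(low = "#DEEBF7", high = "#08519C",
                                 limits = c(0, 1), name = "similarity") +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
}

#' @rdname autoplot.frailty_treemap
#' @param tree A `frailty_treemap`.
#' @export
plot_treemap <- function(tree, ...) autoplot.frailty_treemap(tree, ...)
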