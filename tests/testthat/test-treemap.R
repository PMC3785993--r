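cohort_for_treemap <- function(seed, n = 7) {
  generate_cohort(cohort_spec(n_male = n, n_female = n, iterations = 1,
                              seed = seed))
}

test_that("a two-instance stack yields a depth-2 tree with one child", {
  sch <- mini_schema(q = c("a", "b"))
  stk <- mini_stack(list(`1` = list(a = 1, b = 2),
                         `2` = list(a = 2, b = 1)), sch)
  tm <- build_treemap(stk, root = 1)
  expect_equal(tm$instance_id, 1L)
  expect_equal(tm$similarity_coefficient, 1)
  expect_true(is.na(tm$parent_instance_id))
  expect_length(tm$children, 1)
  expect_equal(tm$children[[1]]$instance_id, 2L)
  expect_equal(max(tidy(tm)$depth), 2)
})

test_that("defaults give three level-2 children and four ranked lists", {
  stk <- cohort_for_treemap(31)
  tm <- build_treemap(stk, root = 1)
  g <- glance(tm)
  expect_length(tm$children, 3)
  expect_equal(g$depth, 3)
  expect_equal(g$max_children, 3)
  expect_equal(g$n_ranked_lists, 4)
  expect_equal(g$n_nodes, 13)
})

test_that("tree shape, ordering and uniqueness hold across seeds", {
  for (seed in 1:8) {
    stk <- cohort_for_treemap(seed)
    set.seed(1000 + seed)
    root <- sample(stack_instances(stk)$instance_id, 1)
    tm <- build_treemap(stk, root = root)
    nodes <- tidy(tm)
    expect_lte(max(nodes$depth), 3)
    expect_false(any(duplicated(nodes$instance_id)))
    kid_counts <- table(nodes$parent_instance_id)
    expect_true(all(kid_counts <= 3))
    # sibling similarity non-increasing, and the first level-2 child is the
    # best candidate overall
    check_order <- function(nd) {
      sims <- vapply(nd$children, function(k) k$similarity_coefficient, 1)
      expect_true(all(diff(sims) <= 0))
      for (k in nd$children) check_order(k)
    }
    check_order(tm)
    best <- rank_neighbors(stk, root)$coefficient[1]
    expect_equal(tm$children[[1]]$similarity_coefficient, best)
  }
})

test_that("child similarities are computed against the child's own parent", {
  stk <- cohort_for_treemap(17)
  tm <- build_treemap(stk, root = 1)
  lvl2 <- tm$children[[2]]
  placed_before <- c(1L, vapply(tm$children, function(k) k$instance_id, 1L),
                     vapply(tm$children[[1]]$children,
                            function(k) k$instance_id, 1L))
  expected <- rank_neighbors(stk, lvl2$instance_id, exclude = placed_before)
  got <- vapply(lvl2$children, function(k) k$similarity_coefficient, 1)
  expect_equal(got, expected$coefficient[seq_along(got)])
})

test_that("trees and their serializations are deterministic", {
  stk <- cohort_for_treemap(9)
  tm1 <- build_treemap(stk, root = 3)
  tm2 <- build_treemap(stk, root = 3)
  expect_identical(tm1, tm2)
  expect_identical(treemap_to_json(tm1), treemap_to_json(tm2))
})

test_that("JSON serialization is lossless and carries exactly 4 attributes", {
  stk <- cohort_for_treemap(13)
  tm <- build_treemap(stk, root = 2)
  path <- withr::local_tempfile(fileext = ".json")
  treemap_to_json(tm, path = path)
  back <- treemap_from_json(path = path)
  strip <- function(x) { x <- unclass(x); attributes(x) <- list(names = names(x)); x }
  expect_identical(strip(back), strip(tm))

  # schema walk: every object holds the 4 attributes plus children
  raw <- jsonlite::fromJSON(readLines(path) |> paste(collapse = ""),
                            simplifyVector = FALSE)
  walk <- function(v) {
    expect_setequal(names(v), c("parent_instance_id", "instance_id", "age",
                                "similarity_coefficient", "children"))
    for (ch in v$children) walk(ch)
  }
  walk(raw)

  # single root serializes to one object with empty children
  single <- build_treemap(mini_stack(list(`1` = list(a = 1)),
                                     mini_schema(q = "a")), root = 1)
  raw1 <- jsonlite::fromJSON(treemap_to_json(single), simplifyVector = FALSE)
  expect_length(raw1$children, 0)
  expect_null(raw1$parent_instance_id)
})

test_that("slice-and-dice layout tiles parents proportionally to similarity", {
  # two equal-similarity children split the canvas in half
  sch <- mini_schema(q = "wt")
  stk <- mini_stack(list(`1` = list(wt = 5), `3` = list(wt = 4),
                         `5` = list(wt = 6)), sch)
  tm <- build_treemap(stk, root = 1, tm_config = treemap_config(max_depth = 2))
  l <- layout_treemap(tm)
  kids <- l[l$depth == 2, ]
  expect_equal(kids$w, c(0.5, 0.5))
  expect_equal(kids$h, c(1, 1))

  # similarity 0.6 vs 0.2 -> area ratio 3:1
  tree <- structure(list(
    parent_instance_id = NA_integer_, instance_id = 1L, age = 80,
    similarity_coefficient = 1, children = list(
      list(parent_instance_id = 1L, instance_id = 2L, age = 81,
           similarity_coefficient = 0.6, children = list()),
      list(parent_instance_id = 1L, instance_id = 3L, age = 82,
           similarity_coefficient = 0.2, children = list()))),
    class = "frailty_treemap")
  l2 <- layout_treemap(tree)
  a <- l2[l2$depth == 2, ]
  expect_equal(a$w[1] * a$h[1] / (a$w[2] * a$h[2]), 3)

  # conservation: each parent's area equals the sum of its children's
  stk2 <- cohort_for_treemap(21)
  l3 <- layout_treemap(build_treemap(stk2, root = 1))
  for (p in unique(stats::na.omit(l3$parent_instance_id))) {
    kids <- l3[!is.na(l3$parent_instance_id) & l3$parent_instance_id == p, ]
    parent <- l3[l3$instance_id == p, ]
    expect_equal(sum(kids$w * kids$h), parent$w * parent$h)
    # nesting: children stay inside the parent rectangle
    expect_true(all(kids$x >= parent$x - 1e-12))
    expect_true(all(kids$x + kids$w <= parent$x + parent$w + 1e-12))
    expect_true(all(kids$y >= parent$y - 1e-12))
    expect_true(all(kids$y + kids$h <= parent$y + parent$h + 1e-12))
  }
  expect_error(layout_treemap(tree, width = 0), "positive")
})

test_that("SVG export writes one rect per node, byte-deterministically", {
  stk <- cohort_for_treemap(25)
  tm <- build_treemap(stk, root = 1)
  l <- layout_treemap(tm)
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  write_treemap_svg(l, f1)
  write_treemap_svg(l, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  svg <- readLines(f1)
  expect_equal(sum(grepl("<rect ", svg)), nrow(tidy(tm)))

  single <- build_treemap(mini_stack(list(`1` = list(a = 1)),
                                     mini_schema(q = "a")), root = 1)
  f3 <- withr::local_tempfile(fileext = ".svg")
  write_treemap_svg(layout_treemap(single), f3)
  expect_equal(sum(grepl("<rect ", readLines(f3))), 1)
})

test_that("the placed-nodes exclusion policy prevents repeats; path-only may not", {
  stk <- cohort_for_treemap(3, n = 8)
  tm <- build_treemap(stk, root = 1,
                      tm_config = treemap_config(exclusion_policy = "placed_nodes"))
  expect_false(any(duplicated(tidy(tm)$instance_id)))
  tmp <- build_treemap(stk, root = 1,
                       tm_config = treemap_config(exclusion_policy = "path_only"))
  nodes <- tidy(tmp)
  # path-only still never repeats a node within its own ancestry
  leafs <- nodes[nodes$depth == 3, ]
  expect_false(any(leafs$instance_id == 1))
})

test_that("the same-patient rule can exclude the root's other instances", {
  stk <- generate_cohort(cohort_spec(n_male = 3, n_female = 3, iterations = 2,
                                     seed = 6))
  tm <- build_treemap(stk, root = 1,
                      tm_config = treemap_config(same_patient_rule = "exclude"))
  meta <- stack_instances(stk)
  own <- meta$instance_id[meta$patient_id ==
                            meta$patient_id[meta$instance_id == 1]]
  expect_false(any(setdiff(own, 1) %in% tidy(tm)$instance_id))
})
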