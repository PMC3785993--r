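test_that("per-variable scores follow the mixed-type Gower rules", {
  sch <- mini_schema(q = c("wt", "ht"))
  # two variables, equal weights: one identical, one at the range extremes
  stk <- mini_stack(list(`1` = list(wt = 5, ht = 0),
                         `2` = list(wt = 5, ht = 10)), sch)
  p <- gower_similarity(stk, 1, 2)
  expect_equal(p$coefficient, 0.5)
  expect_equal(p$effective_weight, 2)

  # identical instances score exactly 1 under any positive weights
  stk2 <- mini_stack(list(`1` = list(wt = 3, ht = 4),
                          `2` = list(wt = 3, ht = 4)), sch)
  w <- tibble::tibble(variable = c("wt", "ht"), weight = c(0.8, 0.3))
  expect_equal(gower_similarity(stk2, 1, 2, weights = w)$coefficient, 1)

  # a missing value drops its term from numerator and denominator
  sch3 <- mini_schema(q = c("a", "b", "c"))
  stk3 <- mini_stack(list(`1` = list(a = 1, b = 2, c = 9),
                          `2` = list(a = 1, b = 2, c = NA)), sch3)
  p3 <- gower_similarity(stk3, 1, 2)
  expect_equal(p3$coefficient, 1)
  expect_equal(p3$effective_weight, 2)
})

test_that("zero-range variables score 1 for every comparable pair", {
  sch <- mini_schema(q = c("wt", "ht"))
  stk <- mini_stack(list(`1` = list(wt = 5, ht = 1),
                         `2` = list(wt = 5, ht = 3)), sch)
  # wt has zero range across the stack -> contributes s = 1
  p <- gower_similarity(stk, 1, 2)
  expect_equal(p$coefficient, (1 + 0) / 2)
})

test_that("binary co-absence is agreement in symmetric mode, dropped in asymmetric", {
  sch <- mini_schema(b = c("fl", "fr"))
  stk <- mini_stack(list(`1` = list(fl = "false", fr = "true"),
                         `2` = list(fl = "false", fr = "true")), sch)
  sym <- gower_similarity(stk, 1, 2, config = similarity_config("symmetric"))
  expect_equal(sym$coefficient, 1)
  expect_equal(sym$effective_weight, 2)
  asym <- gower_similarity(stk, 1, 2, config = similarity_config("asymmetric"))
  # fl is co-absent -> not comparable; only fr (both true) remains
  expect_equal(asym$effective_weight, 1)
  expect_equal(asym$coefficient, 1)

  stk2 <- mini_stack(list(`1` = list(fl = "false", fr = "false"),
                          `2` = list(fl = "false", fr = "false")), sch)
  expect_error(gower_similarity(stk2, 1, 2,
                                config = similarity_config("asymmetric")),
               "no comparable")
})

test_that("pairs with no comparable weighted variable are an explicit error", {
  sch <- mini_schema(q = c("a", "b"))
  stk <- mini_stack(list(`1` = list(a = 1, b = NA),
                         `2` = list(a = NA, b = 2),
                         `3` = list(a = 1, b = 2)), sch)
  expect_error(gower_similarity(stk, 1, 2), "no comparable")
  sm <- similarity_matrix(stk)
  expect_true(is.na(sm["1", "2"]))
  expect_equal(nrow(attr(sm, "incomparable")), 1)
})

test_that("similarity requires a kept-resolved stack", {
  expect_error(similarity_matrix(table_pattern_fixture()), "resolve_kept")
})

test_that("the matrix is symmetric, bounded, unit-diagonal and complete", {
  stk <- generate_cohort(cohort_spec(n_male = 4, n_female = 4, iterations = 1,
                                     seed = 11))
  sm <- similarity_matrix(stk)
  expect_equal(unclass(sm), t(unclass(sm)), ignore_attr = TRUE)
  expect_true(all(diag(sm) == 1))
  expect_true(all(sm >= 0 & sm <= 1))
  expect_equal(nrow(tidy(sm)), 8 * 7 / 2)
})

test_that("matrix entries equal the term-by-term oracle on random mixed stacks", {
  for (seed in 1:12) {
    stk <- random_small_stack(seed, n = 5)
    w <- random_weights(stack_schema(stk), seed + 100)
    if (sum(w$weight) == 0) w$weight[1] <- 0.5
    for (mode in c("symmetric", "asymmetric")) {
      sm <- similarity_matrix(stk, weights = w,
                              config = similarity_config(mode))
      for (i in 1:4) for (j in (i + 1):5) {
        expect_equal(sm[i, j],
                     gower_oracle(stk, i, j, w, binary_mode = mode),
                     tolerance = 1e-12,
                     label = sprintf("seed %d pair (%d,%d) %s", seed, i, j, mode))
      }
    }
  }
})

test_that("coefficients agree with cluster::daisy on purely present data", {
  set.seed(42)
  sch <- mini_schema(q = c("wt", "ht"), c = "col", b = "fl")
  n <- 6
  vals <- lapply(seq_len(n), function(i)
    list(wt = runif(1, 0, 10), ht = runif(1, 0, 10),
         col = sample(c("red", "green", "blue"), 1),
         fl = sample(c("true", "false"), 1)))
  names(vals) <- seq_len(n)
  stk <- mini_stack(vals, sch)
  sm <- similarity_matrix(stk)

  df <- data.frame(
    wt = vapply(vals, function(v) v$wt, 1),
    ht = vapply(vals, function(v) v$ht, 1),
    col = factor(vapply(vals, function(v) v$col, "")),
    fl = factor(vapply(vals, function(v) v$fl, "")))
  dd <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unclass(sm), 1 - dd, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("zero-weighted variables cannot influence the coefficient", {
  sch <- mini_schema(q = c("a", "b"), c = "col")
  w <- tibble::tibble(variable = c("a", "b", "col"), weight = c(1, 0, 1))
  stk1 <- mini_stack(list(`1` = list(a = 1, b = 0, col = "red"),
                          `2` = list(a = 4, b = 0, col = "red")), sch)
  stk2 <- mini_stack(list(`1` = list(a = 1, b = 9, col = "red"),
                          `2` = list(a = 4, b = 2, col = "red")), sch)
  expect_equal(gower_similarity(stk1, 1, 2, weights = w)$coefficient,
               gower_similarity(stk2, 1, 2, weights = w)$coefficient)
})

test_that("neighbor ranking sorts by coefficient with id tie-breaks", {
  # one quantitative variable; candidates 3 and 5 are equidistant from the
  # target, candidate 2 is farther away
  sch <- mini_schema(q = "wt")
  stk <- mini_stack(list(`1` = list(wt = 5), `2` = list(wt = 0),
                         `3` = list(wt = 4), `5` = list(wt = 6)), sch)
  r <- rank_neighbors(stk, 1)
  expect_equal(r$j, c(3, 5, 2))
  expect_equal(r$coefficient[1], r$coefficient[2])

  # excluding all candidates yields an empty (not failing) ranking
  r2 <- rank_neighbors(stk, 1, exclude = c(2, 3, 5))
  expect_equal(nrow(r2), 0)
  # single candidate
  r3 <- rank_neighbors(stk, 1, exclude = c(2, 3))
  expect_equal(r3$j, 5)
})

test_that("unit normalization converts to canonical units before comparison", {
  stk <- generate_cohort(cohort_spec(n_male = 2, n_female = 2, iterations = 1,
                                     seed = 5))
  i <- which(stk$variable == "weight" & stk$instance_id == 1)
  stk$value_num[i] <- 70000
  stk$unit[i] <- "g"
  norm <- normalize_units(stk)
  expect_equal(norm$value_num[i], 70)
  expect_equal(norm$unit[i], "kg")
  # identity on already-canonical values
  j <- which(stk$variable == "weight" & stk$instance_id == 2)
  expect_equal(norm$value_num[j], stk$value_num[j])

  bad <- stk
  bad$unit[i] <- "stone"
  expect_error(normalize_units(bad), "stone")
})

test_that("weight profiles read from JSON with group expansion", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"groups": {"nutritional": 0.5}, "weight": 1, "dementia": 0.25}',
             path)
  w <- read_weight_profile(path)
  sch <- frailty_schema()
  expect_equal(w$weight[w$variable == "weight"], 1)
  expect_equal(w$weight[w$variable == "dementia"], 0.25)
  nut <- sch$name[sch$group == "nutritional"]
  expect_true(all(w$weight[w$variable %in% nut] == 0.5))
  expect_true(all(w$weight[!w$variable %in% c(nut, "weight", "dementia")] == 0))

  writeLines('{"bogus_variable": 1}', path)
  expect_error(read_weight_profile(path), "bogus_variable")
})
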