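#' Similarity configuration
#'
#' Options for the Gower general similarity coefficient.
#'
#' * `binary_mode = "symmetric"` (default): two patients both *without* a
#'   geriatric syndrome agree on it (score 1). `"asymmetric"` is Gower's
#'   original dichotomous rule: co-absence is not comparable (the variable
#'   drops out of both numerator and denominator for that pair).
#' * Quantitative ranges are always taken from the non-missing values of the
#'   current stack (`range_policy = "stack_range"`); a variable whose stack
#'   range is zero scores 1 for every comparable pair.
#' * Neighbor ties are broken by ascending instance id.
#'
#' @param binary_mode `"symmetric"` or `"asymmetric"`.
#' @return A list of class `similarity_config`.
#' @export
similarity_config <- function(binary_mode = c("symmetric", "asymmetric")) {
  structure(list(binary_mode = match.arg(binary_mode),
                 range_policy = "stack_range",
                 zero_range_rule = "similarity_one",
                 tie_break = "ascending_instance_id"),
            class = "similarity_config")
}

# Precompute, per variable: weight, kind dispatch data and stack range.
# The stack must be kept-resolved; similarity on unresolved stacks would
# silently treat carried-forward values as missing.
prepare_gower <- function(stack, weights, config) {
  if (any(stack$state == "kept"))
    data_error("stack contains unresolved 'kept' values; call resolve_kept() first")
  schema <- stack_schema(stack)
  w <- stats::setNames(rep(0, nrow(schema)), schema$name)
  w[weights$variable] <- weights$weight
  if (sum(w) <= 0) data_error("total weight must be positive")

  ids <- sort(unique(stack$instance_id))
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)

  vars <- vector("list", nrow(schema))
  names(vars) <- schema$name
  by_var <- split(as_tibble(stack), factor(stack$variable, levels = schema$name))
  for (k in seq_len(nrow(schema))) {
    v <- by_var[[schema$name[k]]]
    ord <- idx[as.character(v$instance_id)]
    present <- logical(n); present[ord] <- v$state == "present"
    if (schema$kind[k] == "quantitative") {
      num <- rep(NA_real_, n); num[ord] <- v$value_num
      num[!present] <- NA_real_
      rng <- if (any(present)) diff(range(num[present])) else 0
      if (is.na(rng) || rng < 0) data_error("negative or undefined range")
      vars[[k]] <- list(kind = "quantitative", w = w[[k]], present = present,
                        num = num, range = rng)
    } else {
      chr <- rep(NA_character_, n); chr[ord] <- v$value_chr
      chr[!present] <- NA_character_
      vars[[k]] <- list(kind = schema$kind[k], w = w[[k]], present = present,
                        chr = chr)
    }
  }
  list(ids = ids, n = n, vars = vars, config = config)
}

# Similarity of instance at position i against all positions: returns
# list(num, den) vectors of length n (S = num/den where den > 0).
gower_row <- function(prep, i) {
  n <- prep$n
  num <- numeric(n); den <- numeric(n)
  asym <- prep$config$binary_mode == "asymmetric"
  for (v in prep$vars) {
    if (v$w == 0) next
    if (!v$present[i]) next
    delta <- v$present
    if (v$kind == "quantitative") {
      s <- if (v$range == 0) rep(1, n) else 1 - abs(v$num - v$num[i]) / v$range
    } else if (v$kind == "binary" && asym) {
      # Gower's dichotomous rule: co-absence is not comparable
      co_absent <- v$present & v$chr[i] == "false" & v$chr == "false"
      co_absent[is.na(co_absent)] <- FALSE
      delta <- delta & !co_absent
      s <- as.numeric(v$chr == v$chr[i])
    } else {
      s <- as.numeric(v$chr == v$chr[i])
    }
    s[!delta | is.na(s)] <- 0
    num <- num + v$w * as.numeric(delta) * s
    den <- den + v$w * as.numeric(delta)
  }
  list(num = num, den = den)
}

#' Weighted Gower similarity between two patient instances
#'
#' Computes the Gower general similarity coefficient
#' \deqn{S_{ij} = \frac{\sum_k w_k \delta_{ijk} s_{ijk}}
#'                     {\sum_k w_k \delta_{ijk}}}
#' over the schema variables: per-variable score \eqn{s_{ijk}} is
#' \eqn{1 - |x_{ik} - x_{jk}|/R_k} for quantitative variables (range
#' \eqn{R_k} over the stack's non-missing values; zero range scores 1),
#' exact-match 0/1 for qualitative and binary variables; the comparability
#' indicator \eqn{\delta_{ijk}} is 0 when either value is missing (and, in
#' asymmetric binary mode, when both are `false`). Weights \eqn{w_k \in
#' [0,1]} let the assessment focus on chosen clinical domains.
#'
#' @param stack A kept-resolved, unit-normalized `frailty_stack`.
#' @param i,j Instance ids to compare.
#' @param weights Weight profile tibble (`variable`, `weight`);
#'   default all schema weights.
#' @param config A [similarity_config()].
#' @return One-row tibble: `i`, `j`, `coefficient`, `effective_weight`
#'   (\eqn{\sum_k w_k \delta_{ijk}}).
#' @examples
#' stk <- generate_cohort(cohort_spec(seed = 1))
#' gower_similarity(stk, 1, 2)
#' @export
gower_similarity <- function(stack, i, j, weights = default_weights(stack_schema(stack)),
                             config = similarity_config()) {
  prep <- prepare_gower(stack, check_weights(weights), config)
  pi <- match(i, prep$ids); pj <- match(j, prep$ids)
  if (is.na(pi)) data_error(paste0("instance ", i, " not in stack"))
  if (is.na(pj)) data_error(paste0("instance ", j, " not in stack"))
  r <- gower_row(prep, pi)
  if (r$den[pj] <= 0)
    data_error(sprintf("instances %s and %s share no comparable weighted variable", i, j))
  tibble(i = as.integer(i), j = as.integer(j),
         coefficient = r$num[pj] / r$den[pj],
         effective_weight = r$den[pj])
}

#' Pairwise Gower similarity matrix
#'
#' @inheritParams gower_similarity
#' @return A `frailty_simmat`: a symmetric numeric matrix with instance ids
#'   as dimnames, diagonal 1 where defined; pairs with no comparable
#'   weighted variable are `NA` and listed in the `"incomparable"`
#'   attribute. The `"effective_weight"` attribute carries
#'   \eqn{\sum_k w_k \delta_{ijk}} per pair.
#' @export
similarity_matrix <- function(stack, weights = default_weights(stack_schema(stack)),
                              config = similarity_config()) {
  prep <- prepare_gower(stack, check_weights(weights), config)
  n <- prep$n
  if (n < 2) data_error("similarity matrix needs at least 2 instances")
  S <- matrix(NA_real_, n, n, dimnames = list(prep$ids, prep$ids))
  D <- matrix(0, n, n, dimnames = list(prep$ids, prep$ids))
  for (p in seq_len(n)) {
    r <- gower_row(prep, p)
    ok <- r$den > 0
    S[p, ok] <- r$num[ok] / r$den[ok]
    D[p, ] <- r$den
  }
  incomp <- which(is.na(S) & upper.tri(S), arr.ind = TRUE)
  structure(S, effective_weight = D,
            incomparable = tibble(i = as.integer(prep$ids[incomp[, 1]]),
                                  j = as.integer(prep$ids[incomp[, 2]])),
            class = c("frailty_simmat", class(S)))
}

#' Rank the neighbors of a studied instance
#'
#' All non-excluded instances of the stack, ordered by their Gower
#' similarity to the target (descending); ties broken by ascending instance
#' id. Pairs with no comparable weighted variable are dropped from the
#' ranking.
#'
#' @inheritParams gower_similarity
#' @param target Instance id of the studied instance.
#' @param exclude Instance ids to leave out of the candidate set (the
#'   target itself is always excluded).
#' @return Tibble with columns `i` (target), `j` (candidate),
#'   `coefficient`, `effective_weight`, ordered best-first.
#' @export
rank_neighbors <- function(stack, target, weights = default_weights(stack_schema(stack)),
                           config = similarity_config(), exclude = integer()) {
  prep <- prepare_gower(stack, check_weights(weights), config)
  p <- match(target, prep$ids)
  if (is.na(p)) data_error(paste0("instance ", target, " not in stack"))
  r <- gower_row(prep, p)
  cand <- setdiff(prep$ids, c(target, exclude))
  pos <- match(cand, prep$ids)
  keep <- r$den[pos] > 0
  out <- tibble(i = as.integer(target), j = as.integer(cand[keep]),
                coefficient = r$num[pos[keep]] / r$den[pos[keep]],
                effective_weight = r$den[pos[keep]])
  arrange(out, dplyr::desc(.data$coefficient), .data$j)
}

#' Export a similarity matrix as CSV
#'
#' @param simmat A `frailty_simmat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(simmat, path) {
  df <- as.data.frame(unclass(simmat))
  df <- cbind(instance_id = rownames(simmat), df)
  readr::write_csv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}
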