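#' Marginal effects of design factors on a response
#'
#' One-way summaries per design factor: level means with 2.5/97.5%
#' quantiles over scenarios and replicates, pairwise level comparisons
#' from the one-way linear model (pooled variance t tests), and a
#' compact letter display at the chosen significance level. Levels that
#' share no letter differ at `p < alpha`.
#'
#' @param records stage-record tibble (filter to one stage first, or
#'   pass `stage`).
#' @param response response column (default `"merit"`).
#' @param factors character vector of factor columns.
#' @param alpha significance level (default 0.01).
#' @param stage optional stage to filter on (e.g. `"S"` or `"C4"`).
#' @return tibble with factor, level, n, mean, q2.5, q97.5, letters.
#' @export
marginal_effects <- function(records, response = "merit",
                             factors = c("h2", "platform",
                                         "seeds_per_landrace",
                                         "n_selected_landraces",
                                         "tested_seeds_per_landrace",
                                         "n_synthetic_phenotypes"),
                             alpha = 0.01, stage = NULL) {
  if (!is.null(stage)) records <- records[records$stage == stage, ]
  if (nrow(records) == 0) stop("no records after filtering")
  y_all <- records[[response]]
  out <- lapply(factors, function(f) {
    g <- factor(records[[f]])
    if (nlevels(g) < 2) stop("factor ", f, " has fewer than 2 levels")
    ok <- !is.na(y_all)
    y <- y_all[ok]
    gg <- droplevels(g[ok])
    means <- tapply(y, gg, mean)
    ns <- tapply(y, gg, length)
    q <- tapply(y, gg, quantile, probs = c(0.025, 0.975))
    p_mat <- pairwise_p(y, gg)
    letters <- cld_letters(means, p_mat < alpha)
    tibble::tibble(
      factor = f, level = levels(gg), n = as.integer(ns),
      mean = as.numeric(means),
      q2.5 = vapply(q, `[[`, numeric(1), 1),
      q97.5 = vapply(q, `[[`, numeric(1), 2),
      letters = letters
    )
  })
  do.call(rbind, out)
}

# Pairwise t tests with the pooled residual variance of the one-way
# model; returns a symmetric p-value matrix.
pairwise_p <- function(y, g) {
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  df <- length(y) - k
  s2 <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df
  p <- matrix(1, k, k, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(s2 * (1 / ns[i] + 1 / ns[j]))
      tt <- (means[i] - means[j]) / se
      p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), df)
    }
  }
  p
}

# Compact letter display by insert-and-absorb: levels sharing a letter
# are not significantly different.
cld_letters <- function(means, sig) {
  k <- length(means)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (s in seq_along(sets)) {
        if (all(c(i, j) %in% sets[[s]])) {
          a <- setdiff(sets[[s]], i)
          b <- setdiff(sets[[s]], j)
          sets[[s]] <- a
          sets <- c(sets, list(b))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(sets))
      for (s in seq_along(sets)) {
        for (t in seq_along(sets)) {
          if (s != t && keep[t] && keep[s] &&
              all(sets[[s]] %in% sets[[t]]) &&
              length(sets[[s]]) < length(sets[[t]])) {
            keep[s] <- FALSE
          }
        }
      }
      sets <- sets[keep]
    }
  }
  ord <- order(vapply(sets, function(s) -max(means[s]), numeric(1)))
  sets <- sets[ord]
  out <- character(k)
  for (s in seq_along(sets)) {
    for (l in sets[[s]]) out[l] <- paste0(out[l], letters[s])
  }
  out
}

#' Build a significance-gated regression tree over design factors
#'
#' Recursive partitioning in the conditional-inference style: at each
#' node the factor with the smallest permutation F-test p-value is
#' chosen; if that p-value is below `alpha` the node splits into the
#' two level groups that maximize the between-group sum of squares
#' (order-preserving groupings for ordinal factors, all bipartitions
#' for unordered ones), subject to `min_leaf` observations per child.
#' Permutation testing avoids distributional assumptions on the
#' response.
#'
#' @param records stage-record tibble (one stage).
#' @param response response column (default `"merit"`).
#' @param factors character vector of factor columns (each with at
#'   most 12 levels).
#' @param alpha split significance gate (default 0.01).
#' @param min_leaf minimum observations per leaf (default 20).
#' @param n_perm permutations per test (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param stage optional stage filter.
#' @return an object of class `prebreed_tree`.
#' @export
build_tree <- function(records, response = "merit",
                       factors = c("h2", "platform", "seeds_per_landrace",
                                   "n_selected_landraces",
                                   "tested_seeds_per_landrace",
                                   "n_synthetic_phenotypes"),
                       alpha = 0.01, min_leaf = 20, n_perm = 1000,
                       seed = 1, stage = NULL) {
  if (!is.null(stage)) records <- records[records$stage == stage, ]
  ok <- !is.na(records[[response]])
  records <- records[ok, ]
  if (nrow(records) == 0) stop("no records after filtering")
  for (f in factors) {
    lev <- unique(records[[f]])
    if (length(lev) > 12) stop("factor ", f, " has more than 12 levels")
  }
  y <- as.numeric(records[[response]])
  X <- records[, factors, drop = FALSE]
  node <- with_seed(seed, grow_node(y, X, factors, alpha, min_leaf, n_perm))
  structure(list(root = node, response = response, factors = factors,
                 alpha = alpha, min_leaf = min_leaf, n_perm = n_perm,
                 n = length(y)),
            class = "prebreed_tree")
}

leaf_node <- function(y) {
  list(type = "leaf", n = length(y), mean = mean(y),
       q2.5 = as.numeric(quantile(y, 0.025)),
       q97.5 = as.numeric(quantile(y, 0.975)))
}

grow_node <- function(y, X, factors, alpha, min_leaf, n_perm) {
  n <- length(y)
  if (n < 2 * min_leaf || var(y) == 0) return(leaf_node(y))
  ps <- vapply(factors, function(f) {
    g <- factor(X[[f]])
    if (nlevels(droplevels(g)) < 2) return(1)
    perm_f_test(y, droplevels(g), n_perm)
  }, numeric(1))
  best <- which.min(ps)
  if (ps[best] >= alpha) return(leaf_node(y))
  f <- factors[best]
  split <- best_bipartition(y, X[[f]], min_leaf)
  if (is.null(split)) return(leaf_node(y))
  left <- X[[f]] %in% split$left
  list(type = "node", factor = f, p_value = ps[best],
       left_levels = split$left, right_levels = split$right,
       n = n,
       left = grow_node(y[left], X[left, , drop = FALSE], factors,
                        alpha, min_leaf, n_perm),
       right = grow_node(y[!left], X[!left, , drop = FALSE], factors,
                         alpha, min_leaf, n_perm))
}

# One-way permutation F test: p = (1 + #{F_perm >= F_obs}) / (1 + B).
perm_f_test <- function(y, g, n_perm) {
  f_obs <- f_stat(y, g)
  if (!is.finite(f_obs)) return(1)
  count <- 0L
  n <- length(y)
  for (b in seq_len(n_perm)) {
    if (f_stat(y[sample.int(n)], g) >= f_obs) count <- count + 1L
  }
  (1 + count) / (1 + n_perm)
}

f_stat <- function(y, g) {
  ns <- tabulate(g)
  sums <- rowsum(y, g)
  means <- sums / ns
  grand <- mean(y)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(y^2) - sum(sums^2 / ns)
  k <- length(ns)
  (ssb / (k - 1)) / (ssw / (length(y) - k))
}

best_bipartition <- function(y, x, min_leaf) {
  lev <- unique(x)
  if (is.numeric(lev)) lev <- sort(lev)
  k <- length(lev)
  if (k < 2) return(NULL)
  candidates <- if (is.numeric(x)) {
    lapply(seq_len(k - 1), function(i) lev[seq_len(i)])
  } else {
    # all bipartitions; fix the first level on the left to halve the set
    unlist(lapply(seq_len(k - 1), function(m) {
      cs <- utils::combn(lev[-1], m - 1, simplify = FALSE)
      lapply(cs, function(s) c(lev[1], s))
    }), recursive = FALSE)
  }
  best <- NULL
  best_ssb <- -Inf
  for (left_lev in candidates) {
    left <- x %in% left_lev
    nl <- sum(left)
    nr <- length(x) - nl
    if (nl < min_leaf || nr < min_leaf) next
    ssb <- nl * (mean(y[left]) - mean(y))^2 + nr * (mean(y[!left]) - mean(y))^2
    if (ssb > best_ssb) {
      best_ssb <- ssb
      best <- list(left = left_lev, right = setdiff(lev, left_lev))
    }
  }
  best
}

#' Render a decision tree as text or JSON
#'
#' The JSON form round-trips through [tree_from_json()]; the text form
#' is an indented listing with split p-values and leaf summaries.
#'
#' @param tree a `prebreed_tree`.
#' @return character vector of lines (text) or JSON string.
#' @export
render_tree <- function(tree) {
  lines <- character(0)
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf("%s* mean = %.4g (%.4g, %.4g), n = %d",
                                 pad, node$mean, node$q2.5, node$q97.5, node$n))
    } else {
      lines <<- c(lines, sprintf("%s%s (p = %.3g)", pad, node$factor,
                                 node$p_value))
      lines <<- c(lines, sprintf("%s- in {%s}:", pad,
                                 paste(node$left_levels, collapse = ", ")))
      rec(node$left, indent + 1)
      lines <<- c(lines, sprintf("%s- in {%s}:", pad,
                                 paste(node$right_levels, collapse = ", ")))
      rec(node$right, indent + 1)
    }
  }
  rec(tree$root, 0)
  lines
}

#' @rdname render_tree
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(unclass(tree), auto_unbox = TRUE, digits = NA)
}

#' @rdname render_tree
#' @param json JSON string from [tree_to_json()].
#' @export
tree_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(x, class = "prebreed_tree")
}

#' @export
print.prebreed_tree <- function(x, ...) {
  cat(render_tree(x), sep = "\n")
  invisible(x)
}

#' Count nodes of a decision tree
#'
#' @param tree a `prebreed_tree`.
#' @return list with `leaves` and `internal` counts.
#' @export
tree_node_count <- function(tree) {
  rec <- function(node) {
    if (node$type == "leaf") c(leaves = 1L, internal = 0L)
    else c(leaves = 0L, internal = 1L) + rec(node$left) + rec(node$right)
  }
  as.list(rec(tree$root))
}
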