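#' Control parameters for CHAID tree growth
#'
#' CHAID (chi-squared automatic interaction detection) recursively partitions
#' the claims by, at each node, (1) merging the categories of each candidate
#' predictor that are statistically indistinguishable in cost, (2) Bonferroni-
#' adjusting each predictor's omnibus p-value for the number of ways its
#' categories could have been merged, and (3) splitting on the predictor with
#' the smallest adjusted p-value, if small enough and if every child is large
#' enough.
#'
#' Classical CHAID assumes a categorical response; hospitalization cost is
#' continuous. Two response modes are provided: `"continuous_F"` (default)
#' uses two-sample/one-way ANOVA F tests on cost, the standard scale-response
#' CHAID variant; `"binned_chi2"` discretizes cost into bins (default:
#' quintiles of the node's costs) and uses Pearson chi-squared tests, for a
#' strictly chi-squared reading. This choice is the largest interpretation in
#' the module: the two modes can select different splits on weak signals.
#'
#' @param alpha_merge Categories whose pairwise test p-value exceeds this are
#'   merged (default 0.05).
#' @param alpha_split A node is split only if the best Bonferroni-adjusted
#'   p-value is below this (default 0.05).
#' @param min_parent Minimum node size to attempt a split (default 400).
#' @param min_child Minimum size of every child (default 200); must be
#'   `<= min_parent`.
#' @param max_depth Maximum number of split levels below the root (default 4).
#' @param response_mode `"continuous_F"` or `"binned_chi2"`.
#' @param bins Optional numeric vector of interior cost-bin edges for binned
#'   mode; `NULL` means quintile edges computed at each node.
#' @return A `chaid_control` list.
#' @export
chaid_control <- function(alpha_merge = 0.05, alpha_split = 0.05,
                          min_parent = 400, min_child = 200, max_depth = 4,
                          response_mode = c("continuous_F", "binned_chi2"),
                          bins = NULL) {
  response_mode <- match.arg(response_mode)
  stopifnot(alpha_merge > 0, alpha_merge < 1, alpha_split > 0, alpha_split < 1,
            min_child <= min_parent, max_depth >= 1)
  structure(list(alpha_merge = alpha_merge, alpha_split = alpha_split,
                 min_parent = min_parent, min_child = min_child,
                 max_depth = max_depth, response_mode = response_mode,
                 bins = bins),
            class = "chaid_control")
}

# ---- test machinery on aggregated statistics -------------------------------
# All merge/split tests run on per-category aggregates (n, sum, sum of squares
# in continuous mode; bin counts in binned mode), so tree growth is
# O(categories^2) per node regardless of n.

cont_stats <- function(v) list(n = length(v), s = sum(v), q = sum(v^2))

cont_combine <- function(a, b) list(n = a$n + b$n, s = a$s + b$s, q = a$q + b$q)

# One-way ANOVA F test across k >= 1 aggregated groups.
cont_test <- function(stats) {
  k <- length(stats)
  if (k < 2) return(list(statistic = 0, p_value = 1, df = 0))
  n <- vapply(stats, `[[`, numeric(1), "n")
  s <- vapply(stats, `[[`, numeric(1), "s")
  q <- vapply(stats, `[[`, numeric(1), "q")
  N <- sum(n)
  gm <- sum(s) / N
  ssb <- sum(n * (s / n - gm)^2)
  ssw <- sum(q - s^2 / n)
  df1 <- k - 1
  df2 <- N - k
  scale <- max(sum(q), 1)
  if (df2 <= 0) return(list(statistic = NA_real_, p_value = 1, df = df1))
  if (ssw <= 1e-12 * scale) {
    p <- if (ssb <= 1e-12 * scale) 1 else 0
    return(list(statistic = if (p == 1) 0 else Inf, p_value = p, df = df1))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p_value = pf(f, df1, df2, lower.tail = FALSE), df = df1)
}

binned_stats <- function(v, edges) {
  tabulate(findInterval(v, edges) + 1L, nbins = length(edges) + 1L)
}

binned_combine <- function(a, b) a + b

# Pearson chi-squared test on a (groups x bins) count matrix.
binned_test <- function(stats) {
  k <- length(stats)
  if (k < 2) return(list(statistic = 0, p_value = 1, df = 0))
  m <- do.call(rbind, stats)
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2) return(list(statistic = 0, p_value = 1, df = 0))
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  x2 <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = x2, p_value = pchisq(x2, df, lower.tail = FALSE), df = df)
}

# ---- category merging ------------------------------------------------------

#' Merge statistically indistinguishable categories (the CHAID merge step)
#'
#' Iteratively merges the pair of (compound) categories whose pairwise test is
#' least significant, as long as that pairwise p-value exceeds `alpha_merge`.
#' For monotone (ordinal) predictors only adjacent categories may merge, so
#' every compound category is a contiguous run; for free (nominal) predictors
#' any pair may merge. Returns the final partition together with the omnibus
#' test across the merged groups.
#'
#' @param values Named list of numeric cost vectors, one per category, in
#'   category order (the order matters for monotone predictors).
#' @param kind `"free"` (nominal) or `"monotone"` (ordinal).
#' @param control A [chaid_control()].
#' @return A list: `partition` (list of character vectors of merged category
#'   labels), `p_value` and `statistic` of the omnibus test across merged
#'   groups (p = 1 when everything merges into one group), `df`.
#' @export
#' @examples
#' merge_categories(list(a = rnorm(100), b = rnorm(100), c = rnorm(100, 10)))
merge_categories <- function(values, kind = c("free", "monotone"),
                             control = chaid_control()) {
  kind <- match.arg(kind)
  if (!is.list(values) || length(values) < 1 || is.null(names(values))) {
    abort("`values` must be a named list with at least one category")
  }
  cats <- names(values)
  if (control$response_mode == "continuous_F") {
    stats <- lapply(values, cont_stats)
    combine <- cont_combine
    test <- cont_test
  } else {
    edges <- control$bins %||% unique(quantile7(unlist(values, use.names = FALSE),
                                                c(0.2, 0.4, 0.6, 0.8)))
    stats <- lapply(values, binned_stats, edges = edges)
    combine <- binned_combine
    test <- binned_test
  }
  groups <- as.list(seq_along(cats))

  while (length(groups) > 1) {
    g <- length(groups)
    pairs <- if (kind == "monotone") {
      cbind(seq_len(g - 1), seq_len(g - 1) + 1L)
    } else {
      t(utils::combn(g, 2))
    }
    pv <- apply(pairs, 1, function(ij) {
      test(list(stats[[ij[1]]], stats[[ij[2]]]))$p_value
    })
    best <- which.max(pv)
    if (pv[best] <= control$alpha_merge) break
    i <- pairs[best, 1]; j <- pairs[best, 2]
    groups[[i]] <- c(groups[[i]], groups[[j]])
    stats[[i]] <- combine(stats[[i]], stats[[j]])
    groups[[j]] <- NULL
    stats[[j]] <- NULL
  }

  # keep category order inside compound groups and, for monotone predictors,
  # groups in category order
  groups <- lapply(groups, sort)
  ord <- order(vapply(groups, min, numeric(1)))
  groups <- groups[ord]
  stats <- stats[ord]
  omni <- test(stats)
  list(partition = lapply(groups, function(ix) cats[ix]),
       p_value = omni$p_value, statistic = omni$statistic, df = omni$df)
}

#' Bonferroni multiplier for a CHAID split
#'
#' Number of distinct ways `c_original` categories can be reduced to
#' `c_merged` compound categories: for a free (nominal) predictor, the
#' Stirling number of the second kind \eqn{S(c, r)}; for a monotone (ordinal)
#' predictor, the number of contiguous partitions, \eqn{\binom{c-1}{r-1}}.
#' The omnibus split p-value is multiplied by this count (capped at 1) before
#' predictors are compared.
#'
#' @param c_original Number of categories observed at the node.
#' @param c_merged Number of merged groups, `1 <= c_merged <= c_original`.
#' @param kind `"free"` or `"monotone"`.
#' @return The multiplier as a double (integer-valued).
#' @export
#' @examples
#' bonferroni_multiplier(4, 2, "monotone")  # 3
#' bonferroni_multiplier(4, 2, "free")      # 7
bonferroni_multiplier <- function(c_original, c_merged,
                                  kind = c("free", "monotone")) {
  kind <- match.arg(kind)
  stopifnot(c_merged >= 1, c_merged <= c_original)
  if (kind == "monotone") {
    choose(c_original - 1, c_merged - 1)
  } else {
    stirling2(c_original, c_merged)
  }
}

# ---- tree growth -----------------------------------------------------------

new_chaid_node <- function(id, n, mean_cost, sd_cost) {
  list(node_id = id, n = n, mean_cost = mean_cost, sd_cost = sd_cost,
       predictor = NA_character_, kind = NA_character_,
       merged_levels = NULL, adjusted_p = NA_real_, statistic = NA_real_,
       children = list())
}

#' Grow a CHAID tree on hospitalization cost
#'
#' @param data A claims tibble (bands are added with [add_bands()] when a
#'   predictor needs them). Records with missing predictor values are not
#'   handled; filter them out first (e.g. exclude `surgery == "unknown"`
#'   before a grouping run).
#' @param predictors Named character vector mapping predictor columns to
#'   their kind, `"free"` or `"monotone"`; e.g.
#'   `c(hospital_level = "monotone", los_band = "monotone", cc = "free")`.
#'   An unnamed character vector is taken as all-free. The vector's order is
#'   the tie-break order when two predictors have equal adjusted p-values.
#' @param response Response column (default `"cost"`).
#' @param control A [chaid_control()].
#' @return A `chaid_tree` object; see [extract_rules()], [tidy.chaid_tree()],
#'   [write_chaid_json()].
#' @export
#' @examples
#' claims <- simulate_claims(3000, seed = 11)
#' tree <- grow_tree(claims, c(hospital_level = "monotone", cc = "free"),
#'                   control = chaid_control(min_parent = 100, min_child = 50))
#' print(tree)
grow_tree <- function(data, predictors, response = "cost",
                      control = chaid_control()) {
  if (is.null(names(predictors))) {
    predictors <- setNames(rep("free", length(predictors)), predictors)
  }
  if (!all(predictors %in% c("free", "monotone"))) {
    abort('predictor kinds must be "free" or "monotone"')
  }
  if (any(c("age_band", "los_band") %in% names(predictors)) &&
      !all(c("age_band", "los_band") %in% names(data))) {
    data <- add_bands(data)
  }
  missing_vars <- setdiff(c(response, names(predictors)), names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("unknown column(s): ", paste(missing_vars, collapse = ", ")))
  }
  y <- data[[response]]
  if (anyNA(y)) abort("response contains missing values")
  pred_cols <- lapply(names(predictors), function(v) {
    x <- data[[v]]
    if (anyNA(x)) abort(paste0("predictor ", v, " contains missing values"))
    as.character(x)
  })
  names(pred_cols) <- names(predictors)
  # category order: factor level order when available, else first appearance
  level_order <- lapply(names(predictors), function(v) {
    x <- data[[v]]
    if (is.factor(x)) levels(x) else unique(as.character(x))
  })
  names(level_order) <- names(predictors)

  counter <- new.env(parent = emptyenv())
  counter$next_id <- 1L

  build <- function(idx, depth) {
    id <- counter$next_id
    counter$next_id <- id + 1L
    yv <- y[idx]
    node <- new_chaid_node(id, length(idx), mean(yv),
                           if (length(idx) > 1) sd(yv) else 0)
    if (depth >= control$max_depth || length(idx) < control$min_parent) {
      return(node)
    }
    cand <- purrr::map(names(predictors), function(v) {
      xv <- pred_cols[[v]][idx]
      obs <- level_order[[v]][level_order[[v]] %in% xv]
      if (length(obs) < 2) return(NULL)
      vals <- split(yv, factor(xv, levels = obs))
      mc <- merge_categories(vals, kind = predictors[[v]], control = control)
      if (length(mc$partition) < 2) return(NULL)
      mult <- bonferroni_multiplier(length(obs), length(mc$partition),
                                    predictors[[v]])
      list(variable = v, kind = predictors[[v]], partition = mc$partition,
           adjusted_p = min(1, mc$p_value * mult), statistic = mc$statistic)
    })
    cand <- purrr::compact(cand)
    if (length(cand) == 0) return(node)
    # smallest adjusted p first; ties broken by declared predictor order,
    # which is the order cand was built in (order() is stable)
    cand <- cand[order(vapply(cand, `[[`, numeric(1), "adjusted_p"))]
    for (ch in cand) {
      if (ch$adjusted_p >= control$alpha_split) break
      branch_idx <- lapply(ch$partition, function(lv) {
        idx[pred_cols[[ch$variable]][idx] %in% lv]
      })
      if (all(lengths(branch_idx) >= control$min_child)) {
        node$predictor <- ch$variable
        node$kind <- ch$kind
        node$merged_levels <- ch$partition
        node$adjusted_p <- ch$adjusted_p
        node$statistic <- ch$statistic
        node$children <- lapply(branch_idx, build, depth = depth + 1L)
        break
      }
    }
    node
  }

  root <- build(seq_along(y), 0L)
  structure(list(root = root, control = control, predictors = predictors,
                 response = response, n = length(y),
                 level_order = level_order),
            class = "chaid_tree")
}

walk_nodes <- function(node, parent_id = NA_integer_, depth = 0L,
                       branch = NA_character_) {
  row <- tibble::tibble(
    node_id = node$node_id, parent_id = parent_id, depth = depth,
    branch = branch, n = node$n, mean_cost = node$mean_cost,
    sd_cost = node$sd_cost, predictor = node$predictor,
    adjusted_p = node$adjusted_p, is_leaf = length(node$children) == 0
  )
  kids <- purrr::imap(node$children, function(ch, i) {
    walk_nodes(ch, node$node_id, depth + 1L,
               paste(node$merged_levels[[i]], collapse = "|"))
  })
  dplyr::bind_rows(row, kids)
}

#' Tidy a CHAID tree into one row per node
#'
#' @param x A `chaid_tree`.
#' @param ... Unused.
#' @return A tibble with `node_id`, `parent_id`, `depth`, `branch` (the merged
#'   category set leading into the node), `n`, `mean_cost`, `sd_cost`,
#'   `predictor` (split variable, `NA` for leaves), `adjusted_p`, `is_leaf`.
#' @method tidy chaid_tree
#' @export
tidy.chaid_tree <- function(x, ...) {
  walk_nodes(x$root)
}

#' @method glance chaid_tree
#' @export
glance.chaid_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble::tibble(n = x$n, n_nodes = nrow(nodes),
                 n_leaves = sum(nodes$is_leaf),
                 depth = max(nodes$depth),
                 split_variables = paste(sort(unique(
                   nodes$predictor[!is.na(nodes$predictor)])), collapse = ","))
}

#' @export
print.chaid_tree <- function(x, ...) {
  nodes <- tidy(x)
  cat(sprintf("CHAID tree on %s: n = %d, %d leaves, depth %d (%s mode)\n",
              x$response, x$n, sum(nodes$is_leaf), max(nodes$depth),
              x$control$response_mode))
  for (i in seq_len(nrow(nodes))) {
    r <- nodes[i, ]
    pad <- strrep("  ", r$depth)
    lab <- if (is.na(r$branch)) "root" else paste0("[", r$branch, "]")
    split_txt <- if (!is.na(r$predictor)) {
      sprintf(" -> split on %s (adj p = %.3g)", r$predictor, r$adjusted_p)
    } else ""
    cat(sprintf("%s%s: n = %d, mean = %.1f%s\n", pad, lab, r$n, r$mean_cost,
                split_txt))
  }
  invisible(x)
}

#' Variables the tree splits on
#'
#' @param tree A `chaid_tree`.
#' @param max_depth Consider only splits at node depth `< max_depth` from the
#'   root (default all).
#' @return Sorted character vector of split variable names.
#' @export
tree_split_variables <- function(tree, max_depth = Inf) {
  nodes <- tidy(tree)
  sel <- !is.na(nodes$predictor) & nodes$depth < max_depth
  sort(unique(nodes$predictor[sel]))
}

#' Serialize a CHAID tree to JSON
#'
#' Writes the node table (with parent pointers and merged-level sets) plus the
#' control settings. Two trees grown on identical data serialize identically.
#'
#' @param tree A `chaid_tree`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_chaid_json <- function(tree, path = NULL) {
  nodes <- tidy(tree)
  payload <- list(response = tree$response, n = tree$n,
                  control = unclass(tree$control),
                  predictors = as.list(tree$predictors),
                  nodes = nodes)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Extract a declarative DRG rule set from a fitted tree
#'
#' Each leaf becomes one rule: the conjunction of merged-category memberships
#' along its root-to-leaf path (conditions on the same predictor at different
#' depths are intersected). The resulting rules are mutually exclusive and
#' exhaustive over the category combinations observed in training.
#'
#' @param tree A `chaid_tree`.
#' @param name Rule-set name (default `"fitted"`).
#' @return A [drg_ruleset()] whose groups are labelled `DRG 1`, `DRG 2`, ...
#'   in left-to-right leaf order, with fallback label `"unassigned"`.
#' @export
extract_rules <- function(tree, name = "fitted") {
  rules <- list()
  walk <- function(node, constraints) {
    if (length(node$children) == 0) {
      conds <- purrr::imap(constraints, function(set, field) {
        list(field = field, op = "in", value = as.list(set))
      })
      rules[[length(rules) + 1]] <<- list(
        group = paste("DRG", length(rules) + 1), all_of = unname(conds))
      return(invisible(NULL))
    }
    for (i in seq_along(node$children)) {
      set <- node$merged_levels[[i]]
      new_constraints <- constraints
      if (node$predictor %in% names(constraints)) {
        new_constraints[[node$predictor]] <-
          intersect(constraints[[node$predictor]], set)
      } else {
        new_constraints[[node$predictor]] <- set
      }
      walk(node$children[[i]], new_constraints)
    }
  }
  walk(tree$root, list())
  if (length(rules) == 0) {
    rules <- list(list(group = "DRG 1", all_of = list()))
  }
  drg_ruleset(name = name,
              uses_los = any(c("los", "los_band") %in%
                               unlist(lapply(rules, function(r)
                                 vapply(r$all_of, `[[`, character(1), "field")))),
              rules = rules, fallback = "unassigned")
}
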