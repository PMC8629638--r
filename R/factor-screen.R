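#' Kruskal--Wallis H test with midranks and tie correction
#'
#' The rank-based one-way test used to screen candidate grouping variables
#' against hospitalization cost. Implements the classical statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_g R_g^2/n_g - 3(N+1)}
#' with midranks for ties, divided by the standard tie-correction factor
#' \eqn{1 - \sum (t^3 - t)/(N^3 - N)}; the p-value comes from the chi-squared
#' distribution with \eqn{k - 1} degrees of freedom.
#'
#' @param groups A list of two or more non-empty numeric vectors, one per
#'   group.
#' @return A list with `statistic` (H), `p_value`, and `df`. When every value
#'   in every group is identical the statistic is 0 and the p-value 1.
#' @export
#' @examples
#' kruskal_h(list(c(1, 2, 3), c(4, 5, 6)))
kruskal_h <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least two groups")
  }
  ng <- lengths(groups)
  if (any(ng == 0)) abort("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) abort("cost values must not be missing")
  g <- rep(seq_along(groups), ng)
  N <- length(values)
  k <- length(groups)
  r <- rank(values)  # midranks
  Rg <- vapply(split(r, g), sum, numeric(1))
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  tie <- table(values)
  correction <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (correction <= 0) {
    # all values identical: no information, by convention H = 0, p = 1
    return(list(statistic = 0, p_value = 1, df = k - 1))
  }
  H <- H / correction
  list(statistic = H, p_value = pchisq(H, df = k - 1, lower.tail = FALSE),
       df = k - 1)
}

screenable_variables <- function() {
  c("gender", "age_band", "insurance", "hospital_level", "los_band",
    "surgery", "discharge", "cc", "htn3")
}

#' Single-factor screening of hospitalization cost
#'
#' Runs a tie-corrected Kruskal--Wallis test of cost across the levels of each
#' candidate variable and tabulates per-level size, share, median cost and
#' cost IQR. Age and length of stay are discretized with [add_bands()] before
#' testing; logical fields are treated as yes/no factors.
#'
#' @param claims A claims tibble.
#' @param variables Character vector of variables to screen (defaults to the
#'   standard demographic/clinical candidates).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per variable: `variable`, `statistic` (H),
#'   `df`, `p_value`, `significant`, `testable` (FALSE when only one level is
#'   observed, in which case the test is not run), and a `levels` list-column
#'   of per-level tibbles (`label`, `n`, `pct`, `median_cost`, `iqr_cost`).
#' @export
#' @examples
#' claims <- simulate_claims(2000, seed = 7)
#' screen_factors(claims)
screen_factors <- function(claims, variables = screenable_variables(),
                           alpha = 0.05) {
  if (nrow(claims) == 0) abort("no claims to screen")
  data <- add_bands(claims)
  data$htn3 <- factor(ifelse(data$htn3, "yes", "no"), levels = c("yes", "no"))
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("unknown variable(s): ", paste(missing_vars, collapse = ", ")))
  }
  purrr::map_dfr(variables, function(v) {
    f <- factor(data[[v]])
    lev <- levels(f)[table(f) > 0]
    level_tbl <- purrr::map_dfr(lev, function(l) {
      cost <- data$cost[f == l]
      tibble::tibble(label = l, n = length(cost),
                     pct = 100 * length(cost) / nrow(data),
                     median_cost = median(cost), iqr_cost = iqr7(cost))
    })
    testable <- length(lev) >= 2
    if (testable) {
      kw <- kruskal_h(split(data$cost, factor(f, levels = lev)))
      tibble::tibble(variable = v, statistic = kw$statistic, df = kw$df,
                     p_value = kw$p_value,
                     significant = kw$p_value < alpha, testable = TRUE,
                     levels = list(level_tbl))
    } else {
      tibble::tibble(variable = v, statistic = NA_real_, df = NA_integer_,
                     p_value = NA_real_, significant = NA, testable = FALSE,
                     levels = list(level_tbl))
    }
  })
}

#' Flatten a factor screen into a long, export-ready table
#'
#' One row per (variable, level), in the layout of a published single-factor
#' analysis table: level size and share, median cost with IQR, and the
#' variable-level test statistic and p-value repeated on each of its rows.
#'
#' @param screen Result of [screen_factors()].
#' @return A tibble.
#' @export
factor_table <- function(screen) {
  tidyr::unnest(
    dplyr::select(screen, "variable", "statistic", "p_value", "levels"),
    "levels"
  )[, c("variable", "label", "n", "pct", "median_cost", "iqr_cost",
        "statistic", "p_value")]
}
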