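#' Case-mix weight of a group
#'
#' Relative resource intensity: the group's average cost divided by the
#' overall average cost. A weight above 1 marks a group consuming more than
#' the average patient.
#'
#' @param group_mean Group mean cost (USD); vectorized.
#' @param overall_mean Overall mean cost (USD); must be positive.
#' @return `group_mean / overall_mean`.
#' @export
#' @examples
#' round(compute_weight(2957, 1284), 2)  # 2.30
compute_weight <- function(group_mean, overall_mean) {
  if (!is.numeric(overall_mean) || length(overall_mean) != 1 ||
      is.na(overall_mean) || overall_mean <= 0) {
    abort("`overall_mean` must be a single positive number")
  }
  group_mean / overall_mean
}

#' Outlier cost limit of a group (P75 + 1.5 IQR fence)
#'
#' The per-group fence above which spending is treated as oversupply:
#' \eqn{P_{75} + 1.5 (P_{75} - P_{25})}, with quantiles by linear
#' interpolation (the type-7 convention). Always at least \eqn{P_{75}}.
#'
#' @param costs Non-empty numeric vector of within-group costs (USD).
#' @return The cost limit (USD).
#' @export
#' @examples
#' compute_cost_limit(1:8)  # 11.5
compute_cost_limit <- function(costs) {
  if (length(costs) == 0) abort("`costs` must be non-empty")
  q <- quantile7(costs, c(0.25, 0.75))
  q[2] + 1.5 * (q[2] - q[1])
}

#' Spending above a group's cost limit
#'
#' @param costs Numeric vector of within-group costs (USD).
#' @param limit Cost limit, typically from [compute_cost_limit()].
#' @return A list: `excess_n` (count of costs strictly above the limit),
#'   `excess_pct` (100 * excess_n / n), `excess_amount_total`
#'   (sum of cost minus limit over those records; >= 0).
#' @export
#' @examples
#' compute_excess(c(1, 1, 1, 10), limit = 2)
compute_excess <- function(costs, limit) {
  over <- costs > limit
  list(excess_n = sum(over),
       excess_pct = if (length(costs) > 0) 100 * sum(over) / length(costs) else 0,
       excess_amount_total = sum(pmax(0, costs - limit)))
}

#' Per-group case-mix summary
#'
#' Computes, for each DRG, the published-table columns: size and share, mean,
#' median and IQR of cost, coefficient of variation (sample standard
#' deviation over mean; CV < 1 is the within-group homogeneity criterion),
#' case-mix weight against the overall mean of all grouped records, the
#' P75 + 1.5 IQR cost limit, outlier excess counts and dollar totals, and the
#' mean age/LOS of outlier versus non-outlier patients.
#'
#' The weighted mean of the weights is exactly 1:
#' \eqn{\sum_g n_g w_g / N = 1}.
#'
#' @param claims A claims tibble with a `drg` column (see [assign_drg()]).
#' @return A `group_summary` tibble, one row per group, with attributes
#'   `overall_mean` and `n_total`. Groups of size 1 have undefined CV,
#'   reported as 0 with `cv_defined = FALSE`.
#' @export
#' @examples
#' claims <- clean_claims(simulate_claims(2000, seed = 9))
#' summarize_groups(assign_drg(claims, builtin_ruleset("with_los")))
summarize_groups <- function(claims) {
  if (!"drg" %in% names(claims)) abort("claims must carry a `drg` column")
  if (nrow(claims) == 0) abort("no grouped claims to summarize")
  overall_mean <- mean(claims$cost)
  n_total <- nrow(claims)
  out <- claims |>
    dplyr::group_by(.data$drg) |>
    dplyr::group_modify(function(g, key) {
      limit <- compute_cost_limit(g$cost)
      ex <- compute_excess(g$cost, limit)
      over <- g$cost > limit
      cv_defined <- nrow(g) > 1
      s <- if (cv_defined) sd(g$cost) else 0
      tibble::tibble(
        n = nrow(g),
        pct = 100 * nrow(g) / n_total,
        mean_cost = mean(g$cost),
        median_cost = median(g$cost),
        iqr_cost = iqr7(g$cost),
        cv = if (cv_defined) s / mean(g$cost) else 0,
        cv_defined = cv_defined,
        homogeneous = (if (cv_defined) s / mean(g$cost) else 0) < 1,
        weight = compute_weight(mean(g$cost), overall_mean),
        cost_limit = limit,
        excess_n = ex$excess_n,
        excess_pct = ex$excess_pct,
        excess_amount_total = ex$excess_amount_total,
        outlier_mean_age = if (any(over)) mean(g$age[over]) else NA_real_,
        inlier_mean_age = if (any(!over)) mean(g$age[!over]) else NA_real_,
        outlier_mean_los = if (any(over)) mean(g$los[over]) else NA_real_,
        inlier_mean_los = if (any(!over)) mean(g$los[!over]) else NA_real_
      )
    }) |>
    dplyr::ungroup()
  attr(out, "overall_mean") <- overall_mean
  attr(out, "n_total") <- n_total
  class(out) <- c("group_summary", class(out))
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Case-mix summary: %d groups, N = %d, overall mean = %.1f USD\n",
              nrow(x), attr(x, "n_total"), attr(x, "overall_mean")))
  NextMethod()
}
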