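#' Clean a claims table with an auditable removal ledger
#'
#' Applies the cohort-definition filters in a fixed, declared order and counts
#' removals per filter:
#'
#' 1. `hospital_type` -- keep only comprehensive hospitals (township,
#'    community, school and other facility types are removed);
#' 2. `cost_outlier` -- remove claims whose log-cost falls outside
#'    \[P25 - k IQR, P75 + k IQR\] of log-cost over the records that survived
#'    filter 1 (type-7 quantiles; `k = fence_mult`, default 3). A zero cost
#'    has log-cost `-Inf` and is always fenced out;
#' 3. `age` -- remove patients younger than 18 (age 18 is retained);
#' 4. `out_of_city` -- remove patients hospitalized outside the study city
#'    but reimbursed by its insurance administration.
#'
#' The filter order is part of the contract: the outlier fence is computed on
#' the post-filter-1 set, so reordering changes the result.
#'
#' @param claims A claims tibble (see [read_claims()] or [simulate_claims()]).
#' @param fence_mult IQR multiplier of the log-cost outlier fence (default 3).
#' @return The cleaned claims tibble with a `cleaning_report` attribute;
#'   retrieve the report with [cleaning_report()].
#' @export
#' @examples
#' claims <- simulate_claims(500, seed = 1)
#' cleaned <- clean_claims(claims)
#' cleaning_report(cleaned)
clean_claims <- function(claims, fence_mult = 3) {
  stopifnot(is.numeric(fence_mult), fence_mult >= 0)
  n_input <- nrow(claims)
  removed <- c(hospital_type = 0L, cost_outlier = 0L, age = 0L, out_of_city = 0L)

  keep <- !is.na(claims$hospital_type) & claims$hospital_type == "comprehensive"
  removed["hospital_type"] <- sum(!keep)
  claims <- claims[keep, ]

  if (nrow(claims) > 0) {
    lc <- suppressWarnings(log(claims$cost))
    finite_lc <- lc[is.finite(lc)]
    if (length(finite_lc) > 0) {
      q <- quantile7(finite_lc, c(0.25, 0.75))
      iqr <- q[2] - q[1]
      lo <- q[1] - fence_mult * iqr
      hi <- q[2] + fence_mult * iqr
      keep <- lc >= lo & lc <= hi
    } else {
      keep <- rep(FALSE, nrow(claims))
    }
    removed["cost_outlier"] <- sum(!keep)
    claims <- claims[keep, ]
  }

  keep <- claims$age >= 18
  removed["age"] <- sum(!keep)
  claims <- claims[keep, ]

  keep <- claims$in_city
  removed["out_of_city"] <- sum(!keep)
  claims <- claims[keep, ]

  report <- structure(
    list(n_input = n_input, removed_by_filter = as.list(removed),
         n_valid = nrow(claims), fence_mult = fence_mult),
    class = "cleaning_report"
  )
  attr(claims, "cleaning_report") <- report
  claims
}

#' Retrieve the cleaning report attached to a cleaned claims tibble
#'
#' @param claims A tibble returned by [clean_claims()].
#' @return A `cleaning_report` object: `n_input`, `removed_by_filter`
#'   (named counts in application order), `n_valid`. Always satisfies
#'   `n_input == n_valid + sum(removed)`.
#' @export
cleaning_report <- function(claims) {
  rep <- attr(claims, "cleaning_report")
  if (is.null(rep)) abort("no cleaning report attached; run clean_claims() first")
  rep
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.cleaning_report <- function(x, ...) {
  c(sprintf("Claims cleaning report: %d in, %d valid", x$n_input, x$n_valid),
    sprintf("  removed by %-14s %d", paste0(names(x$removed_by_filter), ":"),
            unlist(x$removed_by_filter)))
}

#' Tidy a cleaning report into one row per filter
#'
#' @param x A `cleaning_report`.
#' @param ... Unused.
#' @return A tibble with columns `filter`, `n_removed`, plus the totals as
#'   attributes-free rows (`input` and `valid` appear as pseudo-filters is
#'   avoided; totals are in [glance.cleaning_report()]).
#' @method tidy cleaning_report
#' @export
tidy.cleaning_report <- function(x, ...) {
  tibble::tibble(filter = names(x$removed_by_filter),
                 n_removed = unlist(x$removed_by_filter, use.names = FALSE))
}

#' @rdname tidy.cleaning_report
#' @method glance cleaning_report
#' @export
glance.cleaning_report <- function(x, ...) {
  tibble::tibble(n_input = x$n_input, n_valid = x$n_valid,
                 n_removed = x$n_input - x$n_valid, fence_mult = x$fence_mult)
}

#' Serialize a cleaning report to JSON
#'
#' @param report A `cleaning_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
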