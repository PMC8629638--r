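#' Blockwise stepwise linear model of hospitalization cost
#'
#' Multiple-factor analysis: an ordinary least squares model of cost on
#' categorical predictors, built by forward entry and backward elimination of
#' whole variables (every dummy of a categorical predictor enters or leaves
#' together). Block significance is judged by the partial F test comparing
#' the models with and without the block: a block enters when it has the
#' smallest entry p-value and that p-value is below `alpha_in`; a fitted block
#' is dropped when its deletion p-value is the largest above `alpha_out`.
#' Identity-link least squares is used throughout, so the reported
#' t-statistics, \eqn{R^2} and condition index are the usual OLS quantities.
#'
#' A candidate block that adds no rank to the design (perfect collinearity
#' with terms already in the model) is skipped with a warning, never an error.
#'
#' The condition index `kappa` is the square root of the ratio of the largest
#' to smallest eigenvalue of the correlation-scaled cross-product of the final
#' design matrix (intercept excluded); values near 1 indicate no
#' multicollinearity.
#'
#' @param data A data frame of claims; age/LOS bands are added with
#'   [add_bands()] if any candidate needs them.
#' @param response Response column (default `"cost"`).
#' @param candidates Character vector of candidate predictor columns.
#' @param ref_levels Optional named character vector giving the reference
#'   level per factor (e.g. `c(gender = "male")`).
#' @param alpha_in Entry threshold (default 0.05).
#' @param alpha_out Removal threshold (default 0.10); must be `>= alpha_in`
#'   to guarantee termination.
#' @return A `stepwise_fit` object; see [tidy.stepwise_fit()] and
#'   [glance.stepwise_fit()].
#' @export
#' @examples
#' claims <- simulate_claims(2000, seed = 3)
#' fit <- stepwise_fit(claims, candidates = c("gender", "hospital_level", "los_band"))
#' glance(fit)
stepwise_fit <- function(data, response = "cost", candidates,
                         ref_levels = NULL, alpha_in = 0.05, alpha_out = 0.10) {
  stopifnot(alpha_in > 0, alpha_in < 1, alpha_out >= alpha_in, alpha_out < 1)
  if (any(c("age_band", "los_band") %in% candidates) &&
      !all(c("age_band", "los_band") %in% names(data))) {
    data <- add_bands(data)
  }
  missing_vars <- setdiff(c(response, candidates), names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("unknown column(s): ", paste(missing_vars, collapse = ", ")))
  }
  df <- data[, c(response, candidates)]
  df <- df[complete.cases(df), ]
  for (v in candidates) {
    if (!is.numeric(df[[v]])) {
      # plain (unordered) factors so coefficients are reference-level dummies,
      # not polynomial contrasts
      df[[v]] <- factor(as.character(df[[v]]), levels = levels(factor(df[[v]])))
    }
    if (!is.null(ref_levels) && v %in% names(ref_levels)) {
      df[[v]] <- stats::relevel(factor(df[[v]]), ref = ref_levels[[v]])
    } else if (is.factor(df[[v]])) {
      df[[v]] <- factor(df[[v]])  # drop unused levels
    }
  }

  fit_for <- function(terms) {
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    lm(as.formula(paste(response, "~", rhs)), data = df)
  }
  block_p_enter <- function(current, cand) {
    small <- fit_for(current)
    big <- fit_for(c(current, cand))
    # no added rank => perfectly collinear with current terms
    if (big$rank <= small$rank) return(NA_real_)
    a <- anova(small, big)
    p <- a[["Pr(>F)"]][2]
    if (is.na(p)) p <- 0  # zero residual variance in the big model
    p
  }
  block_p_drop <- function(current, v) {
    big <- fit_for(current)
    small <- fit_for(setdiff(current, v))
    if (big$rank <= small$rank) return(1)
    a <- anova(small, big)
    p <- a[["Pr(>F)"]][2]
    if (is.na(p)) p <- 0
    p
  }

  selected <- character(0)
  skipped <- character(0)
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, c(selected, skipped))
    if (length(pool) > 0) {
      pvals <- vapply(pool, function(v) block_p_enter(selected, v), numeric(1))
      collinear <- pool[is.na(pvals)]
      if (length(collinear) > 0) {
        warn(paste0("skipping collinear candidate block(s): ",
                    paste(collinear, collapse = ", ")))
        skipped <- c(skipped, collinear)
        pool <- setdiff(pool, collinear)
        pvals <- pvals[!is.na(pvals)]
      }
      if (length(pool) > 0 && min(pvals) < alpha_in) {
        selected <- c(selected, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    if (length(selected) > 0) {
      dp <- vapply(selected, function(v) block_p_drop(selected, v), numeric(1))
      if (max(dp) > alpha_out) {
        dropped <- selected[which.max(dp)]
        selected <- setdiff(selected, dropped)
        skipped <- c(skipped, dropped)  # do not re-enter a dropped block
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  final <- fit_for(selected)
  X <- model.matrix(final)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  kappa_val <- NA_real_
  if (ncol(X) > 0) {
    sds <- apply(X, 2, sd)
    Xs <- scale(X[, sds > 0, drop = FALSE])
    if (ncol(Xs) > 0) {
      ev <- eigen(crossprod(Xs) / (nrow(Xs) - 1), symmetric = TRUE,
                  only.values = TRUE)$values
      ev <- ev[ev > max(ev) * 1e-12]
      kappa_val <- sqrt(max(ev) / min(ev))
    }
  }
  smry <- summary(final)
  structure(
    list(fit = final, selected = selected, skipped = skipped,
         response = response, r_squared = smry$r.squared,
         adj_r_squared = smry$adj.r.squared, kappa = kappa_val,
         n_used = nrow(df), alpha_in = alpha_in, alpha_out = alpha_out),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Blockwise stepwise OLS of", x$response, "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  n = %d, R-squared = %.3f, kappa = %.2f\n",
              x$n_used, x$r_squared, x$kappa))
  invisible(x)
}

#' Coefficient table of a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (t-value), `p.value` -- the layout of a published multiple-regression
#'   table.
#' @method tidy stepwise_fit
#' @export
tidy.stepwise_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3], p.value = cf[, 4])
}

#' One-row model summary of a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `adj.r.squared`, `kappa` (condition
#'   index), `n`, `n_selected`.
#' @method glance stepwise_fit
#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
                 kappa = x$kappa, n = x$n_used,
                 n_selected = length(x$selected))
}
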