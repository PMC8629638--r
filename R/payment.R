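#' Fee-for-service versus DRG payment under stepped control of oversupply
#'
#' Groups the claims with a DRG rule set, takes each group's mean cost as the
#' DRG payment standard, treats within-group spending above the
#' P75 + 1.5 IQR cost limit as oversupply, and simulates recovering a fraction
#' (the control intensity) of every record's above-limit spend. With total
#' excess \eqn{E = \sum_g \sum_{i: c_i > L_g} (c_i - L_g)} and
#' fee-for-service total \eqn{T}, a scenario at intensity \eqn{c} has
#' society total \eqn{T - cE}, hospital revenue change \eqn{-cE}, and
#' per-patient averages obtained by dividing by \eqn{N}. Savings are exactly
#' linear in the intensity.
#'
#' @param claims A cleaned claims tibble. Records with `surgery == "unknown"`
#'   should be excluded before grouping runs.
#' @param ruleset A [drg_ruleset()].
#' @param intensities Control intensities in \[0, 1\] (default 0.1 ... 1.0).
#' @return A `control_sweep` object: `ruleset_name`, `n`, `ffs_total`,
#'   `excess_total`, `scenarios` (tibble with `intensity`, `society_total`,
#'   `society_avg`, `hospital_total_delta`, `hospital_avg_delta`) and the
#'   underlying `group_summary`. When no record exceeds its group limit the
#'   sweep is flagged (`no_excess = TRUE`) and all scenarios equal FFS.
#' @export
#' @examples
#' claims <- clean_claims(simulate_claims(2000, seed = 13))
#' claims <- dplyr::filter(claims, surgery != "unknown")
#' sweep <- run_control_sweep(claims, builtin_ruleset("with_los"))
#' tidy(sweep)
run_control_sweep <- function(claims, ruleset,
                              intensities = seq(0.1, 1, by = 0.1)) {
  if (any(intensities < 0 | intensities > 1)) {
    abort("intensities must lie in [0, 1]")
  }
  assigned <- assign_drg(claims, ruleset)
  summary <- summarize_groups(assigned)
  ffs_total <- sum(assigned$cost)
  excess_total <- sum(summary$excess_amount_total)
  n <- nrow(assigned)
  if (excess_total == 0) {
    inform("no record exceeds its group cost limit; all scenarios equal FFS")
  }
  scenarios <- tibble::tibble(
    intensity = intensities,
    society_total = ffs_total - intensities * excess_total,
    society_avg = (ffs_total - intensities * excess_total) / n,
    hospital_total_delta = -intensities * excess_total,
    hospital_avg_delta = -intensities * excess_total / n
  )
  structure(
    list(ruleset_name = ruleset$name, n = n, ffs_total = ffs_total,
         ffs_avg = ffs_total / n, excess_total = excess_total,
         no_excess = excess_total == 0, scenarios = scenarios,
         group_summary = summary),
    class = "control_sweep"
  )
}

#' @export
print.control_sweep <- function(x, ...) {
  cat(sprintf("Control sweep ('%s'): n = %d, FFS total = %.0f USD, excess E = %.0f USD\n",
              x$ruleset_name, x$n, x$ffs_total, x$excess_total))
  print(x$scenarios)
  invisible(x)
}

#' Scenario table of a control sweep
#'
#' @param x A `control_sweep`.
#' @param ... Unused.
#' @return The scenarios tibble (one row per control intensity).
#' @method tidy control_sweep
#' @export
tidy.control_sweep <- function(x, ...) x$scenarios

#' @method glance control_sweep
#' @export
glance.control_sweep <- function(x, ...) {
  tibble::tibble(ruleset = x$ruleset_name, n = x$n, ffs_total = x$ffs_total,
                 ffs_avg = x$ffs_avg, excess_total = x$excess_total,
                 max_saving = x$excess_total,
                 n_groups = nrow(x$group_summary))
}

#' Split total spending between insurer and patients
#'
#' @param claims A claims tibble.
#' @param insurer_paid Numeric vector (or column name in `claims`) of the
#'   insurer-paid amount per record; each must lie in \[0, cost\].
#' @return A tibble with `insurer_total`, `patient_total`, `grand_total`
#'   (always `insurer_total + patient_total`, which equals the sum of costs).
#' @export
#' @examples
#' claims <- simulate_claims(100, seed = 2)
#' payer_split(claims, insurer_paid = 0.85 * claims$cost)
payer_split <- function(claims, insurer_paid) {
  if (is.character(insurer_paid) && length(insurer_paid) == 1) {
    insurer_paid <- claims[[insurer_paid]]
    if (is.null(insurer_paid)) abort("insurer_paid column not found")
  }
  if (nrow(claims) == 0) {
    return(tibble::tibble(insurer_total = 0, patient_total = 0, grand_total = 0))
  }
  stopifnot(length(insurer_paid) == nrow(claims))
  bad <- which(insurer_paid > claims$cost | insurer_paid < 0)
  if (length(bad) > 0) {
    abort(paste0("insurer-paid amount outside [0, cost] for row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  tibble::tibble(insurer_total = sum(insurer_paid),
                 patient_total = sum(claims$cost - insurer_paid),
                 grand_total = sum(claims$cost))
}
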