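#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. All
#' stochastic steps (generation, train/test split, tree resampling) draw from
#' the single mandatory seed, so a run is reproducible from its echoed
#' configuration alone.
#'
#' @param seed Integer seed (mandatory).
#' @param n Number of synthetic claims to generate when no input CSV is given.
#' @param claims_csv Optional path to an existing claims CSV; when set, `n`
#'   and the generator config are ignored.
#' @param schema Optional schema (list or YAML path) passed to [read_claims()].
#' @param sim [sim_config()] for the generator.
#' @param fence_mult Cleaning fence multiplier (see [clean_claims()]).
#' @param ruleset `"with_los"`, `"without_los"`, or `"fitted"` (extract rules
#'   from the tree grown on the training split).
#' @param use_los Whether the fitted tree may use the LOS band (only relevant
#'   for `ruleset = "fitted"`).
#' @param chaid [chaid_control()] for tree growth.
#' @param train_fraction Training fraction of the train/test split.
#' @param intensities Control intensities for the payment sweep.
#' @param alpha Significance level of the factor screen.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, n = 10000, claims_csv = NULL, schema = NULL,
                            sim = sim_config(), fence_mult = 3,
                            ruleset = c("with_los", "without_los", "fitted"),
                            use_los = TRUE, chaid = chaid_control(),
                            train_fraction = 0.8,
                            intensities = seq(0.1, 1, by = 0.1),
                            alpha = 0.05) {
  ruleset <- match.arg(ruleset)
  if (missing(seed)) abort("`seed` is mandatory")
  if (!is.null(claims_csv) && !file.exists(claims_csv)) {
    abort(paste0("claims file not found: ", claims_csv))
  }
  structure(list(seed = as.integer(seed), n = n, claims_csv = claims_csv,
                 schema = schema, sim = sim, fence_mult = fence_mult,
                 ruleset = ruleset, use_los = use_los, chaid = chaid,
                 train_fraction = train_fraction, intensities = intensities,
                 alpha = alpha),
            class = "pipeline_config")
}

grouping_predictors <- function(use_los = TRUE) {
  p <- c(hospital_level = "monotone", los_band = "monotone",
         age_band = "monotone", cc = "free", icd = "free", gender = "free",
         insurance = "free", discharge = "free")
  if (!use_los) p <- p[names(p) != "los_band"]
  p
}

write_csv_quiet <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  path
}

#' Run the full case-mix pipeline
#'
#' Chains the package end to end: obtain claims (generate or read), clean,
#' screen factors, fit the stepwise cost model, grow the CHAID tree on the
#' training split, group every cleaned record with the selected rule set, and
#' sweep the payment-control intensities. Each stage's table is written to
#' `output_dir` along with a structured run log (configuration echo and record
#' counts). Outputs carry no timestamps, so two runs with the same
#' configuration and seed produce byte-identical files.
#'
#' Grouping runs exclude records with `surgery == "unknown"` (no reliable
#' surgical information), mirroring standard case-mix practice; the exclusion
#' count is in the run log.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for artifacts (created if needed).
#' @return Invisibly, a list with the in-memory results: `claims`, `cleaned`,
#'   `screen`, `stepwise`, `tree`, `ruleset`, `group_summary`, `sweep`,
#'   `log`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 1, n = 2000)
#' res <- run_pipeline(cfg, output_dir = tempfile("run"))
#' res$sweep
#' }
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  claims <- if (!is.null(config$claims_csv)) {
    read_claims(config$claims_csv, schema = config$schema)
  } else {
    simulate_claims(config$n, seed = config$seed, config = config$sim)
  }
  write_claims(claims, file.path(output_dir, "claims.csv"))

  cleaned <- clean_claims(claims, fence_mult = config$fence_mult)
  report <- cleaning_report(cleaned)
  write_cleaning_report(report, file.path(output_dir, "cleaning_report.json"))

  screen <- screen_factors(cleaned, alpha = config$alpha)
  write_csv_quiet(factor_table(screen),
                  file.path(output_dir, "factor_screen.csv"))

  fit <- stepwise_fit(cleaned,
                      candidates = c("gender", "los_band", "hospital_level",
                                     "surgery", "discharge", "insurance",
                                     "cc", "age_band", "htn3"),
                      ref_levels = c(gender = "male", hospital_level = "secondary_B",
                                     surgery = "yes", discharge = "recovery",
                                     insurance = "urban", cc = "ischemic_supply"))
  write_csv_quiet(tidy(fit), file.path(output_dir, "stepwise.csv"))

  groupable <- dplyr::filter(cleaned, .data$surgery != "unknown")
  split <- split_train_test(groupable, fraction = config$train_fraction,
                            seed = config$seed + 1L)
  tree <- grow_tree(split$train, grouping_predictors(config$use_los),
                    control = config$chaid)
  write_chaid_json(tree, file.path(output_dir, "tree.json"))

  ruleset <- if (config$ruleset == "fitted") {
    extract_rules(tree)
  } else {
    builtin_ruleset(config$ruleset)
  }
  write_ruleset(ruleset, file.path(output_dir, "ruleset.yaml"))

  assigned <- assign_drg(groupable, ruleset)
  summary <- summarize_groups(assigned)
  write_csv_quiet(tibble::as_tibble(summary),
                  file.path(output_dir, "group_summary.csv"))

  sweep <- run_control_sweep(groupable, ruleset,
                             intensities = config$intensities)
  write_csv_quiet(tidy(sweep), file.path(output_dir, "sweep.csv"))

  log <- list(
    seed = config$seed,
    ruleset = ruleset$name,
    n_raw = nrow(claims),
    cleaning = unclass(report),
    n_groupable = nrow(groupable),
    n_surgery_unknown_excluded = nrow(cleaned) - nrow(groupable),
    n_train = nrow(split$train), n_test = nrow(split$test),
    tree_leaves = sum(tidy(tree)$is_leaf),
    ffs_total = sweep$ffs_total, excess_total = sweep$excess_total
  )
  jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(claims = claims, cleaned = cleaned, screen = screen,
                 stepwise = fit, tree = tree, ruleset = ruleset,
                 group_summary = summary, sweep = sweep, log = log))
}
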