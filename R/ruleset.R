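#' Declarative DRG rule set
#'
#' A rule set is an ordered list of rules; each rule is a conjunction of field
#' conditions and carries a group label. Assignment is first-match-wins in the
#' listed order, with a total fallback label for records matching no rule.
#'
#' Supported condition operators: `in` (field value in a category set), `lt`
#' (numeric less-than), `between` (inclusive numeric range, `value` of length
#' 2), `ge` (numeric greater-or-equal).
#'
#' @param name Rule-set name.
#' @param uses_los Whether length of stay appears in any rule (metadata).
#' @param rules List of rules, each `list(group = <label>, all_of =
#'   list(list(field =, op =, value =), ...))`; an empty `all_of` matches
#'   everything.
#' @param fallback Group label for records matching no rule.
#' @return A `drg_ruleset`.
#' @seealso [assign_drg()], [builtin_ruleset()], [read_ruleset()]
#' @export
drg_ruleset <- function(name, uses_los, rules, fallback = "unassigned") {
  ops <- c("in", "lt", "between", "ge")
  for (r in rules) {
    if (is.null(r$group)) abort("every rule needs a `group` label")
    for (cond in r$all_of) {
      if (!cond$op %in% ops) {
        abort(paste0("unsupported op `", cond$op, "` in rule ", r$group))
      }
      if (cond$field == "icd") {
        bad <- setdiff(unlist(cond$value), paste0("I6", 0:9))
        if (length(bad) > 0) {
          abort(paste0("ICD set outside I60-I69 in rule ", r$group, ": ",
                       paste(bad, collapse = ", ")))
        }
      }
    }
  }
  structure(list(name = name, uses_los = isTRUE(uses_los), rules = rules,
                 fallback = fallback),
            class = "drg_ruleset")
}

#' @export
print.drg_ruleset <- function(x, ...) {
  cat(sprintf("DRG rule set '%s' (%d rules, %s LOS; fallback '%s')\n",
              x$name, length(x$rules), if (x$uses_los) "uses" else "no",
              x$fallback))
  for (r in x$rules) {
    conds <- vapply(r$all_of, function(cond) {
      val <- paste(unlist(cond$value), collapse = ",")
      sprintf("%s %s {%s}", cond$field, cond$op, val)
    }, character(1))
    cat(sprintf("  %s: %s\n", r$group,
                if (length(conds)) paste(conds, collapse = " & ") else "(all)"))
  }
  invisible(x)
}

#' Group labels of a rule set
#' @param ruleset A `drg_ruleset`.
#' @return Character vector of group labels in rule order.
#' @export
ruleset_groups <- function(ruleset) {
  vapply(ruleset$rules, `[[`, character(1), "group")
}

eval_condition <- function(claims, cond) {
  x <- claims[[cond$field]]
  if (is.null(x)) abort(paste0("rule references unknown field: ", cond$field))
  v <- cond$value
  switch(cond$op,
    "in" = as.character(x) %in% unlist(v),
    "lt" = as.numeric(x) < as.numeric(v[[1]]),
    "ge" = as.numeric(x) >= as.numeric(v[[1]]),
    "between" = {
      xv <- as.numeric(x)
      xv >= as.numeric(v[[1]]) & xv <= as.numeric(v[[2]])
    }
  )
}

#' Assign claims to DRG groups
#'
#' Evaluates the rule set's rules in order against every record; the first
#' matching rule wins and the fallback label is used when none matches. A
#' warning lists the distinct field combinations of any fallback records, so
#' an incomplete rule set is loud, never silent.
#'
#' @param claims A claims tibble. If a rule references `los_band` or
#'   `age_band` and the column is absent, bands are added with [add_bands()].
#' @return `claims` with a `drg` factor column appended (levels: group labels
#'   in rule order, plus the fallback if any record needed it).
#' @inheritParams assign_all
#' @export
#' @examples
#' claims <- simulate_claims(500, seed = 5)
#' assigned <- assign_drg(clean_claims(claims), builtin_ruleset("with_los"))
#' dplyr::count(assigned, drg)
assign_drg <- function(claims, ruleset) {
  stopifnot(inherits(ruleset, "drg_ruleset"))
  fields <- unique(unlist(lapply(ruleset$rules, function(r)
    vapply(r$all_of, `[[`, character(1), "field"))))
  if (any(c("los_band", "age_band") %in% fields) &&
      !all(c("los_band", "age_band") %in% names(claims))) {
    claims <- add_bands(claims)
  }
  n <- nrow(claims)
  drg <- rep(NA_character_, n)
  for (r in ruleset$rules) {
    open <- is.na(drg)
    if (!any(open)) break
    match <- rep(TRUE, n)
    for (cond in r$all_of) {
      match <- match & eval_condition(claims, cond)
    }
    drg[open & match] <- r$group
  }
  unmatched <- is.na(drg)
  if (any(unmatched)) {
    combos <- dplyr::distinct(claims[unmatched,
                                     intersect(fields, names(claims))])
    warn(paste0(sum(unmatched), " record(s) fell through to fallback '",
                ruleset$fallback, "'; unmatched combinations:\n",
                paste(utils::capture.output(print(as.data.frame(combos))),
                      collapse = "\n")))
    drg[unmatched] <- ruleset$fallback
  }
  lev <- c(ruleset_groups(ruleset),
           if (any(unmatched)) ruleset$fallback)
  claims$drg <- factor(drg, levels = lev)
  claims
}

#' Partition claims by DRG with per-group counts
#'
#' Convenience wrapper around [assign_drg()] that returns the per-group count
#' table (a partition: counts sum to `nrow(claims)`).
#'
#' @param claims A claims tibble.
#' @param ruleset A `drg_ruleset`.
#' @return A tibble with `drg`, `n`, `pct`.
#' @export
assign_all <- function(claims, ruleset) {
  assigned <- assign_drg(claims, ruleset)
  out <- dplyr::count(assigned, .data$drg, .drop = FALSE)
  out$pct <- 100 * out$n / max(sum(out$n), 1)
  out
}

ruleset_to_list <- function(ruleset) {
  list(name = ruleset$name, uses_los = ruleset$uses_los,
       fallback = ruleset$fallback, rules = ruleset$rules)
}

#' Read or write a DRG rule set as YAML
#'
#' The YAML dialect mirrors [drg_ruleset()]: top-level `name`, `uses_los`,
#' `fallback`, and an ordered `rules` list of `{group, all_of: [{field, op,
#' value}]}` entries.
#'
#' @param path YAML file path.
#' @return For `read_ruleset()`, a `drg_ruleset`; for `write_ruleset()`,
#'   `path` invisibly.
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) abort(paste0("ruleset file not found: ", path))
  y <- yaml::read_yaml(path)
  rules <- lapply(y$rules, function(r) {
    list(group = r$group, all_of = lapply(r$all_of %||% list(), function(cond) {
      list(field = cond$field, op = cond$op, value = as.list(cond$value))
    }))
  })
  drg_ruleset(name = y$name, uses_los = y$uses_los, rules = rules,
              fallback = y$fallback %||% "unassigned")
}

#' @rdname read_ruleset
#' @param ruleset A `drg_ruleset`.
#' @export
write_ruleset <- function(ruleset, path) {
  yaml::write_yaml(ruleset_to_list(ruleset), path)
  invisible(path)
}

#' Shipped cerebrovascular DRG rule sets
#'
#' Two reference rule sets for cerebrovascular (ICD-10 I60--I69) inpatient
#' grouping in a two-tier (secondary/tertiary) hospital system:
#'
#' * `"with_los"` -- 7 groups. Hospital level crossed with length-of-stay
#'   bands (secondary under/over 13 days; tertiary under 9 and 9--13 days),
#'   then, for long-stay tertiary patients, a comorbidity/diagnosis split:
#'   non-infarction comorbidity classes versus cerebral-infarction comorbidity
#'   split by principal-diagnosis block (I60/I63/I65/I66/I67/I69 vs
#'   I61/I62/I64/I68).
#' * `"without_los"` -- 8 groups. Secondary vs tertiary-B vs tertiary-A
#'   crossed with the comorbidity classes, with the cerebral-infarction
#'   tertiary groups further split by the same two principal-diagnosis blocks.
#'
#' Evaluation is first-match in the listed order; the hospital-by-LOS rules
#' precede the comorbidity rules in the with-LOS set, so the comorbidity split
#' applies to tertiary stays of 14+ days. The residual comorbidity class
#' (`other`) is carried in the non-infarction groups so both rule sets are
#' total over the claim domain. These published-style rule sets are fixtures:
#' they are what [extract_rules()] would distill from a fitted tree, frozen so
#' grouping and payment analyses are reproducible without refitting.
#'
#' @param name `"with_los"` or `"without_los"`.
#' @return A `drg_ruleset`.
#' @export
#' @examples
#' builtin_ruleset("with_los")
builtin_ruleset <- function(name = c("with_los", "without_los")) {
  name <- match.arg(name)
  path <- system.file("extdata", "rulesets", paste0(name, ".yaml"),
                      package = "casemixr")
  if (path == "") {  # during development, before installation
    path <- file.path("inst", "extdata", "rulesets", paste0(name, ".yaml"))
  }
  read_ruleset(path)
}
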