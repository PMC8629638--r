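test_that("case-mix weights reproduce the published worked examples at 2 dp", {
  expect_equal(round(compute_weight(2957, 1284), 2), 2.30)
  expect_equal(round(compute_weight(838, 1284), 2), 0.65)
  expect_equal(round(compute_weight(3151, 1284), 2), 2.45)
  expect_equal(compute_weight(1284, 1284), 1)
  expect_error(compute_weight(100, 0), "positive")
})

test_that("the cost limit matches the interpolated-quantile oracle", {
  expect_equal(compute_cost_limit(1:8), 11.5)  # P25 = 2.75, P75 = 6.25
  expect_equal(compute_cost_limit(rep(42, 5)), 42)
  set.seed(73)
  for (i in 1:20) {
    x <- rlnorm(sample(2:60, 1), 7, 0.5)
    q <- unname(quantile(x, c(0.25, 0.75), type = 7))
    expect_equal(compute_cost_limit(x), q[2] + 1.5 * (q[2] - q[1]))
    expect_gte(compute_cost_limit(x), q[2])
  }
  expect_error(compute_cost_limit(numeric(0)), "non-empty")
})

test_that("excess counts and percentages reproduce the published cells", {
  # 430 outliers of 1,172 -> 36.69%; 282 of 8,344 -> 3.38%
  mk <- function(n, n_over) c(rep(1, n - n_over), rep(10, n_over))
  ex1 <- compute_excess(mk(1172, 430), limit = 5)
  expect_equal(ex1$excess_n, 430)
  expect_equal(round(ex1$excess_pct, 2), 36.69)
  ex2 <- compute_excess(mk(8344, 282), limit = 5)
  expect_equal(round(ex2$excess_pct, 2), 3.38)
})

test_that("excess is zero when the limit clears every cost, and decreases in the limit", {
  x <- c(10, 20, 30)
  ex <- compute_excess(x, limit = 30)
  expect_equal(ex$excess_n, 0)
  expect_equal(ex$excess_pct, 0)
  expect_equal(ex$excess_amount_total, 0)
  limits <- seq(0, 35, by = 5)
  amounts <- vapply(limits, function(l) compute_excess(x, l)$excess_amount_total,
                    numeric(1))
  expect_true(all(diff(amounts) <= 0))
})

test_that("group summaries satisfy the weight-conservation identity", {
  claims <- assign_drg(clean_claims(simulate_claims(3000, seed = 79)),
                       builtin_ruleset("with_los"))
  gs <- summarize_groups(claims)
  expect_equal(sum(gs$n * gs$weight) / sum(gs$n), 1, tolerance = 1e-12)
  expect_equal(sum(gs$n), nrow(claims))
  expect_equal(sum(gs$pct), 100)
  expect_true(all(gs$cv >= 0))
  expect_true(all(gs$cost_limit >= gs$median_cost))
})

test_that("one group holding all records has weight 1 and pct 100", {
  claims <- simulate_claims(200, seed = 83)
  claims$drg <- factor("DRG 1")
  gs <- summarize_groups(claims)
  expect_equal(nrow(gs), 1)
  expect_equal(gs$weight, 1)
  expect_equal(gs$pct, 100)
})

test_that("degenerate costs give cv = 0 and a size-1 group is flagged", {
  claims <- make_claims(3, cost = c(1, 1, 1))
  claims$drg <- factor("G")
  gs <- summarize_groups(claims)
  expect_equal(gs$cv, 0)
  expect_true(gs$cv_defined)
  one <- make_claims(1)
  one$drg <- factor("G")
  gs1 <- summarize_groups(one)
  expect_equal(gs1$cv, 0)
  expect_false(gs1$cv_defined)
})

test_that("noise-free generation makes group means an exact function of the categories", {
  cfg <- sim_config(noise_sigma = 0, effects = list(
    gender = c(male = 1, female = 1), age_band = c(lt45 = 1, b45_60 = 1, ge60 = 1),
    insurance = c(urban = 1, rural = 1),
    los_band = c(short = 1, mid = 1, long = 1),
    surgery = c(yes = 1, no = 1, unknown = 1),
    discharge = c(recovery = 1, transfer = 1, death = 1, other = 1,
                  midway_checkout = 1),
    cc = c(ischemic_supply = 1, lacunar_infarction = 1, cerebral_infarction = 1,
           chronic_ischemia = 1, other = 1),
    htn3 = c(yes = 1, no = 1), icd_hemorrhagic = c(factor = 1)
  ))
  claims <- simulate_claims(3000, seed = 89, config = cfg)
  rs <- drg_ruleset("levels", uses_los = FALSE, rules = lapply(
    claim_levels()$hospital_level, function(l) {
      list(group = l, all_of = list(list(field = "hospital_level", op = "in",
                                         value = list(l))))
    }))
  gs <- summarize_groups(assign_drg(claims, rs))
  # only the hospital-level effect is active, so each group's mean is exact
  expected <- 700 * cfg$effects$hospital_level[as.character(gs$drg)]
  expect_equal(gs$mean_cost, unname(expected))
  expect_equal(gs$cv, rep(0, nrow(gs)))
})

test_that("estimated weights recover generating ratios within delta-method tolerance", {
  cfg <- sim_config(noise_sigma = 0.3)
  claims <- simulate_claims(2e4, seed = 97, config = cfg)
  rs <- drg_ruleset("levels", uses_los = FALSE, rules = lapply(
    claim_levels()$hospital_level, function(l) {
      list(group = l, all_of = list(list(field = "hospital_level", op = "in",
                                         value = list(l))))
    }))
  gs <- summarize_groups(assign_drg(claims, rs))
  # generating group means are exp(sigma^2/2) * E[other effects] * level factor;
  # the shared factors cancel in the weight, leaving level_factor / E[level factor]
  lev_eff <- cfg$effects$hospital_level
  p_lev <- cfg$category_probs$hospital_level
  true_weight <- lev_eff / sum(p_lev * lev_eff)
  for (i in seq_len(nrow(gs))) {
    g <- as.character(gs$drg[i])
    se <- gs$weight[i] * sqrt(gs$cv[i]^2 / gs$n[i] +
                                (sd(claims$cost) / mean(claims$cost))^2 / nrow(claims))
    expect_lt(abs(gs$weight[i] - true_weight[[g]]), 3 * se,
              label = paste("weight recovery for", g))
  }
})
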