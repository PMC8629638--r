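test_that("Bonferroni multiplier matches brute-force partition enumeration up to 6 categories", {
  for (c_orig in 1:6) {
    for (c_merged in 1:c_orig) {
      expect_equal(bonferroni_multiplier(c_orig, c_merged, "free"),
                   enumerate_partitions(c_orig, c_merged),
                   info = sprintf("free %d->%d", c_orig, c_merged))
      expect_equal(bonferroni_multiplier(c_orig, c_merged, "monotone"),
                   enumerate_contiguous(c_orig, c_merged),
                   info = sprintf("monotone %d->%d", c_orig, c_merged))
    }
  }
  expect_equal(bonferroni_multiplier(4, 2, "monotone"), 3)
  expect_equal(bonferroni_multiplier(4, 2, "free"), 7)
  expect_equal(bonferroni_multiplier(5, 5, "free"), 1)
  expect_equal(bonferroni_multiplier(5, 5, "monotone"), 1)
})

test_that("categories with identical value multisets all merge into one group", {
  v <- c(1, 2, 3, 4, 5)
  res <- merge_categories(list(a = v, b = v, c = v))
  expect_length(res$partition, 1)
  expect_setequal(res$partition[[1]], c("a", "b", "c"))
  expect_equal(res$p_value, 1)
})

test_that("a single category yields the trivial partition with p = 1", {
  res <- merge_categories(list(only = rnorm(10)))
  expect_length(res$partition, 1)
  expect_equal(res$p_value, 1)
})

test_that("a shifted category separates from two equal ones in nearly every replicate", {
  hits <- 0
  isolated <- 0
  for (i in 1:100) {
    claims <- local({
      set.seed(1000 + i)
      list(a = rnorm(500), b = rnorm(500), c = rnorm(500, mean = 10))
    })
    res <- merge_categories(claims)
    ok <- length(res$partition) == 2 &&
      any(vapply(res$partition, function(p) setequal(p, c("a", "b")), logical(1)))
    hits <- hits + ok
    isolated <- isolated +
      any(vapply(res$partition, function(p) identical(p, "c"), logical(1)))
  }
  # the shifted category is always isolated; the two equal ones merge exactly
  # when their (null-uniform) pairwise p exceeds alpha_merge = 0.05, i.e. in
  # 95% of replicates -- so the bound is 3 binomial sd below that
  expect_equal(isolated, 100)
  expect_gte(hits, 88)
})

test_that("monotone merging only joins adjacent categories", {
  # outer categories identical, middle one far away: a free predictor would
  # merge {a, c}, a monotone one cannot
  set.seed(3)
  v <- list(a = rnorm(200), b = rnorm(200, 8), c = rnorm(200, 0.1))
  free <- merge_categories(v, kind = "free")
  mono <- merge_categories(v, kind = "monotone")
  expect_true(any(vapply(free$partition, function(p) setequal(p, c("a", "c")),
                         logical(1))))
  expect_length(mono$partition, 3)
  for (p in mono$partition) {
    idx <- sort(match(p, c("a", "b", "c")))
    expect_true(all(diff(idx) == 1))
  }
})

test_that("binned chi-squared mode also separates a strongly shifted category", {
  set.seed(5)
  v <- list(a = rnorm(400), b = rnorm(400), c = rnorm(400, 10))
  res <- merge_categories(v, control = chaid_control(response_mode = "binned_chi2"))
  expect_length(res$partition, 2)
  expect_true(any(vapply(res$partition, function(p) setequal(p, c("a", "b")),
                         logical(1))))
})

test_that("constant response grows a single leaf", {
  claims <- make_claims(1000, cost = rep(100, 1000),
                        hospital_level = rep(c("secondary_B", "tertiary_A"), 500))
  tree <- grow_tree(claims, c(hospital_level = "monotone"))
  nodes <- tidy(tree)
  expect_equal(nrow(nodes), 1)
  expect_true(nodes$is_leaf)
})

test_that("a two-mean separation on hospital level is recovered at the root in >= 99% of replicates", {
  hits <- 0
  for (i in 1:50) {
    lev <- local({set.seed(2000 + i)
      sample(c("secondary_B", "tertiary_A"), 4000, replace = TRUE)})
    cost <- local({set.seed(3000 + i)
      rnorm(4000, mean = ifelse(lev == "tertiary_A", 2000, 600), sd = 100)})
    claims <- make_claims(4000, cost = cost, hospital_level = lev)
    tree <- grow_tree(claims, c(hospital_level = "monotone", cc = "free",
                                gender = "free"))
    hits <- hits + (tidy(tree)$predictor[1] == "hospital_level")
  }
  expect_gte(hits, 50)  # 50/50 at this separation; the contract is >= 99%
})

test_that("regrowing on identical data serializes identically", {
  claims <- simulate_claims(3000, seed = 41)
  preds <- c(hospital_level = "monotone", los_band = "monotone", cc = "free")
  t1 <- grow_tree(claims, preds)
  t2 <- grow_tree(claims, preds)
  expect_identical(write_chaid_json(t1), write_chaid_json(t2))
})

test_that("child counts sum to parent counts at every node", {
  claims <- simulate_claims(5000, seed = 43)
  tree <- grow_tree(claims, c(hospital_level = "monotone",
                              los_band = "monotone", cc = "free",
                              icd = "free"))
  nodes <- tidy(tree)
  for (id in nodes$node_id[!nodes$is_leaf]) {
    kids <- nodes[!is.na(nodes$parent_id) & nodes$parent_id == id, ]
    expect_equal(sum(kids$n), nodes$n[nodes$node_id == id])
  }
  expect_true(all(nodes$adjusted_p >= 0 & nodes$adjusted_p <= 1, na.rm = TRUE))
})

test_that("adjusted p-values are never below the raw omnibus p", {
  set.seed(47)
  v <- list(a = rnorm(300), b = rnorm(300, 0.5), c = rnorm(300, 3),
            d = rnorm(300, 3.2))
  res <- merge_categories(v, kind = "free")
  mult <- bonferroni_multiplier(4, length(res$partition), "free")
  expect_gte(mult, 1)
  expect_gte(min(1, res$p_value * mult), res$p_value)
})

test_that("split variables are stable across seeded resamples of a strong 2-variable structure", {
  sets <- lapply(1:10, function(i) {
    claims <- simulate_claims(4000, seed = 5000 + i, config = sim_config(
      noise_sigma = 0.2,
      effects = list(gender = c(male = 1, female = 1),
                     age_band = c(lt45 = 1, b45_60 = 1, ge60 = 1),
                     insurance = c(urban = 1, rural = 1),
                     surgery = c(yes = 1, no = 1, unknown = 1),
                     discharge = c(recovery = 1, transfer = 1, death = 1,
                                   other = 1, midway_checkout = 1),
                     cc = c(ischemic_supply = 1, lacunar_infarction = 1,
                            cerebral_infarction = 1, chronic_ischemia = 1,
                            other = 1),
                     htn3 = c(yes = 1, no = 1),
                     icd_hemorrhagic = c(factor = 1))))
    tree <- grow_tree(claims, c(hospital_level = "monotone",
                                los_band = "monotone", cc = "free",
                                gender = "free"))
    paste(tree_split_variables(tree, max_depth = 2), collapse = "+")
  })
  modal <- names(sort(table(unlist(sets)), decreasing = TRUE))[1]
  expect_gte(sum(unlist(sets) == modal), 9)
  expect_equal(modal, "hospital_level+los_band")
})

test_that("extracted rules partition the training records one-to-one", {
  claims <- simulate_claims(4000, seed = 53)
  tree <- grow_tree(claims, c(hospital_level = "monotone",
                              los_band = "monotone", cc = "free"))
  rules <- extract_rules(tree)
  expect_equal(length(rules$rules), sum(tidy(tree)$is_leaf))
  assigned <- assign_drg(add_bands(claims), rules)
  expect_false(any(assigned$drg == rules$fallback))
  counts <- table(assigned$drg)
  expect_equal(sum(counts), nrow(claims))
  leaf_n <- sort(tidy(tree)$n[tidy(tree)$is_leaf])
  expect_equal(sort(unname(as.vector(counts[counts > 0]))), leaf_n)
})

test_that("rules from a depth-2 tree are pairwise disjoint on an exhaustive grid", {
  set.seed(59)
  lev <- sample(c("secondary_B", "tertiary_A"), 3000, replace = TRUE)
  ccv <- sample(c("ischemic_supply", "cerebral_infarction", "other"), 3000,
                replace = TRUE)
  cost <- rnorm(3000,
                mean = 500 + 1500 * (lev == "tertiary_A") +
                  800 * (ccv == "cerebral_infarction"), sd = 80)
  claims <- make_claims(3000, cost = cost, hospital_level = lev, cc = ccv)
  tree <- grow_tree(claims, c(hospital_level = "monotone", cc = "free"))
  rules <- extract_rules(tree)
  grid <- tidyr::expand_grid(
    hospital_level = c("secondary_B", "tertiary_A"),
    cc = c("ischemic_supply", "cerebral_infarction", "other")
  )
  grid_claims <- make_claims(nrow(grid), hospital_level = grid$hospital_level,
                             cc = grid$cc)
  assigned <- assign_drg(grid_claims, rules)
  # every grid cell matches exactly one rule (partition over the domain)
  expect_false(any(is.na(assigned$drg)))
  expect_false(any(assigned$drg == rules$fallback))
})

test_that("a single-leaf tree extracts one catch-all rule", {
  claims <- make_claims(500, cost = rep(7, 500))
  tree <- grow_tree(claims, c(gender = "free"))
  rules <- extract_rules(tree)
  expect_length(rules$rules, 1)
  assigned <- assign_drg(make_claims(5), rules)
  expect_true(all(assigned$drg == "DRG 1"))
})
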