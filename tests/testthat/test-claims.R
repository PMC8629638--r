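test_that("a well-formed CSV reads to records with no row errors", {
  path <- write_raw_claims_csv(c(good_row("P1"), good_row("P2"), good_row("P3")))
  claims <- read_claims(path)
  expect_equal(nrow(claims), 3)
  expect_equal(nrow(claim_problems(claims)), 0)
  expect_s3_class(claims$hospital_level, "factor")
  expect_type(claims$cost, "double")
})

test_that("invalid rows are excluded and reported with field and row number", {
  path <- write_raw_claims_csv(c(
    good_row("P1"),
    good_row("P2", cost = "-5"),
    good_row("P3", icd = "J18"),
    good_row("P4", age = "12.5")
  ))
  claims <- read_claims(path)
  expect_equal(nrow(claims), 1)
  probs <- claim_problems(claims)
  expect_equal(probs$row, c(2L, 3L, 4L))
  expect_match(probs$message[probs$row == 2], "cost negative")
  expect_match(probs$message[probs$row == 3], "icd outside I60-I69")
  expect_match(probs$field[probs$row == 4], "age")
})

test_that("a missing mandatory column is a hard error", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,gender,age", "P1,male,50"), path)
  expect_error(read_claims(path), "missing mandatory column")
})

test_that("a schema maps foreign column names and category codes", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,sex,age,insurance,hospital_level,hospital_type,los,surgery,discharge,cc,htn3,icd,cost,in_city",
    "A1,1,50,urban,secondary_A,comprehensive,5,no,recovery,ischemic_supply,0,I63,100,1"
  ), path)
  schema <- list(
    columns = c(patient_id = "id", gender = "sex"),
    levels = list(gender = list(`1` = "male", `2` = "female"))
  )
  claims <- read_claims(path, schema = schema)
  expect_equal(nrow(claims), 1)
  expect_equal(as.character(claims$gender), "male")
  expect_false(claims$htn3)
})

test_that("claims round-trip through the canonical CSV dialect byte-stably", {
  claims <- simulate_claims(50, seed = 4)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_claims(claims, f1)
  back <- read_claims(f1)
  expect_equal(nrow(claim_problems(back)), 0)
  write_claims(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  for (col in names(claims)) {
    expect_equal(as.character(back[[col]]), as.character(claims[[col]]),
                 info = col)
  }
})

test_that("cleaning filters apply in the declared order with exact counts", {
  claims <- dplyr::bind_rows(
    make_claims(5, cost = c(100, 110, 120, 130, 140)),
    make_claims(1, hospital_type = "township"),
    make_claims(1, age = 17),
    make_claims(1, in_city = FALSE)
  )
  cleaned <- clean_claims(claims)
  rep <- cleaning_report(cleaned)
  expect_equal(rep$n_input, 8)
  expect_equal(rep$removed_by_filter$hospital_type, 1)
  expect_equal(rep$removed_by_filter$age, 1)
  expect_equal(rep$removed_by_filter$out_of_city, 1)
  expect_equal(rep$n_valid, 5)
})

test_that("a single under-age record is removed by the age filter", {
  cleaned <- clean_claims(make_claims(1, age = 17))
  rep <- cleaning_report(cleaned)
  expect_equal(rep$n_valid, 0)
  expect_equal(rep$removed_by_filter$age, 1)
})

test_that("age 18 is retained (strictly-younger boundary)", {
  cleaned <- clean_claims(make_claims(1, age = 18))
  expect_equal(cleaning_report(cleaned)$n_valid, 1)
})

test_that("identical costs collapse the fence and nothing is removed", {
  cleaned <- clean_claims(make_claims(10, cost = rep(500, 10)))
  rep <- cleaning_report(cleaned)
  expect_equal(rep$n_valid, 10)
  expect_equal(rep$removed_by_filter$cost_outlier, 0)
})

test_that("an extreme cost is removed by the fence, matching a brute-force oracle", {
  set.seed(71)
  costs <- c(exp(rnorm(99, log(1000), 0.3)), 1e6 * 1000)
  claims <- make_claims(100, cost = costs)
  cleaned <- clean_claims(claims)
  # independent fence computation on the same 100 log-costs
  lc <- log(costs)
  q <- unname(quantile(lc, c(0.25, 0.75), type = 7))
  expected_keep <- lc >= q[1] - 3 * (q[2] - q[1]) & lc <= q[2] + 3 * (q[2] - q[1])
  expect_equal(cleaning_report(cleaned)$removed_by_filter$cost_outlier,
               sum(!expected_keep))
  expect_false(1e9 %in% cleaned$cost)
  expect_setequal(cleaned$cost, costs[expected_keep])
})

test_that("count conservation holds for arbitrary inputs", {
  for (seed in 1:5) {
    claims <- simulate_claims(400, seed = seed)
    rep <- cleaning_report(clean_claims(claims))
    expect_equal(rep$n_input,
                 rep$n_valid + sum(unlist(rep$removed_by_filter)))
  }
})

test_that("empty input cleans to an empty output with a zeroed report", {
  cleaned <- clean_claims(make_claims(0))
  rep <- cleaning_report(cleaned)
  expect_equal(rep$n_input, 0)
  expect_equal(rep$n_valid, 0)
  expect_true(all(unlist(rep$removed_by_filter) == 0))
})

test_that("cleaning report serializes to JSON and tidies", {
  cleaned <- clean_claims(simulate_claims(200, seed = 8))
  rep <- cleaning_report(cleaned)
  path <- tempfile(fileext = ".json")
  write_cleaning_report(rep, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$n_input, 200)
  expect_equal(js$n_valid, rep$n_valid)
  td <- tidy(rep)
  expect_equal(td$filter, c("hospital_type", "cost_outlier", "age", "out_of_city"))
  expect_equal(sum(td$n_removed), 200 - rep$n_valid)
})
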