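#' Configuration for the synthetic claims generator
#'
#' The generator emulates the category structure of a one-year cerebrovascular
#' inpatient claims extract from a mid-sized city: each categorical field is
#' sampled independently from the cohort proportions below, and cost follows a
#' multiplicative log-normal model,
#' \deqn{cost = \exp(\mu_0 + \sum_j \log f_j + \varepsilon),\quad
#'       \varepsilon \sim N(0, \sigma^2),}
#' where \eqn{f_j} are per-level multiplicative effects. Costs are therefore
#' positive and right-skewed, matching the median-and-IQR scale of real
#' hospitalization bills. Default effect factors carry the directions
#' estimated in cerebrovascular cost regressions: female below male, longer
#' stays and higher hospital levels up, no surgery down, in-hospital death up,
#' rural insurance down, infarction/ischemia comorbidity classes below the
#' arterial-undersupply reference, older patients up. Hemorrhagic principal
#' diagnoses (I61, I62, I64, I68) carry a positive factor so the diagnosis
#' block is informative for grouping.
#'
#' Length of stay is sampled as a band (short/mid/long) and then as a uniform
#' integer day count within the band: 1--8, 9--13, 14--60 days. Age band 1 is
#' sampled on 16--44 years so a raw extract contains a small share of minors
#' for the age filter of [clean_claims()] to act on; bands 2 and 3 are
#' 45--59 and 60--95.
#'
#' @param category_probs Named list of probability vectors, one per sampled
#'   field (see defaults). Each vector must sum to 1 within 0.01 and is
#'   renormalized to sum exactly 1.
#' @param base_log_cost Baseline log-cost \eqn{\mu_0} (log-USD) of a
#'   reference-level patient. Default `log(700)`.
#' @param effects Named list of named multiplicative cost factors per field
#'   level; `icd_hemorrhagic` is a single factor applied when the principal
#'   diagnosis is I61/I62/I64/I68. All factors must be positive.
#' @param noise_sigma Log-scale standard deviation of the noise (default
#'   0.45). `0` makes cost an exact deterministic function of the sampled
#'   categories.
#' @return A `sim_config` list.
#' @seealso [simulate_claims()]
#' @export
sim_config <- function(category_probs = list(), base_log_cost = log(700),
                       effects = list(), noise_sigma = 0.45) {
  default_probs <- list(
    gender = c(male = 0.4276, female = 0.5724),
    age_band = c(lt45 = 0.0437, b45_60 = 0.2000, ge60 = 0.7562),
    insurance = c(urban = 0.6636, rural = 0.3364),
    hospital_level = c(secondary_B = 0.1670, secondary_A = 0.3704,
                       tertiary_B = 0.2020, tertiary_A = 0.2606),
    hospital_type = c(comprehensive = 0.95, township = 0.02, community = 0.02,
                      school = 0.005, other = 0.005),
    los_band = c(short = 0.5018, mid = 0.2094, long = 0.2888),
    surgery = c(yes = 2820, no = 36987, unknown = 5768) / 45575,
    discharge = c(recovery = 0.8226, transfer = 0.0155, death = 0.0057,
                  other = 0.1548, midway_checkout = 0.0013),
    cc = c(ischemic_supply = 0.4594, lacunar_infarction = 0.2219,
           cerebral_infarction = 0.1151, chronic_ischemia = 0.0436,
           other = 0.1600),
    htn3 = c(yes = 0.2041, no = 0.7959),
    icd = setNames(rep(0.1, 10), paste0("I6", 0:9)),
    in_city = c(yes = 0.97, no = 0.03)
  )
  default_effects <- list(
    gender = c(male = 1, female = 0.92),
    age_band = c(lt45 = 1, b45_60 = 1.08, ge60 = 1.16),
    insurance = c(urban = 1, rural = 0.95),
    hospital_level = c(secondary_B = 1, secondary_A = 1.18,
                       tertiary_B = 1.45, tertiary_A = 2.05),
    los_band = c(short = 1, mid = 1.55, long = 2.30),
    surgery = c(yes = 1, no = 0.78, unknown = 0.95),
    discharge = c(recovery = 1, transfer = 0.87, death = 1.70,
                  other = 0.82, midway_checkout = 1),
    cc = c(ischemic_supply = 1, lacunar_infarction = 0.88,
           cerebral_infarction = 0.90, chronic_ischemia = 0.95, other = 0.85),
    htn3 = c(yes = 1.04, no = 1),
    icd_hemorrhagic = c(factor = 1.22)
  )
  probs <- utils::modifyList(default_probs, category_probs)
  eff <- utils::modifyList(default_effects, effects)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 0.01) {
      abort(paste0("category_probs$", nm, " is not a probability vector"))
    }
    probs[[nm]] <- p / sum(p)
  }
  for (nm in names(eff)) {
    if (any(eff[[nm]] <= 0)) abort(paste0("effects$", nm, " must be positive"))
  }
  stopifnot(is.numeric(noise_sigma), noise_sigma >= 0)
  structure(list(category_probs = probs, base_log_cost = base_log_cost,
                 effects = eff, noise_sigma = noise_sigma),
            class = "sim_config")
}

los_band_ranges <- function() list(short = c(1L, 8L), mid = c(9L, 13L), long = c(14L, 60L))
age_band_ranges <- function() list(lt45 = c(16L, 44L), b45_60 = c(45L, 59L), ge60 = c(60L, 95L))

sample_level <- function(n, probs) {
  if (n == 0) return(character(0))
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate seeded synthetic inpatient claims
#'
#' Draws `n` independent hospitalizations under a [sim_config()] model. The
#' same `(config, seed)` pair always yields the identical table, on any
#' platform; the caller's RNG state is untouched.
#'
#' @param n Number of claims (>= 0).
#' @param seed Integer seed; mandatory.
#' @param config A [sim_config()].
#' @return A claims tibble in the canonical layout of [claim_levels()].
#' @export
#' @examples
#' claims <- simulate_claims(1000, seed = 42)
#' dplyr::count(claims, hospital_level)
simulate_claims <- function(n, seed, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), is.numeric(n), n >= 0)
  n <- as.integer(n)
  cp <- config$category_probs
  lv <- claim_levels()
  with_seed(seed, {
    los_band <- sample_level(n, cp$los_band)
    age_band <- sample_level(n, cp$age_band)
    lr <- los_band_ranges()
    ar <- age_band_ranges()
    sample_in_band <- function(bands, ranges) {
      lo <- vapply(ranges, `[[`, integer(1), 1)
      hi <- vapply(ranges, `[[`, integer(1), 2)
      width <- (hi - lo + 1L)[bands]
      # uniform integer within the band; runif < 1 strictly, so floor is safe
      lo[bands] + as.integer(floor(runif(length(bands)) * width))
    }
    claims <- tibble::tibble(
      patient_id = sprintf("P%07d", seq_len(n)),
      gender = factor(sample_level(n, cp$gender), levels = lv$gender),
      age = if (n > 0) sample_in_band(age_band, ar) else integer(0),
      insurance = factor(sample_level(n, cp$insurance), levels = lv$insurance),
      hospital_level = factor(sample_level(n, cp$hospital_level), levels = lv$hospital_level),
      hospital_type = factor(sample_level(n, cp$hospital_type), levels = lv$hospital_type),
      los = if (n > 0) sample_in_band(los_band, lr) else integer(0),
      surgery = factor(sample_level(n, cp$surgery), levels = lv$surgery),
      discharge = factor(sample_level(n, cp$discharge), levels = lv$discharge),
      cc = factor(sample_level(n, cp$cc), levels = lv$cc),
      htn3 = sample_level(n, cp$htn3) == "yes",
      icd = sample_level(n, cp$icd),
      in_city = sample_level(n, cp$in_city) == "yes"
    )
    eff <- config$effects
    log_effect <- log(eff$gender)[as.character(claims$gender)] +
      log(eff$age_band)[age_band] +
      log(eff$insurance)[as.character(claims$insurance)] +
      log(eff$hospital_level)[as.character(claims$hospital_level)] +
      log(eff$los_band)[los_band] +
      log(eff$surgery)[as.character(claims$surgery)] +
      log(eff$discharge)[as.character(claims$discharge)] +
      log(eff$cc)[as.character(claims$cc)] +
      log(eff$htn3)[ifelse(claims$htn3, "yes", "no")] +
      ifelse(claims$icd %in% c("I61", "I62", "I64", "I68"),
             log(eff$icd_hemorrhagic[["factor"]]), 0)
    noise <- if (config$noise_sigma > 0) rnorm(n, 0, config$noise_sigma) else numeric(n)
    claims$cost <- exp(config$base_log_cost + unname(log_effect) + noise)
    claims[, claim_columns()]
  })
}

#' Split claims into training and test sets
#'
#' Simple random split without replacement: `round(fraction * n)` rows go to
#' the training set, the rest to the test set; the two are disjoint and
#' exhaustive, and the split is deterministic under `seed`.
#'
#' @param claims A claims tibble.
#' @param fraction Training fraction, strictly between 0 and 1 (default 0.8).
#' @param seed Integer seed; mandatory.
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(claims, fraction = 0.8, seed) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be strictly between 0 and 1")
  }
  n <- nrow(claims)
  n_train <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = claims[sort(idx), ], test = claims[setdiff(seq_len(n), idx), ])
}

#' Add analysis bands for age and length of stay
#'
#' Discretizes `age` into `<45`, `45--60`, `>=60` and `los` into `<=8`,
#' `9--13`, `>=14` day bands -- the bands used by the factor screen and the
#' grouping trees. Bands are ordered factors.
#'
#' @param claims A claims tibble.
#' @return `claims` with `age_band` and `los_band` columns appended.
#' @export
add_bands <- function(claims) {
  dplyr::mutate(
    claims,
    age_band = factor(dplyr::case_when(.data$age < 45 ~ "lt45",
                                       .data$age < 60 ~ "b45_60",
                                       TRUE ~ "ge60"),
                      levels = c("lt45", "b45_60", "ge60"), ordered = TRUE),
    los_band = factor(dplyr::case_when(.data$los <= 8 ~ "short",
                                       .data$los <= 13 ~ "mid",
                                       TRUE ~ "long"),
                      levels = c("short", "mid", "long"), ordered = TRUE)
  )
}
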