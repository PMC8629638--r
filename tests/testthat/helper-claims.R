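# Shared fixtures, built in code.

# A minimal well-formed claims tibble with full control over the fields.
make_claims <- function(n = 3, cost = rep(100, n), age = rep(50, n),
                        los = rep(5, n), hospital_type = "comprehensive",
                        hospital_level = "secondary_A", cc = "ischemic_supply",
                        icd = "I63", in_city = TRUE, surgery = "no",
                        discharge = "recovery", gender = "female",
                        insurance = "urban", htn3 = FALSE) {
  lv <- claim_levels()
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    gender = factor(rep_len(gender, n), levels = lv$gender),
    age = as.integer(rep_len(age, n)),
    insurance = factor(rep_len(insurance, n), levels = lv$insurance),
    hospital_level = factor(rep_len(hospital_level, n), levels = lv$hospital_level),
    hospital_type = factor(rep_len(hospital_type, n), levels = lv$hospital_type),
    los = as.integer(rep_len(los, n)),
    surgery = factor(rep_len(surgery, n), levels = lv$surgery),
    discharge = factor(rep_len(discharge, n), levels = lv$discharge),
    cc = factor(rep_len(cc, n), levels = lv$cc),
    htn3 = rep_len(htn3, n),
    icd = rep_len(icd, n),
    cost = rep_len(cost, n),
    in_city = rep_len(in_city, n)
  )
}

# Write a claims CSV from raw character rows (header + canonical columns),
# for exercising the reader's row-level validation.
write_raw_claims_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste(c("patient_id", "gender", "age", "insurance",
                    "hospital_level", "hospital_type", "los", "surgery",
                    "discharge", "cc", "htn3", "icd", "cost", "in_city"),
                  collapse = ",")
  writeLines(c(header, rows), path)
  path
}

good_row <- function(id = "P1", cost = "100", icd = "I63", age = "50") {
  paste(id, "male", age, "urban", "secondary_A", "comprehensive", "5", "no",
        "recovery", "ischemic_supply", "FALSE", icd, cost, "TRUE", sep = ",")
}

# Brute-force enumeration of set partitions of 1..n into exactly k non-empty
# blocks (oracle for the free-predictor Bonferroni multiplier).
enumerate_partitions <- function(n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  assignments <- list(integer(0))
  counts <- 0
  recurse <- function(i, blocks) {
    if (i > n) {
      if (length(blocks) == k) counts <<- counts + 1
      return(invisible(NULL))
    }
    for (b in seq_along(blocks)) {
      nb <- blocks
      nb[[b]] <- c(nb[[b]], i)
      recurse(i + 1, nb)
    }
    if (length(blocks) < k) recurse(i + 1, c(blocks, list(i)))
  }
  recurse(2, list(1L))
  counts
}

# Contiguous partitions of n ordered items into k blocks (monotone oracle):
# choose which of the n-1 gaps get a cut, counted by enumeration.
enumerate_contiguous <- function(n, k) {
  if (k > n || k < 1) return(0)
  if (k == 1) return(1)
  ncol(utils::combn(seq_len(n - 1), k - 1))
}
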