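# Shared fixtures, all built in code.

# Stratified pairs reconstructed from the printed margins of three published
# drug-abuse / psychiatric feature-pair examples, at cohort size 23,566.
reference_pairs <- function() {
  n <- 23566
  list(
    drug_abuse_suicide_attempts = stratified_pair(
      "drug_abuse_unspec", "suicide attempts|positive",
      cells_from_margins(2356, 3741, 1003, n),
      cells_from_margins(148, 563, 53, n)
    ),
    ideation_section_xii = stratified_pair(
      "suicidal_ideation", "section xii|positive",
      cells_from_margins(1820, 3045, 1299, n),
      cells_from_margins(127, 403, 81, n)
    ),
    ideation_schizoaffective = stratified_pair(
      "suicidal_ideation", "schizoaffective schizophrenia|positive",
      cells_from_margins(1820, 676, 223, n),
      cells_from_margins(127, 118, 21, n)
    )
  )
}

# Minimal event tibble builder with sensible defaults.
mk_events <- function(subject_id, encounter_id, date,
                      concept_code = "dx_x", domain = "diagnosis",
                      value_flag = "", mention_type = "") {
  tibble::tibble(
    subject_id = subject_id, encounter_id = encounter_id,
    concept_code = concept_code, domain = domain,
    date = as.Date(date), value_flag = value_flag,
    mention_type = mention_type
  )
}

mk_labels <- function(subject_id, is_case = 0L, index_date = as.Date(NA)) {
  tibble::tibble(subject_id = subject_id, is_case = as.integer(is_case),
                 index_date = as.Date(index_date))
}

# One moderately sized simulated cohort with a planted pair, reused across
# test files (computed once per test run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pp <- planted_pair("dx_001", "nlp_001|positive",
                         or_case = 6, or_noncase = 6,
                         p_a_case = 0.2, p_a_noncase = 0.15,
                         p_b_case = 0.2, p_b_noncase = 0.15)
      cache <<- simulate_cohort(sim_config(
        n_subjects = 8000, case_fraction = 0.05,
        planted_pairs = list(pp), seed = 101
      ))
    }
    cache
  }
})

# Brute-force AUC oracle: exhaustive pair counting with the 1/2 tie rule.
auc_by_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1L]; s0 <- scores[labels == 0L]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}
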