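#' Stratified 2x2 contingency tables for one feature pair
#'
#' Holds, for a structured feature A and an unstructured feature B, the 2x2
#' first-occurrence contingency table within each outcome stratum (case and
#' non-case cohorts). Cells follow the conventional layout a = both, b = A
#' only, c = B only, d = neither.
#'
#' @param A,B feature identifiers.
#' @param case,noncase length-4 nonnegative count vectors `c(a, b, c, d)`
#'   for the case and non-case cohorts.
#' @return object of class `stratified_pair`.
#' @export
stratified_pair <- function(A, B, case, noncase) {
  case <- as.numeric(case); noncase <- as.numeric(noncase)
  stopifnot(length(case) == 4L, length(noncase) == 4L)
  if (any(case < 0) || any(noncase < 0)) stop("cells must be nonnegative")
  names(case) <- names(noncase) <- c("a", "b", "c", "d")
  structure(list(A = A, B = B, case = case, noncase = noncase),
            class = "stratified_pair")
}

#' @export
print.stratified_pair <- function(x, ...) {
  cat("Pair", x$A, "x", x$B, "\n  case:    ",
      paste(sprintf("%s=%g", names(x$case), x$case), collapse = " "),
      "\n  noncase: ",
      paste(sprintf("%s=%g", names(x$noncase), x$noncase), collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct a 2x2 table from its margins
#'
#' Given the marginal counts |A|, |B|, the joint count |AB| and the cohort
#' size n, returns `c(a, b, c, d)` — the arithmetic used to rebuild
#' published contingency tables from printed margins.
#'
#' @param n_a,n_b marginal counts of A and B.
#' @param n_ab joint count.
#' @param n cohort size.
#' @export
cells_from_margins <- function(n_a, n_b, n_ab, n) {
  cells <- c(a = n_ab, b = n_a - n_ab, c = n_b - n_ab, d = n - n_a - n_b + n_ab)
  if (any(cells < 0)) stop("inconsistent margins: negative cell")
  cells
}

#' Randomly sample equal-size case and non-case cohorts
#'
#' Draws two label-pure, equal-size subject samples without replacement, so
#' contingency statistics are not driven by the raw case:non-case imbalance.
#'
#' @param fm a `feature_matrix`.
#' @param cohort_size subjects per cohort; defaults to the smaller class
#'   count.
#' @param seed integer seed.
#' @return list with `case` and `noncase` feature matrices.
#' @export
sample_equal_cohorts <- function(fm, cohort_size = NULL, seed = 1L) {
  cases <- which(fm$labels == 1L)
  noncases <- which(fm$labels == 0L)
  cohort_size <- cohort_size %||% min(length(cases), length(noncases))
  if (cohort_size > length(cases) || cohort_size > length(noncases))
    stop("cohort_size exceeds available subjects; maximum is ",
         min(length(cases), length(noncases)))
  set.seed(seed)
  list(case = fm_subset(fm, sort(cases[sample.int(length(cases), cohort_size)])),
       noncase = fm_subset(fm, sort(noncases[sample.int(length(noncases), cohort_size)])))
}

#' Build a pair's stratified contingency tables from feature matrices
#'
#' Counts subjects by joint first-occurrence presence of a structured
#' feature A and an unstructured feature B within each cohort.
#'
#' @param case_fm,noncase_fm label-pure `feature_matrix` cohorts.
#' @param A structured feature id.
#' @param B unstructured feature id.
#' @return a [stratified_pair()].
#' @export
build_contingency <- function(case_fm, noncase_fm, A, B) {
  cells <- function(fm) {
    for (f in c(A, B)) if (!f %in% fm$features)
      stop("feature '", f, "' absent from matrix")
    bin <- fm_binary(fm)
    va <- bin[, A]; vb <- bin[, B]
    c(a = sum(va & vb), b = sum(va & !vb), c = sum(!va & vb), d = sum(!va & !vb))
  }
  stratified_pair(A, B, cells(case_fm), cells(noncase_fm))
}

stratum_cells <- function(pair, stratum = c("case", "noncase")) {
  pair[[match.arg(stratum)]]
}

#' Expected joint count under within-cohort independence
#'
#' E[a] = (a + c)(a + b) / n: the joint count expected if A and B were
#' independent within the stratum, given their margins.
#'
#' @param pair a `stratified_pair`.
#' @param stratum `"case"` or `"noncase"`.
#' @export
expected_count <- function(pair, stratum = c("case", "noncase")) {
  t <- stratum_cells(pair, stratum)
  n <- sum(t)
  if (n == 0) stop("empty stratum: n = 0")
  unname((t["a"] + t["c"]) * (t["a"] + t["b"]) / n)
}

#' Pearson chi-squared test of A-B independence within one stratum
#'
#' The statistic is the Pearson sum of (observed - expected)^2 / expected
#' over all four cells, with expectations from the margins; under
#' independence it is asymptotically chi-squared with one degree of freedom.
#'
#' @param pair a `stratified_pair`.
#' @param stratum `"case"` or `"noncase"`.
#' @return named numeric `c(statistic, p_value)`.
#' @export
pearson_chi2 <- function(pair, stratum = c("case", "noncase")) {
  t <- stratum_cells(pair, stratum)
  n <- sum(t)
  if (n == 0) stop("empty stratum: n = 0")
  rA <- t["a"] + t["b"]; rNA <- t["c"] + t["d"]
  cB <- t["a"] + t["c"]; cNB <- t["b"] + t["d"]
  E <- c(rA * cB, rA * cNB, rNA * cB, rNA * cNB) / n
  if (any(E == 0))
    stop("zero expected cell: a margin of the table is degenerate")
  O <- c(t["a"], t["b"], t["c"], t["d"])
  stat <- sum((O - E)^2 / E)
  c(statistic = unname(stat), p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

stratum_logor_w <- function(t, zero_cell_correction) {
  if (any(t == 0)) t <- t + zero_cell_correction
  lor <- log(t["a"] * t["d"] / (t["b"] * t["c"]))
  w <- 1 / (1 / t["a"] + 1 / t["b"] + 1 / t["c"] + 1 / t["d"])
  c(logor = unname(lor), w = unname(w))
}

#' Woolf homogeneity of odds ratios: interaction heterogeneity (IH)
#'
#' Tests whether the A-B odds ratio differs between the case and non-case
#' strata. Per stratum, logOR = log(ad/bc) (natural log) with
#' inverse-variance weight w = (1/a + 1/b + 1/c + 1/d)^-1; IH is the
#' weighted sum of squared deviations of the stratum logORs from their
#' weighted mean, asymptotically chi-squared with k - 1 = 1 degree of
#' freedom over the two strata. If any cell of a stratum is zero,
#' `zero_cell_correction` is added to all four cells of that stratum
#' (Haldane-Anscombe).
#'
#' @param pair a `stratified_pair`.
#' @param zero_cell_correction pseudocount applied to zero-cell strata
#'   (default 0.5).
#' @return named numeric `c(ih, p_value)`.
#' @export
woolf_ih <- function(pair, zero_cell_correction = 0.5) {
  if (sum(pair$case) == 0 || sum(pair$noncase) == 0)
    stop("a whole stratum is empty")
  s1 <- stratum_logor_w(pair$case, zero_cell_correction)
  s0 <- stratum_logor_w(pair$noncase, zero_cell_correction)
  wsum <- s1["w"] + s0["w"]
  mbar <- (s1["w"] * s1["logor"] + s0["w"] * s0["logor"]) / wsum
  ih <- s1["w"] * (s1["logor"] - mbar)^2 + s0["w"] * (s0["logor"] - mbar)^2
  c(ih = unname(ih),
    p_value = pchisq(unname(ih), df = 1, lower.tail = FALSE))
}

#' Joint risk of a feature pair
#'
#' log10 of the ratio of the expected joint occurrence counts of AB in the
#' case versus non-case cohorts — a marginal-association summary of how much
#' more often the pair is expected together among cases.
#'
#' @param pair a `stratified_pair`.
#' @param base logarithm base (default 10, matching the published scale).
#' @export
joint_risk <- function(pair, base = 10) {
  e1 <- expected_count(pair, "case")
  e0 <- expected_count(pair, "noncase")
  if (e0 == 0) stop("expected non-case joint count is 0")
  log(e1 / e0, base = base)
}

#' Posterior outcome probability given joint feature presence
#'
#' P(Y = 1 | A = 1, B = 1) by Bayes' rule on the stratified tables, after
#' the case-cohort cells are rescaled by `case_scale` (default 1/100) to
#' restore the ~1/99 case:non-case ratio of the clinical population that
#' equal-cohort sampling removed. Computed both through the full
#' three-factor Bayes chain and through its algebraic simplification
#' a1 / (a1 + a0); the two paths must agree to 1e-12.
#'
#' @param pair a `stratified_pair`.
#' @param case_scale multiplier applied to case-stratum cells (default 1/100).
#' @return probability in [0, 1].
#' @export
posterior_risk <- function(pair, case_scale = 1 / 100) {
  a1 <- pair$case["a"] * case_scale
  b1 <- pair$case["b"] * case_scale
  a0 <- pair$noncase["a"]
  b0 <- pair$noncase["b"]
  if (a1 + b1 + a0 + b0 == 0) stop("no subject has feature B")
  if (a1 + a0 == 0) stop("no subject has both A and B")
  # full chain: P(A|Y,B) P(Y|B) / P(A|B)
  p_a_yb <- a1 / (a1 + b1)
  p_y_b <- (a1 + b1) / (a0 + b0 + a1 + b1)
  p_a_b <- (a1 + a0) / (a1 + b1 + a0 + b0)
  chain <- p_a_yb * p_y_b / p_a_b
  simple <- a1 / (a1 + a0)
  if (abs(chain - simple) > 1e-12)
    stop("internal error: Bayes chain and simplified posterior disagree")
  unname(simple)
}

#' All statistics for one stratified pair
#'
#' @param pair a `stratified_pair`.
#' @param zero_cell_correction passed to [woolf_ih()].
#' @param case_scale passed to [posterior_risk()].
#' @return one-row tibble of the pair's contingency statistics.
#' @export
pair_stats <- function(pair, zero_cell_correction = 0.5, case_scale = 1 / 100) {
  chi1 <- tryCatch(pearson_chi2(pair, "case"),
                   error = function(e) c(statistic = NA_real_, p_value = 1))
  chi0 <- tryCatch(pearson_chi2(pair, "noncase"),
                   error = function(e) c(statistic = NA_real_, p_value = 1))
  s1 <- stratum_logor_w(pair$case, zero_cell_correction)
  s0 <- stratum_logor_w(pair$noncase, zero_cell_correction)
  ih <- woolf_ih(pair, zero_cell_correction)
  ih_stat <- ih[["ih"]]; ih_pval <- ih[["p_value"]]
  post <- tryCatch(posterior_risk(pair, case_scale),
                   error = function(e) NA_real_)
  tibble(
    A = pair$A, B = pair$B,
    a_case = pair$case[["a"]], a_noncase = pair$noncase[["a"]],
    n_A_case = pair$case[["a"]] + pair$case[["b"]],
    n_B_case = pair$case[["a"]] + pair$case[["c"]],
    n_A_noncase = pair$noncase[["a"]] + pair$noncase[["b"]],
    n_B_noncase = pair$noncase[["a"]] + pair$noncase[["c"]],
    T_case = chi1[["statistic"]], p_case = chi1[["p_value"]],
    T_noncase = chi0[["statistic"]], p_noncase = chi0[["p_value"]],
    E_case = expected_count(pair, "case"),
    E_noncase = expected_count(pair, "noncase"),
    log_or_case = s1[["logor"]], log_or_noncase = s0[["logor"]],
    w_case = s1[["w"]], w_noncase = s0[["w"]],
    ih = ih_stat, ih_p = ih_pval,
    joint_risk = joint_risk(pair),
    posterior = post
  )
}

#' Screen and rank structured-unstructured feature pairs
#'
#' Applies, in order: the mention-type filter on B (keep only the affirmed
#' mention suffixes, by default positive and family-history), membership of
#' both A and B in the top-k features by absolute risk score, chi-squared
#' significance of the A-B association in both cohorts, IH significance, and
#' a minimum joint-occurrence filter (at least `min_joint` joint occurrences
#' in either cohort) for the ranked output. Survivor counts per filter are
#' returned alongside the ranked table.
#'
#' @param case_fm,noncase_fm equal-cohort feature matrices
#'   ([sample_equal_cohorts()]).
#' @param nbc an `nbc_model` fitted on the same feature universe.
#' @param top_k size of the importance shortlist (default 200).
#' @param alpha_chi2,alpha_ih significance levels (default 0.05, uncorrected).
#' @param min_joint minimum joint occurrences in either cohort (default 10).
#' @param mention_types mention suffixes retained for B (default positive
#'   and FH).
#' @param p_adjust optional multiple-testing adjustment (`"none"` or
#'   `"BH"`) applied to the chi-squared and IH p-values.
#' @return list: `pairs` (tibble of surviving pairs with all statistics,
#'   sorted by IH descending, ties by joint risk then ids) and `survival`
#'   (named integer vector of pair counts after each filter).
#' @export
select_pairs <- function(case_fm, noncase_fm, nbc, top_k = 200L,
                         alpha_chi2 = 0.05, alpha_ih = 0.05, min_joint = 10L,
                         mention_types = c("positive", "FH"),
                         p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  a_univ <- case_fm$features[case_fm$feature_type == "structured"]
  b_univ <- case_fm$features[case_fm$feature_type == "unstructured"]
  keep_b <- b_univ[sub("^.*\\|", "", b_univ) %in% mention_types]
  survival <- c(universe = length(a_univ) * length(b_univ),
                mention = length(a_univ) * length(keep_b))

  top <- top_features(nbc, min(top_k, nrow(nbc$table)))
  a_top <- intersect(a_univ, top)
  b_top <- intersect(keep_b, top)
  survival["top_k"] <- length(a_top) * length(b_top)

  if (!length(a_top) || !length(b_top))
    return(list(pairs = tibble(), survival = survival))

  grid <- expand.grid(A = a_top, B = b_top, stringsAsFactors = FALSE)
  stats <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    pair_stats(build_contingency(case_fm, noncase_fm, grid$A[i], grid$B[i]))
  }))
  if (p_adjust == "BH") {
    stats$p_case <- stats::p.adjust(stats$p_case, "BH")
    stats$p_noncase <- stats::p.adjust(stats$p_noncase, "BH")
    stats$ih_p <- stats::p.adjust(stats$ih_p, "BH")
  }

  chi_ok <- stats$p_case < alpha_chi2 & stats$p_noncase < alpha_chi2
  survival["chi2"] <- sum(chi_ok)
  stats <- stats[chi_ok, ]
  ih_ok <- stats$ih_p < alpha_ih
  survival["ih"] <- sum(ih_ok)
  stats <- stats[ih_ok, ]
  joint_ok <- stats$a_case >= min_joint | stats$a_noncase >= min_joint
  survival["min_joint"] <- sum(joint_ok)
  stats <- stats[joint_ok, ]

  stats <- dplyr::arrange(stats, dplyr::desc(.data$ih),
                          dplyr::desc(.data$joint_risk), .data$A, .data$B)
  list(pairs = stats, survival = survival)
}

#' Ranked pair reports split by risk direction
#'
#' `direction = "risk"` keeps pairs whose structured feature A has a
#' positive risk score (A enriched in cases); `"protective"` keeps negative
#' scores. Pairs with score exactly 0 appear in neither report. Two layouts
#' are returned: the margins layout (per-stratum |A|, |B|, expected and
#' actual joint counts, IH) and the summary layout (A, B, joint risk, IH).
#'
#' @param pairs tibble from [select_pairs()]`$pairs`.
#' @param nbc the `nbc_model` supplying score(A).
#' @param direction `"risk"` or `"protective"`.
#' @return list of tibbles `margins` and `summary`.
#' @export
rank_report <- function(pairs, nbc, direction = c("risk", "protective")) {
  direction <- match.arg(direction)
  if (!nrow(pairs))
    return(list(margins = tibble(), summary = tibble()))
  sA <- nbc$table$score[match(pairs$A, nbc$table$feature_id)]
  keep <- if (direction == "risk") sA > 0 else sA < 0
  keep[is.na(keep)] <- FALSE
  sel <- pairs[keep, ]
  list(
    margins = sel[, c("A", "B", "n_A_case", "n_B_case", "E_case", "a_case",
                      "n_A_noncase", "n_B_noncase", "E_noncase", "a_noncase",
                      "ih")],
    summary = sel[, c("A", "B", "joint_risk", "ih")]
  )
}
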