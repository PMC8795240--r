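test_that("equal cohort sampling is label-pure, sized and deterministic", {
  set.seed(30)
  fm <- feature_matrix(matrix(rbinom(1100 * 2, 1, 0.2), 1100),
                       labels = rep(c(1L, 0L), c(100, 1000)))
  co <- sample_equal_cohorts(fm, cohort_size = 100, seed = 2)
  expect_equal(length(co$case$subjects), 100)
  expect_equal(length(co$noncase$subjects), 100)
  expect_true(all(co$case$labels == 1L))
  expect_true(all(co$noncase$labels == 0L))

  # default size: the smaller class
  co2 <- sample_equal_cohorts(fm, seed = 2)
  expect_equal(length(co2$case$subjects), 100)

  co3 <- sample_equal_cohorts(fm, cohort_size = 100, seed = 2)
  expect_identical(co$case$subjects, co3$case$subjects)

  expect_error(sample_equal_cohorts(fm, cohort_size = 500), "maximum")
})

test_that("contingency cells agree between margin arithmetic and raw recount", {
  # degenerate extremes
  n <- 50
  counts <- cbind(A = rep(1, n), `B|positive` = rep(0, n))
  fm1 <- feature_matrix(counts, rep(1L, n))
  fm0 <- feature_matrix(counts, rep(0L, n))
  pr <- build_contingency(fm1, fm0, "A", "B|positive")
  expect_equal(unname(pr$case), c(0, n, 0, 0))

  # the printed-margin reconstruction of a published pair
  cells <- cells_from_margins(2356, 3741, 1003, 23566)
  expect_equal(unname(cells), c(1003, 1353, 2738, 18472))

  # brute-force recount over subject rows equals the margin arithmetic
  set.seed(31)
  for (i in 1:20) {
    m <- 200
    a_col <- rbinom(m, 1, 0.4); b_col <- rbinom(m, 1, 0.3)
    fmc <- feature_matrix(cbind(A = a_col, `B|positive` = b_col), rep(1L, m))
    fmn <- feature_matrix(cbind(A = rev(a_col), `B|positive` = b_col), rep(0L, m))
    pr <- build_contingency(fmc, fmn, "A", "B|positive")
    expect_equal(unname(pr$case),
                 unname(cells_from_margins(sum(a_col), sum(b_col),
                                           sum(a_col & b_col), m)))
  }

  expect_error(build_contingency(fm1, fm0, "missing", "B|positive"), "missing")
  expect_error(cells_from_margins(10, 3, 5, 100), "negative cell")
})

test_that("expected joint counts follow the margin product rule", {
  pr <- stratified_pair("A", "B", c(20, 30, 20, 30),
                        cells_from_margins(148, 563, 53, 23566))
  # (148 * 563) / 23566 prints as 3.54
  expect_equal(expected_count(pr, "noncase"), 148 * 563 / 23566)
  expect_identical(sprintf("%.2f", expected_count(pr, "noncase")), "3.54")
  # independence fixed point: E equals a exactly
  expect_equal(expected_count(pr, "case"), 20)
  # single-subject degenerate table
  expect_equal(expected_count(stratified_pair("A", "B", c(1, 0, 0, 0),
                                              c(1, 0, 0, 0)), "case"), 1)
})

test_that("the Pearson statistic matches hand values and the shortcut formula", {
  ind <- stratified_pair("A", "B", c(25, 25, 25, 25), c(25, 25, 25, 25))
  expect_equal(unname(pearson_chi2(ind, "case")), c(0, 1))

  pr <- stratified_pair("A", "B", c(30, 20, 20, 30), c(30, 20, 20, 30))
  expect_equal(pearson_chi2(pr, "case")[["statistic"]], 4.0)

  # the large published case table is overwhelmingly significant
  big <- reference_pairs()$drug_abuse_suicide_attempts
  expect_lt(pearson_chi2(big, "case")[["p_value"]], 1e-10)

  # shortcut equivalence: n(ad-bc)^2 / (r1 r2 c1 c2) on 1,000 random tables
  set.seed(32)
  for (i in 1:1000) {
    t <- as.numeric(rmultinom(1, sample(50:5000, 1), runif(4, 0.05, 1))[, 1])
    if (any(c(t[1] + t[2], t[3] + t[4], t[1] + t[3], t[2] + t[4]) == 0)) next
    p <- stratified_pair("A", "B", t, t)
    n <- sum(t)
    shortcut <- n * (t[1] * t[4] - t[2] * t[3])^2 /
      ((t[1] + t[2]) * (t[3] + t[4]) * (t[1] + t[3]) * (t[2] + t[4]))
    stat <- pearson_chi2(p, "case")[["statistic"]]
    expect_equal(stat, shortcut, tolerance = 1e-9)
  }

  degen <- stratified_pair("A", "B", c(0, 0, 10, 10), c(1, 1, 1, 1))
  expect_error(pearson_chi2(degen, "case"), "degenerate")
})

test_that("Woolf interaction heterogeneity matches frozen reference values", {
  # identical strata: perfectly homogeneous
  same <- stratified_pair("A", "B", c(30, 20, 20, 30), c(30, 20, 20, 30))
  expect_equal(woolf_ih(same)[["ih"]], 0)

  rp <- reference_pairs()
  expect_equal(woolf_ih(rp$drug_abuse_suicide_attempts)[["ih"]],
               77.39970, tolerance = 1e-6)
  expect_equal(woolf_ih(rp$ideation_section_xii)[["ih"]],
               54.57754, tolerance = 1e-6)
  expect_equal(woolf_ih(rp$ideation_schizoaffective)[["ih"]],
               52.58383, tolerance = 1e-6)

  # scaling one stratum by lambda scales its weight, not its log OR
  t <- c(12, 34, 56, 78)
  for (lam in c(2, 10)) {
    s1 <- ihscreen:::stratum_logor_w(t, 0.5)
    s2 <- ihscreen:::stratum_logor_w(lam * t, 0.5)
    expect_equal(s2[["logor"]], s1[["logor"]], tolerance = 1e-12)
    expect_equal(s2[["w"]], lam * s1[["w"]], tolerance = 1e-12)
  }

  # zero cells draw the Haldane-Anscombe correction and stay finite
  z <- stratified_pair("A", "B", c(0, 20, 20, 30), c(30, 20, 20, 30))
  expect_true(is.finite(woolf_ih(z)[["ih"]]))
  expect_error(woolf_ih(stratified_pair("A", "B", c(0, 0, 0, 0),
                                        c(1, 1, 1, 1))), "empty")
})

test_that("joint risk is a log10 expected-count ratio, antisymmetric in strata", {
  eq <- stratified_pair("A", "B", c(20, 30, 20, 30), c(20, 30, 20, 30))
  expect_equal(joint_risk(eq), 0)

  rp <- reference_pairs()$drug_abuse_suicide_attempts
  expect_equal(round(joint_risk(rp), 2), 2.02)

  # one decade apart
  dec <- stratified_pair("A", "B", c(100, 100, 100, 700),
                         cells_from_margins(20, 20, 10, 100))
  e1 <- expected_count(dec, "case"); e0 <- expected_count(dec, "noncase")
  expect_equal(joint_risk(dec), log10(e1 / e0))

  swapped <- stratified_pair("A", "B", rp$noncase, rp$case)
  expect_equal(joint_risk(swapped), -joint_risk(rp))
})

test_that("posterior outcome probability agrees with the full Bayes chain", {
  # symmetric after scaling: 0.5
  sym <- stratified_pair("A", "B", c(500, 300, 100, 100), c(5, 3, 100, 100))
  expect_equal(posterior_risk(sym, case_scale = 1 / 100), 0.5)

  rp <- reference_pairs()$drug_abuse_suicide_attempts
  expect_equal(posterior_risk(rp), 10.03 / 63.03, tolerance = 1e-12)

  ident <- stratified_pair("A", "B", c(30, 20, 20, 30), c(30, 20, 20, 30))
  expect_equal(posterior_risk(ident, case_scale = 1), 0.5)

  # the simplified form equals the three-factor chain on random tables
  set.seed(34)
  for (i in 1:200) {
    t1 <- rmultinom(1, 2000, runif(4, 0.05, 1))[, 1] + 1
    t0 <- rmultinom(1, 2000, runif(4, 0.05, 1))[, 1] + 1
    pr <- stratified_pair("A", "B", t1, t0)
    a1 <- t1[1] / 100; b1 <- t1[2] / 100; a0 <- t0[1]; b0 <- t0[2]
    chain <- (a1 / (a1 + b1)) * ((a1 + b1) / (a0 + b0 + a1 + b1)) /
      ((a1 + a0) / (a1 + b1 + a0 + b0))
    expect_equal(posterior_risk(pr), chain, tolerance = 1e-12)
  }

  none <- stratified_pair("A", "B", c(0, 10, 10, 10), c(0, 10, 10, 10))
  expect_error(posterior_risk(none), "both A and B")
})

test_that("pair selection applies its filters in order with a survival log", {
  # two planted heterogeneous pairs must be the only survivors
  set.seed(36)
  n <- 500
  draw_pair <- function(n, pa, pb, or) {
    cells <- solve_cell_probs(pa, pb, or)
    cat4 <- sample.int(4, n, replace = TRUE, prob = as.vector(t(cells)))
    cbind(as.integer(cat4 %in% c(1, 2)), as.integer(cat4 %in% c(1, 3)))
  }
  # case cohort: (A1,B1) OR 12, (A2,B2) OR 1/8; non-case: OR 3 and OR 4
  c1 <- draw_pair(n, 0.4, 0.4, 12); c2 <- draw_pair(n, 0.4, 0.4, 1 / 8)
  n1 <- draw_pair(n, 0.25, 0.25, 3); n2 <- draw_pair(n, 0.25, 0.25, 4)
  # A3 / B4|FH: equal prevalence everywhere, tiny |score| -> outside top-k
  # B3|NEG: filtered by mention type
  case_X <- cbind(A1 = c1[, 1], A2 = c2[, 1], A3 = rbinom(n, 1, 0.3),
                  `B1|positive` = c1[, 2], `B2|positive` = c2[, 2],
                  `B3|NEG` = rbinom(n, 1, 0.3), `B4|FH` = rbinom(n, 1, 0.3))
  nonc_X <- cbind(A1 = n1[, 1], A2 = n2[, 1], A3 = rbinom(n, 1, 0.3),
                  `B1|positive` = n1[, 2], `B2|positive` = n2[, 2],
                  `B3|NEG` = rbinom(n, 1, 0.3), `B4|FH` = rbinom(n, 1, 0.3))
  case_fm <- feature_matrix(case_X, rep(1L, n))
  nonc_fm <- feature_matrix(nonc_X, rep(0L, n))
  combined <- feature_matrix(rbind(case_X, nonc_X), rep(c(1L, 0L), c(n, n)))
  nbc <- fit_nbc(combined)

  sel <- select_pairs(case_fm, nonc_fm, nbc, top_k = 4,
                      alpha_chi2 = 0.05, alpha_ih = 0.05, min_joint = 10)
  expect_equal(nrow(sel$pairs), 2)
  expect_setequal(paste(sel$pairs$A, sel$pairs$B),
                  c("A1 B1|positive", "A2 B2|positive"))
  expect_named(sel$survival, c("universe", "mention", "top_k", "chi2", "ih",
                               "min_joint"))
  expect_equal(sel$survival[["universe"]], 3 * 4)
  expect_equal(sel$survival[["mention"]], 3 * 3)
  expect_equal(sel$survival[["top_k"]], 4)

  # homogeneous association passes the chi-squared gate but not the IH gate
  h1 <- draw_pair(2000, 0.4, 0.4, 6); h0 <- draw_pair(2000, 0.4, 0.4, 6)
  cf <- feature_matrix(cbind(A = h1[, 1], `B|positive` = h1[, 2]), rep(1L, 2000))
  nf <- feature_matrix(cbind(A = h0[, 1], `B|positive` = h0[, 2]), rep(0L, 2000))
  nbc2 <- fit_nbc(feature_matrix(rbind(cf$counts, nf$counts),
                                 rep(c(1L, 0L), c(2000, 2000))))
  sel2 <- select_pairs(cf, nf, nbc2, top_k = 2)
  expect_equal(sel2$survival[["chi2"]], 1)
  expect_equal(sel2$survival[["ih"]], 0)
  expect_equal(nrow(sel2$pairs), 0)
})

test_that("the minimum joint-occurrence rule excludes 9/9 pairs", {
  make_cohort <- function(a) {
    A <- c(rep(1, a + 40), rep(0, 160 - a))
    B <- c(rep(1, a), rep(0, 40), rep(1, 60), rep(0, 100 - a))
    feature_matrix(cbind(A = A, `B|positive` = B), rep(1L, 200))
  }
  cf <- make_cohort(9); nf <- make_cohort(9)
  nf$labels <- rep(0L, 200)
  nbc <- fit_nbc(feature_matrix(rbind(cf$counts, nf$counts),
                                rep(c(1L, 0L), c(200, 200))))
  # disable the significance gates to isolate the joint-occurrence rule
  sel9 <- select_pairs(cf, nf, nbc, top_k = 2, alpha_chi2 = 1.1,
                       alpha_ih = 1.1, min_joint = 10)
  expect_equal(sel9$survival[["min_joint"]], 0)
  cf10 <- make_cohort(10)
  sel10 <- select_pairs(cf10, nf, nbc, top_k = 2, alpha_chi2 = 1.1,
                        alpha_ih = 1.1, min_joint = 10)
  expect_equal(sel10$survival[["min_joint"]], 1)
})

test_that("with all thresholds disabled the mention-filtered universe survives", {
  set.seed(37)
  X <- matrix(rbinom(300 * 6, 1, 0.4), 300,
              dimnames = list(NULL, c("A1", "A2", "B1|positive", "B2|NEG",
                                      "B3|FH", "B4|NFH")))
  cf <- feature_matrix(X, rep(1L, 300))
  nf <- feature_matrix(X[sample(300), ], rep(0L, 300))
  nbc <- fit_nbc(feature_matrix(rbind(cf$counts, nf$counts),
                                rep(c(1L, 0L), c(300, 300))))
  sel <- select_pairs(cf, nf, nbc, top_k = 6, alpha_chi2 = 1.1,
                      alpha_ih = 1.1, min_joint = 0)
  # 2 structured x 2 affirmed mentions (positive, FH)
  expect_equal(nrow(sel$pairs), 4)
  expect_true(all(grepl("\\|(positive|FH)$", sel$pairs$B)))
})

test_that("ranked reports split by the sign of the structured feature's score", {
  rp <- reference_pairs()$drug_abuse_suicide_attempts
  pairs <- pair_stats(rp)
  mk_model <- function(score) structure(list(
    table = tibble::tibble(feature_id = rp$A, k_case = 0L, k_noncase = 0L,
                           score = score),
    alpha = 0.5, n_case = 1, n_noncase = 1), class = "nbc_model")

  risk <- rank_report(pairs, mk_model(2), "risk")
  expect_equal(nrow(risk$summary), 1)
  expect_equal(nrow(rank_report(pairs, mk_model(2), "protective")$summary), 0)
  expect_equal(nrow(rank_report(pairs, mk_model(-2), "risk")$summary), 0)
  # exactly zero score lands in neither report
  expect_equal(nrow(rank_report(pairs, mk_model(0), "risk")$summary), 0)
  expect_equal(nrow(rank_report(pairs, mk_model(0), "protective")$summary), 0)

  # the report row carries the hand-computed statistics
  expect_equal(risk$summary$joint_risk, joint_risk(rp))
  expect_equal(risk$summary$ih, woolf_ih(rp)[["ih"]])
  expect_equal(risk$margins$E_noncase, 148 * 563 / 23566)
})
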