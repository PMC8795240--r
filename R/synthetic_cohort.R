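#' Solve 2x2 cell probabilities from marginals and a target odds ratio
#'
#' Inverts the (marginal, odds-ratio) parameterisation of a bivariate binary
#' distribution: given P(A = 1), P(B = 1) and a target cross-product ratio,
#' returns the unique joint cell probabilities (the Plackett solution). This
#' is the generative core used to plant known per-cohort odds ratios between
#' structured and unstructured features in simulated cohorts.
#'
#' @param p_a,p_b marginal probabilities of the two binary features, each in
#'   (0, 1).
#' @param or_target target odds ratio p11*p00/(p10*p01), strictly positive.
#' @return a 2x2 numeric matrix of cell probabilities, rows indexing A = 1, 0
#'   and columns B = 1, 0; cells are nonnegative, sum to 1, reproduce the
#'   marginals exactly and the odds ratio to relative tolerance 1e-9.
#' @examples
#' solve_cell_probs(0.5, 0.5, 1)    # independence: all cells 0.25
#' solve_cell_probs(0.1, 0.2, 5)
#' @export
solve_cell_probs <- function(p_a, p_b, or_target) {
  stopifnot(length(p_a) == 1L, length(p_b) == 1L, length(or_target) == 1L)
  if (!is.finite(p_a) || p_a <= 0 || p_a >= 1)
    stop("infeasible marginal: p_a must lie strictly in (0, 1), got ", p_a)
  if (!is.finite(p_b) || p_b <= 0 || p_b >= 1)
    stop("infeasible marginal: p_b must lie strictly in (0, 1), got ", p_b)
  if (!is.finite(or_target) || or_target <= 0)
    stop("infeasible odds ratio: or_target must be > 0, got ", or_target)

  if (abs(or_target - 1) < 1e-12) {
    p11 <- p_a * p_b
  } else {
    # (OR-1) p11^2 - [(OR-1)(p_a+p_b) + 1] p11 + OR p_a p_b = 0; the root
    # taken is the one inside the Frechet bounds.
    A <- or_target - 1
    B <- (or_target - 1) * (p_a + p_b) + 1
    C <- or_target * p_a * p_b
    disc <- B^2 - 4 * A * C
    if (disc < 0)
      stop("infeasible (marginal, OR) combination: negative discriminant")
    p11 <- (B - sqrt(disc)) / (2 * A)
  }
  cells <- matrix(
    c(p11, p_a - p11, p_b - p11, 1 - p_a - p_b + p11),
    nrow = 2, byrow = TRUE,
    dimnames = list(A = c("1", "0"), B = c("1", "0"))
  )
  if (any(cells < -1e-12))
    stop("infeasible (marginal, OR) combination: a cell probability is negative")
  cells[cells < 0] <- 0
  or_real <- (cells[1, 1] * cells[2, 2]) / (cells[1, 2] * cells[2, 1])
  if (abs(or_real / or_target - 1) > 1e-9)
    stop("infeasible (marginal, OR) combination: solved cells miss the target OR")
  cells
}

#' Declare a planted structured-unstructured feature pair
#'
#' A planted pair fixes, per cohort, the marginal prevalences of one
#' structured and one unstructured (NLP) feature and the odds ratio between
#' them, giving the simulation a known interaction-heterogeneity ground truth
#' (`or_case != or_noncase` plants heterogeneity; equal ORs plant the null).
#'
#' @param structured_feature_id,nlp_feature_id expanded feature identifiers;
#'   the NLP id must carry a mention-type suffix such as `"|positive"`.
#' @param or_case,or_noncase planted odds ratio within the case and non-case
#'   cohorts.
#' @param p_a_case,p_a_noncase,p_b_case,p_b_noncase per-cohort marginal
#'   prevalence of the structured (A) and NLP (B) feature.
#' @return an object of class `planted_pair`.
#' @export
planted_pair <- function(structured_feature_id, nlp_feature_id,
                         or_case, or_noncase,
                         p_a_case, p_a_noncase, p_b_case, p_b_noncase) {
  pp <- list(
    structured_feature_id = as.character(structured_feature_id),
    nlp_feature_id = as.character(nlp_feature_id),
    or_case = or_case, or_noncase = or_noncase,
    p_a_case = p_a_case, p_a_noncase = p_a_noncase,
    p_b_case = p_b_case, p_b_noncase = p_b_noncase
  )
  # fail fast if either cohort's cells are infeasible
  solve_cell_probs(p_a_case, p_b_case, or_case)
  solve_cell_probs(p_a_noncase, p_b_noncase, or_noncase)
  structure(pp, class = "planted_pair")
}

#' Simulation configuration for a synthetic EHR cohort
#'
#' @param n_subjects number of subjects to simulate.
#' @param case_fraction probability that a subject is a case; the study
#'   default 0.01 reflects the ~1% prevalence of the outcome in clinical
#'   populations.
#' @param date_range length-2 Date (or coercible) vector, start strictly
#'   before end, within which all encounters fall.
#' @param visits_mean,visits_dispersion mean and negative-binomial size of
#'   the per-subject visit-count distribution (minimum one visit); the
#'   over-dispersion guarantees subjects below any visit-count inclusion
#'   threshold exist.
#' @param n_structured_features,n_nlp_features number of structured (coded)
#'   and NLP concept features beyond any referenced by `planted_pairs`.
#' @param marginal_prevalence_range range from which non-planted feature
#'   prevalences are drawn.
#' @param planted_pairs list of [planted_pair()] objects.
#' @param feature_effects optional data frame (`feature_id`, `p_case`,
#'   `p_noncase`) overriding per-cohort prevalence of selected non-planted
#'   features, used to plant main-effect (marginal) signal.
#' @param seed integer seed; a fixed seed makes [simulate_cohort()] output
#'   byte-identical.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects,
                       case_fraction = 0.01,
                       date_range = as.Date(c("2000-01-01", "2018-12-31")),
                       visits_mean = 8, visits_dispersion = 1.5,
                       n_structured_features = 40,
                       n_nlp_features = 15,
                       marginal_prevalence_range = c(0.01, 0.20),
                       planted_pairs = list(),
                       feature_effects = NULL,
                       seed = 1L) {
  date_range <- as.Date(date_range)
  stopifnot(
    length(n_subjects) == 1L, n_subjects >= 1,
    length(date_range) == 2L,
    visits_mean > 1, visits_dispersion > 0,
    n_structured_features >= 0, n_nlp_features >= 0,
    length(marginal_prevalence_range) == 2L,
    marginal_prevalence_range[1] > 0, marginal_prevalence_range[2] < 1,
    marginal_prevalence_range[1] <= marginal_prevalence_range[2]
  )
  if (!(case_fraction > 0 && case_fraction < 1))
    stop("case_fraction must lie in (0, 1)")
  if (!(date_range[1] < date_range[2]))
    stop("date_range start must precede end")
  if (!all(vapply(planted_pairs, inherits, logical(1), "planted_pair")))
    stop("planted_pairs must be a list of planted_pair objects")
  if (!is.null(feature_effects)) {
    feature_effects <- as_tibble(feature_effects)
    stopifnot(all(c("feature_id", "p_case", "p_noncase") %in%
                    names(feature_effects)))
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), case_fraction = case_fraction,
      date_range = date_range, visits_mean = visits_mean,
      visits_dispersion = visits_dispersion,
      n_structured_features = as.integer(n_structured_features),
      n_nlp_features = as.integer(n_nlp_features),
      marginal_prevalence_range = marginal_prevalence_range,
      planted_pairs = planted_pairs, feature_effects = feature_effects,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

.domains <- c("diagnosis", "procedure", "medication", "lab", "demographic", "nlp")
.value_flags <- c("L", "N", "H", "A", "U")
.mention_types <- c("positive", "NEG", "FH", "NFH")

# Feature dictionary: expanded feature id, underlying concept code, domain,
# value flag / mention type, and per-cohort prevalence. Planted-pair features
# are listed but their joint distribution is sampled from solve_cell_probs.
build_feature_dictionary <- function(config) {
  ns <- config$n_structured_features
  nn <- config$n_nlp_features
  pr <- config$marginal_prevalence_range

  n_lab <- ceiling(0.2 * ns)
  n_dx <- ns - n_lab
  dx_codes <- sprintf("dx_%03d", seq_len(max(n_dx, 0)))
  lab_codes <- sprintf("lab_%03d", seq_len(max(n_lab, 0)))
  lab_flags <- rep_len(.value_flags, max(n_lab, 0))
  nlp_codes <- sprintf("nlp_%03d", seq_len(max(nn, 0)))
  nlp_mentions <- rep_len(.mention_types[c(1, 1, 2, 3, 4)], max(nn, 0))

  dict <- tibble(
    feature_id = c(dx_codes, paste0(lab_codes, "|", lab_flags),
                   paste0(nlp_codes, "|", nlp_mentions)),
    concept_code = c(dx_codes, lab_codes, nlp_codes),
    domain = c(rep("diagnosis", length(dx_codes)),
               rep("lab", length(lab_codes)),
               rep("nlp", length(nlp_codes))),
    value_flag = c(rep("", length(dx_codes)), lab_flags,
                   rep("", length(nlp_codes))),
    mention_type = c(rep("", length(dx_codes) + length(lab_codes)),
                     nlp_mentions)
  )
  prev <- runif(nrow(dict), pr[1], pr[2])
  dict$p_case <- prev
  dict$p_noncase <- prev

  if (!is.null(config$feature_effects)) {
    fe <- config$feature_effects
    miss <- setdiff(fe$feature_id, dict$feature_id)
    if (length(miss))
      stop("feature_effects references unknown features: ",
           paste(miss, collapse = ", "))
    i <- match(fe$feature_id, dict$feature_id)
    dict$p_case[i] <- fe$p_case
    dict$p_noncase[i] <- fe$p_noncase
  }

  # planted features: append if absent, then pin their marginals
  for (pp in config$planted_pairs) {
    for (side in c("a", "b")) {
      fid <- if (side == "a") pp$structured_feature_id else pp$nlp_feature_id
      if (!fid %in% dict$feature_id) {
        parts <- strsplit(fid, "|", fixed = TRUE)[[1]]
        is_nlp <- side == "b"
        dict <- dplyr::bind_rows(dict, tibble(
          feature_id = fid,
          concept_code = parts[1],
          domain = if (is_nlp) "nlp" else "diagnosis",
          value_flag = "",
          mention_type = if (is_nlp) parts[2] else "",
          p_case = 0, p_noncase = 0
        ))
      }
      i <- match(fid, dict$feature_id)
      dict$p_case[i] <- if (side == "a") pp$p_a_case else pp$p_b_case
      dict$p_noncase[i] <- if (side == "a") pp$p_a_noncase else pp$p_b_noncase
    }
    if (dict$domain[match(pp$nlp_feature_id, dict$feature_id)] != "nlp")
      stop("planted nlp_feature_id ", pp$nlp_feature_id,
           " does not resolve to an nlp feature")
  }
  dict
}

# Draw subject-level first-occurrence indicators: planted pairs jointly from
# their cohort cell probabilities, all other features independent Bernoulli.
draw_indicators <- function(config, dict, is_case) {
  n <- length(is_case)
  p <- nrow(dict)
  ind <- matrix(FALSE, n, p, dimnames = list(NULL, dict$feature_id))
  planted_ids <- unlist(lapply(config$planted_pairs, function(pp)
    c(pp$structured_feature_id, pp$nlp_feature_id)))
  if (anyDuplicated(planted_ids))
    stop("a feature may appear in at most one planted pair")
  free <- !(dict$feature_id %in% planted_ids)

  for (cohort in c(TRUE, FALSE)) {
    rows <- which(is_case == cohort)
    if (!length(rows)) next
    pcol <- if (cohort) dict$p_case else dict$p_noncase
    for (j in which(free)) {
      ind[rows, j] <- runif(length(rows)) < pcol[j]
    }
    for (pp in config$planted_pairs) {
      cells <- if (cohort) solve_cell_probs(pp$p_a_case, pp$p_b_case, pp$or_case)
               else solve_cell_probs(pp$p_a_noncase, pp$p_b_noncase, pp$or_noncase)
      # categories: 1 = A&B, 2 = A only, 3 = B only, 4 = neither
      cat <- sample.int(4L, length(rows), replace = TRUE,
                        prob = c(cells[1, 1], cells[1, 2], cells[2, 1], cells[2, 2]))
      ind[rows, pp$structured_feature_id] <- cat %in% c(1L, 2L)
      ind[rows, pp$nlp_feature_id] <- cat %in% c(1L, 3L)
    }
  }
  ind
}

#' Simulate a longitudinal EHR cohort with known ground truth
#'
#' Generates two labelled cohorts (cases at `case_fraction`), per-subject
#' longitudinal encounters, structured events (diagnoses, labs with 5-level
#' value flags) and NLP concept events with mention types, with controllable
#' per-cohort prevalences and planted per-cohort odds ratios between
#' designated structured-unstructured pairs. Cases receive a structured
#' index-event diagnosis at their final encounter; all feature events of a
#' case are dated strictly before the index encounter, so first-occurrence
#' indicators survive censoring unchanged and planted odds ratios are
#' recoverable downstream.
#'
#' Pair and feature indicators are sampled at the subject level (first
#' occurrence) and then expanded to dated events; a present feature may recur
#' at additional visits, exercising the per-visit multiplicity used by the
#' risk-score accumulation.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_cohort`: list with `events` (tibble, one
#'   row per concept occurrence at one encounter), `labels` (tibble:
#'   `subject_id`, `is_case`, `index_date`), `features` (the feature
#'   dictionary with ground-truth prevalences) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects

  subject_id <- sprintf("S%06d", seq_len(n))
  is_case <- rbinom(n, 1L, config$case_fraction) == 1L
  n_visits <- 1L + rnbinom(n, size = config$visits_dispersion,
                           mu = config$visits_mean - 1)

  dict <- build_feature_dictionary(config)
  ind <- draw_indicators(config, dict, is_case)

  # encounter scaffold: sorted uniform dates within date_range
  span <- as.integer(config$date_range[2] - config$date_range[1])
  subj_rep <- rep.int(seq_len(n), n_visits)
  offs <- unlist(lapply(n_visits, function(m) sort(sample.int(span + 1L, m,
                                                              replace = TRUE)) - 1L),
                 use.names = FALSE)
  enc <- tibble(
    subj = subj_rep,
    visit_rank = unlist(lapply(n_visits, seq_len), use.names = FALSE),
    date = config$date_range[1] + offs
  )
  enc$encounter_id <- sprintf("%s_e%02d", subject_id[enc$subj], enc$visit_rank)

  # cases: index event at the final encounter
  last_rank <- n_visits
  index_date <- rep(as.Date(NA), n)
  idx_rows <- enc$visit_rank == last_rank[enc$subj] & is_case[enc$subj]
  index_date[enc$subj[idx_rows]] <- enc$date[idx_rows]

  labels <- tibble(subject_id = subject_id, is_case = as.integer(is_case),
                   index_date = index_date)

  # eligible visits for feature events: strictly pre-index for cases
  n_elig <- ifelse(is_case, n_visits - 1L, n_visits)

  hit <- which(ind, arr.ind = TRUE)
  hit <- hit[n_elig[hit[, 1]] >= 1L, , drop = FALSE]
  # base occurrence plus an occasional repeat at another eligible visit
  s1 <- hit[, 1]
  v1 <- 1L + floor(runif(length(s1)) * n_elig[s1])
  repeat_mask <- runif(length(s1)) < 0.25 & n_elig[s1] >= 2L
  s2 <- s1[repeat_mask]
  v2 <- 1L + floor(runif(length(s2)) * n_elig[s2])
  occ <- tibble(
    subj = c(s1, s2),
    fidx = c(hit[, 2], hit[repeat_mask, 2]),
    visit_rank = c(v1, v2)
  )
  occ <- dplyr::distinct(occ)

  enc_key <- enc[, c("subj", "visit_rank", "encounter_id", "date")]
  occ <- dplyr::inner_join(occ, enc_key, by = c("subj", "visit_rank"))

  events <- tibble(
    subject_id = subject_id[occ$subj],
    encounter_id = occ$encounter_id,
    concept_code = dict$concept_code[occ$fidx],
    domain = dict$domain[occ$fidx],
    date = occ$date,
    value_flag = dict$value_flag[occ$fidx],
    mention_type = dict$mention_type[occ$fidx]
  )
  # every encounter carries a registration record, as in real EHRs where the
  # visit itself is documented; keeps visit structure (and hence inclusion)
  # independent of which clinical features a subject happened to draw
  events <- dplyr::bind_rows(events, tibble(
    subject_id = subject_id[enc$subj],
    encounter_id = enc$encounter_id,
    concept_code = "demo_visit",
    domain = "demographic",
    date = enc$date,
    value_flag = "",
    mention_type = ""
  ))
  # structured index-event code for cases at the index encounter
  case_rows <- which(idx_rows)
  if (length(case_rows)) {
    events <- dplyr::bind_rows(events, tibble(
      subject_id = subject_id[enc$subj[case_rows]],
      encounter_id = enc$encounter_id[case_rows],
      concept_code = "dx_index_event",
      domain = "diagnosis",
      date = enc$date[case_rows],
      value_flag = "",
      mention_type = ""
    ))
  }
  events <- dplyr::arrange(events, .data$subject_id, .data$date,
                           .data$encounter_id, .data$concept_code)

  dict <- dplyr::bind_rows(dict, tibble(
    feature_id = "demo_visit", concept_code = "demo_visit",
    domain = "demographic", value_flag = "", mention_type = "",
    p_case = 1, p_noncase = 1
  ))

  structure(
    list(events = events, labels = labels, features = dict, config = config),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated EHR cohort:", nrow(x$labels), "subjects (",
      sum(x$labels$is_case), "cases ),", nrow(x$events), "events,",
      nrow(x$features), "features\n")
  invisible(x)
}

event_columns <- c("subject_id", "encounter_id", "concept_code", "domain",
                   "date", "value_flag", "mention_type")

#' Write / read an event stream as delimited text
#'
#' UTF-8 tab-delimited with a header row and columns exactly `subject_id`,
#' `encounter_id`, `concept_code`, `domain`, `date` (ISO-8601),
#' `value_flag`, `mention_type`; inapplicable fields are empty strings.
#' `read_events(write_events(x))` is the identity on all fields.
#'
#' @param events tibble of event records.
#' @param path file path.
#' @return `read_events` returns the validated event tibble.
#' @export
write_events <- function(events, path) {
  stopifnot(all(event_columns %in% names(events)))
  out <- events[, event_columns]
  out$date <- format(out$date, "%Y-%m-%d")
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      encounter_id = readr::col_character(),
      concept_code = readr::col_character(),
      domain = readr::col_character(),
      date = readr::col_date("%Y-%m-%d"),
      value_flag = readr::col_character(),
      mention_type = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  if (!identical(names(ev), event_columns))
    stop("event file must have columns exactly: ",
         paste(event_columns, collapse = ", "))
  probs <- readr::problems(ev)
  if (nrow(probs))
    stop("malformed event row(s) at line ", paste(probs$row, collapse = ", "))
  if (nrow(ev)) {
    bad <- which(!ev$domain %in% .domains)
    if (length(bad))
      stop("unknown domain '", ev$domain[bad[1]], "' in field 'domain', row ", bad[1])
    bad <- which(ev$value_flag != "" & !ev$value_flag %in% .value_flags)
    if (length(bad))
      stop("unknown value_flag '", ev$value_flag[bad[1]],
           "' in field 'value_flag', row ", bad[1])
    bad <- which(ev$mention_type != "" & !ev$mention_type %in% .mention_types)
    if (length(bad))
      stop("unknown mention_type '", ev$mention_type[bad[1]],
           "' in field 'mention_type', row ", bad[1])
    bad <- which((ev$domain == "lab") != (ev$value_flag != ""))
    if (length(bad))
      stop("value_flag must be nonempty iff domain is 'lab'; violated at row ", bad[1])
    bad <- which((ev$domain == "nlp") != (ev$mention_type != ""))
    if (length(bad))
      stop("mention_type must be nonempty iff domain is 'nlp'; violated at row ", bad[1])
  }
  ev
}

#' Write / read a cohort label table
#'
#' Columns: `subject_id`, `is_case` (0/1), `index_date` (ISO-8601, empty for
#' non-cases).
#' @param labels tibble with the three label columns.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("subject_id", "is_case", "index_date") %in% names(labels)))
  out <- labels[, c("subject_id", "is_case", "index_date")]
  out$index_date <- ifelse(is.na(out$index_date), "",
                           format(out$index_date, "%Y-%m-%d"))
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  lb <- readr::read_tsv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      is_case = readr::col_integer(),
      index_date = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  if (!all(lb$is_case %in% c(0L, 1L)))
    stop("is_case must be 0/1")
  lb$index_date <- as.Date(ifelse(lb$index_date == "", NA, lb$index_date))
  lb
}

#' Sample one pair's 2x2 first-occurrence table for a cohort
#'
#' Draws `n` subjects' joint (A, B) indicators from the cell probabilities
#' solved for the given marginals and odds ratio, and returns the realised
#' 2x2 count table. This is the same pair-sampling core [simulate_cohort()]
#' uses for planted pairs, exposed directly for parameter-recovery and
#' null-calibration studies where the encounter scaffold is irrelevant.
#'
#' @param n cohort size.
#' @param p_a,p_b marginal prevalences.
#' @param or_target planted odds ratio.
#' @return 2x2 integer matrix of counts (rows A = 1/0, columns B = 1/0).
#' @export
sample_pair_table <- function(n, p_a, p_b, or_target) {
  cells <- solve_cell_probs(p_a, p_b, or_target)
  k <- stats::rmultinom(1L, n, as.vector(t(cells)))[, 1]
  matrix(k, nrow = 2, byrow = TRUE,
         dimnames = list(A = c("1", "0"), B = c("1", "0")))
}
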