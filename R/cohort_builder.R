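#' Inclusion criteria configuration
#'
#' Defaults mirror common EHR cohort rules: at least three recorded visits,
#' at least 30 days between the first and last event, and (when birthdates
#' exist) at least one encounter inside an age window. The synthetic data
#' carry no birthdate, so age filtering is disabled by default.
#'
#' @param min_visits minimum distinct encounters (default 3).
#' @param min_span_days minimum days between first and last event (default 30).
#' @param age_window optional `c(min, max)` in years, or `NULL` to disable.
#' @export
inclusion_config <- function(min_visits = 3L, min_span_days = 30L,
                             age_window = NULL) {
  stopifnot(min_visits >= 1, min_span_days >= 0)
  structure(list(min_visits = as.integer(min_visits),
                 min_span_days = as.integer(min_span_days),
                 age_window = age_window),
            class = "inclusion_config")
}

#' Apply inclusion criteria to an event stream
#'
#' A subject is retained iff their distinct encounter count is at least
#' `min_visits` and the span between their first and last event dates is at
#' least `min_span_days` (and, when ages are available, at least one
#' encounter falls inside the age window). The exclusion log records the
#' first rule that fired for each excluded subject.
#'
#' @param events event tibble.
#' @param labels label tibble; every event subject must appear here.
#' @param config an [inclusion_config()].
#' @param birthdates optional tibble (`subject_id`, `birthdate`); required
#'   when `config$age_window` is set.
#' @return list with `retained` (character vector of subject ids, in label
#'   order) and `exclusion_log` (tibble: `subject_id`, `rule`).
#' @export
apply_inclusion_criteria <- function(events, labels, config = inclusion_config(),
                                     birthdates = NULL) {
  stray <- setdiff(unique(events$subject_id), labels$subject_id)
  if (length(stray))
    stop("events reference subjects absent from labels: ",
         paste(head(stray, 3), collapse = ", "))

  per <- events |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_enc = dplyr::n_distinct(.data$encounter_id),
      span = as.integer(max(.data$date) - min(.data$date)),
      .groups = "drop"
    )
  per <- dplyr::left_join(tibble(subject_id = labels$subject_id), per,
                          by = "subject_id")

  rule <- rep(NA_character_, nrow(per))
  rule[is.na(per$n_enc)] <- "no events"
  rule[is.na(rule) & per$n_enc < config$min_visits] <- "min_visits"
  rule[is.na(rule) & per$span < config$min_span_days] <- "min_span_days"

  if (!is.null(config$age_window)) {
    if (is.null(birthdates))
      stop("age_window is set but no birthdates were supplied")
    bd <- birthdates$birthdate[match(events$subject_id, birthdates$subject_id)]
    age <- as.numeric(events$date - bd) / 365.25
    in_win <- age >= config$age_window[1] & age <= config$age_window[2]
    ok_age <- tapply(in_win, events$subject_id, any)
    fails_age <- per$subject_id[!per$subject_id %in% names(ok_age)[unlist(ok_age)]]
    rule[is.na(rule) & per$subject_id %in% fails_age] <- "age_window"
  }

  list(
    retained = per$subject_id[is.na(rule)],
    exclusion_log = tibble(subject_id = per$subject_id[!is.na(rule)],
                           rule = rule[!is.na(rule)])
  )
}

#' Censor case histories at the index event
#'
#' For each case, all events at or after the index encounter are removed
#' (including the index encounter itself, so predictions use strictly
#' pre-index data) and the prediction point is the latest remaining
#' encounter — the penultimate visit. Non-cases keep all events and predict
#' at their last visit. Cases left with no pre-index encounters are dropped
#' and logged.
#'
#' @param events event tibble (subjects already filtered for inclusion).
#' @param labels label tibble; each case's `index_date` must coincide with
#'   one of its encounter dates.
#' @return list with `events` (censored), `prediction_points` (tibble:
#'   `subject_id`, `prediction_date`) and `dropped` (tibble: `subject_id`,
#'   `reason`).
#' @export
censor_case_history <- function(events, labels) {
  labels <- labels[labels$subject_id %in% unique(events$subject_id), ]
  cases <- labels[labels$is_case == 1L, ]

  if (nrow(cases)) {
    idx <- cases$index_date[match(events$subject_id, cases$subject_id)]
    ev_case <- events$subject_id %in% cases$subject_id
    # validate: index date must match an encounter date
    has_idx <- tapply(events$date[ev_case] == idx[ev_case],
                      events$subject_id[ev_case], any)
    bad <- names(has_idx)[!unlist(has_idx)]
    if (length(bad))
      stop("index_date matches no encounter for case subject(s): ",
           paste(head(bad, 3), collapse = ", "))
    keep <- !ev_case | events$date < idx
    events <- events[keep, ]
  }

  left <- if (nrow(events)) {
    events |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(prediction_date = max(.data$date), .groups = "drop")
  } else {
    tibble(subject_id = character(), prediction_date = as.Date(character()))
  }

  dropped_ids <- setdiff(labels$subject_id, left$subject_id)
  pp <- dplyr::left_join(tibble(subject_id = setdiff(labels$subject_id, dropped_ids)),
                         left, by = "subject_id")
  list(
    events = events[!events$subject_id %in% dropped_ids, ],
    prediction_points = pp,
    dropped = tibble(subject_id = dropped_ids,
                     reason = rep("no pre-index encounters", length(dropped_ids)))
  )
}

#' Expand lab and NLP events into suffixed dummy features
#'
#' Lab concept codes become `code|flag` (five value-flag levels L/N/H/A/U);
#' NLP concept codes become `code|mention_type` (positive/NEG/FH/NFH),
#' quadrupling the potential NLP feature space. Other domains keep the bare
#' concept code. The expanded universe partitions into STRUCTURED (non-NLP)
#' and UNSTRUCTURED (NLP) features.
#'
#' @param events event tibble.
#' @return the events with an added `feature_id` column.
#' @export
expand_features <- function(events) {
  lab_bad <- events$domain == "lab" & events$value_flag == ""
  if (any(lab_bad))
    stop("lab event without value_flag at row ", which(lab_bad)[1])
  nlp_bad <- events$domain == "nlp" & events$mention_type == ""
  if (any(nlp_bad))
    stop("nlp event without mention_type at row ", which(nlp_bad)[1])
  events$feature_id <- dplyr::case_when(
    events$domain == "lab" ~ paste0(events$concept_code, "|", events$value_flag),
    events$domain == "nlp" ~ paste0(events$concept_code, "|", events$mention_type),
    TRUE ~ events$concept_code
  )
  events
}

#' Classify expanded feature ids as structured or unstructured
#'
#' @param feature_ids character vector of expanded feature ids.
#' @return character vector, `"unstructured"` for NLP mention-suffixed ids,
#'   `"structured"` otherwise.
#' @export
feature_types <- function(feature_ids) {
  ifelse(grepl("\\|(positive|NEG|FH|NFH)$", feature_ids),
         "unstructured", "structured")
}

#' Construct a feature matrix by hand
#'
#' Container for subjects x features occurrence counts with 0/1 labels. The
#' binary first-occurrence view (`counts > 0`) drives prevalence and
#' contingency work; the counts view retains per-visit multiplicity for
#' risk-score accumulation.
#'
#' @param counts numeric matrix or sparse Matrix, subjects x features.
#' @param labels integer 0/1 vector, one per subject.
#' @param subjects,features optional id vectors (default from dimnames).
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(counts, labels, subjects = rownames(counts),
                           features = colnames(counts)) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  stopifnot(nrow(counts) == length(labels), all(labels %in% c(0L, 1L)))
  if (is.null(subjects)) subjects <- sprintf("S%06d", seq_len(nrow(counts)))
  if (is.null(features)) features <- sprintf("f%04d", seq_len(ncol(counts)))
  if (anyDuplicated(features)) stop("feature ids must be unique")
  dimnames(counts) <- list(subjects, features)
  structure(
    list(subjects = subjects, features = features, counts = counts,
         labels = as.integer(labels), feature_type = feature_types(features)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", length(x$subjects), "subjects x", length(x$features),
      "features;", sum(x$labels), "cases;",
      sum(x$feature_type == "structured"), "structured /",
      sum(x$feature_type == "unstructured"), "unstructured\n")
  invisible(x)
}

#' Binary first-occurrence view of a feature matrix
#' @param fm a `feature_matrix`.
#' @return sparse logical matrix, TRUE where the subject ever had the
#'   feature at or before their prediction point.
#' @export
fm_binary <- function(fm) fm$counts > 0

fm_subset <- function(fm, i = seq_along(fm$subjects), j = seq_along(fm$features)) {
  feature_matrix(fm$counts[i, j, drop = FALSE], fm$labels[i],
                 subjects = fm$subjects[i], features = fm$features[j])
}

#' Restrict a feature matrix to a feature subset
#' @param fm a `feature_matrix`.
#' @param features feature ids to keep (order preserved).
#' @export
fm_select_features <- function(fm, features) {
  miss <- setdiff(features, fm$features)
  if (length(miss)) stop("features absent from matrix: ",
                         paste(head(miss, 3), collapse = ", "))
  fm_subset(fm, j = match(features, fm$features))
}

#' Build the subjects x features occurrence matrix
#'
#' Counts, per subject and expanded feature, the number of distinct
#' encounters at which the feature was recorded at or before the subject's
#' prediction point. The binary view (`counts > 0`) is the first-occurrence
#' indicator used by the contingency analysis; the counts carry the
#' per-visit multiplicity used by the risk-score accumulation.
#'
#' @param expanded events with a `feature_id` column ([expand_features()]).
#' @param labels label tibble.
#' @param prediction_points tibble (`subject_id`, `prediction_date`) from
#'   [censor_case_history()]; defines both the subject set and the cutoff.
#' @param feature_universe optional character vector fixing the column set
#'   (unseen features get all-zero columns).
#' @return a [feature_matrix()].
#' @export
build_feature_matrix <- function(expanded, labels, prediction_points,
                                 feature_universe = NULL) {
  subjects <- prediction_points$subject_id
  ev <- expanded[expanded$subject_id %in% subjects, ]
  cut <- prediction_points$prediction_date[match(ev$subject_id, subjects)]
  ev <- ev[ev$date <= cut, ]

  occ <- ev |>
    dplyr::distinct(.data$subject_id, .data$feature_id, .data$encounter_id) |>
    dplyr::count(.data$subject_id, .data$feature_id, name = "n_visits")

  features <- feature_universe %||% sort(unique(occ$feature_id))
  miss <- setdiff(occ$feature_id, features)
  if (length(miss))
    stop("events contain features outside the supplied universe: ",
         paste(head(miss, 3), collapse = ", "))

  counts <- Matrix::sparseMatrix(
    i = match(occ$subject_id, subjects),
    j = match(occ$feature_id, features),
    x = occ$n_visits,
    dims = c(length(subjects), length(features)),
    dimnames = list(subjects, features)
  )
  feature_matrix(counts, labels$is_case[match(subjects, labels$subject_id)],
                 subjects = subjects, features = features)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified subject-level train/test split
#'
#' Disjoint, exhaustive split stratified by label so that both sides contain
#' cases even at ~1% prevalence.
#'
#' @param fm a `feature_matrix`.
#' @param test_fraction proportion held out (default 0.30).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with `train` and `test` feature matrices.
#' @export
split_train_test <- function(fm, test_fraction = 0.30, seed = 1L) {
  stopifnot(length(fm$subjects) > 0, test_fraction > 0, test_fraction < 1)
  if (sum(fm$labels == 1L) < 2L)
    stop("need at least 2 cases to stratify the split")
  set.seed(seed)
  test_idx <- integer(0)
  for (lab in c(1L, 0L)) {
    grp <- which(fm$labels == lab)
    n_test <- round(test_fraction * length(grp))
    test_idx <- c(test_idx, sample(grp, n_test))
  }
  train_idx <- setdiff(seq_along(fm$subjects), test_idx)
  list(train = fm_subset(fm, sort(train_idx)),
       test = fm_subset(fm, sort(test_idx)))
}

#' Subsample training data to a target case prevalence
#'
#' Lifts the training case fraction (e.g. from ~1% to 12%) by keeping the
#' required number of cases and sampling non-cases without replacement; the
#' test set is never touched.
#'
#' @param train training `feature_matrix`.
#' @param target_case_fraction target prevalence (default 0.12).
#' @param total_n size of the reduced training set.
#' @param seed integer seed.
#' @export
subsample_training <- function(train, target_case_fraction = 0.12, total_n,
                               seed = 1L) {
  n_case_want <- round(target_case_fraction * total_n)
  n_nonc_want <- total_n - n_case_want
  cases <- which(train$labels == 1L)
  noncases <- which(train$labels == 0L)
  if (length(cases) < n_case_want) {
    max_frac <- length(cases) / (length(cases) + n_nonc_want)
    stop(sprintf(
      "target case fraction %.3f infeasible: only %d cases available (maximum attainable fraction at total_n=%d is %.4f)",
      target_case_fraction, length(cases), total_n, max_frac))
  }
  if (length(noncases) < n_nonc_want)
    stop("not enough non-cases for total_n = ", total_n)
  set.seed(seed)
  keep <- sort(c(sample(cases, n_case_want), sample(noncases, n_nonc_want)))
  fm_subset(train, keep)
}

#' Run the full cohort-building pipeline on an event stream
#'
#' Convenience wrapper: inclusion criteria, index-event censoring, feature
#' expansion and matrix construction in one call.
#'
#' @param events raw event tibble.
#' @param labels label tibble.
#' @param config an [inclusion_config()].
#' @param feature_universe optional fixed feature column set.
#' @return list: `matrix` (feature_matrix), `exclusion_log`, `dropped`,
#'   `prediction_points`.
#' @export
build_cohort <- function(events, labels, config = inclusion_config(),
                         feature_universe = NULL) {
  inc <- apply_inclusion_criteria(events, labels, config)
  ev <- events[events$subject_id %in% inc$retained, ]
  lb <- labels[labels$subject_id %in% inc$retained, ]
  cen <- censor_case_history(ev, lb)
  exp_ev <- expand_features(cen$events)
  fm <- build_feature_matrix(exp_ev, lb, cen$prediction_points,
                             feature_universe = feature_universe)
  list(matrix = fm, exclusion_log = inc$exclusion_log, dropped = cen$dropped,
       prediction_points = cen$prediction_points)
}
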