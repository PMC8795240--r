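#' Fit the naive-Bayes odds-ratio risk score
#'
#' For each feature with first-occurrence (subject-level) counts k1 among n1
#' cases and k0 among n0 non-cases, the risk score is the smoothed log odds
#' ratio of its prevalence in the two populations:
#'
#'   score(f) = log( ((k1 + a) / (n1 - k1 + a)) / ((k0 + a) / (n0 - k0 + a)) )
#'
#' with pseudocount a (Haldane-Anscombe-style, default 0.5) keeping every
#' score finite at k = 0 and k = n. Interactions between features are
#' ignored; a patient's cumulative risk is the sum of scores over their
#' visit history ([score_patients()]).
#'
#' @param train a `feature_matrix` with at least one case and one non-case.
#' @param alpha smoothing pseudocount, must be > 0.
#' @return object of class `nbc_model`: tibble of per-feature counts and
#'   scores plus training metadata.
#' @export
fit_nbc <- function(train, alpha = 0.5) {
  if (alpha <= 0) stop("alpha must be > 0")
  case <- train$labels == 1L
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 < 1 || n0 < 1) stop("training data must contain both classes")
  bin <- fm_binary(train)
  k1 <- Matrix::colSums(bin[case, , drop = FALSE])
  k0 <- Matrix::colSums(bin[!case, , drop = FALSE])
  score <- log(((k1 + alpha) / (n1 - k1 + alpha)) /
                 ((k0 + alpha) / (n0 - k0 + alpha)))
  structure(
    list(
      table = tibble(feature_id = train$features,
                     k_case = as.integer(k1), k_noncase = as.integer(k0),
                     score = unname(score)),
      alpha = alpha, n_case = n1, n_noncase = n0
    ),
    class = "nbc_model"
  )
}

#' @export
print.nbc_model <- function(x, ...) {
  cat("NBC risk-score model:", nrow(x$table), "features; trained on",
      x$n_case, "cases /", x$n_noncase, "non-cases (alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Cumulative risk scores for patients
#'
#' A patient's risk is the sum of feature scores over all (feature, visit)
#' occurrences in their history: a feature recorded at three visits
#' contributes three times its score. Features unknown to the model
#' contribute 0.
#'
#' @param model an `nbc_model`.
#' @param fm a `feature_matrix` whose counts carry per-visit multiplicity.
#' @return numeric vector of cumulative scores, one per subject.
#' @export
score_patients <- function(model, fm) {
  s <- model$table$score[match(fm$features, model$table$feature_id)]
  s[is.na(s)] <- 0
  as.numeric(fm$counts %*% s)
}

#' Top features by absolute risk score
#'
#' Features ranked by |score| descending, ties broken lexicographically by
#' feature id so the ranking is deterministic.
#'
#' @param model an `nbc_model`.
#' @param k number of features to return (default 200).
#' @return character vector of feature ids.
#' @export
top_features <- function(model, k = 200L) {
  tab <- model$table
  if (k > nrow(tab)) {
    warning("k = ", k, " exceeds the ", nrow(tab),
            "-feature universe; returning the full ranking")
    k <- nrow(tab)
  }
  ord <- order(-abs(tab$score), tab$feature_id)
  tab$feature_id[ord][seq_len(k)]
}

#' Serialize / load an NBC model as a delimited table
#'
#' Columns: feature_id, k_case, k_noncase, score, plus a header comment line
#' carrying alpha and training counts.
#' @param model an `nbc_model`.
#' @param path file path.
#' @export
write_nbc <- function(model, path) {
  writeLines(sprintf("# alpha=%.10g n_case=%d n_noncase=%d",
                     model$alpha, model$n_case, model$n_noncase), path)
  readr::write_tsv(model$table, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_nbc
#' @export
read_nbc <- function(path) {
  hdr <- readLines(path, n = 1L)
  grab <- function(key)
    as.numeric(sub(paste0(".*", key, "=([0-9.eE+-]+).*"), "\\1", hdr))
  tab <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(
                           feature_id = readr::col_character(),
                           k_case = readr::col_integer(),
                           k_noncase = readr::col_integer(),
                           score = readr::col_double()
                         ), progress = FALSE)
  structure(list(table = tab, alpha = grab("alpha"),
                 n_case = as.integer(grab("n_case")),
                 n_noncase = as.integer(grab("n_noncase"))),
            class = "nbc_model")
}
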