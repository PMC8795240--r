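#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed as the Mann-Whitney probability that a random case outscores a
#' random non-case, with ties contributing 1/2 (midrank convention).
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcome labels.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PPV and sensitivity at fixed specificity levels
#'
#' For each level, the threshold is the smallest score cut whose specificity
#' is at least the level (predicted positive means score strictly above the
#' cut); PPV and sensitivity are reported at that cut. An unattainable level
#' is flagged with NA metrics.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 labels.
#' @param spec_levels specificity targets, default the four report levels.
#' @return tibble: specificity target, threshold, achieved specificity,
#'   ppv, sensitivity.
#' @export
metrics_at_specificity <- function(scores, labels,
                                   spec_levels = c(0.99, 0.95, 0.90, 0.80)) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  cuts <- sort(unique(scores))
  # specificity at cut t: fraction of non-cases with score <= t
  spec_at <- vapply(cuts, function(t) mean(scores[labels == 0L] <= t), 0)
  out <- lapply(spec_levels, function(level) {
    ok <- which(spec_at >= level)
    if (!length(ok))
      return(tibble(specificity = level, threshold = NA_real_,
                    achieved_specificity = NA_real_,
                    ppv = NA_real_, sensitivity = NA_real_))
    t <- cuts[min(ok)]
    pos <- scores > t
    tp <- sum(pos & labels == 1L); fp <- sum(pos & labels == 0L)
    tibble(specificity = level, threshold = t,
           achieved_specificity = spec_at[min(ok)],
           ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           sensitivity = tp / n1)
  })
  dplyr::bind_rows(out)
}

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Resamples subjects with replacement `n_boot` times and takes the 2.5 and
#' 97.5 empirical percentiles. Single-class resamples are redrawn (and
#' counted in the `redraws` attribute).
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return named numeric `c(auc, lower, upper)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  set.seed(seed)
  n <- length(scores)
  point <- roc_auc(scores, labels)
  redraws <- 0L
  stat <- vapply(seq_len(n_boot), function(b) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) == 2L) break
      redraws <<- redraws + 1L
    }
    roc_auc(scores[i], labels[i])
  }, 0)
  ci <- unname(quantile(stat, c(0.025, 0.975)))
  structure(c(auc = point, lower = ci[1], upper = ci[2]), redraws = redraws)
}

#' Paired-bootstrap test for an AUC difference
#'
#' Two models scored on the same subjects: bootstrap resamples are shared
#' between the models, giving a paired distribution of delta-AUC. The
#' two-sided p-value is 2 * min(P(delta <= 0), P(delta >= 0)) over the
#' bootstrap draws (a point mass exactly at 0 counts toward both tails),
#' capped at 1.
#'
#' @param scores_m1,scores_m2 scores of the two models on identical subjects.
#' @param labels shared 0/1 labels.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list: `delta` (observed AUC1 - AUC2), `p_value`, `deltas`
#'   (bootstrap draws).
#' @export
compare_auc <- function(scores_m1, scores_m2, labels, n_boot = 1000L, seed = 1L) {
  if (length(scores_m1) != length(labels) || length(scores_m2) != length(labels))
    stop("scores must be paired on identical subjects")
  set.seed(seed)
  n <- length(labels)
  deltas <- vapply(seq_len(n_boot), function(b) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) == 2L) break
    }
    roc_auc(scores_m1[i], labels[i]) - roc_auc(scores_m2[i], labels[i])
  }, 0)
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  list(delta = roc_auc(scores_m1, labels) - roc_auc(scores_m2, labels),
       p_value = min(p, 1), deltas = deltas)
}

#' Full evaluation report for one score vector
#'
#' AUC with percentile-bootstrap CI plus PPV/sensitivity at the standard
#' specificity levels, in the layout of the model-performance tables.
#'
#' @inheritParams bootstrap_auc_ci
#' @param spec_levels specificity targets.
#' @return list: `auc` (named vector with CI), `operating` (tibble from
#'   [metrics_at_specificity()]).
#' @export
eval_report <- function(scores, labels, n_boot = 1000L, seed = 1L,
                        spec_levels = c(0.99, 0.95, 0.90, 0.80)) {
  list(auc = bootstrap_auc_ci(scores, labels, n_boot = n_boot, seed = seed),
       operating = metrics_at_specificity(scores, labels, spec_levels))
}
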