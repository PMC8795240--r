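#' Balanced random forest configuration
#'
#' Ensemble-level parameters of the balanced random forest benchmark:
#' defaults are 30 trees, 50% of features sampled per tree, bootstrap size
#' equal to the training size, and a 1:4 case to non-case ratio in every
#' bootstrap sample, achieved by random undersampling of the majority class.
#'
#' @param n_trees number of trees (default 30).
#' @param feature_fraction proportion of features sampled per tree, in
#'   (0, 1] (default 0.5).
#' @param bootstrap_size bootstrap sample size; `NULL` means the training n.
#' @param ratio case:non-case ratio per bootstrap, as `"1:4"` or a length-2
#'   positive integer vector.
#' @param seed integer seed; per-tree randomness derives deterministically
#'   from it.
#' @export
brfc_config <- function(n_trees = 30L, feature_fraction = 0.5,
                        bootstrap_size = NULL, ratio = "1:4", seed = 1L) {
  if (is.character(ratio)) {
    parts <- as.integer(strsplit(ratio, ":", fixed = TRUE)[[1]])
  } else parts <- as.integer(ratio)
  if (length(parts) != 2L || any(is.na(parts)) || any(parts <= 0))
    stop("ratio must parse to two positive integers, e.g. '1:4'")
  stopifnot(n_trees >= 1, feature_fraction > 0, feature_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 feature_fraction = feature_fraction,
                 bootstrap_size = bootstrap_size,
                 ratio = parts, seed = as.integer(seed)),
            class = "brfc_config")
}

# Deterministic per-tree seed stream derived from the config seed.
brfc_tree_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$n_trees)
}

#' Balanced bootstrap sample for one tree
#'
#' Returns a subject index multiset of the configured bootstrap size with
#' the case:non-case composition met exactly: for ratio r:s, cases =
#' round(size * r / (r + s)), remainder non-cases. Cases are sampled with
#' replacement from all cases; non-cases with replacement from a per-tree
#' undersampled majority pool (drawn without replacement before the
#' with-replacement draws).
#'
#' @param labels 0/1 training labels, or a `feature_matrix`.
#' @param config a [brfc_config()].
#' @param tree_index which tree's sample to draw (determines the seed).
#' @return integer vector of subject indices (with repeats).
#' @export
balanced_bootstrap_sample <- function(labels, config, tree_index) {
  if (inherits(labels, "feature_matrix")) labels <- labels$labels
  size <- config$bootstrap_size %||% length(labels)
  if (size < sum(config$ratio))
    stop("bootstrap size ", size, " infeasible for ratio ",
         paste(config$ratio, collapse = ":"))
  cases <- which(labels == 1L)
  noncases <- which(labels == 0L)
  if (!length(cases)) stop("training data has no cases")
  n_case <- round(size * config$ratio[1] / sum(config$ratio))
  n_nonc <- size - n_case
  set.seed(brfc_tree_seeds(config)[tree_index])
  pool <- noncases[sample.int(length(noncases), min(n_nonc, length(noncases)))]
  c(cases[sample.int(length(cases), n_case, replace = TRUE)],
    pool[sample.int(length(pool), n_nonc, replace = TRUE)])
}

#' Fit a balanced random forest
#'
#' An ensemble of CART trees (Gini impurity, grown without a depth limit via
#' rpart), each trained on its own balanced bootstrap sample and a per-tree
#' random subset of ceiling(feature_fraction * p) features. The forest
#' prediction is the mean of the per-tree case-probability outputs. Unlike
#' the additive risk score, the trees can represent interactions between
#' structured and unstructured features.
#'
#' @param train a `feature_matrix` with binary labels.
#' @param config a [brfc_config()].
#' @return object of class `balanced_forest`.
#' @export
fit_balanced_forest <- function(train, config = brfc_config()) {
  stopifnot(inherits(train, "feature_matrix"))
  if (!any(train$labels == 1L) || !any(train$labels == 0L))
    stop("training data must contain both classes")
  p <- length(train$features)
  m <- ceiling(config$feature_fraction * p)
  X <- as.matrix(fm_binary(train)) * 1
  seeds <- brfc_tree_seeds(config)

  trees <- lapply(seq_len(config$n_trees), function(t) {
    idx <- balanced_bootstrap_sample(train$labels, config, t)
    set.seed(seeds[t] %% (.Machine$integer.max - 1L) + 1L)
    feats <- sample.int(p, m)
    df <- as.data.frame(X[idx, feats, drop = FALSE])
    names(df) <- paste0("f", feats)
    df$.y <- factor(train$labels[idx], levels = c(0L, 1L))
    fit <- rpart::rpart(
      .y ~ ., data = df, method = "class",
      control = rpart::rpart.control(cp = 0, minsplit = 10, xval = 0,
                                     maxdepth = 30, maxsurrogate = 0,
                                     maxcompete = 0)
    )
    list(fit = fit, features = feats)
  })
  structure(list(trees = trees, config = config, features = train$features),
            class = "balanced_forest")
}

#' @export
print.balanced_forest <- function(x, ...) {
  cat("balanced_forest:", length(x$trees), "trees over",
      length(x$features), "features (ratio ",
      paste(x$config$ratio, collapse = ":"), ")\n")
  invisible(x)
}

#' @param object a `balanced_forest`.
#' @param newdata a `feature_matrix` over the same feature universe.
#' @param ... unused.
#' @return numeric vector of case probabilities (mean over trees).
#' @rdname fit_balanced_forest
#' @export
predict.balanced_forest <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_matrix"))
  if (!identical(newdata$features, object$features))
    stop("newdata feature universe differs from the training universe")
  X <- as.matrix(fm_binary(newdata)) * 1
  probs <- vapply(object$trees, function(tr) {
    df <- as.data.frame(X[, tr$features, drop = FALSE])
    names(df) <- paste0("f", tr$features)
    predict(tr$fit, newdata = df, type = "prob")[, "1"]
  }, numeric(nrow(X)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

#' Compare structured, unstructured and combined feature sets
#'
#' Fits the NBC risk score and the balanced random forest on each of the
#' three column subsets (unstructured only, structured only, both) and
#' reports AUC with percentile-bootstrap CI plus PPV/sensitivity at the four
#' standard specificity levels.
#'
#' @param train,test `feature_matrix` objects over the same universe.
#' @param config a [brfc_config()].
#' @param alpha NBC smoothing pseudocount.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed integer seed for the bootstrap.
#' @param models which model families to run.
#' @return list: `auc` (tibble: model, feature_set, auc, lower, upper),
#'   `operating` (tibble of per-level PPV/sensitivity), `scores` (named list
#'   of test-score vectors for downstream paired comparisons).
#' @export
run_feature_set_comparison <- function(train, test, config = brfc_config(),
                                       alpha = 0.5, n_boot = 1000L, seed = 1L,
                                       models = c("nbc", "brfc")) {
  sets <- list(
    unstructured = train$features[train$feature_type == "unstructured"],
    structured = train$features[train$feature_type == "structured"],
    both = train$features
  )
  empty <- names(sets)[vapply(sets, length, 0L) == 0]
  if (length(empty))
    stop("empty feature subset: ", paste(empty, collapse = ", "))

  auc_rows <- list(); op_rows <- list(); scores <- list()
  for (set_name in names(sets)) {
    tr <- fm_select_features(train, sets[[set_name]])
    te <- fm_select_features(test, sets[[set_name]])
    for (model in models) {
      s <- if (model == "nbc") {
        score_patients(fit_nbc(tr, alpha = alpha), te)
      } else {
        predict(fit_balanced_forest(tr, config), te)
      }
      rep <- eval_report(s, te$labels, n_boot = n_boot, seed = seed)
      auc_rows[[paste(model, set_name)]] <- tibble(
        model = model, feature_set = set_name,
        auc = rep$auc[["auc"]], lower = rep$auc[["lower"]],
        upper = rep$auc[["upper"]])
      op_rows[[paste(model, set_name)]] <- dplyr::mutate(
        rep$operating, model = model, feature_set = set_name,
        .before = 1)
      scores[[paste(model, set_name, sep = "_")]] <- s
    }
  }
  list(auc = dplyr::bind_rows(auc_rows),
       operating = dplyr::bind_rows(op_rows),
       scores = scores, labels = test$labels)
}

#' Small grid search with 5-fold cross-validation
#'
#' Scaffold for selecting ensemble parameters: evaluates each candidate
#' config by 5-fold cross-validated AUC on the training data and returns the
#' grid with the winner flagged.
#'
#' @param train a `feature_matrix`.
#' @param grid a data frame of candidate parameters with columns among
#'   `n_trees`, `feature_fraction`; one row per candidate.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return tibble: the grid plus `cv_auc`, sorted best first.
#' @export
grid_search_brfc <- function(train, grid, folds = 5L, seed = 1L) {
  set.seed(seed)
  # stratified fold assignment
  fold <- integer(length(train$labels))
  for (lab in c(0L, 1L)) {
    idx <- which(train$labels == lab)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  grid <- as_tibble(grid)
  grid$cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- brfc_config(
      n_trees = grid$n_trees[g] %||% 30L,
      feature_fraction = grid$feature_fraction[g] %||% 0.5,
      seed = seed + g
    )
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fm_subset(train, which(fold != f))
      te <- fm_subset(train, which(fold == f))
      roc_auc(predict(fit_balanced_forest(tr, cfg), te), te$labels)
    }, 0)
    mean(aucs)
  }, 0)
  dplyr::arrange(grid, dplyr::desc(.data$cv_auc))
}
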