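# Recursive feature elimination and random-forest classification of
# per-residue contact energies.
#
# Continuous per-residue energies are discretized into five equal-frequency
# classes (quantile bins), the data are split 70/30 stratified by class,
# and recursive feature elimination over the 94 pair-descriptor features
# selects the subset maximizing cross-validated accuracy; a random forest
# trained on the selected features is evaluated on the held-out split with
# confusion-matrix statistics (accuracy with exact binomial CI, Cohen's
# kappa, McNemar against the majority-class baseline).

#' Equal-frequency discretization into k classes
#'
#' Bin edges are the k-quantiles of `values` (20/40/60/80th percentiles for
#' k = 5); edges are returned so the same bins can be applied to held-out
#' data. Heavy ties can merge bins; the result then carries fewer
#' effective classes and a warning is raised.
#'
#' @param values Numeric vector (length >= k).
#' @param k Number of classes (default 5).
#' @param edges Optional previously fitted edges to reuse.
#' @return List: `labels` (factor Q1..Qk), `edges` (numeric breaks),
#'   `k_effective`.
#' @export
discretize_quantiles <- function(values, k = 5, edges = NULL) {
  if (is.null(edges)) {
    if (length(values) < k) stop("need at least k values to fit k bins")
    qs <- stats::quantile(values, probs = seq_len(k - 1) / k, names = FALSE)
    edges <- unique(qs)
    if (length(edges) < k - 1)
      warning("massive ties: ", k - 1 - length(edges),
              " bin edge(s) merged; fewer effective classes")
  }
  breaks <- c(-Inf, edges, Inf)
  labels <- cut(values, breaks = breaks,
                labels = paste0("Q", seq_len(length(breaks) - 1)),
                include.lowest = TRUE)
  list(labels = labels, edges = edges,
       k_effective = length(unique(labels[!is.na(labels)])))
}

#' Assemble a train/test dataset for the energy-classification task
#'
#' @param features data.frame of descriptor features (94 columns).
#' @param target Numeric per-row contact energy.
#' @param k Number of target classes.
#' @param train_fraction Training share (default 0.7), stratified by class.
#' @param bin_on `"pooled"` (default): bins fitted on the full data before
#'   splitting; `"train"`: bins fitted on the training split only and
#'   applied to the test split.
#' @param seed RNG seed for the split.
#' @return List with `train`/`test` (each `x`, `y`), `edges`, `bin_on`.
#' @export
make_ml_dataset <- function(features, target, k = 5, train_fraction = 0.7,
                            bin_on = c("pooled", "train"), seed = 1) {
  bin_on <- match.arg(bin_on)
  stopifnot(nrow(features) == length(target))
  set.seed(seed)
  if (bin_on == "pooled") {
    pre <- discretize_quantiles(target, k)
    train_idx <- sort(unlist(lapply(split(seq_along(target), pre$labels),
                                    function(i)
      sample(i, floor(train_fraction * length(i))))))
    edges <- pre$edges
    y_train <- pre$labels[train_idx]
    y_test <- pre$labels[-train_idx]
  } else {
    # train-only binning: the split must not look at any target value, so
    # it is a simple random split rather than a class-stratified one
    train_idx <- sort(sample(seq_along(target),
                             floor(train_fraction * length(target))))
    fit <- discretize_quantiles(target[train_idx], k)
    edges <- fit$edges
    y_train <- fit$labels
    y_test <- discretize_quantiles(target[-train_idx], k, edges = edges)$labels
  }
  list(train = list(x = features[train_idx, , drop = FALSE],
                    y = droplevels(y_train)),
       test = list(x = features[-train_idx, , drop = FALSE],
                   y = y_test),
       edges = edges, bin_on = bin_on, train_idx = train_idx)
}

#' Recursive feature elimination with random-forest importance
#'
#' Cross-validated recursive elimination over candidate subset sizes,
#' driven by random-forest variable importance (caret's rfFuncs backend).
#'
#' @param x Training feature data.frame.
#' @param y Training class factor.
#' @param sizes Candidate subset sizes.
#' @param cv_folds Number of CV folds (default 10).
#' @param ntree Trees per forest.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return List: `selected` (optimal feature names), `ranking` (all
#'   features by importance rank), `results` (per-size CV accuracy),
#'   `size` (optimal size).
#' @export
rfe_select <- function(x, y, sizes = c(1:20, 25, 30, 40, 60, 94),
                       cv_folds = 10, ntree = 500, seed = 1) {
  y <- droplevels(as.factor(y))
  if (nrow(x) < cv_folds) stop("fewer rows than CV folds")
  sizes <- sizes[sizes <= ncol(x)]
  set.seed(seed)
  ctrl <- caret::rfeControl(functions = caret::rfFuncs, method = "cv",
                            number = cv_folds, verbose = FALSE)
  fit <- caret::rfe(x = x, y = y, sizes = sizes, rfeControl = ctrl,
                    ntree = ntree)
  ranking <- fit$optVariables
  all_ranked <- unique(c(ranking, caret::predictors(fit),
                         rownames(caret::varImp(fit))))
  all_ranked <- all_ranked[all_ranked %in% colnames(x)]
  list(selected = fit$optVariables,
       ranking = all_ranked,
       results = fit$results,
       size = fit$optsize)
}

#' Train and evaluate the final random-forest classifier
#'
#' @param dataset Output of [make_ml_dataset()].
#' @param features Feature names to use (from [rfe_select()]); default all.
#' @param ntree Trees.
#' @param seed RNG seed.
#' @return List of metrics: accuracy, accuracy_ci95, kappa, mcnemar_p
#'   (versus the majority-class baseline on the shared test rows),
#'   confusion (table), plus the fitted forest and predictions.
#' @export
train_eval <- function(dataset, features = NULL, ntree = 500, seed = 1) {
  tr <- dataset$train; te <- dataset$test
  if (is.null(features)) features <- colnames(tr$x)
  set.seed(seed)
  fit <- randomForest::randomForest(x = tr$x[, features, drop = FALSE],
                                    y = droplevels(tr$y), ntree = ntree)
  pred <- stats::predict(fit, te$x[, features, drop = FALSE])
  lev <- union(levels(droplevels(tr$y)), levels(droplevels(te$y)))
  pred <- factor(as.character(pred), levels = lev)
  truth <- factor(as.character(te$y), levels = lev)
  cm <- caret::confusionMatrix(pred, truth)
  majority <- names(which.max(table(tr$y)))
  base_correct <- truth == majority
  model_correct <- pred == truth
  mcn <- .paired_mcnemar(model_correct, base_correct)
  list(accuracy = unname(cm$overall["Accuracy"]),
       accuracy_ci95 = unname(cm$overall[c("AccuracyLower",
                                           "AccuracyUpper")]),
       kappa = unname(cm$overall["Kappa"]),
       mcnemar_p = mcn,
       confusion = cm$table,
       fit = fit, predictions = pred, truth = truth)
}

# McNemar on paired correctness indicators of two classifiers over the
# same test rows.
.paired_mcnemar <- function(correct_a, correct_b) {
  b <- sum(correct_a & !correct_b)
  c_ <- sum(!correct_a & correct_b)
  if (b + c_ == 0) return(NA_real_)
  stats::mcnemar.test(matrix(c(sum(correct_a & correct_b), b, c_,
                               sum(!correct_a & !correct_b)), 2))$p.value
}
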