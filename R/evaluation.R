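#' Nested cross-validation configuration
#'
#' Settings for the combined feature-selection and classification procedure:
#' an outer stratified k-fold loop estimates generalization of a model whose
#' features are chosen, per outer training set, by best-first forward search
#' scored with inner stratified k-fold cross-validation of a small bagged
#' random-forest ensemble.
#'
#' @param outer_folds Outer CV folds (default 10; at least 2).
#' @param inner_folds Inner CV folds used to score candidate feature subsets
#'   (default 10).
#' @param trees Trees in the random-forest ensemble (default 10).
#' @param stale_limit Stop the best-first search after this many consecutive
#'   node expansions without improving the best subset (default 5).
#' @param seed Integer seed controlling folds, SMOTE and forest fits.
#' @param undefined_as_zero Treat undefined per-class precision (class never
#'   predicted in a fold) as 0 instead of excluding it from fold averaging.
#'
#' @return An object of class `nested_cv_config`.
#' @examples
#' nested_cv_config(seed = 1)
#' @export
nested_cv_config <- function(outer_folds = 10, inner_folds = 10, trees = 10,
                             stale_limit = 5, seed = 1,
                             undefined_as_zero = FALSE) {
  if (outer_folds < 2) abort("`outer_folds` must be at least 2.")
  if (inner_folds < 2) abort("`inner_folds` must be at least 2.")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 trees = as.integer(trees),
                 stale_limit = as.integer(stale_limit),
                 seed = as.integer(seed),
                 undefined_as_zero = isTRUE(undefined_as_zero)),
            class = "nested_cv_config")
}

#' Stratified fold assignment
#'
#' Partitions indices into `k` disjoint folds keeping each class's relative
#' representation intact: every fold receives `floor(n_c / k)` or
#' `ceiling(n_c / k)` members of class `c`, and classes' remainders are dealt
#' to the currently least-loaded folds so fold sizes differ by at most one.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (at least 2).
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return A list of `k` integer index vectors covering `seq_along(labels)`.
#' @examples
#' folds <- stratified_folds(rep(c("a", "b"), each = 10), 10, seed = 1)
#' lengths(folds)
#' @export
stratified_folds <- function(labels, k, seed = NULL) {
  if (k < 2) abort("`k` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  small <- names(which(table(labels) < k))
  if (length(small))
    warn(sprintf("Class(es) %s have fewer than %d members; some folds will lack them.",
                 paste(small, collapse = ", "), k))
  folds <- vector("list", k)
  load <- integer(k)
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    base <- n %/% k; extra <- n %% k
    take <- rep(base, k)
    if (extra > 0) {
      recipients <- order(load, seq_len(k))[seq_len(extra)]
      take[recipients] <- take[recipients] + 1L
    }
    pos <- 1L
    for (f in seq_len(k)) {
      if (take[f] > 0) {
        folds[[f]] <- c(folds[[f]], idx[pos:(pos + take[f] - 1L)])
        pos <- pos + take[f]
      }
    }
    load <- load + take
  }
  lapply(folds, sort)
}

#' Classification metrics from a confusion matrix
#'
#' Rows are actual classes, columns predicted classes. Total accuracy is the
#' trace over the total; per-class precision is the diagonal over the column
#' sum (predicted-as-k) and per-class recall the diagonal over the row sum
#' (actually-k). A zero denominator yields `NA` — the undefined marker that
#' fold averaging excludes (see [nested_cv_config()] for the
#' `undefined_as_zero` alternative).
#'
#' @param cm Square numeric matrix with matching row/column names (classes).
#' @return A list with `accuracy` (scalar), `precision` and `recall` (named
#'   vectors over classes).
#' @examples
#' cm <- matrix(c(8, 1, 2, 9), 2, byrow = TRUE,
#'              dimnames = list(c("a", "b"), c("a", "b")))
#' metrics_from_confusion(cm)
#' @export
metrics_from_confusion <- function(cm) {
  if (length(cm) == 0 || sum(cm) == 0) abort("Empty confusion matrix.")
  if (nrow(cm) != ncol(cm)) abort("Confusion matrix must be square.")
  d <- diag(as.matrix(cm))
  col_tot <- colSums(cm); row_tot <- rowSums(cm)
  list(accuracy = sum(d) / sum(cm),
       precision = ifelse(col_tot > 0, d / col_tot, NA_real_),
       recall = ifelse(row_tot > 0, d / row_tot, NA_real_))
}

#' Macro-averaged F-measure of a confusion matrix
#'
#' Harmonic mean of precision and recall per class, averaged over classes.
#' A class with undefined precision or zero harmonic denominator contributes
#' an F of 0 (so a constant classifier on balanced two-class data scores
#' exactly 1/3).
#'
#' @param cm Square confusion matrix (rows actual, columns predicted).
#' @return Macro F-measure in `[0, 1]`.
#' @export
macro_f1 <- function(cm) {
  m <- metrics_from_confusion(cm)
  p <- ifelse(is.na(m$precision), 0, m$precision)
  r <- ifelse(is.na(m$recall), 0, m$recall)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  mean(f)
}

#' Mean and sample SD over folds
#'
#' The `m(s)` summary: empirical mean and sample standard deviation
#' (divisor n-1) of per-fold metric values. `NA` values (undefined markers)
#' are excluded from both.
#'
#' @param x Numeric vector of per-fold values.
#' @return A list with `mean`, `sd` and `n` (count of defined values).
#' @examples
#' summarize_folds(c(0.8, 1.0))
#' @export
summarize_folds <- function(x) {
  x <- x[!is.na(x)]
  list(mean = mean(x), sd = if (length(x) >= 2) sd(x) else NA_real_,
       n = length(x))
}

# Fit the bagged-tree ensemble; x matrices, y factor. A feature matrix with
# no varying column cannot grow a tree (and stalls the forest code), so it
# degenerates to a majority-class predictor.
fit_forest <- function(x_train, y_train, trees) {
  varying <- apply(x_train, 2, function(v) any(v != v[1]))
  if (!any(varying)) {
    maj <- names(which.max(table(y_train)))
    return(structure(list(majority = maj, levels = levels(y_train)),
                     class = "majority_stub"))
  }
  randomForest::randomForest(x_train, y_train, ntree = trees)
}

#' @export
predict.majority_stub <- function(object, newdata, ...) {
  factor(rep(object$majority, nrow(newdata)), levels = object$levels)
}

confusion <- function(actual, predicted, classes) {
  table(factor(actual, levels = classes),
        factor(predicted, levels = classes))
}

# Mean macro F over an inner stratified CV of the ensemble on one subset.
score_subset <- function(x, y, subset, folds, trees, classes) {
  fs <- numeric(length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    if (length(te) == 0 || length(unique(y[-te])) < 2) { fs[f] <- 0; next }
    fit <- fit_forest(x[-te, subset, drop = FALSE], y[-te], trees)
    pred <- predict(fit, x[te, subset, drop = FALSE])
    fs[f] <- macro_f1(confusion(y[te], pred, classes))
  }
  mean(fs)
}

#' Best-first forward wrapper feature selection
#'
#' Searches feature subsets starting from the empty set, expanding the
#' best-scoring open subset by single-feature additions. Each candidate
#' subset is scored by the mean macro F-measure of the random-forest
#' ensemble under inner stratified k-fold cross-validation on the training
#' table; scores are cached so no subset is evaluated twice. The search
#' stops after `stale_limit` consecutive expansions that fail to improve the
#' best subset found, and returns that best subset.
#'
#' @param data Training data frame: numeric feature columns plus a label
#'   column.
#' @param label_col Name of the label column (default `"label"`).
#' @param config A [nested_cv_config()]; uses `inner_folds`, `trees` and
#'   `stale_limit`. The caller controls the RNG state.
#' @return Character vector of selected feature names (possibly empty).
#' @export
best_first_selection <- function(data, label_col = "label", config = nested_cv_config()) {
  y <- factor(as.character(data[[label_col]]))
  if (nlevels(y) < 2) abort("Need at least 2 classes for feature selection.")
  feat <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], label_col)
  x <- as.matrix(data[feat])
  classes <- levels(y)
  k <- min(config$inner_folds, length(y))
  folds <- suppressWarnings(stratified_folds(y, k))

  cache <- new.env(parent = emptyenv())
  eval_subset <- function(subset) { # subset: sorted integer vector
    key <- paste(subset, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    sc <- score_subset(x, y, subset, folds, config$trees, classes)
    cache[[key]] <- sc
    sc
  }

  open <- list(list(subset = integer(0), score = 0))
  best_subset <- integer(0); best_score <- 0
  stale <- 0L
  while (length(open) > 0 && stale < config$stale_limit) {
    scores <- vapply(open, `[[`, numeric(1), "score")
    b <- which.max(scores)
    node <- open[[b]]; open[[b]] <- NULL
    additions <- setdiff(seq_along(feat), node$subset)
    improved <- FALSE
    for (a in additions) {
      child <- sort(c(node$subset, a))
      key <- paste(child, collapse = ",")
      seen <- !is.null(cache[[key]])
      sc <- eval_subset(child)
      if (!seen) open[[length(open) + 1]] <- list(subset = child, score = sc)
      if (sc > best_score + 1e-12) {
        best_score <- sc; best_subset <- child; improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
    # macro F is bounded by 1: once attained, no candidate can strictly
    # improve, so the remaining stale expansions cannot change the result
    if (best_score >= 1) break
  }
  feat[best_subset]
}

#' Nested cross-validation of the texture-classification pipeline
#'
#' For each outer stratified fold: optionally SMOTE-balance the outer
#' training portion, select features on it with [best_first_selection()],
#' train the random-forest ensemble on the selected features, and predict
#' the untouched outer test fold. No test instance ever influences feature
#' selection or training. Per-fold confusion matrices and metrics are
#' collected and summarized as mean (SD) over folds.
#'
#' SMOTE placement: `"within-folds"` (default) applies SMOTE inside each
#' outer training partition only, so synthetic points never derive from test
#' subjects; `"pre-split"` balances the whole table before splitting (the
#' historically common but leak-prone protocol, kept for comparability);
#' `"off"` disables rebalancing.
#'
#' @param data Cohort table: numeric feature columns plus a label column.
#' @param config A [nested_cv_config()].
#' @param smote `"within-folds"`, `"pre-split"` or `"off"`.
#' @param smote_k Neighbour count for SMOTE (default 5).
#' @param label_col Name of the label column.
#'
#' @return An object of class `nested_cv`: list with `folds` (per-fold
#'   tibble of metrics), `confusions` (list of matrices), `selected` (list
#'   of feature-name vectors), `summary` (tibble of mean/sd per metric),
#'   `classes`, `config`, `smote`.
#' @examples
#' d <- tibble::tibble(f1 = c(rnorm(15, 0), rnorm(15, 4)),
#'                     f2 = rnorm(30),
#'                     label = rep(c("A", "B"), each = 15))
#' fit <- run_nested_cv(d, nested_cv_config(outer_folds = 3, inner_folds = 3,
#'                                          seed = 1))
#' glance(fit)
#' @export
run_nested_cv <- function(data, config = nested_cv_config(),
                          smote = c("within-folds", "pre-split", "off"),
                          smote_k = 5, label_col = "label") {
  smote <- match.arg(smote)
  stopifnot(inherits(config, "nested_cv_config"))
  set.seed(config$seed)

  data <- as_tibble(data)
  if (smote == "pre-split") data <- smote_balance(data, label_col, k = smote_k)
  y <- factor(as.character(data[[label_col]]))
  classes <- levels(y)
  feat <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], label_col)
  folds <- suppressWarnings(stratified_folds(y, config$outer_folds))

  conf_list <- vector("list", length(folds))
  sel_list <- vector("list", length(folds))
  met_rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    train <- data[-te, c(feat, label_col)]
    if (smote == "within-folds")
      train <- smote_balance(train, label_col, k = smote_k)
    sel <- best_first_selection(train, label_col, config)
    use <- if (length(sel)) sel else feat # empty selection: fall back to all
    fit <- fit_forest(as.matrix(train[use]),
                      factor(as.character(train[[label_col]]), levels = classes),
                      config$trees)
    pred <- predict(fit, as.matrix(data[te, use]))
    cm <- confusion(y[te], pred, classes)
    m <- metrics_from_confusion(cm)
    if (config$undefined_as_zero) {
      m$precision[is.na(m$precision)] <- 0
      m$recall[is.na(m$recall)] <- 0
    }
    conf_list[[f]] <- cm
    sel_list[[f]] <- sel
    met_rows[[f]] <- tibble(
      fold = f,
      metric = c("accuracy",
                 paste0("precision_", classes), paste0("recall_", classes)),
      value = c(m$accuracy, unname(m$precision), unname(m$recall)))
  }
  per_fold <- dplyr::bind_rows(met_rows)
  summ <- per_fold |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value[!is.na(.data$value)]),
                     n_folds = sum(!is.na(.data$value)),
                     .groups = "drop")
  structure(list(folds = per_fold, confusions = conf_list,
                 selected = sel_list, summary = summ, classes = classes,
                 config = config, smote = smote),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("<nested_cv> %d outer folds, %d classes (%s), SMOTE: %s\n",
              length(x$confusions), length(x$classes),
              paste(x$classes, collapse = ", "), x$smote))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %.2f (%.2f)\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' @describeIn run_nested_cv Per-fold metric values as a long tibble
#'   (`fold`, `metric`, `value`).
#' @param x A `nested_cv` object.
#' @param ... Unused.
#' @export
tidy.nested_cv <- function(x, ...) x$folds

#' @describeIn run_nested_cv One row per metric with `mean`, `sd` and the
#'   number of folds where the metric was defined — the "m(s)" report.
#' @export
glance.nested_cv <- function(x, ...) x$summary

#' @describeIn run_nested_cv Dot-and-interval plot of per-fold metrics.
#' @param object A `nested_cv` object.
#' @export
autoplot.nested_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6, na.rm = TRUE) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 3, na.rm = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "per-fold value (red = mean)", x = NULL) +
    ggplot2::theme_minimal()
}
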