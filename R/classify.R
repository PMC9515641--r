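#' Classifier configuration
#'
#' Named presets mirroring the common interactive ML-toolbox classifiers
#' used for cytometry feature tables: linear / quadratic / cubic SVM
#' (box constraint 1, kernel scale 1, one-vs-one multiclass), fine KNN
#' (1 neighbour, Euclidean), cosine KNN (10 neighbours, cosine distance,
#' equal weights) and a depth-limited decision tree (at most 20 splits).
#'
#' @param kind One of `"linear_svm"`, `"quadratic_svm"`, `"cubic_svm"`,
#'   `"fine_knn"`, `"cosine_knn"`, `"medium_tree"`.
#' @param box_constraint SVM cost parameter C.
#' @param kernel_scale SVM kernel scale s; the polynomial kernel is
#'   `(u.v / s^2 + 1)^degree`.
#' @param knn_k Neighbour count (defaults: 1 for fine, 10 for cosine KNN).
#' @param knn_metric `"euclidean"` or `"cosine"`.
#' @param tree_max_splits Maximum split count of the decision tree.
#' @param folds Cross-validation folds (default 5).
#' @param repeats Number of repeated CV runs (default 5).
#' @param seed Integer seed for fold assignment.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("quadratic_svm", "linear_svm",
                                       "cubic_svm", "fine_knn", "cosine_knn",
                                       "medium_tree"),
                              box_constraint = 1, kernel_scale = 1,
                              knn_k = NULL, knn_metric = NULL,
                              tree_max_splits = 20, folds = 5, repeats = 5,
                              seed = 1) {
  kind <- match.arg(kind)
  stopifnot(folds >= 2, repeats >= 1, box_constraint > 0, kernel_scale > 0)
  if (is.null(knn_k))
    knn_k <- switch(kind, fine_knn = 1L, cosine_knn = 10L, 1L)
  if (is.null(knn_metric))
    knn_metric <- switch(kind, cosine_knn = "cosine", "euclidean")
  stopifnot(knn_k >= 1)
  structure(list(kind = kind, box_constraint = box_constraint,
                 kernel_scale = kernel_scale, knn_k = as.integer(knn_k),
                 knn_metric = knn_metric,
                 tree_max_splits = as.integer(tree_max_splits),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

.feature_matrix <- function(features) {
  std <- c("D_um", "nc_ratio", "ri_n", "ri_c")
  if (all(std %in% names(features))) return(as.matrix(features[, std]))
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  num <- setdiff(num, c("residual"))
  if (length(num) == 0) stop("no numeric feature columns found")
  as.matrix(features[, num, drop = FALSE])
}

.check_features <- function(features, folds) {
  if (!"label" %in% names(features)) stop("features need a 'label' column")
  if (any(features$flagged %||% FALSE))
    features <- features[!features$flagged, ]
  X <- .feature_matrix(features)
  if (anyNA(X) || anyNA(features$label))
    stop("feature table contains missing values")
  y <- factor(features$label)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (any(table(y) < folds))
    stop("every class needs at least as many members as folds")
  list(X = X, y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stratified fold assignment, one integer in 1..k per observation
.make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# k-nearest-neighbour prediction with equal weights; distance ties resolve
# by training order, vote ties by the lowest class index
.knn_predict <- function(Xtr, ytr, Xte, k, metric) {
  if (metric == "cosine") {
    nt <- sqrt(rowSums(Xtr^2)); nq <- sqrt(rowSums(Xte^2))
    nt[nt == 0] <- 1; nq[nq == 0] <- 1
    D <- 1 - (Xte %*% t(Xtr)) / outer(nq, nt)
  } else {
    D <- outer(rowSums(Xte^2), rep(1, nrow(Xtr))) +
      outer(rep(1, nrow(Xte)), rowSums(Xtr^2)) - 2 * Xte %*% t(Xtr)
    D[D < 0] <- 0
  }
  lev <- levels(ytr)
  pred <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    nb <- ytr[order(D[i, ])[seq_len(min(k, ncol(D)))]]
    votes <- table(nb)
    pred[i] <- names(votes)[which.max(votes)]  # first max = lowest index
  }
  factor(pred, levels = lev)
}

.fit_predict <- function(cfg, Xtr, ytr, Xte) {
  kind <- cfg$kind
  if (kind %in% c("linear_svm", "quadratic_svm", "cubic_svm")) {
    deg <- switch(kind, linear_svm = 1L, quadratic_svm = 2L, cubic_svm = 3L)
    kernel <- if (kind == "linear_svm") "linear" else "polynomial"
    fit <- e1071::svm(Xtr, ytr, kernel = kernel, degree = deg,
                      gamma = 1 / cfg$kernel_scale^2, coef0 = 1,
                      cost = cfg$box_constraint, scale = FALSE)
    predict(fit, Xte)
  } else if (kind %in% c("fine_knn", "cosine_knn")) {
    .knn_predict(Xtr, ytr, Xte, cfg$knn_k, cfg$knn_metric)
  } else {
    df <- data.frame(Xtr, y = ytr, check.names = FALSE)
    fit <- rpart::rpart(y ~ ., df, method = "class",
                        control = rpart::rpart.control(cp = 0, xval = 0,
                                                       minsplit = 10,
                                                       maxsurrogate = 0))
    cpt <- fit$cptable
    ok <- which(cpt[, "nsplit"] <= cfg$tree_max_splits)
    if (length(ok) > 0 && max(cpt[, "nsplit"]) > cfg$tree_max_splits)
      fit <- rpart::prune(fit, cp = cpt[max(ok), "CP"])
    predict(fit, data.frame(Xte, check.names = FALSE), type = "class")
  }
}

#' Repeated stratified cross-validation of a classifier
#'
#' Runs stratified k-fold cross-validation `repeats` times (distinct fold
#' assignments derived from the config seed) on a four-feature table.
#' Features are z-scored using training-fold statistics only, so no
#' information leaks from held-out cells into the scaler.
#'
#' @param features Feature data frame with columns `D_um`, `nc_ratio`,
#'   `ri_n`, `ri_c` and `label` (e.g. from [batch_extract_features()]).
#' @param cfg A [classifier_config()].
#' @param fold_sets Optional list of precomputed fold vectors (one per
#'   repeat), used by [compare_classifiers()] for paired comparisons.
#' @return Object of class `classification_report`: per-repeat confusion
#'   matrices and accuracies, the pooled confusion matrix, per-class PPV
#'   and FDR (percent, from the pooled matrix), mean overall accuracy
#'   (percent) and misclassification cost (mean off-diagonal count per
#'   repeat at unit cost).
#' @export
cross_validate <- function(features, cfg = classifier_config(),
                           fold_sets = NULL) {
  stopifnot(inherits(cfg, "classifier_config"))
  dat <- .check_features(features, cfg$folds)
  X <- dat$X; y <- dat$y
  if (is.null(fold_sets)) {
    set.seed(cfg$seed)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$repeats)
    fold_sets <- lapply(rep_seeds, function(s) .make_folds(y, cfg$folds, s))
  }
  lev <- levels(y)
  confusions <- vector("list", length(fold_sets))
  for (r in seq_along(fold_sets)) {
    fold <- fold_sets[[r]]
    pred <- factor(rep(NA_character_, length(y)), levels = lev)
    for (f in sort(unique(fold))) {
      tr <- fold != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sg <- apply(X[tr, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
      pred[!tr] <- .fit_predict(cfg, Xtr, y[tr], Xte)
    }
    confusions[[r]] <- table(true = y, predicted = pred)
  }
  .build_report(confusions, cfg, length(y))
}

.build_report <- function(confusions, cfg, n) {
  acc <- vapply(confusions,
                function(cm) 100 * sum(diag(cm)) / sum(cm), numeric(1))
  cost <- vapply(confusions,
                 function(cm) sum(cm) - sum(diag(cm)), numeric(1))
  pooled <- Reduce(`+`, lapply(confusions, unclass))
  cs <- confusion_stats(pooled)
  structure(list(confusions = confusions, pooled_confusion = pooled,
                 accuracy_per_repeat = acc, mean_accuracy = mean(acc),
                 ppv = cs$ppv, fdr = cs$fdr,
                 cost_per_repeat = cost, cost = mean(cost),
                 n = n, config = cfg),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%s: %d-fold CV x %d repeats on n = %d\n", x$config$kind,
              x$config$folds, length(x$confusions), x$n))
  cat(sprintf("  mean accuracy %.1f%% (per repeat: %s)\n", x$mean_accuracy,
              paste(sprintf("%.1f", x$accuracy_per_repeat), collapse = ", ")))
  cat(sprintf("  mean misclassification cost %.1f\n", x$cost))
  cat("  PPV% per class: ",
      paste(sprintf("%s %.1f", names(x$ppv), x$ppv), collapse = ", "), "\n")
  cat("  pooled confusion (true x predicted):\n")
  print(x$pooled_confusion)
  invisible(x)
}

#' Confusion-matrix summary statistics
#'
#' Positive predictive value per class (`100 * TP / column sum`, i.e. the
#' per-class precision), the complementary false discovery rate, overall
#' accuracy and the total misclassification count at unit cost. A class
#' never predicted has undefined PPV, reported as `NA`.
#'
#' @param confmat Square nonnegative integer matrix, rows = true classes,
#'   columns = predicted classes.
#' @return List with `ppv`, `fdr` (percent, named by class), `accuracy`
#'   (percent) and `cost` (count).
#' @examples
#' confusion_stats(matrix(c(8, 3, 2, 7), 2,
#'                        dimnames = list(c("M1", "M2"), c("M1", "M2"))))
#' @export
confusion_stats <- function(confmat) {
  cm <- as.matrix(confmat)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0) || any(cm != round(cm)))
    stop("confusion matrix must hold nonnegative integer counts")
  colsum <- colSums(cm)
  ppv <- ifelse(colsum > 0, 100 * diag(cm) / colsum, NA_real_)
  nms <- colnames(cm) %||% paste0("class", seq_len(ncol(cm)))
  names(ppv) <- nms
  list(ppv = ppv, fdr = 100 - ppv,
       accuracy = 100 * sum(diag(cm)) / sum(cm),
       cost = sum(cm) - sum(diag(cm)))
}

#' Paired comparison of several classifiers
#'
#' Evaluates each configuration on identical cross-validation splits
#' (derived from `seed`), so accuracy differences reflect the classifiers,
#' not fold luck.
#'
#' @param features Feature data frame (see [cross_validate()]).
#' @param kinds Character vector of classifier kinds, or a list of
#'   [classifier_config()] objects.
#' @param folds,repeats,seed Shared cross-validation settings (ignored for
#'   entries passed as full configs except for the shared splits).
#' @return Data frame ranked by decreasing mean accuracy, with the full
#'   reports in attribute `"reports"`.
#' @export
compare_classifiers <- function(features,
                                kinds = c("quadratic_svm", "linear_svm",
                                          "fine_knn", "medium_tree"),
                                folds = 5, repeats = 5, seed = 1) {
  cfgs <- lapply(kinds, function(k) {
    if (inherits(k, "classifier_config")) k
    else classifier_config(k, folds = folds, repeats = repeats, seed = seed)
  })
  if (length(cfgs) < 2) stop("need at least two classifier configurations")
  dat <- .check_features(features, folds)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  fold_sets <- lapply(rep_seeds, function(s) .make_folds(dat$y, folds, s))
  reports <- lapply(cfgs, function(cfg)
    cross_validate(features, cfg, fold_sets = fold_sets))
  out <- data.frame(
    kind = vapply(cfgs, `[[`, character(1), "kind"),
    mean_accuracy = vapply(reports, `[[`, numeric(1), "mean_accuracy"),
    cost = vapply(reports, `[[`, numeric(1), "cost"))
  ord <- order(-out$mean_accuracy)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "reports") <- reports[ord]
  out
}

#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Classical one-way analysis of variance across phenotype groups followed
#' by Tukey's honest significant difference test, with the usual
#' significance codes (n.s. > 0.05, * < 0.05, ** < 0.01, *** < 0.001).
#' Degenerate input with zero variance everywhere is reported as an
#' infinite F with p = 0 and flagged.
#'
#' @param values Numeric response (e.g. recovered diameters).
#' @param groups Group labels, coerced to factor.
#' @return Object of class `anova_tukey`: `F`, `p`, `df`, `tukey` (data
#'   frame of pairwise adjusted p-values with significance codes),
#'   `degenerate` flag.
#' @examples
#' anova_tukey(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
anova_tukey <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs at least two values")
  if (anyNA(values)) stop("values contain NA")
  df <- data.frame(v = as.numeric(values), g = g)
  fit <- aov(v ~ g, data = df)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  degenerate <- FALSE
  if (an[["Sum Sq"]][2] <= .Machine$double.eps * sum(values^2)) {
    degenerate <- TRUE
    if (an[["Sum Sq"]][1] > 0) { Fv <- Inf; pv <- 0 }
  }
  tk <- TukeyHSD(fit)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      code = .sig_code(tk[, "p adj"]),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(F = Fv, p = pv,
                 df = c(between = an[["Df"]][1], within = an[["Df"]][2]),
                 tukey = tukey, degenerate = degenerate),
            class = "anova_tukey")
}

.sig_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "n.s.")))
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g %s%s\n",
              x$df[1], x$df[2], x$F, x$p, .sig_code(x$p),
              if (x$degenerate) " [degenerate: zero within-group variance]"
              else ""))
  cat("Tukey HSD:\n")
  print(x$tukey, row.names = FALSE, digits = 4)
  invisible(x)
}
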