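#' Gini impurity of a node
#'
#' `1 - sum(p_k^2)` over class proportions: 0 for a pure node, 0.5 at
#' maximum impurity in binary classification.
#'
#' @param class_counts non-negative integer vector of per-class counts
#' @return impurity in \[0, 1)
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) == 0)
    stop("class_counts must be non-negative and not all zero")
  p <- class_counts / sum(class_counts)
  1 - sum(p^2)
}

#' Tree-growing control parameters
#'
#' Defaults follow the rpart vocabulary: a node must hold at least `minsplit`
#' observations before a split is attempted; each child must hold at least
#' `minbucket`; a split is kept only if it improves the resubstitution
#' misclassification risk by at least `cp` times the root risk (cost-
#' complexity gate); cross-validation uses `folds` stratified folds.
#'
#' @param minsplit minimum node size to attempt a split (default 20)
#' @param minbucket minimum child size (default 7)
#' @param cp complexity parameter in \[0, 1\] (default 0.01)
#' @param folds number of CV folds (default 10)
#' @param seed RNG seed for fold assignment
#' @return a `keen_fit_params` list
#' @export
fit_params <- function(minsplit = 20L, minbucket = 7L, cp = 0.01,
                       folds = 10L, seed = 1L) {
  stopifnot(minbucket >= 1, minsplit >= 2, cp >= 0, cp <= 1, folds >= 2)
  structure(list(minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket),
                 cp = cp, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "keen_fit_params")
}

# classes are handled as a factor with levels c("no_neglect", "neglect");
# ties at a leaf resolve to the first level (no_neglect), favouring specificity.
CLASS_LEVELS <- c("no_neglect", "neglect")

as_label_factor <- function(y) {
  y <- as.character(y)
  if (!all(y %in% CLASS_LEVELS))
    stop("labels must be in {", paste(CLASS_LEVELS, collapse = ", "), "}")
  factor(y, levels = CLASS_LEVELS)
}

node_majority <- function(counts) {
  # counts ordered as CLASS_LEVELS; tie -> no_neglect (index 1)
  CLASS_LEVELS[which.max(counts)]
}

node_risk <- function(counts) sum(counts) - max(counts)

# Best split of one node: enumerate features and midpoints of consecutive
# sorted unique values; maximize Gini impurity decrease, ties broken by
# (lower feature name, lower threshold).
best_split <- function(x, y, minbucket) {
  n <- nrow(x)
  parent_counts <- tabulate(y, nbins = 2L)
  parent_gini <- gini_impurity(parent_counts)
  best <- NULL
  for (feat in sort(names(x))) {
    v <- x[[feat]]
    uq <- sort(unique(v))
    if (length(uq) < 2L) next
    thresholds <- (uq[-length(uq)] + uq[-1]) / 2
    for (thr in thresholds) {
      left <- v < thr
      nl <- sum(left); nr <- n - nl
      if (nl < minbucket || nr < minbucket) next
      cl <- tabulate(y[left], nbins = 2L)
      cr <- tabulate(y[!left], nbins = 2L)
      decrease <- parent_gini -
        (nl / n) * gini_impurity(cl) - (nr / n) * gini_impurity(cr)
      if (is.null(best) || decrease > best$decrease + 1e-12) {
        best <- list(feature = feat, threshold = thr, decrease = decrease,
                     left_counts = cl, right_counts = cr, left_mask = left)
      }
    }
  }
  best
}

grow_node <- function(x, y, params, root_risk) {
  counts <- tabulate(y, nbins = 2L)
  leaf <- list(type = "leaf",
               class = node_majority(counts),
               counts = counts,
               prop = counts / sum(counts))
  if (sum(counts) < params$minsplit || min(counts) == 0L) return(leaf)
  sp <- best_split(x, y, params$minbucket)
  if (is.null(sp)) return(leaf)
  improvement <- node_risk(counts) -
    (node_risk(sp$left_counts) + node_risk(sp$right_counts))
  if (improvement < params$cp * root_risk - 1e-12) return(leaf)
  list(type = "split",
       feature = sp$feature, threshold = sp$threshold,
       counts = counts,
       left = grow_node(x[sp$left_mask, , drop = FALSE], y[sp$left_mask],
                        params, root_risk),
       right = grow_node(x[!sp$left_mask, , drop = FALSE], y[!sp$left_mask],
                         params, root_risk))
}

#' Fit a binary classification tree (Gini splits, cost-complexity gate)
#'
#' Greedy binary recursive partitioning for the two-class neglect /
#' no-neglect problem. At each node every (feature, midpoint-threshold)
#' candidate is scored by Gini impurity decrease; the best split is accepted
#' only if the node holds at least `minsplit` samples, both children at least
#' `minbucket`, and the split reduces the resubstitution misclassification
#' risk by at least `cp` times the root risk. Leaf class is the majority,
#' ties resolving to `no_neglect`. Ties in impurity decrease break
#' deterministically toward the alphabetically lower feature name and lower
#' threshold.
#'
#' @param data data.frame of numeric feature columns (no missing values)
#' @param labels vector of "neglect"/"no_neglect", length `nrow(data)`
#' @param params a [fit_params()] list
#' @return a `keen_cart` model (nested node records; `root_risk` holds the
#'   misclassification count at the root)
#' @examples
#' d <- data.frame(LSB = c(rep(2, 15), rep(25, 15)))
#' lab <- rep(c("no_neglect", "neglect"), each = 15)
#' fit_cart(d, lab, fit_params(minsplit = 10, minbucket = 5))
#' @export
fit_cart <- function(data, labels, params = fit_params()) {
  stopifnot(is.data.frame(data), nrow(data) >= 2L)
  if (anyNA(data)) stop("missing values in features are not supported")
  if (anyDuplicated(names(data))) stop("feature names must be unique")
  y <- as_label_factor(labels)
  if (length(y) != nrow(data)) stop("labels length must match nrow(data)")
  counts <- tabulate(y, nbins = 2L)
  if (min(counts) == 0L)
    warning("single-class data: returning a single-leaf tree")
  root_risk <- node_risk(counts)
  root <- grow_node(data, y, params, max(root_risk, 1L))
  structure(list(root = root, root_risk = root_risk,
                 features = names(data), params = params),
            class = "keen_cart")
}

#' Predict with a fitted tree
#'
#' Deterministic root-to-leaf routing: at each split, a feature value below
#' the threshold goes left.
#'
#' @param object a `keen_cart` model
#' @param newdata data.frame with every feature the tree uses
#' @param ... unused
#' @return character vector of "neglect"/"no_neglect"
#' @export
predict.keen_cart <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  route <- function(node, row) {
    while (node$type == "split") {
      val <- row[[node$feature]]
      if (is.null(val) || is.na(val))
        stop("missing feature for prediction: ", node$feature)
      node <- if (val < node$threshold) node$left else node$right
    }
    node$class
  }
  vapply(seq_len(nrow(newdata)), function(i)
    route(object$root, newdata[i, , drop = FALSE]), character(1))
}

tree_nodes <- function(node) {
  if (node$type == "leaf") return(1L)
  1L + tree_nodes(node$left) + tree_nodes(node$right)
}

#' Number of nodes in a fitted tree
#' @param model a `keen_cart`
#' @return integer node count (leaves + internal)
#' @export
tree_size <- function(model) tree_nodes(model$root)

#' @export
print.keen_cart <- function(x, ...) {
  rec <- function(node, depth) {
    pad <- strrep("  ", depth)
    if (node$type == "leaf") {
      cat(sprintf("%s* %s (%d/%d)\n", pad, node$class,
                  node$counts[1], node$counts[2]))
    } else {
      cat(sprintf("%s%s < %g ?\n", pad, node$feature, node$threshold))
      rec(node$left, depth + 1L)
      rec(node$right, depth + 1L)
    }
  }
  cat("<keen_cart>\n"); rec(x$root, 0L)
  invisible(x)
}

#' Serialize a fitted tree to JSON
#' @param model a `keen_cart`
#' @param path output path
#' @export
write_cart_json <- function(model, path) {
  jsonlite::write_json(list(root = model$root, root_risk = model$root_risk,
                            features = model$features,
                            params = unclass(model$params)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Stratified k-fold cross-validation of the tree classifier
#'
#' Partitions the data into `params$folds` class-stratified folds using the
#' seeded RNG, fits on the remaining folds and evaluates on each held-out
#' fold. Metrics are reported per fold and pooled over all held-out
#' predictions. If a fold loses a class entirely a warning is raised and the
#' fold is flagged.
#'
#' @param data data.frame of numeric features
#' @param labels "neglect"/"no_neglect" vector
#' @param params a [fit_params()] (folds + seed control the partition)
#' @return list with `pooled` (a `keen_confusion`), `pooled_metrics`,
#'   `fold_metrics` (data.frame), `fold_assignment` (integer vector), and
#'   `resubstitution_metrics` (metrics of the tree fitted on all data,
#'   evaluated on the same data — reported alongside the cross-validated
#'   metrics, clearly labelled, since published single-value model metrics
#'   may be of either kind)
#' @export
cross_validate <- function(data, labels, params = fit_params()) {
  y <- as_label_factor(labels)
  n <- length(y)
  if (n < params$folds) stop("need at least as many samples as folds")
  fold <- integer(n)
  with_seed(params$seed, {
    for (cl in CLASS_LEVELS) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(params$folds), length(idx))
    }
  })
  truth_all <- character(0); pred_all <- character(0)
  fold_rows <- list()
  for (f in seq_len(params$folds)) {
    test <- fold == f
    if (length(unique(y[!test])) < 2L) {
      warning("fold ", f, " leaves single-class training data; flagged")
      fold_rows[[f]] <- data.frame(fold = f, n = sum(test),
                                   accuracy = NA_real_, flagged = TRUE)
      next
    }
    model <- fit_cart(data[!test, , drop = FALSE], y[!test], params)
    pred <- predict(model, data[test, , drop = FALSE])
    truth_all <- c(truth_all, as.character(y[test]))
    pred_all <- c(pred_all, pred)
    fold_rows[[f]] <- data.frame(
      fold = f, n = sum(test),
      accuracy = mean(pred == as.character(y[test])),
      flagged = !all(CLASS_LEVELS %in% y[test]))
  }
  pooled <- confusion_matrix(truth_all, pred_all)
  full <- fit_cart(data, y, params)
  resub <- confusion_matrix(as.character(y), predict(full, data))
  list(pooled = pooled,
       pooled_metrics = confusion_metrics(pooled),
       fold_metrics = do.call(rbind, fold_rows),
       fold_assignment = fold,
       model = full,
       resubstitution_metrics = confusion_metrics(resub))
}
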