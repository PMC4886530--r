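# Day-7 wine-quality prediction: Gini decision stumps over genus abundances
# and a shallow tree restricted to Lactobacillus / Thermoactinomyces.

gini <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

majority_label <- function(labels, classes = c("good", "poor")) {
  n_good <- sum(labels == classes[1])
  n_poor <- sum(labels == classes[2])
  # ties err toward flagging spoilage
  if (n_good > n_poor) classes[1] else classes[2]
}

#' Fit a single-feature decision stump
#'
#' Candidate thresholds are the midpoints between adjacent distinct sorted
#' feature values; the split minimising weighted Gini impurity is chosen,
#' ties going to the smaller threshold. Values less than or equal to the
#' threshold descend left. Leaves take the majority class, with ties
#' labelled `"poor"` (conservative: prediction errs toward flagging
#' spoilage). A stump whose best split does not reduce impurity is flagged
#' uninformative.
#'
#' @param data Tibble of day-7 samples: one column per genus plus the label
#'   column.
#' @param feature Genus column to split on.
#' @param label_col Name of the class-label column (default `"quality"`),
#'   with values in `classes`.
#' @param classes Class labels, `c(good, poor)`.
#' @return A `decision_stump` object.
#' @export
fit_decision_stump <- function(data, feature, label_col = "quality",
                               classes = c("good", "poor")) {
  if (!feature %in% names(data)) {
    abort(sprintf("feature `%s` not found", feature))
  }
  x <- data[[feature]]
  y <- data[[label_col]]
  if (length(unique(y)) < 2L) {
    abort("both classes must be present to fit a stump")
  }
  parent <- gini(y)
  v <- sort(unique(x))
  out <- list(feature = feature, threshold = NA_real_,
              left = majority_label(y, classes),
              right = majority_label(y, classes),
              impurity = parent, parent_impurity = parent, gain = 0,
              n = length(y), uninformative = TRUE, classes = classes)
  if (length(v) >= 2L) {
    cand <- (v[-length(v)] + v[-1]) / 2
    imp <- vapply(cand, function(t) {
      l <- y[x <= t]
      r <- y[x > t]
      (length(l) * gini(l) + length(r) * gini(r)) / length(y)
    }, numeric(1))
    best <- which.min(imp)  # ties -> smaller threshold (first in sorted order)
    t <- cand[best]
    out$threshold <- t
    out$left <- majority_label(y[x <= t], classes)
    out$right <- majority_label(y[x > t], classes)
    out$impurity <- imp[best]
    out$gain <- parent - imp[best]
    out$uninformative <- out$gain <= 1e-12
  }
  structure(out, class = "decision_stump")
}

#' @export
print.decision_stump <- function(x, ...) {
  cat(sprintf("Decision stump on %s: <= %.4f -> %s | > %.4f -> %s\n",
              x$feature, x$threshold, x$left, x$threshold, x$right))
  cat(sprintf("  weighted Gini %.4f (parent %.4f, gain %.4f)%s\n",
              x$impurity, x$parent_impurity, x$gain,
              if (x$uninformative) " [uninformative]" else ""))
  invisible(x)
}

#' @method tidy decision_stump
#' @export
tidy.decision_stump <- function(x, ...) {
  tibble(feature = x$feature, threshold = x$threshold,
         left_label = x$left, right_label = x$right,
         impurity = x$impurity, gain = x$gain,
         uninformative = x$uninformative)
}

#' Fit a shallow quality decision tree
#'
#' Recursive stump fitting restricted to the given feature list (by default
#' the two genera whose day-7 abundances separate good from failed
#' fermentations: Lactobacillus and Thermoactinomyces). At each node the
#' feature with the best impurity gain is chosen; impure nodes are split
#' until `max_depth` or until no split helps.
#'
#' @inheritParams fit_decision_stump
#' @param features Candidate genus columns (default Lactobacillus and
#'   Thermoactinomyces).
#' @param max_depth Maximum number of split levels (default 2).
#' @return A `quality_tree` object.
#' @export
fit_quality_tree <- function(data,
                             features = c("Lactobacillus",
                                          "Thermoactinomyces"),
                             max_depth = 2, label_col = "quality",
                             classes = c("good", "poor")) {
  missing <- setdiff(features, names(data))
  if (length(missing) > 0L) {
    abort(paste0("feature(s) not found: ", paste(missing, collapse = ", ")))
  }
  y <- data[[label_col]]
  if (length(unique(y)) < 2L) abort("both classes must be present")

  grow <- function(rows, depth) {
    y <- rows[[label_col]]
    if (length(unique(y)) == 1L || depth >= max_depth) {
      return(list(type = "leaf", label = majority_label(y, classes),
                  n = length(y)))
    }
    stumps <- lapply(features, function(f) {
      fit_decision_stump(rows, f, label_col = label_col, classes = classes)
    })
    gains <- vapply(stumps, `[[`, numeric(1), "gain")
    best <- stumps[[which.max(gains)]]
    if (best$uninformative || is.na(best$threshold)) {
      return(list(type = "leaf", label = majority_label(y, classes),
                  n = length(y)))
    }
    left_rows <- rows[rows[[best$feature]] <= best$threshold, , drop = FALSE]
    right_rows <- rows[rows[[best$feature]] > best$threshold, , drop = FALSE]
    list(type = "split", feature = best$feature, threshold = best$threshold,
         gain = best$gain, n = nrow(rows),
         left = grow(left_rows, depth + 1L),
         right = grow(right_rows, depth + 1L))
  }
  root <- grow(data, 0L)
  model <- structure(
    list(root = root, features = features, max_depth = max_depth,
         classes = classes, n = nrow(data), label_col = label_col),
    class = "quality_tree"
  )
  model$training_accuracy <- mean(predict_quality(model, data) == y)
  model
}

#' Predict wine quality from genus abundances
#'
#' Descends the fitted rules: a feature value less than or equal to the node
#' threshold goes left (so the printed day-7 rule "Lactobacillus <=
#' threshold implies good" is boundary-inclusive on the good side).
#'
#' @param model A `quality_tree` or `decision_stump`.
#' @param newdata Tibble of samples with the model's feature columns.
#' @return Character vector of class labels.
#' @export
predict_quality <- function(model, newdata) {
  if (inherits(model, "decision_stump")) {
    if (!model$feature %in% names(newdata)) {
      abort(sprintf("feature `%s` missing from newdata", model$feature))
    }
    x <- newdata[[model$feature]]
    return(ifelse(x <= model$threshold, model$left, model$right))
  }
  stopifnot(inherits(model, "quality_tree"))
  walk <- function(node, row) {
    if (node$type == "leaf") return(node$label)
    if (!node$feature %in% names(row)) {
      abort(sprintf("feature `%s` missing from newdata", node$feature))
    }
    if (row[[node$feature]] <= node$threshold) walk(node$left, row)
    else walk(node$right, row)
  }
  vapply(seq_len(nrow(newdata)), function(i) walk(model$root, newdata[i, ]),
         character(1))
}

#' @export
predict.quality_tree <- function(object, newdata, ...) {
  predict_quality(object, newdata)
}

tree_rules <- function(node, depth = 0L, path = "root") {
  if (node$type == "leaf") {
    leaf_label <- node$label
    leaf_n <- node$n
    return(tibble(node = path, depth = depth, feature = NA_character_,
                  threshold = NA_real_, label = leaf_label, n = leaf_n))
  }
  feat <- node$feature
  thr <- node$threshold
  n_node <- node$n
  bind_rows(
    tibble(node = path, depth = depth, feature = feat,
           threshold = thr, label = NA_character_, n = n_node),
    tree_rules(node$left, depth + 1L, paste0(path, "/L")),
    tree_rules(node$right, depth + 1L, paste0(path, "/R"))
  )
}

#' @method tidy quality_tree
#' @export
tidy.quality_tree <- function(x, ...) tree_rules(x$root)

#' @method glance quality_tree
#' @export
glance.quality_tree <- function(x, ...) {
  rules <- tree_rules(x$root)
  tibble(
    n = x$n,
    depth = max(rules$depth),  # leaf level: a single stump has depth 1
    n_splits = sum(is.na(rules$label)),
    n_leaves = sum(!is.na(rules$label)),
    training_accuracy = x$training_accuracy
  )
}

#' @export
print.quality_tree <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s-> %s (n = %d)\n", pad, node$label, node$n))
    } else {
      cat(sprintf("%s%s <= %.4f?\n", pad, node$feature, node$threshold))
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  cat(sprintf("Quality tree (%d samples, training accuracy %.2f)\n",
              x$n, x$training_accuracy))
  show(x$root, 0L)
  invisible(x)
}

#' Serialise a quality tree to JSON
#'
#' @param model A `quality_tree`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_quality_tree <- function(model, path) {
  stopifnot(inherits(model, "quality_tree"))
  jsonlite::write_json(
    list(features = model$features, max_depth = model$max_depth,
         classes = model$classes, n = model$n, root = model$root),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a quality tree serialised by [write_quality_tree()]
#'
#' @param path JSON file path.
#' @return A `quality_tree`.
#' @export
read_quality_tree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  structure(
    list(root = x$root, features = unlist(x$features),
         max_depth = x$max_depth, classes = unlist(x$classes), n = x$n,
         label_col = "quality", training_accuracy = NA_real_),
    class = "quality_tree"
  )
}
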