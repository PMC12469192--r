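NO_FINDING <- c("", "none", "na")

#' Label in vivo treatments for necrosis classification
#'
#' A treatment (non-control group) is necrosis-positive when at least one
#' member sample has a finding matching `pattern` (case-insensitive
#' substring, default "necrosis"), necrosis-negative when every member
#' sample has no pathological finding, and excluded otherwise (only
#' non-necrosis findings), since neither class definition applies.
#'
#' @param pathology data.frame with `sample_id`, `finding`.
#' @param meta Sample metadata (in vivo).
#' @param pattern Regular expression matched against findings.
#' @param include_controls Whether control groups are labeled too (default
#'   `FALSE`; only treated groups are classified).
#' @return data.frame: `key`, `label` (`"positive"`/`"negative"`), one row
#'   per qualifying treatment.
#' @export
label_treatments <- function(pathology, meta, pattern = "necrosis",
                             include_controls = FALSE) {
  unknown <- setdiff(pathology$sample_id, meta$sample_id)
  if (length(unknown))
    stop("pathology references unknown samples: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  finding <- setNames(tolower(pathology$finding), pathology$sample_id)
  groups <- group_treatments(meta)
  if (!include_controls) groups <- groups[groups$dose != "control", , drop = FALSE]
  keys <- character(0); labels <- character(0)
  for (i in seq_len(nrow(groups))) {
    f <- finding[groups$sample_ids[[i]]]
    f[is.na(f)] <- "none"
    has_necrosis <- any(grepl(pattern, f, ignore.case = TRUE))
    all_clean <- all(f %in% NO_FINDING)
    if (has_necrosis) {
      keys <- c(keys, groups$key[i]); labels <- c(labels, "positive")
    } else if (all_clean) {
      keys <- c(keys, groups$key[i]); labels <- c(labels, "negative")
    } # only non-necrosis findings: excluded
  }
  data.frame(key = keys, label = labels, stringsAsFactors = FALSE)
}

#' Balance a labeled treatment set 1:1
#'
#' Keeps all positives and a seeded random subset of negatives of equal
#' size (76 positives and 990 negatives give 152 treatments). When
#' negatives are fewer than positives, all treatments are kept with a
#' warning.
#'
#' @param labels data.frame from [label_treatments()].
#' @param seed Seed for the negative subsample.
#' @return Balanced labels data.frame.
#' @export
balance_labels <- function(labels, seed = 1) {
  pos <- labels[labels$label == "positive", , drop = FALSE]
  neg <- labels[labels$label == "negative", , drop = FALSE]
  if (nrow(neg) < nrow(pos)) {
    warning("fewer negatives than positives; keeping all treatments")
    return(labels)
  }
  keep <- with_seed(seed, sample(nrow(neg), nrow(pos)))
  out <- rbind(pos, neg[sort(keep), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Replicate-averaged treatment feature matrix
#'
#' One feature row per treatment: gene expression averaged across the
#' group's biological replicates.
#'
#' @param dataset List with `expr` (genes x samples), `meta`.
#' @param keys Treatment keys to assemble (rows).
#' @param expr_override Optional replacement expression matrix (e.g.
#'   synthetic profiles aligned to the real sample ids).
#' @return Matrix treatments x genes.
#' @export
treatment_features <- function(dataset, keys, expr_override = NULL) {
  expr <- expr_override %||% dataset$expr
  groups <- group_treatments(dataset$meta)
  rownames(groups) <- groups$key
  miss <- setdiff(keys, groups$key)
  if (length(miss)) stop("unknown treatment keys: ", paste(utils::head(miss, 3),
                                                           collapse = ", "))
  out <- matrix(NA_real_, length(keys), nrow(expr),
                dimnames = list(keys, rownames(expr)))
  for (k in keys)
    out[k, ] <- rowMeans(expr[, groups[k, "sample_ids"][[1]], drop = FALSE])
  out
}

#' Train the gradient-boosted necrosis classifier
#'
#' Binary gradient-boosted decision trees (100 rounds, learning rate 0.1,
#' maximum depth 10 by default) on replicate-averaged treatment features.
#'
#' @param features Matrix treatments x genes.
#' @param labels Character vector (`"positive"`/`"negative"`) aligned to
#'   rows.
#' @param n_estimators,learning_rate,max_depth Booster parameters.
#' @param seed Seed.
#' @return A `necrosis_model`: the fitted booster plus echoed parameters.
#' @export
train_classifier <- function(features, labels, n_estimators = 100,
                             learning_rate = 0.1, max_depth = 10, seed = 1) {
  stopifnot(nrow(features) == length(labels))
  y <- factor(labels, levels = c("negative", "positive"))
  if (length(unique(y)) < 2) stop("training set has a single class")
  booster <- with_seed(seed, xgboost::xgboost(
    x = features, y = y, objective = "binary:logistic",
    nrounds = n_estimators, learning_rate = learning_rate,
    max_depth = max_depth, nthreads = 1, seed = seed, verbosity = 0))
  structure(list(booster = booster,
                 params = list(n_estimators = n_estimators,
                               learning_rate = learning_rate,
                               max_depth = max_depth),
                 seed = seed),
            class = "necrosis_model")
}

#' Evaluate the necrosis classifier
#'
#' Predictions above 0.5 are called positive. Returns the confusion matrix
#' and the accuracy as a percentage, `(TP + TN) / total * 100`.
#'
#' @param model A `necrosis_model`.
#' @param features Matrix treatments x genes (test).
#' @param labels Character vector of true labels.
#' @return List with `confusion` (`TP`, `TN`, `FP`, `FN`), `accuracy`
#'   (percent), `predictions`.
#' @export
evaluate_classifier <- function(model, features, labels) {
  if (!nrow(features)) stop("empty test set")
  stopifnot(nrow(features) == length(labels))
  p <- predict(model$booster, features)
  pred <- ifelse(p > 0.5, "positive", "negative")
  cm <- confusion_counts(truth = labels, predicted = pred)
  list(confusion = cm, accuracy = confusion_accuracy(cm), predictions = p)
}

#' Confusion-matrix helpers
#'
#' `confusion_counts` tabulates TP/TN/FP/FN from label vectors;
#' `confusion_accuracy` turns a confusion list into percent accuracy
#' (the printed convention: 61.15 means 61.15%).
#'
#' @param truth,predicted Character vectors of `"positive"`/`"negative"`.
#' @return `confusion_counts`: list `TP, TN, FP, FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  list(TP = sum(truth == "positive" & predicted == "positive"),
       TN = sum(truth == "negative" & predicted == "negative"),
       FP = sum(truth == "negative" & predicted == "positive"),
       FN = sum(truth == "positive" & predicted == "negative"))
}

#' @rdname confusion_counts
#' @param cm List with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_accuracy <- function(cm) {
  tot <- cm$TP + cm$TN + cm$FP + cm$FN
  if (tot == 0) stop("empty confusion matrix")
  (cm$TP + cm$TN) / tot * 100
}
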