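#' Profile similarity metrics
#'
#' `metric_cosine` is the inner product over the product of norms;
#' `metric_rmse` the root mean squared difference; `metric_mape` the mean
#' absolute relative error of `synthetic` against `real`, reported as a
#' fraction (0.04 means 4%). Coordinates where `|real| < eps` are dropped
#' from MAPE.
#'
#' @param a,b Equal-length finite numeric vectors.
#' @param real,synthetic Reference and estimate vectors for MAPE.
#' @param eps Denominator guard for MAPE.
#' @return A single number.
#' @export
metric_cosine <- function(a, b) {
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine undefined for zero-norm vectors")
  sum(a * b) / (na * nb)
}

#' @rdname metric_cosine
#' @export
metric_rmse <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2))
}

#' @rdname metric_cosine
#' @export
metric_mape <- function(real, synthetic, eps = 1e-8) {
  stopifnot(length(real) == length(synthetic))
  keep <- abs(real) >= eps
  if (!any(keep)) stop("MAPE undefined: all reference values below eps")
  mean(abs((real[keep] - synthetic[keep]) / real[keep]))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both groups have zero variance and equal
#' means the statistic is defined as 0 with p = 1.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Build the three comparison groups for model evaluation
#'
#' The model group pairs each synthetic profile with its matched real in
#' vivo target. The replicate control enumerates all within-treatment pairs
#' of real profiles (biological replicates). The baseline control is a
#' seeded random subsample of cross-treatment real pairs, with replicate
#' pairs excluded by construction.
#'
#' @param real_vivo List with `expr` (genes x samples) and `meta`.
#' @param synthetic Matrix of synthetic profiles (pairs x genes).
#' @param target_sample Character vector: the real in vivo sample matched
#'   to each synthetic row.
#' @param n_baseline Maximum number of baseline pairs to sample.
#' @param seed Seed for the baseline subsample.
#' @return List of three data.frames (`model`, `baseline`, `replicate`)
#'   of sample-id pairs; synthetic rows are referenced by index.
#' @export
build_comparison_groups <- function(real_vivo, synthetic, target_sample,
                                    n_baseline = 10000, seed = 1) {
  meta <- real_vivo$meta
  stopifnot(nrow(synthetic) == length(target_sample),
            all(target_sample %in% meta$sample_id))
  key <- setNames(treatment_key(meta$compound, meta$system, meta$dose,
                                meta$time_h), meta$sample_id)

  model <- data.frame(synthetic_row = seq_len(nrow(synthetic)),
                      real_sample = target_sample, stringsAsFactors = FALSE)

  ids <- meta$sample_id
  by_treat <- split(ids, key[ids])
  rep_a <- character(0); rep_b <- character(0)
  for (g in by_treat) {
    if (length(g) < 2) next
    cmb <- utils::combn(g, 2)
    rep_a <- c(rep_a, cmb[1, ]); rep_b <- c(rep_b, cmb[2, ])
  }
  if (!length(rep_a)) warning("no treatment has >= 2 replicates; replicate control empty")
  replicate <- data.frame(sample_a = rep_a, sample_b = rep_b,
                          stringsAsFactors = FALSE)

  baseline <- with_seed(seed, {
    n <- length(ids)
    want <- min(n_baseline, n * (n - 1) / 2)
    a <- character(0); b <- character(0)
    guard <- 0
    while (length(a) < want && guard < 60) {
      m <- ceiling((want - length(a)) * 1.5)
      i <- sample(n, m, replace = TRUE)
      j <- sample(n, m, replace = TRUE)
      ok <- i < j & key[ids[i]] != key[ids[j]]
      a <- c(a, ids[i[ok]]); b <- c(b, ids[j[ok]])
      dup <- duplicated(paste(a, b))
      a <- a[!dup]; b <- b[!dup]
      guard <- guard + 1
    }
    keep <- seq_len(min(length(a), want))
    data.frame(sample_a = a[keep], sample_b = b[keep], stringsAsFactors = FALSE)
  })
  list(model = model, baseline = baseline, replicate = replicate)
}

#' Compute the similarity report over the three comparison groups
#'
#' Computes cosine, RMSE and MAPE per pair in each group (on unscaled log2
#' profiles) and Welch's t-test contrasting the model group against each
#' control, per metric.
#'
#' @param groups Output of [build_comparison_groups()].
#' @param real_vivo List with `expr`, `meta`.
#' @param synthetic Matrix pairs x genes matching `groups$model`.
#' @return A `comparison_report`: list with `per_pair` (long data.frame:
#'   group, metric columns), `means`, and `tests`.
#' @export
similarity_report <- function(groups, real_vivo, synthetic) {
  expr <- real_vivo$expr
  metrics_for <- function(A, B) {
    data.frame(
      cosine = vapply(seq_len(nrow(A)), function(i) metric_cosine(A[i, ], B[i, ]), 0),
      rmse = vapply(seq_len(nrow(A)), function(i) metric_rmse(A[i, ], B[i, ]), 0),
      mape = vapply(seq_len(nrow(A)), function(i) metric_mape(A[i, ], B[i, ]), 0))
  }
  per <- list()
  if (nrow(groups$model)) {
    A <- t(expr[, groups$model$real_sample, drop = FALSE])
    per$model <- metrics_for(A, synthetic[groups$model$synthetic_row, , drop = FALSE])
  }
  for (g in c("baseline", "replicate")) {
    df <- groups[[g]]
    if (!nrow(df)) { per[[g]] <- NULL; next }
    per[[g]] <- metrics_for(t(expr[, df$sample_a, drop = FALSE]),
                            t(expr[, df$sample_b, drop = FALSE]))
  }
  long <- do.call(rbind, lapply(names(per), function(g)
    cbind(group = g, per[[g]], stringsAsFactors = FALSE)))
  means <- stats::aggregate(long[c("cosine", "rmse", "mape")],
                            by = list(group = long$group), FUN = mean)
  tests <- list()
  for (ctrl in intersect(c("baseline", "replicate"), names(per))) {
    for (m in c("cosine", "rmse", "mape")) {
      tests[[paste(ctrl, m, sep = ".")]] <-
        welch_t(per$model[[m]], per[[ctrl]][[m]])
    }
  }
  structure(list(per_pair = long, means = means, tests = tests,
                 sizes = vapply(per, nrow, integer(1))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n")
  print(x$means, row.names = FALSE)
  invisible(x)
}
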