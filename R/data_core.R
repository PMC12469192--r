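#' Group samples into treatment groups
#'
#' A treatment group is the set of replicate samples sharing
#' `(compound, system, dose, time_h)`; controls form their own groups.
#'
#' @param meta Validated metadata data.frame.
#' @return data.frame with one row per group: `compound, system, dose,
#'   time_h, key, n`, plus a list-column `sample_ids`.
#' @export
group_treatments <- function(meta) {
  if (nrow(meta) == 0) {
    return(data.frame(compound = character(), system = character(),
                      dose = character(), time_h = numeric(),
                      key = character(), n = integer(),
                      sample_ids = I(list())))
  }
  key <- treatment_key(meta$compound, meta$system, meta$dose, meta$time_h)
  idx <- split(seq_len(nrow(meta)), key)
  first <- vapply(idx, `[`, integer(1), 1)
  out <- data.frame(compound = meta$compound[first],
                    system = meta$system[first],
                    dose = meta$dose[first],
                    time_h = meta$time_h[first],
                    key = names(idx),
                    n = lengths(idx),
                    stringsAsFactors = FALSE)
  out$sample_ids <- I(lapply(idx, function(i) meta$sample_id[i]))
  for (i in seq_along(idx)) {
    reps <- meta$replicate[idx[[i]]]
    if (anyDuplicated(reps)) stop("duplicate replicate index within group ", out$key[i])
  }
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Encode an experiment label as a 16-bit binary vector
#'
#' The 16 bits are four one-hot blocks: system (2 bits), dose including
#' control (4 bits), time slot (5 bits, indexing the per-system time
#' vocabulary) and replicate 1-5 (5 bits). The encoding is a bijection
#' between the configured vocabulary and its image.
#'
#' @param system `"in_vitro"` or `"in_vivo"`.
#' @param dose One of `control, low, middle, high`.
#' @param time_h Time in hours; must be in the system's time vocabulary.
#' @param replicate Integer 1-5.
#' @param time_vocab List with per-system time vocabularies (<= 5 entries
#'   each), see [default_time_vocab()].
#' @return Integer vector of 16 zeros/ones.
#' @export
encode_label <- function(system, dose, time_h, replicate,
                         time_vocab = default_time_vocab()) {
  s <- match(system, SYSTEMS)
  if (is.na(s)) stop("unknown system: ", system)
  d <- match(dose, DOSE_LEVELS)
  if (is.na(d)) stop("unknown dose: ", dose)
  vocab <- time_vocab[[system]]
  if (length(vocab) > 5) stop("time vocabulary larger than 5 slots")
  t <- match(time_h, vocab)
  if (is.na(t)) stop("time ", time_h, " h not in the ", system, " vocabulary")
  if (!replicate %in% 1:5) stop("replicate must be 1..5, got ", replicate)
  bits <- integer(16)
  bits[s] <- 1L
  bits[2 + d] <- 1L
  bits[6 + t] <- 1L
  bits[11 + replicate] <- 1L
  bits
}

#' @rdname encode_label
#' @param bits Length-16 binary vector produced by [encode_label()].
#' @return For `decode_label`, a list with `system, dose, time_h, replicate`.
#' @export
decode_label <- function(bits, time_vocab = default_time_vocab()) {
  stopifnot(length(bits) == 16, all(bits %in% c(0, 1)))
  blocks <- list(bits[1:2], bits[3:6], bits[7:11], bits[12:16])
  if (any(vapply(blocks, sum, numeric(1)) != 1))
    stop("each one-hot block must have exactly one set bit")
  system <- SYSTEMS[which(blocks[[1]] == 1)]
  dose <- DOSE_LEVELS[which(blocks[[2]] == 1)]
  tslot <- which(blocks[[3]] == 1)
  vocab <- time_vocab[[system]]
  if (tslot > length(vocab)) stop("time slot outside the ", system, " vocabulary")
  list(system = system, dose = dose, time_h = vocab[tslot],
       replicate = which(blocks[[4]] == 1))
}

encode_label_rows <- function(meta, time_vocab = default_time_vocab()) {
  out <- matrix(0L, nrow(meta), 16)
  for (i in seq_len(nrow(meta))) {
    out[i, ] <- encode_label(meta$system[i], meta$dose[i], meta$time_h[i],
                             meta$replicate[i], time_vocab)
  }
  out
}

#' Per-gene min-max scaler
#'
#' Fits per-gene minimum and maximum on training samples only. `scale_expr`
#' maps values through `(x - min) / (max - min)` and clips to `[0, 1]`, so
#' out-of-range test values saturate rather than leak outside the unit
#' interval; genes constant in training map to 0. `unscale_expr` inverts the
#' map on `[0, 1]`.
#'
#' @param train Expression matrix (genes x samples) of training samples.
#' @return `fit_scaler`: list with `min`, `max` (named per gene).
#' @export
fit_scaler <- function(train) {
  validate_expression(train)
  list(min = apply(train, 1, min), max = apply(train, 1, max))
}

#' @rdname fit_scaler
#' @param x Matrix genes x samples (or named vector) on the log2 scale.
#' @param params Scaler parameters from [fit_scaler()].
#' @export
scale_expr <- function(x, params) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  stopifnot(nrow(x) == length(params$min))
  rng <- params$max - params$min
  y <- (x - params$min) / ifelse(rng > 0, rng, 1)
  y[rng == 0, ] <- 0
  y <- clip01(y)
  if (vec) y[, 1] else y
}

#' @rdname fit_scaler
#' @param y Scaled matrix/vector in `[0, 1]`.
#' @export
unscale_expr <- function(y, params) {
  vec <- is.null(dim(y))
  if (vec) y <- matrix(y, ncol = 1, dimnames = list(names(y), NULL))
  stopifnot(nrow(y) == length(params$min))
  rng <- params$max - params$min
  x <- y * rng + params$min
  if (vec) x[, 1] else x
}

#' Split compounds into training and test sets
#'
#' Compound-level split: all samples of a compound land on one side, so no
#' compound leaks across the partition. The training size is round-half-up
#' of `train_fraction * n` (140 compounds at 0.8 give 112 train / 28 test).
#'
#' @param compounds Character vector of compound names (unique).
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Integer seed for the random assignment.
#' @return List with `train` and `test` character vectors.
#' @export
split_by_compound <- function(compounds, train_fraction = 0.8, seed = 1) {
  stopifnot(length(compounds) > 0)
  if (anyDuplicated(compounds)) stop("compound list must be unique")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- length(compounds)
  n_train <- floor(train_fraction * n + 0.5)
  train <- with_seed(seed, sample(compounds, n_train))
  list(train = sort(train), test = sort(setdiff(compounds, train)))
}

#' Build in vitro / in vivo paired examples
#'
#' Within each compound, every in vitro treatment sample is paired with every
#' in vivo treatment sample (dose and time may differ; the labels carry the
#' difference) and control samples pair only with control samples. Compounds
#' missing from either system are skipped with a warning.
#'
#' @param vitro,vivo Lists with elements `expr` (genes x samples matrix) and
#'   `meta` (metadata data.frame).
#' @param compounds Compounds to pair (e.g. one side of
#'   [split_by_compound()]).
#' @param time_vocab Per-system time vocabularies for label encoding.
#' @return A `pair_set`: list with row-aligned matrices `vitro`, `vivo`
#'   (pairs x genes, log2 scale), `source_label`, `target_label`
#'   (pairs x 16), and vectors `compound`, `vitro_sample`, `vivo_sample`.
#' @export
build_pairs <- function(vitro, vivo, compounds,
                        time_vocab = default_time_vocab()) {
  stopifnot(identical(rownames(vitro$expr), rownames(vivo$expr)))
  mva <- validate_meta(vitro$meta, vitro$expr)
  mvo <- validate_meta(vivo$meta, vivo$expr)
  i_idx <- integer(0); j_idx <- integer(0)
  for (cmp in compounds) {
    a <- which(mva$compound == cmp)
    b <- which(mvo$compound == cmp)
    if (!length(a) || !length(b)) {
      warning("compound ", cmp, " absent from one system; skipped")
      next
    }
    for (stratum in c("treatment", "control")) {
      ai <- a[(mva$dose[a] == "control") == (stratum == "control")]
      bi <- b[(mvo$dose[b] == "control") == (stratum == "control")]
      if (!length(ai) || !length(bi)) next
      grid <- expand.grid(i = ai, j = bi)
      i_idx <- c(i_idx, grid$i)
      j_idx <- c(j_idx, grid$j)
    }
  }
  src <- encode_label_rows(mva, time_vocab)[i_idx, , drop = FALSE]
  tgt <- encode_label_rows(mvo, time_vocab)[j_idx, , drop = FALSE]
  structure(list(
    vitro = t(vitro$expr)[mva$sample_id[i_idx], , drop = FALSE],
    vivo = t(vivo$expr)[mvo$sample_id[j_idx], , drop = FALSE],
    source_label = src,
    target_label = tgt,
    compound = mva$compound[i_idx],
    vitro_sample = mva$sample_id[i_idx],
    vivo_sample = mvo$sample_id[j_idx],
    genes = rownames(vitro$expr)
  ), class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat("pair_set:", nrow(x$vitro), "pairs,", length(x$genes), "genes,",
      length(unique(x$compound)), "compounds\n")
  invisible(x)
}

#' Number of pairs in a pair set
#' @param pairs A `pair_set`.
#' @return Integer pair count.
#' @export
n_pairs <- function(pairs) nrow(pairs$vitro)

#' Subset a pair set by row index
#' @param pairs A `pair_set`.
#' @param idx Integer or logical index over pairs.
#' @return A `pair_set` with the selected pairs.
#' @export
subset_pairs <- function(pairs, idx) {
  structure(list(
    vitro = pairs$vitro[idx, , drop = FALSE],
    vivo = pairs$vivo[idx, , drop = FALSE],
    source_label = pairs$source_label[idx, , drop = FALSE],
    target_label = pairs$target_label[idx, , drop = FALSE],
    compound = pairs$compound[idx],
    vitro_sample = pairs$vitro_sample[idx],
    vivo_sample = pairs$vivo_sample[idx],
    genes = pairs$genes
  ), class = "pair_set")
}

#' Scale the profiles of a pair set to the unit interval
#'
#' Applies the two fitted per-gene min-max scalers (in vitro space and in
#' vivo space) to the pair matrices, as the translator consumes and emits
#' values in `[0, 1]`.
#'
#' @param pairs A `pair_set` on the log2 scale.
#' @param scaler_vitro,scaler_vivo Scalers from [fit_scaler()].
#' @return A `pair_set` with scaled `vitro`/`vivo` matrices.
#' @export
scale_pairs <- function(pairs, scaler_vitro, scaler_vivo) {
  pairs$vitro <- t(scale_expr(t(pairs$vitro), scaler_vitro))
  pairs$vivo <- t(scale_expr(t(pairs$vivo), scaler_vivo))
  pairs
}
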