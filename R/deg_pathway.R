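#' Call differentially expressed genes against a time-matched control
#'
#' The fold change of a gene is the difference of replicate-averaged log2
#' expression between the treatment group and its control group (a log2
#' ratio, so a fold change of 1 is a 2-fold linear change). A gene is a DEG
#' iff `|fc| > threshold`, strictly.
#'
#' @param treatment Matrix genes x replicates of treated log2 profiles (or a
#'   single profile vector).
#' @param control Matrix genes x replicates of the time-matched control.
#' @param threshold Absolute log2 fold-change threshold (default 1).
#' @return A `DEG set`: data.frame with `gene`, `log2fc`, one row per DEG.
#' @export
call_degs <- function(treatment, control, threshold = 1) {
  if (is.null(dim(treatment))) treatment <- matrix(treatment, ncol = 1,
                                                   dimnames = list(names(treatment), NULL))
  if (is.null(dim(control))) control <- matrix(control, ncol = 1,
                                               dimnames = list(names(control), NULL))
  stopifnot(nrow(treatment) == nrow(control))
  fc <- rowMeans(treatment) - rowMeans(control)
  hit <- abs(fc) > threshold
  data.frame(gene = rownames(treatment)[hit], log2fc = unname(fc[hit]),
             stringsAsFactors = FALSE)
}

#' Call DEG sets for every treatment group of a dataset
#'
#' For each non-control treatment group, computes fold changes against the
#' time-matched control group of the same compound and system. Expression
#' may be overridden (e.g. synthetic profiles aligned to the real samples)
#' while keeping the real control profiles as reference.
#'
#' @param dataset List with `expr` (genes x samples) and `meta`.
#' @param threshold DEG threshold.
#' @param expr_override Optional matrix replacing the treatment profiles
#'   (same dimnames as `dataset$expr`); controls are always taken from
#'   `dataset$expr`.
#' @return Named list of DEG-set data.frames, keyed by [treatment_key()].
#' @export
call_degs_dataset <- function(dataset, threshold = 1, expr_override = NULL) {
  meta <- dataset$meta
  expr <- dataset$expr
  treat_expr <- expr_override %||% expr
  groups <- group_treatments(meta)
  ctrl <- groups[groups$dose == "control", , drop = FALSE]
  out <- list()
  for (i in which(groups$dose != "control")) {
    g <- groups[i, ]
    m <- ctrl[ctrl$compound == g$compound & ctrl$system == g$system &
                ctrl$time_h == g$time_h, , drop = FALSE]
    if (nrow(m) == 0)
      stop("no time-matched control for ", g$key)
    out[[g$key]] <- call_degs(
      treat_expr[, g$sample_ids[[1]], drop = FALSE],
      expr[, m$sample_ids[[1]], drop = FALSE], threshold)
  }
  out
}

#' Union of per-triplet synthetic DEG sets
#'
#' Synthetic profiles aimed at one in vivo treatment arise from several
#' source dose/time combinations; DEGs are called per generated triplet and
#' the treatment's final synthetic DEG set is their union. Each gene keeps
#' the fold change of largest magnitude among the sets containing it.
#'
#' @param deg_sets Non-empty list of DEG-set data.frames for one target
#'   treatment.
#' @return One DEG-set data.frame.
#' @export
union_synthetic_degs <- function(deg_sets) {
  if (!length(deg_sets)) stop("empty DEG set list")
  all <- do.call(rbind, deg_sets)
  if (!nrow(all)) return(all[0, , drop = FALSE])
  ord <- order(-abs(all$log2fc))
  all <- all[ord, , drop = FALSE]
  all <- all[!duplicated(all$gene), , drop = FALSE]
  rownames(all) <- NULL
  all[order(all$gene), , drop = FALSE]
}

#' Group synthetic profiles aimed at one target into triplets
#'
#' Chunks the rows (generation order) into groups of `size`; a shorter
#' remainder chunk is kept.
#'
#' @param n Number of synthetic profiles.
#' @param size Chunk size (default 3, mirroring typical in vivo replicate
#'   counts).
#' @return List of integer index vectors.
#' @export
triplet_chunks <- function(n, size = 3) {
  if (n == 0) return(list())
  split(seq_len(n), ceiling(seq_len(n) / size))
}

#' DEG overlap ratio between real and synthetic sets
#'
#' `|real intersect synthetic| / |real|`; treatments with no real DEGs are
#' excluded (returns `NA`).
#'
#' @param real,synthetic DEG-set data.frames (or character gene vectors).
#' @return Ratio in `[0, 1]`, or `NA` when the real set is empty.
#' @export
deg_overlap_ratio <- function(real, synthetic) {
  rg <- if (is.data.frame(real)) real$gene else real
  sg <- if (is.data.frame(synthetic)) synthetic$gene else synthetic
  if (!length(rg)) return(NA_real_)
  length(intersect(rg, sg)) / length(unique(rg))
}

#' Over-representation analysis of a DEG list over gene sets
#'
#' One-sided hypergeometric test per gene set (probability of at least the
#' observed overlap when drawing `|degs|` genes from the universe), with
#' Bonferroni correction over the tested sets and a significance call at
#' adjusted p <= 0.05. Gene sets are intersected with the universe first;
#' the universe is the analysis gene panel.
#'
#' @param degs Character vector of DEG identifiers (subset of `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all genes considered.
#' @param alpha Significance cutoff on the adjusted p-value.
#' @return data.frame: `set, overlap, size, p, p_adj, significant`.
#' @export
enrich <- function(degs, gene_sets, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  degs <- intersect(unique(degs), universe)
  N <- length(universe); n <- length(degs)
  res <- data.frame(set = names(gene_sets), overlap = NA_integer_,
                    size = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(gene_sets)) {
    gs <- intersect(gene_sets[[i]], universe)
    K <- length(gs)
    k <- length(intersect(gs, degs))
    res$overlap[i] <- k
    res$size[i] <- K
    res$p[i] <- if (K == 0 || n == 0) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  res$p_adj <- pmin(1, res$p * nrow(res))
  res$significant <- res$p_adj <= alpha
  res
}

#' Tie-aware top-k selection of enriched gene sets
#'
#' Sets are ranked by adjusted p-value, then by decreasing overlap count.
#' Every set tied with the k-th ranked set (on both keys) is retained, so
#' the kept list may exceed `k`; with fewer than `k` sets all are kept.
#'
#' @param real,synthetic Enrichment data.frames from [enrich()].
#' @param k Nominal list length.
#' @return List with `kept_real`, `kept_synthetic` (character vectors of
#'   set names) and their `intersection`.
#' @export
topk_overlap <- function(real, synthetic, k = 20) {
  top <- function(df) {
    if (nrow(df) <= k) return(df$set)
    ord <- order(df$p_adj, -df$overlap)
    df <- df[ord, , drop = FALSE]
    pk <- df$p_adj[k]; ok <- df$overlap[k]
    keep <- df$p_adj < pk | (df$p_adj == pk & df$overlap >= ok)
    df$set[keep]
  }
  kr <- top(real); ks <- top(synthetic)
  list(kept_real = kr, kept_synthetic = ks,
       intersection = intersect(kr, ks))
}

#' Percent error of synthetic expression for a gene panel subset
#'
#' For each (gene, compound) cell: `(real - synthetic) / real * 100`,
#' computed on replicate-averaged profiles of the high-dose, 24-h treatment
#' groups. Cells with `|real| < eps` are masked and excluded from summary
#' fractions.
#'
#' @param real,synthetic Matrices genes x compounds of replicate-averaged
#'   log2 expression (aligned dimnames).
#' @param eps Denominator guard.
#' @return An `aop_error` list: `error` (genes x compounds, `NA` where
#'   masked) and `mask` (logical, `TRUE` where masked).
#' @export
aop_percent_error <- function(real, synthetic, eps = 1e-8) {
  stopifnot(identical(dim(real), dim(synthetic)))
  mask <- abs(real) < eps
  err <- (real - synthetic) / real * 100
  err[mask] <- NA_real_
  structure(list(error = err, mask = mask), class = "aop_error")
}

#' @rdname aop_percent_error
#' @param x An `aop_error`.
#' @param cutoff Percent-error cutoff (default 5). The comparison allows a
#'   1e-9 numeric slack so errors sitting exactly on the cutoff (e.g. 8 vs
#'   7.6 giving 5%) count as within despite floating-point rounding.
#' @return Fraction of defined cells with `|error| <= cutoff`.
#' @export
fraction_within <- function(x, cutoff = 5) {
  vals <- x$error[!x$mask]
  if (!length(vals)) stop("no defined cells")
  mean(abs(vals) <= cutoff + 1e-9)
}

#' Replicate-averaged expression of selected genes per compound
#'
#' Helper assembling the genes x compounds input of
#' [aop_percent_error()]: averages replicates of each compound's group at
#' the requested dose and time.
#'
#' @param dataset List with `expr`, `meta`.
#' @param genes Genes (rows) to keep.
#' @param dose,time_h Treatment stratum (defaults: high dose, 24 h).
#' @param expr_override Optional replacement expression matrix.
#' @return Matrix genes x compounds.
#' @export
treatment_mean_matrix <- function(dataset, genes, dose = "high", time_h = 24,
                                  expr_override = NULL) {
  meta <- dataset$meta
  expr <- expr_override %||% dataset$expr
  stopifnot(all(genes %in% rownames(expr)))
  sel <- meta[meta$dose == dose & meta$time_h == time_h, , drop = FALSE]
  if (!nrow(sel)) stop("no samples at dose=", dose, ", time=", time_h)
  cmps <- sort(unique(sel$compound))
  out <- matrix(NA_real_, length(genes), length(cmps),
                dimnames = list(genes, cmps))
  for (cm in cmps) {
    ids <- sel$sample_id[sel$compound == cm]
    out[, cm] <- rowMeans(expr[genes, ids, drop = FALSE])
  }
  out
}

#' Report treatments whose gene-group response exists only in vivo
#'
#' For 24-h treatments (the only time point shared by the two systems),
#' finds treatments where no gene of `gene_group` is differentially
#' expressed in the real in vitro profiles but at least one is in the real
#' in vivo profiles, and tabulates how many group genes are DEGs in vitro,
#' in real in vivo, and in synthetic in vivo. This is the schema used to ask
#' whether the translator restores liver-specific (e.g. CYP) programs that
#' hepatocyte cultures lose.
#'
#' @param vitro_degs,real_vivo_degs,synthetic_vivo_degs Named DEG-set lists
#'   keyed by [treatment_key()].
#' @param gene_group Character vector of group genes (e.g. CYP genes).
#' @param gene_panel Panel genes; the group must intersect it.
#' @return data.frame: `treatment, in_vitro, in_vivo_real, in_vivo_synthetic`.
#' @export
in_vivo_only_gene_report <- function(vitro_degs, real_vivo_degs,
                                     synthetic_vivo_degs, gene_group,
                                     gene_panel = NULL) {
  if (!is.null(gene_panel)) {
    gene_group <- intersect(gene_group, gene_panel)
    if (!length(gene_group)) stop("gene group disjoint from the panel")
  }
  parse_key <- function(k) strsplit(k, "|", fixed = TRUE)[[1]]
  count <- function(df) length(intersect(df$gene, gene_group))
  rows <- list()
  for (key in names(real_vivo_degs)) {
    p <- parse_key(key)
    if (as.numeric(p[4]) != 24) next
    vit_key <- treatment_key(p[1], "in_vitro", p[3], 24)
    if (!vit_key %in% names(vitro_degs)) next
    n_vit <- count(vitro_degs[[vit_key]])
    n_real <- count(real_vivo_degs[[key]])
    if (n_vit != 0 || n_real < 1) next
    n_syn <- if (key %in% names(synthetic_vivo_degs))
      count(synthetic_vivo_degs[[key]]) else 0L
    rows[[key]] <- data.frame(treatment = key, in_vitro = n_vit,
                              in_vivo_real = n_real, in_vivo_synthetic = n_syn,
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment = character(0), in_vitro = integer(0),
               in_vivo_real = integer(0), in_vivo_synthetic = integer(0))
  rownames(out) <- NULL
  out
}
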