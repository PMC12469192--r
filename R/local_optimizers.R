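#' Genes the translator under-represents among real in vivo DEGs
#'
#' A gene is "not adequately represented" when, among the matched training
#' treatments where it is a DEG in the real in vivo profiles, it is missing
#' from the synthetic DEG set in at least a fraction `f` of them.
#'
#' @param real_degs,synthetic_degs Named lists of DEG-set data.frames with
#'   matching treatment keys.
#' @param f Missed-fraction threshold (default 0.5).
#' @return Character vector of under-represented genes.
#' @export
find_underrepresented_degs <- function(real_degs, synthetic_degs, f = 0.5) {
  keys <- intersect(names(real_degs), names(synthetic_degs))
  if (!length(keys)) stop("no matched treatment groups")
  n_real <- list(); n_miss <- list()
  for (k in keys) {
    rg <- real_degs[[k]]$gene
    sg <- synthetic_degs[[k]]$gene
    for (g in rg) {
      n_real[[g]] <- (n_real[[g]] %||% 0) + 1
      if (!g %in% sg) n_miss[[g]] <- (n_miss[[g]] %||% 0) + 1
    }
  }
  genes <- names(n_real)
  miss <- vapply(genes, function(g) (n_miss[[g]] %||% 0) / n_real[[g]], 0)
  sort(genes[miss >= f])
}

#' Select co-expression modules eligible for local optimization
#'
#' Modules are intersected with the gene panel; a module is kept when the
#' intersection has at least `min_overlap` genes and (optionally) contains
#' at least one under-represented gene.
#'
#' @param modules Named list of module gene vectors (hub-gene names).
#' @param gene_panel Character vector of panel genes.
#' @param underrepresented Character vector from
#'   [find_underrepresented_degs()], or `NULL` to skip that filter.
#' @param min_overlap Minimum panel overlap (default 5).
#' @param require_underrepresented Whether membership of an
#'   under-represented gene is required.
#' @return Named list of intersected modules.
#' @export
select_modules <- function(modules, gene_panel, underrepresented = NULL,
                           min_overlap = 5, require_underrepresented = TRUE) {
  out <- list()
  for (nm in names(modules)) {
    inter <- intersect(modules[[nm]], gene_panel)
    if (length(inter) < min_overlap) next
    if (require_underrepresented && !is.null(underrepresented) &&
        !any(inter %in% underrepresented)) next
    out[[nm]] <- sort(inter)
  }
  out
}

refiner_net <- function(m, label_len = 16) {
  mlp_new(c(m + label_len, 4 * m, m), c("lrelu", "linear"))
}

#' Train a per-module local optimizer
#'
#' A small fully connected refiner (one hidden layer of four times the
#' module size, LeakyReLU, linear output clipped to `[0, 1]` at
#' application) mapping the translator's scaled module-gene outputs plus
#' the 16-bit target label to refined module values. Trained with Adam on
#' the squared error against the real scaled in vivo module values.
#'
#' @param module_genes Character vector of module member genes.
#' @param translator_out Matrix pairs x genes of scaled translator outputs
#'   (column names = panel genes).
#' @param real_vivo Matrix pairs x genes of scaled real in vivo targets.
#' @param target_label Matrix pairs x 16.
#' @param name Module name (its hub gene).
#' @param epochs,lr,batch_size Training schedule.
#' @param seed Seed for initialization/shuffling.
#' @return A `local_optimizer`: module name, genes, refiner net, loss
#'   history, `accepted = NA` until [accept_modules()] decides.
#' @export
train_local_optimizer <- function(module_genes, translator_out, real_vivo,
                                  target_label, name = module_genes[1],
                                  epochs = 300, lr = 1e-3, batch_size = 128,
                                  seed = 1) {
  m <- length(module_genes)
  if (m < 1) stop("module must contain at least one gene")
  stopifnot(all(module_genes %in% colnames(translator_out)))
  X0 <- translator_out[, module_genes, drop = FALSE]
  Y <- real_vivo[, module_genes, drop = FALSE]
  n <- nrow(X0)
  with_seed(seed, {
    net <- refiner_net(m, ncol(target_label))
    opt <- opt_adam(net, lr = lr)
    hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      tot <- 0
      for (st in seq(1, n, by = batch_size)) {
        idx <- ord[st:min(st + batch_size - 1, n)]
        inp <- cbind(X0[idx, , drop = FALSE], target_label[idx, , drop = FALSE])
        fw <- mlp_forward(net, inp, training = TRUE)
        resid <- fw$out - Y[idx, , drop = FALSE]
        tot <- tot + sum(resid^2)
        bk <- mlp_backward(net, fw$cache, dOut = 2 * resid / length(resid))
        stp <- opt_adam_step(net, bk$grads, opt)
        net <- stp$net; opt <- stp$state
      }
      hist[ep] <- tot / (n * m)
    }
    structure(list(module = name, genes = module_genes, net = net,
                   history = hist, accepted = NA),
              class = "local_optimizer")
  })
}

refine_module <- function(optimizer, translator_out, target_label) {
  inp <- cbind(translator_out[, optimizer$genes, drop = FALSE], target_label)
  clip01(mlp_forward(optimizer$net, inp, training = FALSE)$out)
}

#' Accept local optimizers that improve module-level reconstruction
#'
#' An optimizer is accepted iff its refined module-level RMSE on the
#' validation pairs is strictly below the unrefined translator RMSE for
#' that module; ties and regressions are rejected, leaving the translator
#' output untouched for that module.
#'
#' @param candidates List of `local_optimizer` objects.
#' @param translator_out Matrix validation-pairs x genes (scaled).
#' @param real_vivo Matrix validation-pairs x genes (scaled targets).
#' @param target_label Matrix validation-pairs x 16.
#' @return List with `accepted` (the accepted optimizers) and `table`
#'   (per-module RMSE before/after and the decision).
#' @export
accept_modules <- function(candidates, translator_out, real_vivo,
                           target_label) {
  if (!nrow(translator_out)) stop("empty validation set")
  rows <- list(); accepted <- list()
  for (cand in candidates) {
    base <- metric_rmse(as.numeric(translator_out[, cand$genes, drop = FALSE]),
                        as.numeric(real_vivo[, cand$genes, drop = FALSE]))
    ref <- refine_module(cand, translator_out, target_label)
    after <- metric_rmse(as.numeric(ref),
                         as.numeric(real_vivo[, cand$genes, drop = FALSE]))
    ok <- after < base
    cand$accepted <- ok
    if (ok) accepted[[cand$module]] <- cand
    rows[[cand$module]] <- data.frame(module = cand$module,
                                      n_genes = length(cand$genes),
                                      rmse_translator = base,
                                      rmse_refined = after,
                                      accepted = ok, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), n_genes = integer(0),
               rmse_translator = numeric(0), rmse_refined = numeric(0),
               accepted = logical(0))
  rownames(tab) <- NULL
  list(accepted = accepted, table = tab)
}

#' Apply accepted local optimizers to translator output
#'
#' Overwrites exactly the module-gene coordinates of each accepted
#' optimizer with its refined (clipped) values; all other genes are
#' bit-identical before and after. Accepted modules must be pairwise
#' disjoint.
#'
#' @param translator_out Matrix pairs x genes of scaled translator output,
#'   or an unnamed matrix accompanied by `genes`.
#' @param optimizers List of accepted `local_optimizer` objects.
#' @param target_label Matrix pairs x 16.
#' @param genes Panel gene identifiers naming the columns (defaults to
#'   existing column names).
#' @return Matrix of the same shape, refined, still within `[0, 1]`.
#' @export
apply_local_optimizers <- function(translator_out, optimizers, target_label,
                                   genes = colnames(translator_out)) {
  if (!length(optimizers)) return(translator_out)
  if (is.null(colnames(translator_out))) colnames(translator_out) <- genes
  all_genes <- unlist(lapply(optimizers, `[[`, "genes"))
  if (anyDuplicated(all_genes))
    stop("accepted modules overlap; module sets must be pairwise disjoint")
  for (opt in optimizers) {
    translator_out[, opt$genes] <-
      refine_module(opt, translator_out, target_label)
  }
  translator_out
}
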