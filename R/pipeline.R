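#' Average synthetic profiles per targeted in vivo sample
#'
#' Each real in vivo sample is the target of several pairs (one per source
#' in vitro sample); their translated profiles are averaged into a single
#' synthetic profile aligned to that sample id.
#'
#' @param pairs A `pair_set`.
#' @param synthetic Matrix pairs x genes (unscaled), row-aligned to `pairs`.
#' @return Matrix genes x targeted samples.
#' @export
synthetic_sample_matrix <- function(pairs, synthetic) {
  ids <- sort(unique(pairs$vivo_sample))
  out <- matrix(NA_real_, length(pairs$genes), length(ids),
                dimnames = list(pairs$genes, ids))
  for (id in ids) {
    rows <- which(pairs$vivo_sample == id)
    out[, id] <- colMeans(synthetic[rows, , drop = FALSE])
  }
  out
}

#' Synthetic DEG sets per in vivo treatment (triplet-union rule)
#'
#' Synthetic profiles aimed at one in vivo treatment arise from many source
#' dose/time combinations; they are chunked into triplets by generation
#' order, DEGs are called per triplet against the real time-matched control,
#' and the treatment's DEG set is the union over triplets.
#'
#' @param pairs A `pair_set` (test or training).
#' @param synthetic Matrix pairs x genes of unscaled synthetic profiles.
#' @param vivo Real in vivo dataset (`expr`, `meta`) supplying controls.
#' @param threshold DEG threshold.
#' @param chunk_size Triplet size (default 3).
#' @return Named list of DEG-set data.frames keyed by [treatment_key()].
#' @export
synthetic_deg_sets <- function(pairs, synthetic, vivo, threshold = 1,
                               chunk_size = 3) {
  meta <- vivo$meta
  groups <- group_treatments(meta)
  ctrl <- groups[groups$dose == "control", , drop = FALSE]
  samp_key <- setNames(treatment_key(meta$compound, meta$system, meta$dose,
                                     meta$time_h), meta$sample_id)
  pair_key <- samp_key[pairs$vivo_sample]
  out <- list()
  for (i in which(groups$dose != "control")) {
    g <- groups[i, ]
    rows <- which(pair_key == g$key)
    if (!length(rows)) next
    m <- ctrl[ctrl$compound == g$compound & ctrl$system == g$system &
                ctrl$time_h == g$time_h, , drop = FALSE]
    if (nrow(m) == 0) stop("no time-matched control for ", g$key)
    ctrl_mat <- vivo$expr[, m$sample_ids[[1]], drop = FALSE]
    sets <- lapply(triplet_chunks(length(rows), chunk_size), function(ix) {
      call_degs(t(synthetic[rows[ix], , drop = FALSE]), ctrl_mat, threshold)
    })
    out[[g$key]] <- union_synthetic_degs(sets)
  }
  out
}

#' Pipeline run configuration
#'
#' Bundles the simulation settings, translator hyperparameters, local
#' optimizer settings and evaluation settings behind one validated object.
#' When `inputs` is supplied (paths to expression/meta/modules/pathology
#' files) the study is loaded instead of simulated.
#'
#' @param sim A [sim_config()] describing the synthetic study.
#' @param inputs Optional named list of file paths: `vitro_expr`,
#'   `vitro_meta`, `vivo_expr`, `vivo_meta`, `modules`, `pathology`.
#' @param width_factor Generator/discriminator width multiplier.
#' @param epochs,batch_size,cycle_weight,gen_lr,disc_lr Translator training
#'   settings (see [train_translator()]).
#' @param val_fraction Fraction of training compounds held out to accept
#'   local optimizers.
#' @param missed_fraction `f` of [find_underrepresented_degs()].
#' @param min_overlap Module panel-overlap threshold.
#' @param optimizer_epochs,optimizer_lr Refiner training schedule.
#' @param deg_threshold Absolute log2 fold-change cutoff.
#' @param n_baseline Baseline-control subsample size.
#' @param n_gene_sets Number of simulated pathway gene sets.
#' @param aop_n Number of panel genes used for the percent-error grid.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A `run_config`.
#' @export
run_config <- function(sim = sim_config(n_genes = 100, n_compounds = 12,
                                        n_modules = 8,
                                        module_size_range = c(5, 10)),
                       inputs = NULL,
                       width_factor = 1 / 64, epochs = 40, batch_size = 128,
                       cycle_weight = 10, gen_lr = 1e-3, disc_lr = 1e-4,
                       val_fraction = 0.2, missed_fraction = 0.5,
                       min_overlap = 5, optimizer_epochs = 200,
                       optimizer_lr = 1e-3, deg_threshold = 1,
                       n_baseline = 2000, n_gene_sets = 30, aop_n = 15,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(epochs >= 0, val_fraction > 0, val_fraction < 1)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with `run_config` fields (a `sim` sub-map is passed
#'   to [sim_config()]).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(run_config, raw)
}

load_study_inputs <- function(inputs) {
  need <- c("vitro_expr", "vitro_meta", "vivo_expr", "vivo_meta",
            "modules", "pathology")
  for (f in need) {
    if (is.null(inputs[[f]]))
      stop("pre-flight: input path '", f, "' missing from config")
    if (!file.exists(inputs[[f]]))
      stop("pre-flight: ", f, " file not found: ", inputs[[f]])
  }
  vitro_expr <- read_expression(inputs$vitro_expr)
  vivo_expr <- read_expression(inputs$vivo_expr)
  list(vitro = list(expr = vitro_expr,
                    meta = read_meta(inputs$vitro_meta, vitro_expr)),
       vivo = list(expr = vivo_expr,
                   meta = read_meta(inputs$vivo_meta, vivo_expr)),
       modules = read_gmt(inputs$modules),
       pathology = read_pathology(inputs$pathology),
       truth = NULL)
}

subset_dataset <- function(ds, compounds) {
  keep <- ds$meta$compound %in% compounds
  list(expr = ds$expr[, ds$meta$sample_id[keep], drop = FALSE],
       meta = ds$meta[keep, , drop = FALSE])
}

#' Run the full extrapolation pipeline
#'
#' Stages, in order: simulate (or load) the study; split compounds 80/20;
#' build and scale pairs; train the cycle-consistent translator; detect
#' under-represented DEGs, train and accept per-module local optimizers on
#' a held-out validation slice of the training compounds; translate the
#' test set; similarity evaluation against baseline and replicate controls;
#' DEG overlap, pathway over-representation overlap, percent-error grid and
#' in-vivo-only gene report; necrosis classification on real and synthetic
#' test features. Every randomized step draws a seed derived from the
#' global seed, so a rerun with the same configuration reproduces the
#' summary exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for artifacts (`summary.json`, report
#'   TSVs, the model bundle). `NULL` skips writing.
#' @return List with `summary` (flat named numbers) and the stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  study <- stage("simulate", {
    if (!is.null(config$inputs)) load_study_inputs(config$inputs)
    else {
      cfg <- config$sim
      cfg$seed <- derive_seed(config$seed, "simulate")
      sim <- simulate_study(cfg)
      sim$gene_sets <- simulate_gene_sets(sim, n_sets = config$n_gene_sets,
                                          seed = derive_seed(config$seed, "gene_sets"))
      sim
    }
  })
  genes <- rownames(study$vivo$expr)
  G <- length(genes)

  split <- stage("split", split_by_compound(
    sort(unique(study$vivo$meta$compound)),
    seed = derive_seed(config$seed, "split")))
  inner <- stage("split", split_by_compound(
    split$train, train_fraction = 1 - config$val_fraction,
    seed = derive_seed(config$seed, "validation_split")))

  vitro_train <- subset_dataset(study$vitro, split$train)
  vivo_train <- subset_dataset(study$vivo, split$train)
  scaler_vitro <- fit_scaler(vitro_train$expr)
  scaler_vivo <- fit_scaler(vivo_train$expr)

  pairs <- stage("pair", list(
    core = build_pairs(study$vitro, study$vivo, inner$train),
    val = build_pairs(study$vitro, study$vivo, inner$test),
    test = build_pairs(study$vitro, study$vivo, split$test)))

  state <- stage("train", train_translator(
    scale_pairs(pairs$core, scaler_vitro, scaler_vivo),
    build_generator(G, 16, config$width_factor),
    build_discriminator(G, config$width_factor),
    epochs = config$epochs, batch_size = config$batch_size,
    cycle_weight = config$cycle_weight, gen_lr = config$gen_lr,
    disc_lr = config$disc_lr, seed = derive_seed(config$seed, "train")))
  bundle0 <- make_bundle(state, scaler_vitro, scaler_vivo, genes)

  opt <- stage("optimize", {
    syn_core <- translate_pairs(bundle0, pairs$core, noise_seed =
                                  derive_seed(config$seed, "translate_core"),
                                apply_optimizers = FALSE)
    vivo_core <- subset_dataset(study$vivo, inner$train)
    real_degs <- call_degs_dataset(vivo_core, config$deg_threshold)
    syn_degs <- synthetic_deg_sets(pairs$core, syn_core, vivo_core,
                                   config$deg_threshold)
    underrep <- find_underrepresented_degs(real_degs, syn_degs,
                                           f = config$missed_fraction)
    selected <- select_modules(study$modules, genes, underrep,
                               min_overlap = config$min_overlap)
    core_scaled <- scale_pairs(pairs$core, scaler_vitro, scaler_vivo)
    val_scaled <- scale_pairs(pairs$val, scaler_vitro, scaler_vivo)
    out_core <- t(scale_expr(t(syn_core), scaler_vivo))
    colnames(out_core) <- genes
    syn_val <- translate_pairs(bundle0, pairs$val, noise_seed =
                                 derive_seed(config$seed, "translate_val"),
                               apply_optimizers = FALSE)
    out_val <- t(scale_expr(t(syn_val), scaler_vivo))
    colnames(out_val) <- genes
    cands <- lapply(names(selected), function(nm)
      train_local_optimizer(selected[[nm]], out_core, core_scaled$vivo,
                            core_scaled$target_label,
                            name = nm, epochs = config$optimizer_epochs,
                            lr = config$optimizer_lr,
                            seed = derive_seed(config$seed, paste0("opt_", nm))))
    acc <- accept_modules(cands, out_val, val_scaled$vivo,
                          val_scaled$target_label)
    c(acc, list(selected = selected, underrepresented = underrep))
  })
  bundle <- make_bundle(state, scaler_vitro, scaler_vivo, genes,
                        optimizers = opt$accepted)

  ev <- stage("evaluate", {
    syn_test <- translate_pairs(bundle, pairs$test, noise_seed =
                                  derive_seed(config$seed, "translate_test"))
    vivo_test <- subset_dataset(study$vivo, split$test)
    groups <- build_comparison_groups(vivo_test, syn_test,
                                      pairs$test$vivo_sample,
                                      n_baseline = config$n_baseline,
                                      seed = derive_seed(config$seed, "baseline"))
    list(synthetic = syn_test, vivo_test = vivo_test,
         report = similarity_report(groups, vivo_test, syn_test))
  })

  bio <- stage("deg", {
    vivo_test <- ev$vivo_test
    real_degs <- call_degs_dataset(vivo_test, config$deg_threshold)
    syn_degs <- synthetic_deg_sets(pairs$test, ev$synthetic, vivo_test,
                                   config$deg_threshold)
    ratios <- vapply(names(real_degs), function(k)
      deg_overlap_ratio(real_degs[[k]], syn_degs[[k]] %||%
                          data.frame(gene = character(0))), 0)
    gene_sets <- study$gene_sets %||%
      simulate_gene_sets(study, n_sets = config$n_gene_sets,
                         seed = derive_seed(config$seed, "gene_sets"))
    pool <- function(sets) unique(unlist(lapply(sets, `[[`, "gene")))
    er <- enrich(pool(real_degs), gene_sets, genes)
    es <- enrich(pool(syn_degs), gene_sets, genes)
    path_overlap <- if (sum(er$significant) == 0) NA_real_ else
      length(intersect(er$set[er$significant], es$set[es$significant])) /
      sum(er$significant)
    topk <- topk_overlap(er, es, k = 20)

    aop_genes <- utils::head(unlist(study$modules[
      study$truth$injury %||% seq_along(study$modules)], use.names = FALSE),
      config$aop_n)
    syn_by_sample <- synthetic_sample_matrix(pairs$test, ev$synthetic)
    real_hi <- treatment_mean_matrix(vivo_test, aop_genes)
    vivo_syn <- list(expr = vivo_test$expr, meta = vivo_test$meta[
      vivo_test$meta$sample_id %in% colnames(syn_by_sample), , drop = FALSE])
    syn_hi <- treatment_mean_matrix(vivo_syn, aop_genes,
                                    expr_override = syn_by_sample)
    aop <- aop_percent_error(real_hi, syn_hi[, colnames(real_hi), drop = FALSE])

    vivo_only_genes <- if (!is.null(study$truth))
      unlist(study$modules[study$truth$vivo_only], use.names = FALSE)
      else character(0)
    vitro_test <- subset_dataset(study$vitro, split$test)
    cyp <- if (length(vivo_only_genes))
      in_vivo_only_gene_report(call_degs_dataset(vitro_test, config$deg_threshold),
                               real_degs, syn_degs, vivo_only_genes, genes)
      else NULL
    list(real_degs = real_degs, syn_degs = syn_degs, ratios = ratios,
         enrich_real = er, enrich_syn = es, path_overlap = path_overlap,
         topk = topk, aop = aop, cyp = cyp)
  })

  nec <- stage("necrosis", {
    labels <- label_treatments(study$pathology, study$vivo$meta)
    keys <- labels$key
    in_train <- vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 1) %in%
      split$train
    train_lab <- balance_labels(labels[in_train, , drop = FALSE],
                                seed = derive_seed(config$seed, "balance"))
    test_lab <- labels[!in_train, , drop = FALSE]
    if (nrow(test_lab) == 0 || length(unique(train_lab$label)) < 2)
      stop("insufficient labeled treatments for classification")
    feat_train <- treatment_features(study$vivo, train_lab$key)
    model <- train_classifier(feat_train, train_lab$label,
                              seed = derive_seed(config$seed, "xgb"))
    feat_real <- treatment_features(study$vivo, test_lab$key)
    syn_by_sample <- synthetic_sample_matrix(pairs$test, ev$synthetic)
    vivo_syn <- list(expr = syn_by_sample,
                     meta = study$vivo$meta[
                       study$vivo$meta$sample_id %in% colnames(syn_by_sample),
                       , drop = FALSE])
    feat_syn <- treatment_features(vivo_syn, test_lab$key)
    list(model = model,
         real = evaluate_classifier(model, feat_real, test_lab$label),
         synthetic = evaluate_classifier(model, feat_syn, test_lab$label),
         n_train = nrow(train_lab), n_test = nrow(test_lab))
  })

  means <- ev$report$means
  mrow <- function(g, m) means[means$group == g, m]
  summary <- list(
    seed = config$seed,
    n_genes = G,
    n_compounds = length(unique(study$vivo$meta$compound)),
    n_train_pairs = n_pairs(pairs$core) + n_pairs(pairs$val),
    n_test_pairs = n_pairs(pairs$test),
    epochs = config$epochs,
    best_epoch = state$best_epoch,
    cosine_model = mrow("model", "cosine"),
    cosine_baseline = mrow("baseline", "cosine"),
    cosine_replicate = mrow("replicate", "cosine"),
    rmse_model = mrow("model", "rmse"),
    rmse_baseline = mrow("baseline", "rmse"),
    mape_model = mrow("model", "mape"),
    mape_baseline = mrow("baseline", "mape"),
    p_cosine_vs_baseline = ev$report$tests$baseline.cosine$p,
    deg_overlap_mean = mean(bio$ratios, na.rm = TRUE),
    pathway_overlap = bio$path_overlap,
    topk_shared = length(bio$topk$intersection),
    aop_fraction_within_5pct = fraction_within(bio$aop, 5),
    modules_selected = length(opt$selected),
    modules_accepted = length(opt$accepted),
    necrosis_accuracy_real = nec$real$accuracy,
    necrosis_accuracy_synthetic = nec$synthetic$accuracy)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(config[setdiff(names(config), "sim")],
                     file.path(out_dir, "config.yaml"))
    save_bundle(bundle, file.path(out_dir, "model.bundle"))
    write.table(ev$report$per_pair, file.path(out_dir, "similarity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(opt$table, file.path(out_dir, "modules.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  invisible(list(summary = summary, study = study, split = split,
                 pairs = pairs, bundle = bundle, optimizers = opt,
                 evaluation = ev, biology = bio, necrosis = nec))
}
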