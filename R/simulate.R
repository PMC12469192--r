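#' Configuration for the synthetic paired-study generator
#'
#' Defaults emulate the structure of a large rat-liver toxicogenomics
#' repository: ~140 compounds at control/low/middle/high doses, primary
#' hepatocyte (in vitro) sampling at 2/8/24 h with up to 2 replicates,
#' single-dose animal (in vivo) sampling at 3/6/9/24 h with 3 replicates,
#' a ~3,453-gene sentinel panel, and 27 disjoint co-expression modules of
#' 5-41 genes. A configurable fraction of modules is expressed only in vivo,
#' emulating the loss of liver-specific (e.g. CYP) programs in hepatocyte
#' culture. Effects are additive on the log2 scale; a linear time ramp grows
#' them from half strength at the earliest time point to full strength at
#' 24 h.
#'
#' @param n_genes Gene-panel size.
#' @param n_compounds Number of compounds.
#' @param n_modules Number of disjoint co-expression modules.
#' @param module_size_range Inclusive size range for modules.
#' @param dose_multipliers Effect multipliers for control/low/middle/high.
#' @param vitro_times,vivo_times Sampling times (hours) per system.
#' @param vitro_reps,vivo_reps Biological replicates per treatment group.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution (log2).
#' @param effect_sd SD of per-compound x per-module treatment effects (log2).
#' @param noise_sd Residual replicate noise SD (log2).
#' @param vivo_only_fraction Fraction of modules silenced in vitro.
#' @param injury_fraction Fraction of modules designated as the injury
#'   subset driving the latent toxicity score.
#' @param necrosis_threshold Latent-toxicity threshold above which an in
#'   vivo treatment is recorded as necrotic. The latent toxicity of a
#'   treatment is the dose- and time-scaled mean absolute effect over the
#'   injury modules, so the score (and this threshold) is comparable across
#'   study sizes. Treatments between 70% of the threshold and the threshold
#'   receive a non-necrosis finding ("steatosis").
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 3453, n_compounds = 140, n_modules = 27,
                       module_size_range = c(5, 41),
                       dose_multipliers = c(control = 0, low = 0.5,
                                            middle = 1, high = 2),
                       vitro_times = c(2, 8, 24),
                       vivo_times = c(3, 6, 9, 24),
                       vitro_reps = 2, vivo_reps = 3,
                       baseline_mean = 7, baseline_sd = 1.5,
                       effect_sd = 1, noise_sd = 0.3,
                       vivo_only_fraction = 0.25,
                       injury_fraction = 0.15,
                       necrosis_threshold = 1.2,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, n_compounds >= 1, n_modules >= 0,
            length(module_size_range) == 2,
            module_size_range[1] <= module_size_range[2],
            baseline_sd > 0, effect_sd >= 0, noise_sd >= 0,
            vivo_only_fraction >= 0, vivo_only_fraction <= 1,
            vitro_reps >= 1, vitro_reps <= 2,
            vivo_reps >= 1, vivo_reps <= 5)
  structure(cfg, class = "sim_config")
}

time_ramp <- function(time_h, times) {
  tmin <- min(times)
  if (tmin >= 24) return(rep(1, length(time_h)))
  0.5 + 0.5 * (time_h - tmin) / (24 - tmin)
}

sim_meta <- function(compounds, system, times, reps) {
  df <- expand.grid(replicate = seq_len(reps), time_h = times,
                    dose = DOSE_LEVELS, compound = compounds,
                    stringsAsFactors = FALSE)
  df$system <- system
  df$sample_id <- sprintf("%s_%s_%s_%sh_r%d",
                          substr(system, 4, 9), df$compound, df$dose,
                          format(df$time_h, trim = TRUE), df$replicate)
  df[, c("sample_id", "compound", "system", "dose", "time_h", "replicate")]
}

sim_expr_system <- function(cfg, meta, baseline, effect_by_gene, gain,
                            times) {
  mult <- cfg$dose_multipliers[meta$dose]
  ramp <- time_ramp(meta$time_h, times)
  n <- nrow(meta)
  mat <- matrix(rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes, n)
  for (s in seq_len(n)) {
    mat[, s] <- mat[, s] + baseline +
      mult[s] * ramp[s] * gain * effect_by_gene[, meta$compound[s]]
  }
  dimnames(mat) <- list(names(baseline), meta$sample_id)
  mat
}

#' Simulate a paired in vitro / in vivo study with known ground truth
#'
#' Expression for gene g in sample s is
#' `baseline_g + dose_multiplier * time_ramp * system_gain * effect(compound,
#' module(g)) + N(0, noise_sd)`, where `system_gain` is 0 in vitro for
#' in-vivo-only modules and 1 otherwise, and genes outside every module carry
#' no treatment effect. A latent toxicity score per in vivo treatment (dose-
#' and time-scaled sum of absolute effects over the injury modules) drives
#' the recorded pathology findings.
#'
#' @param cfg A [sim_config()].
#' @return List with `vitro` and `vivo` (each `list(expr, meta)`), `modules`
#'   (named list, hub-gene names), `pathology` (data.frame), and `truth`
#'   (module membership, effects, in-vivo-only mask, injury modules, latent
#'   toxicity per treatment).
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    compounds <- sprintf("cmpd%03d", seq_len(cfg$n_compounds))

    sizes <- if (cfg$n_modules > 0)
      sample(seq(cfg$module_size_range[1], cfg$module_size_range[2]),
             cfg$n_modules, replace = TRUE) else integer(0)
    if (sum(sizes) > cfg$n_genes)
      stop("module sizes exceed n_genes; reduce n_modules or sizes")
    perm <- sample(genes)
    module_of <- setNames(rep(NA_integer_, cfg$n_genes), genes)
    modules <- list()
    at <- 1
    for (m in seq_along(sizes)) {
      members <- sort(perm[at:(at + sizes[m] - 1)])
      at <- at + sizes[m]
      modules[[members[1]]] <- members   # named after its hub gene
      module_of[members] <- m
    }

    n_mod <- length(modules)
    vivo_only <- rep(FALSE, n_mod)
    if (n_mod > 0)
      vivo_only <- seq_len(n_mod) %in%
        sample(n_mod, round(cfg$vivo_only_fraction * n_mod))
    injury <- seq_len(max(1, ceiling(cfg$injury_fraction * n_mod)))
    injury <- injury[injury <= n_mod]

    effects <- matrix(rnorm(cfg$n_compounds * max(n_mod, 1), 0, cfg$effect_sd),
                      max(n_mod, 1), cfg$n_compounds,
                      dimnames = list(NULL, compounds))
    # per-gene effect column per compound (0 for unassigned genes)
    effect_by_gene <- matrix(0, cfg$n_genes, cfg$n_compounds,
                             dimnames = list(genes, compounds))
    assigned <- !is.na(module_of)
    if (any(assigned))
      effect_by_gene[assigned, ] <- effects[module_of[assigned], , drop = FALSE]

    baseline <- setNames(rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd),
                         genes)
    gain_vitro <- rep(1, cfg$n_genes)
    if (any(assigned))
      gain_vitro[assigned] <- ifelse(vivo_only[module_of[assigned]], 0, 1)

    meta_vitro <- sim_meta(compounds, "in_vitro", cfg$vitro_times, cfg$vitro_reps)
    meta_vivo <- sim_meta(compounds, "in_vivo", cfg$vivo_times, cfg$vivo_reps)
    expr_vitro <- sim_expr_system(cfg, meta_vitro, baseline, effect_by_gene,
                                  gain_vitro, cfg$vitro_times)
    expr_vivo <- sim_expr_system(cfg, meta_vivo, baseline, effect_by_gene,
                                 rep(1, cfg$n_genes), cfg$vivo_times)

    injury_load <- colMeans(abs(effects[injury, , drop = FALSE]))
    groups <- group_treatments(meta_vivo)
    tox <- cfg$dose_multipliers[groups$dose] *
      time_ramp(groups$time_h, cfg$vivo_times) * injury_load[groups$compound]
    toxicity <- data.frame(key = groups$key, toxicity = as.numeric(tox),
                           stringsAsFactors = FALSE)

    finding_of <- function(t) {
      if (t > cfg$necrosis_threshold) "necrosis"
      else if (t > 0.7 * cfg$necrosis_threshold) "steatosis"
      else "none"
    }
    samp_tox <- setNames(rep(0, nrow(meta_vivo)), meta_vivo$sample_id)
    for (i in seq_len(nrow(groups)))
      samp_tox[groups$sample_ids[[i]]] <- tox[i]
    pathology <- data.frame(sample_id = meta_vivo$sample_id,
                            finding = vapply(samp_tox, finding_of, character(1)),
                            stringsAsFactors = FALSE)

    list(vitro = list(expr = expr_vitro, meta = meta_vitro),
         vivo = list(expr = expr_vivo, meta = meta_vivo),
         modules = modules,
         pathology = pathology,
         truth = list(module_of = module_of, modules = modules,
                      vivo_only = vivo_only, injury = injury,
                      effects = effects, baseline = baseline,
                      toxicity = toxicity),
         config = cfg)
  })
}

#' Simulate pathway-style gene sets over a study's gene panel
#'
#' Half of the sets are seeded on true modules (module genes plus random
#' padding), so over-representation analysis has signal to find; the rest
#' are random draws from the panel.
#'
#' @param study Output of [simulate_study()].
#' @param n_sets Number of gene sets.
#' @param size_range Inclusive set-size range.
#' @param seed Integer seed.
#' @return Named list of gene sets.
#' @export
simulate_gene_sets <- function(study, n_sets = 30, size_range = c(10, 60),
                               seed = 1) {
  genes <- rownames(study$vivo$expr)
  mods <- study$modules
  with_seed(seed, {
    sets <- list()
    for (i in seq_len(n_sets)) {
      size <- sample(seq(size_range[1], size_range[2]), 1)
      if (length(mods) && i %% 2 == 0) {
        core <- mods[[1 + (i %/% 2 - 1) %% length(mods)]]
        pad <- sample(setdiff(genes, core), max(0, size - length(core)))
        sets[[sprintf("path%02d", i)]] <- sort(c(core, pad))
      } else {
        sets[[sprintf("path%02d", i)]] <- sort(sample(genes, size))
      }
    }
    sets
  })
}

#' Write a simulated study to a directory
#'
#' Writes the five artifacts in the package's text formats:
#' `vitro_expression.tsv`, `vitro_meta.tsv`, `vivo_expression.tsv`,
#' `vivo_meta.tsv`, `modules.gmt`, `pathology.tsv`, plus the ground truth as
#' `truth.json`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(study$vitro$expr, file.path(dir, "vitro_expression.tsv"))
  write_meta(study$vitro$meta, file.path(dir, "vitro_meta.tsv"))
  write_expression(study$vivo$expr, file.path(dir, "vivo_expression.tsv"))
  write_meta(study$vivo$meta, file.path(dir, "vivo_meta.tsv"))
  write_gmt(study$modules, file.path(dir, "modules.gmt"))
  write_pathology(study$pathology, file.path(dir, "pathology.tsv"))
  truth <- study$truth
  truth$modules <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Paired fixture with a known per-gene affine in vitro to in vivo map
#'
#' Generates in vitro profiles with baseline, dose/time-scaled latent
#' treatment effects and replicate jitter, then sets each paired in vivo
#' profile to `A * vitro + b` per gene (plus optional noise). The affine
#' parameters are returned, so translator recovery can be scored against an
#' exact oracle; at `noise_sd = 0` a least-squares regression of in vivo on
#' in vitro recovers `(A, b)` exactly.
#'
#' @param n_genes Panel size.
#' @param n_pairs Number of paired examples.
#' @param A,b Affine slope/intercept, scalar or per-gene vectors.
#' @param noise_sd In vivo residual noise SD (0 for the exact relation).
#' @param n_compounds Number of compounds the pairs are spread over.
#' @param signal_sd Scale of latent treatment effects.
#' @param jitter_sd Per-replicate in vitro jitter SD.
#' @param seed Integer seed.
#' @return List: `pairs` (a `pair_set`, 1-1 matched), `vitro`/`vivo`
#'   datasets (`expr`, `meta`), and the true `A`, `b`, `baseline`.
#' @export
known_map_fixture <- function(n_genes = 50, n_pairs = 200, A = 1, b = 0,
                              noise_sd = 0, n_compounds = 10,
                              signal_sd = 0.8, jitter_sd = 0.1, seed = 1) {
  A <- rep_len(A, n_genes); b <- rep_len(b, n_genes)
  vocab <- default_time_vocab()
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    baseline <- setNames(rnorm(n_genes, 7, 1), genes)
    w1 <- rnorm(n_genes); w2 <- rnorm(n_genes)

    compound <- sprintf("cmpd%02d", 1 + (seq_len(n_pairs) - 1) %% n_compounds)
    dose <- DOSE_LEVELS[1 + ((seq_len(n_pairs) - 1) %/% n_compounds) %% 4]
    time_h <- vocab$in_vitro[1 + ((seq_len(n_pairs) - 1) %/% (n_compounds * 4)) %%
                               length(vocab$in_vitro)]
    tk <- paste(compound, dose, time_h)
    replicate <- stats::ave(seq_len(n_pairs), tk, FUN = seq_along)
    if (max(replicate) > 5)
      stop("n_pairs too large for the replicate budget; increase n_compounds")
    mult <- c(control = 0, low = 0.5, middle = 1, high = 2)[dose]
    ramp <- time_ramp(time_h, vocab$in_vitro)

    u1 <- setNames(rnorm(length(unique(tk))), unique(tk))
    u2 <- setNames(rnorm(length(unique(tk))), unique(tk))
    vitro <- matrix(rnorm(n_genes * n_pairs, 0, jitter_sd), n_genes, n_pairs)
    for (s in seq_len(n_pairs)) {
      vitro[, s] <- vitro[, s] + baseline +
        mult[s] * ramp[s] * signal_sd * (u1[tk[s]] * w1 + u2[tk[s]] * w2)
    }
    vivo <- A * vitro + b +
      matrix(rnorm(n_genes * n_pairs, 0, noise_sd), n_genes, n_pairs)

    meta_vitro <- data.frame(
      sample_id = sprintf("fx_vitro_%03d", seq_len(n_pairs)),
      compound = compound, system = "in_vitro", dose = dose,
      time_h = time_h, replicate = replicate, stringsAsFactors = FALSE)
    meta_vivo <- meta_vitro
    meta_vivo$sample_id <- sprintf("fx_vivo_%03d", seq_len(n_pairs))
    meta_vivo$system <- "in_vivo"
    meta_vivo$time_h <- 24
    # one in vivo sample per (compound, dose); replicate index re-derived
    meta_vivo$replicate <- stats::ave(seq_len(n_pairs),
                                      paste(compound, dose), FUN = seq_along)
    dimnames(vitro) <- list(genes, meta_vitro$sample_id)
    dimnames(vivo) <- list(genes, meta_vivo$sample_id)

    pairs <- structure(list(
      vitro = t(vitro), vivo = t(vivo),
      source_label = encode_label_rows(meta_vitro, vocab),
      target_label = encode_label_rows(meta_vivo, vocab),
      compound = compound,
      vitro_sample = meta_vitro$sample_id,
      vivo_sample = meta_vivo$sample_id,
      genes = genes), class = "pair_set")

    list(pairs = pairs,
         vitro = list(expr = vitro, meta = meta_vitro),
         vivo = list(expr = vivo, meta = meta_vivo),
         A = A, b = b, baseline = baseline)
  })
}
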