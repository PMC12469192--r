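# Fixtures are built in code; nothing is read from disk except round-trip
# temp files created by the tests themselves.

tiny_expr <- function(genes = 3, samples = 2, seed = 1) {
  with_seed(seed, {
    m <- matrix(rnorm(genes * samples, 7, 1), genes, samples,
                dimnames = list(sprintf("g%03d", seq_len(genes)),
                                sprintf("s%03d", seq_len(samples))))
    m
  })
}

# metadata for a fully crossed design of one system
tiny_meta <- function(compounds, system = "in_vivo",
                      doses = DOSE_LEVELS, times = c(3, 24), reps = 2) {
  df <- expand.grid(replicate = seq_len(reps), time_h = times, dose = doses,
                    compound = compounds, stringsAsFactors = FALSE)
  df$system <- system
  df$sample_id <- sprintf("%s_%s_%s_%s_r%d", system, df$compound, df$dose,
                          df$time_h, df$replicate)
  df[, c("sample_id", "compound", "system", "dose", "time_h", "replicate")]
}

dataset_for <- function(meta, seed = 1) {
  expr <- with_seed(seed, matrix(rnorm(20 * nrow(meta), 7, 1), 20, nrow(meta),
                                 dimnames = list(sprintf("g%03d", 1:20),
                                                 meta$sample_id)))
  list(expr = expr, meta = meta)
}

# brute-force expected pair count: per compound, treatment x treatment plus
# control x control cross-products
oracle_pair_count <- function(meta_vitro, meta_vivo, compounds) {
  total <- 0
  for (cmp in compounds) {
    a <- meta_vitro[meta_vitro$compound == cmp, ]
    b <- meta_vivo[meta_vivo$compound == cmp, ]
    if (!nrow(a) || !nrow(b)) next
    total <- total +
      sum(a$dose != "control") * sum(b$dose != "control") +
      sum(a$dose == "control") * sum(b$dose == "control")
  }
  total
}

# independent identity-refiner: a local_optimizer whose network reproduces
# its module inputs exactly (positive inputs pass through LeakyReLU)
identity_optimizer <- function(genes) {
  m <- length(genes)
  net <- mlp_new(c(m + 16, 4 * m, m), c("lrelu", "linear"))
  net$layers[[1]]$W[] <- 0
  net$layers[[1]]$W[cbind(seq_len(m), seq_len(m))] <- 1
  net$layers[[1]]$b[] <- 0
  net$layers[[2]]$W[] <- 0
  net$layers[[2]]$W[cbind(seq_len(m), seq_len(m))] <- 1
  net$layers[[2]]$b[] <- 0
  structure(list(module = genes[1], genes = genes, net = net,
                 history = numeric(0), accepted = NA),
            class = "local_optimizer")
}
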