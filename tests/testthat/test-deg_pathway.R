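mk_degs <- function(genes, fc = 2) {
  data.frame(gene = genes, log2fc = rep_len(fc, length(genes)),
             stringsAsFactors = FALSE)
}

test_that("DEG calling uses mean log2 differences with a strict threshold", {
  tr <- matrix(c(7.5, 7.5, 5, 5), 2, 2, byrow = TRUE,
               dimnames = list(c("gA", "gB"), NULL))
  ct <- matrix(5, 2, 2, dimnames = list(c("gA", "gB"), NULL))
  d <- call_degs(tr, ct)
  expect_equal(d$gene, "gA")
  expect_equal(d$log2fc, 2.5)

  expect_equal(nrow(call_degs(ct, ct)), 0)
  # |fc| exactly at the threshold is NOT a DEG
  tr2 <- matrix(c(6, 4), 2, 1, dimnames = list(c("gA", "gB"), NULL))
  ct2 <- matrix(c(5, 5), 2, 1, dimnames = list(c("gA", "gB"), NULL))
  expect_equal(nrow(call_degs(tr2, ct2, threshold = 1)), 0)
  expect_equal(nrow(call_degs(tr2, ct2, threshold = 0.999)), 2)
})

test_that("dataset-wide DEG calling matches a per-group manual computation", {
  meta <- tiny_meta("a", doses = c("control", "high"), times = c(3, 24),
                    reps = 2)
  ds <- dataset_for(meta, seed = 9)
  sets <- call_degs_dataset(ds, threshold = 0.5)
  expect_length(sets, 2)  # high-dose groups at 3 h and 24 h
  g <- meta$sample_id[meta$dose == "high" & meta$time_h == 3]
  ctl <- meta$sample_id[meta$dose == "control" & meta$time_h == 3]
  fc <- rowMeans(ds$expr[, g]) - rowMeans(ds$expr[, ctl])
  key <- treatment_key("a", "in_vivo", "high", 3)
  expect_setequal(sets[[key]]$gene, names(fc)[abs(fc) > 0.5])

  no_ctl <- list(expr = ds$expr, meta = meta[meta$dose != "control", ])
  expect_error(call_degs_dataset(no_ctl), "control")
})

test_that("triplet union keeps the largest-magnitude fold change", {
  u <- union_synthetic_degs(list(mk_degs(c("A", "B")), mk_degs(c("B", "C"))))
  expect_setequal(u$gene, c("A", "B", "C"))
  u <- union_synthetic_degs(list(
    data.frame(gene = "A", log2fc = 1.5),
    data.frame(gene = "A", log2fc = -3)))
  expect_equal(u$log2fc, -3)
  one <- mk_degs(c("X", "Y"))
  expect_equal(union_synthetic_degs(list(one)), one, ignore_attr = TRUE)
  # brute force on random triplets
  for (i in 1:20) {
    sets <- with_seed(i, lapply(1:3, function(j)
      mk_degs(sample(LETTERS[1:10], sample(0:5, 1)), fc = rnorm(1) * 3)))
    u <- union_synthetic_degs(sets)
    expect_setequal(u$gene, unique(unlist(lapply(sets, `[[`, "gene"))))
  }
  expect_error(union_synthetic_degs(list()), "empty")
  expect_equal(triplet_chunks(7), list(`1` = 1:3, `2` = 4:6, `3` = 7L))
})

test_that("DEG overlap ratio is |real * synthetic| / |real| with exclusions", {
  expect_equal(deg_overlap_ratio(mk_degs(letters[1:4]), mk_degs(letters[1:4])), 1)
  expect_equal(deg_overlap_ratio(mk_degs(c("a", "b")), mk_degs(c("x", "y"))), 0)
  expect_equal(deg_overlap_ratio(mk_degs(c("a", "b", "c", "d")),
                                 mk_degs(c("b", "d", "e"))), 0.5)
  expect_true(is.na(deg_overlap_ratio(mk_degs(character(0)), mk_degs("a"))))
  # synthetic superset of real implies ratio 1
  for (i in 1:20) {
    real <- with_seed(i, sample(letters, sample(1:10, 1)))
    extra <- with_seed(i + 50, sample(letters, 5))
    expect_equal(deg_overlap_ratio(real, union(real, extra)), 1)
  }
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  uni <- sprintf("u%02d", 1:20)
  res <- enrich(uni[1:5], list(s = uni[1:5]), uni)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  expect_equal(sum(enrich(character(0), list(s = uni[1:5]), uni)$significant), 0)
  expect_error(enrich("a", list(s = "a"), character(0)), "empty universe")

  # independent oracle: tail sum of the hypergeometric pmf via choose()
  exact_tail <- function(k, K, N, n) {
    j <- k:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  for (i in 1:100) {
    par <- with_seed(i, {
      N <- sample(10:30, 1)
      K <- sample(1:(N - 1), 1)
      n <- sample(1:(N - 1), 1)
      list(N = N, K = K, n = n,
           uni = sprintf("g%02d", 1:N))
    })
    set <- par$uni[1:par$K]
    degs <- with_seed(i + 999, sample(par$uni, par$n))
    res <- enrich(degs, list(s = set), par$uni)
    k <- length(intersect(set, degs))
    expect_equal(res$p, exact_tail(k, par$K, par$N, par$n), tolerance = 1e-12)
    expect_gte(res$p_adj, res$p)  # Bonferroni never creates significance
  }
})

test_that("Bonferroni adjustment is monotone over multiple sets", {
  uni <- sprintf("g%02d", 1:25)
  sets <- with_seed(5, lapply(1:8, function(i) sample(uni, 6)))
  names(sets) <- paste0("s", 1:8)
  res <- enrich(with_seed(6, sample(uni, 7)), sets, uni)
  expect_equal(res$p_adj, pmin(1, res$p * 8))
  expect_true(all(res$p_adj[res$significant] <= 0.05))
})

test_that("top-k selection keeps all sets tied with the k-th rank", {
  mk <- function(p_adj, overlap) data.frame(
    set = sprintf("s%02d", seq_along(p_adj)), overlap = overlap,
    size = 10, p = p_adj, p_adj = p_adj,
    significant = p_adj <= 0.05, stringsAsFactors = FALSE)
  # distinct ranks: exactly k kept
  r <- mk(seq(0.001, 0.025, length.out = 25), 25:1)
  tk <- topk_overlap(r, r, k = 20)
  expect_length(tk$kept_real, 20)
  expect_length(tk$intersection, 20)
  # a tie group spanning rank 20 inflates the kept list (the 22-pathway
  # mechanism): ranks 19-22 share p_adj and overlap
  p <- c(seq(0.001, 0.018, length.out = 18), rep(0.02, 4), seq(0.03, 0.05,
                                                               length.out = 3))
  r2 <- mk(p, c(25:8, rep(7, 4), 3:1))
  expect_length(topk_overlap(r2, r2, k = 20)$kept_real, 22)
  # fewer than k sets: all kept
  r3 <- mk(c(0.01, 0.02), c(2, 1))
  expect_length(topk_overlap(r3, r3, k = 20)$kept_real, 2)
  # brute-force agreement on random tied tables
  for (i in 1:25) {
    tbl <- with_seed(i, mk(sample(seq(0.005, 0.05, by = 0.005), 30,
                                  replace = TRUE),
                           sample(1:5, 30, replace = TRUE)))
    kept <- topk_overlap(tbl, tbl, k = 10)$kept_real
    ord <- order(tbl$p_adj, -tbl$overlap)
    kth <- tbl[ord[10], ]
    bf <- tbl$set[tbl$p_adj < kth$p_adj |
                    (tbl$p_adj == kth$p_adj & tbl$overlap >= kth$overlap)]
    expect_setequal(kept, bf)
    expect_gte(length(kept), 10)
  }
})

test_that("percent-error grids follow the sign convention and masking", {
  real <- matrix(8, 15, 28, dimnames = list(sprintf("g%02d", 1:15),
                                            sprintf("c%02d", 1:28)))
  syn <- real
  ae <- aop_percent_error(real, syn)
  expect_equal(length(ae$error), 420)
  expect_true(all(ae$error == 0))
  expect_equal(fraction_within(ae), 1)

  # 8 vs 7.6 is exactly 5% and counts as within at the <= cutoff
  ae2 <- aop_percent_error(matrix(8), matrix(7.6))
  expect_equal(ae2$error[1], 5)
  expect_equal(fraction_within(ae2, 5), 1)

  # swapping real and synthetic flips the error sign (same-sign profiles)
  r <- matrix(c(4, 5, 6), 1); s <- matrix(c(5, 4, 6), 1)
  e1 <- aop_percent_error(r, s)$error
  e2 <- aop_percent_error(s, r)$error
  expect_equal(sign(e1), -sign(e2), ignore_attr = TRUE)
  expect_equal(e1[1, 1], (4 - 5) / 4 * 100)

  masked <- aop_percent_error(matrix(c(0, 2), 1), matrix(c(1, 1), 1))
  expect_true(masked$mask[1, 1])
  expect_equal(fraction_within(masked, 50), 1)  # only the defined cell counts
})

test_that("the in-vivo-only gene report flags restored expression", {
  grp <- c("cypA", "cypB")
  key24 <- function(cmp, dose) treatment_key(cmp, "in_vivo", dose, 24)
  vit_key <- function(cmp, dose) treatment_key(cmp, "in_vitro", dose, 24)
  vitro <- setNames(list(mk_degs("other"), mk_degs(c("cypA"))),
                    c(vit_key("a", "high"), vit_key("b", "high")))
  real <- setNames(list(mk_degs(c("cypA", "cypB")), mk_degs("cypB")),
                   c(key24("a", "high"), key24("b", "high")))
  syn <- setNames(list(mk_degs("cypA"), mk_degs("cypB")),
                  c(key24("a", "high"), key24("b", "high")))
  rep_ <- in_vivo_only_gene_report(vitro, real, syn, grp)
  # compound b is disqualified: cypA is already a DEG in vitro
  expect_equal(rep_$treatment, key24("a", "high"))
  expect_equal(rep_$in_vitro, 0)
  expect_equal(rep_$in_vivo_real, 2)
  expect_equal(rep_$in_vivo_synthetic, 1)
  expect_named(rep_, c("treatment", "in_vitro", "in_vivo_real",
                       "in_vivo_synthetic"))
  # a synthetic set that captures nothing reports zero
  syn0 <- setNames(list(mk_degs("other")), key24("a", "high"))
  expect_equal(in_vivo_only_gene_report(vitro, real, syn0,
                                        grp)$in_vivo_synthetic, 0)
  expect_error(in_vivo_only_gene_report(vitro, real, syn, "absent",
                                        gene_panel = c("cypA", "cypB")),
               "disjoint")
})
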