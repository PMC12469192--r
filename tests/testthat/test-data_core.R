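test_that("treatment grouping partitions samples exactly", {
  meta <- tiny_meta("cmpdA", doses = c("low", "high"), times = 3, reps = 3)
  gr <- group_treatments(meta)
  expect_equal(nrow(gr), 2)
  expect_equal(sort(gr$n), c(3L, 3L))

  # every sample lands in exactly one group (random designs)
  for (seed in 1:5) {
    meta <- with_seed(seed, {
      m <- tiny_meta(c("a", "b", "c"), doses = sample(DOSE_LEVELS, 3),
                     times = sample(c(3, 6, 24), 2), reps = sample(1:3, 1))
      m[sample(nrow(m)), ]
    })
    gr <- group_treatments(meta)
    ids <- unlist(gr$sample_ids)
    expect_setequal(ids, meta$sample_id)
    expect_equal(anyDuplicated(ids), 0L)
    key <- treatment_key(meta$compound, meta$system, meta$dose, meta$time_h)
    expect_equal(nrow(gr), length(unique(key)))
  }
})

test_that("a crossed two-compound design yields 16 in vivo groups", {
  meta <- tiny_meta(c("a", "b"), doses = DOSE_LEVELS, times = c(6, 24),
                    reps = 2)
  expect_equal(nrow(group_treatments(meta)), 2 * 4 * 2)
  expect_equal(nrow(group_treatments(meta[1, ])), 1)
  expect_equal(nrow(group_treatments(meta[0, ])), 0)
})

test_that("label encoding is a 16-bit bijection over the vocabulary", {
  vocab <- default_time_vocab()
  lb <- encode_label("in_vitro", "control", 2, 1)
  expect_length(lb, 16)
  expect_equal(sum(lb), 4)

  seen <- character(0)
  for (sys in SYSTEMS) for (d in DOSE_LEVELS)
    for (t in vocab[[sys]]) for (r in 1:5) {
      bits <- encode_label(sys, d, t, r, vocab)
      expect_length(bits, 16)
      seen <- c(seen, paste(bits, collapse = ""))
      dec <- decode_label(bits, vocab)
      expect_identical(dec, list(system = sys, dose = d, time_h = t,
                                 replicate = r))
    }
  expect_equal(anyDuplicated(seen), 0L)

  expect_error(encode_label("in_vitro", "low", 5, 1), "vocabulary")
  expect_error(encode_label("in_vivo", "low", 24, 6), "replicate")
})

test_that("min-max scaling round-trips, clips, and handles constant genes", {
  m <- matrix(c(4, 8, 5, 5), 2, 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  sc <- fit_scaler(m)
  expect_equal(scale_expr(c(gA = 6, gB = 5), sc), c(gA = 0.5, gB = 0))
  expect_equal(scale_expr(c(gA = 10, gB = 5), sc)[["gA"]], 1)  # clipped

  train <- tiny_expr(15, 8, seed = 3)
  sc <- fit_scaler(train)
  y <- scale_expr(train, sc)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(unscale_expr(y, sc), train, tolerance = 1e-9)
})

test_that("compound split reproduces the 112/28 partition and rounding", {
  cmpds <- sprintf("c%03d", 1:140)
  sp <- split_by_compound(cmpds, 0.8, seed = 7)
  expect_length(sp$train, 112)
  expect_length(sp$test, 28)
  expect_setequal(c(sp$train, sp$test), cmpds)
  expect_length(intersect(sp$train, sp$test), 0)

  expect_length(split_by_compound(letters[1:5], 0.8, seed = 1)$train, 4)
  s1 <- split_by_compound(letters[1:10], 0.8, seed = 1)
  expect_identical(s1, split_by_compound(letters[1:10], 0.8, seed = 1))
  expect_error(split_by_compound(letters[1:5], 1.2), "train_fraction")
})

test_that("pair counts match the stratified cross-product oracle", {
  # 2 x 3 treatment samples plus 1 x 2 controls -> 8 pairs
  mv <- tiny_meta("a", system = "in_vitro", doses = c("control", "high"),
                  times = 2, reps = 2)
  mv <- mv[c(which(mv$dose == "high"), which(mv$dose == "control")[1]), ]
  mo <- tiny_meta("a", doses = c("control", "high"), times = 3, reps = 3)
  mo <- mo[c(which(mo$dose == "high"), which(mo$dose == "control")[1:2]), ]
  vitro <- dataset_for(mv, seed = 1); vivo <- dataset_for(mo, seed = 2)
  pr <- build_pairs(vitro, vivo, "a")
  expect_equal(n_pairs(pr), 8)
  expect_equal(n_pairs(pr), oracle_pair_count(mv, mo, "a"))

  # random designs: oracle equality and stratum purity
  for (seed in 1:6) {
    cmpds <- c("a", "b", "c")
    mva <- with_seed(seed, tiny_meta(cmpds, system = "in_vitro",
                                     doses = sample(DOSE_LEVELS, 3),
                                     times = c(2, 24), reps = 2))
    mvo <- with_seed(seed + 100, tiny_meta(cmpds,
                                           doses = sample(DOSE_LEVELS, 3),
                                           times = c(6, 24), reps = 3))
    pr <- build_pairs(dataset_for(mva, 1), dataset_for(mvo, 2), cmpds)
    expect_equal(n_pairs(pr), oracle_pair_count(mva, mvo, cmpds))
    src_dose <- apply(pr$source_label[, 3:6, drop = FALSE], 1, which.max)
    tgt_dose <- apply(pr$target_label[, 3:6, drop = FALSE], 1, which.max)
    expect_true(all((src_dose == 1) == (tgt_dose == 1)))  # control w/ control
  }
})

test_that("pairing skips compounds missing from one system with a warning", {
  mv <- tiny_meta("a", system = "in_vitro", times = 2, reps = 1)
  mo <- tiny_meta(c("a", "b"), times = 3, reps = 1)
  expect_warning(pr <- build_pairs(dataset_for(mv, 1), dataset_for(mo, 2),
                                   c("a", "b")), "skipped")
  expect_true(all(pr$compound == "a"))
})

test_that("no sample of a test compound enters the training pairs", {
  cmpds <- sprintf("c%02d", 1:10)
  mva <- tiny_meta(cmpds, system = "in_vitro", times = c(2, 8), reps = 2)
  mvo <- tiny_meta(cmpds, times = c(3, 24), reps = 2)
  sp <- split_by_compound(cmpds, 0.8, seed = 3)
  pr <- build_pairs(dataset_for(mva, 1), dataset_for(mvo, 2), sp$train)
  test_samples <- c(mva$sample_id[mva$compound %in% sp$test],
                    mvo$sample_id[mvo$compound %in% sp$test])
  expect_length(intersect(c(pr$vitro_sample, pr$vivo_sample), test_samples), 0)
})
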