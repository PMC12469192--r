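test_that("generator spec reproduces the reference dimensionality", {
  gs <- build_generator(3453, 16)
  expect_equal(gs$input_dim, 6938)
  expect_equal(gs$hidden, c(8192, 7168, 7168, 4096, 4096))
  expect_equal(gs$dropout, c(0.8, 0.8, 0.8, 0.4, 0))
  expect_equal(build_generator(50, 16)$input_dim, 132)
  expect_equal(build_generator(50, 16, 1 / 64)$hidden,
               c(128, 112, 112, 64, 64))
  ds <- build_discriminator(3453)
  expect_equal(ds$hidden, c(256, 64))
  expect_equal(ds$optimizer, list(kind = "sgd", lr = 1e-4, momentum = 0.9))
})

test_that("network parameter shapes match the spec for any width factor", {
  for (case in list(c(20, 1), c(37, 0.25), c(100, 1 / 64))) {
    G <- case[1]; wf <- case[2]
    gs <- build_generator(G, 16, wf)
    net <- aivive:::spec_to_mlp(gs)
    widths <- c(gs$input_dim, ceiling(wf * c(8192, 7168, 7168, 4096, 4096)), G)
    for (l in seq_len(6)) {
      expect_equal(dim(net$layers[[l]]$W), c(widths[l], widths[l + 1]))
      expect_length(net$layers[[l]]$b, widths[l + 1])
    }
    expect_equal(net$layers[[6]]$act, "sigmoid")
    dnet <- aivive:::spec_to_mlp(build_discriminator(G, wf))
    expect_equal(dim(dnet$layers[[1]]$W), c(G, ceiling(wf * 256)))
    expect_equal(dim(dnet$layers[[3]]$W), c(ceiling(wf * 64), 1))
  }
})

test_that("generator input is profile | labels | standard normal noise", {
  x <- runif(3)
  s <- encode_label("in_vitro", "low", 2, 1)
  t <- encode_label("in_vivo", "low", 24, 1)
  v <- make_generator_input(x, s, t, noise_seed = 4)
  expect_equal(ncol(v), 2 * 3 + 32)
  expect_equal(as.numeric(v[1, 1:3]), x)
  expect_equal(as.numeric(v[1, 4:19]), s)
  expect_identical(v, make_generator_input(x, s, t, noise_seed = 4))
  expect_false(identical(v, make_generator_input(x, s, t, noise_seed = 5)))

  big <- make_generator_input(matrix(runif(1e5), 100, 1000),
                              matrix(0L, 100, 16), matrix(0L, 100, 16),
                              noise_seed = 8)
  noise <- big[, (2032 - 999):2032]
  expect_equal(mean(noise), 0, tolerance = 0.02)
  expect_equal(sd(noise), 1, tolerance = 0.02)
  expect_error(make_generator_input(matrix(0, 2, 3), matrix(0, 3, 16),
                                    matrix(0, 2, 16)), "row counts")
})

test_that("checkpoint selection finds the first stable window", {
  expect_equal(select_checkpoint(rep(1, 40), window = 10, tolerance = 0.05), 10)
  # strictly decreasing then flat: first window fully in the flat region
  h <- c(seq(10, 1, length.out = 30), rep(1, 30))
  expect_equal(select_checkpoint(h, window = 10, tolerance = 0.01), 39)
  # never stable: falls back to the smoothed argmin
  h <- with_seed(3, 5 + 3 * sin(1:80) + rnorm(80))
  w <- 10
  sm <- as.numeric(stats::filter(h, rep(1 / w, w), sides = 1))
  expect_equal(select_checkpoint(h, window = w, tolerance = 1e-4),
               which.min(sm))
  expect_error(select_checkpoint(numeric(0)), "empty")
})

test_that("zero training epochs give an untrained state with empty history", {
  fx <- known_map_fixture(n_genes = 8, n_pairs = 20, seed = 2)
  sp <- scale_pairs(fx$pairs, fit_scaler(fx$vitro$expr),
                    fit_scaler(fx$vivo$expr))
  st <- train_translator(sp, build_generator(8, 16, 1 / 64),
                         build_discriminator(8, 1 / 64), epochs = 0, seed = 1)
  expect_equal(nrow(st$history), 0)
  expect_true(is.na(st$best_epoch))
})

test_that("training is deterministic given its seed and rejects raw inputs", {
  fx <- known_map_fixture(n_genes = 8, n_pairs = 24, seed = 3)
  sc_vi <- fit_scaler(fx$vitro$expr); sc_vo <- fit_scaler(fx$vivo$expr)
  sp <- scale_pairs(fx$pairs, sc_vi, sc_vo)
  gs <- build_generator(8, 16, 1 / 64); ds <- build_discriminator(8, 1 / 64)
  a <- train_translator(sp, gs, ds, epochs = 3, batch_size = 8, seed = 77)
  b <- train_translator(sp, gs, ds, epochs = 3, batch_size = 8, seed = 77)
  expect_identical(a$gen_f, b$gen_f)
  expect_identical(a$history, b$history)
  expect_true(all(is.finite(as.matrix(a$history))))
  expect_error(train_translator(fx$pairs, gs, ds, epochs = 1), "scaled")
})

test_that("translation is deterministic and bounded by the training range", {
  fx <- known_map_fixture(n_genes = 8, n_pairs = 24, seed = 3)
  sc_vi <- fit_scaler(fx$vitro$expr); sc_vo <- fit_scaler(fx$vivo$expr)
  sp <- scale_pairs(fx$pairs, sc_vi, sc_vo)
  st <- train_translator(sp, build_generator(8, 16, 1 / 64),
                         build_discriminator(8, 1 / 64), epochs = 2,
                         batch_size = 8, seed = 1)
  bd <- make_bundle(st, sc_vi, sc_vo, fx$pairs$genes)
  syn <- translate_pairs(bd, fx$pairs, noise_seed = 6)
  expect_identical(syn, translate_pairs(bd, fx$pairs, noise_seed = 6))
  expect_false(identical(syn, translate_pairs(bd, fx$pairs, noise_seed = 7)))
  rng <- t(syn) >= sc_vo$min - 1e-9 & t(syn) <= sc_vo$max + 1e-9
  expect_true(all(rng))

  # single-profile interface agrees with a one-pair batch
  one <- translate(bd, fx$vitro$expr[, 3], fx$pairs$source_label[3, ],
                   fx$pairs$target_label[3, ], noise_seed = 6)
  batch1 <- translate_pairs(bd, subset_pairs(fx$pairs, 3), noise_seed = 6)
  expect_equal(unname(one), unname(batch1[1, ]), tolerance = 1e-12)

  p <- withr::local_tempfile(fileext = ".rds")
  save_bundle(bd, p)
  expect_identical(translate_pairs(load_bundle(p), fx$pairs, noise_seed = 6),
                   syn)
})
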