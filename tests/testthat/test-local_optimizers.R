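mk_set <- function(genes) data.frame(gene = genes,
                                     log2fc = rep_len(2, length(genes)),
                                     stringsAsFactors = FALSE)

test_that("under-represented DEG detection applies the missed-fraction rule", {
  real <- list(t1 = mk_set(c("a", "b")), t2 = mk_set(c("a", "c")))
  # synthetic identical to real: nothing is missed
  expect_length(find_underrepresented_degs(real, real), 0)
  # synthetic finds nothing: every real DEG is under-represented
  empty <- list(t1 = mk_set(character(0)), t2 = mk_set(character(0)))
  expect_setequal(find_underrepresented_degs(real, empty), c("a", "b", "c"))
  # gene "a" missed in 1 of its 2 treatments: included at f = 0.5
  syn <- list(t1 = mk_set(c("a", "b")), t2 = mk_set("c"))
  expect_setequal(find_underrepresented_degs(real, syn, f = 0.5), "a")
  expect_length(find_underrepresented_degs(real, syn, f = 0.6), 0)
  expect_error(find_underrepresented_degs(real, list(x = mk_set("a"))),
               "no matched")
})

test_that("module selection enforces the 5-gene panel overlap boundary", {
  panel <- sprintf("g%02d", 1:40)
  mods <- list(m4 = panel[1:4],                       # too small
               m5 = panel[5:9],                       # boundary pass
               m6 = c(panel[10:14], "offpanel"),      # 5 after intersection
               m_no_urep = panel[20:26])
  urep <- c(panel[5], panel[10])
  sel <- select_modules(mods, panel, urep)
  expect_setequal(names(sel), c("m5", "m6"))
  expect_setequal(sel$m6, panel[10:14])
  # without the under-represented filter the larger module returns
  sel2 <- select_modules(mods, panel, urep, require_underrepresented = FALSE)
  expect_setequal(names(sel2), c("m5", "m6", "m_no_urep"))

  # brute-force agreement on random module collections
  for (i in 1:20) {
    rmods <- with_seed(i, lapply(1:6, function(j)
      sample(c(panel, sprintf("x%02d", 1:10)), sample(3:12, 1))))
    names(rmods) <- paste0("m", 1:6)
    ru <- with_seed(i + 70, sample(panel, 6))
    got <- select_modules(rmods, panel, ru)
    want <- Filter(function(m) length(m) >= 5 && any(m %in% ru),
                   lapply(rmods, intersect, panel))
    expect_setequal(names(got), names(want))
  }
})

test_that("refinement touches exactly the accepted module coordinates", {
  with_seed(3, {
    out <- matrix(runif(60), 10, 6,
                  dimnames = list(NULL, sprintf("g%02d", 1:6)))
    lbl <- matrix(rbinom(160, 1, 0.3), 10, 16)
  })
  expect_identical(apply_local_optimizers(out, list(), lbl), out)

  opt <- identity_optimizer(c("g02", "g04", "g05"))
  opt$net$layers[[2]]$b[] <- 0.05   # shift the module by a constant
  ref <- apply_local_optimizers(out, list(opt), lbl)
  changed <- colSums(ref != out) > 0
  expect_equal(sum(changed), 3)
  expect_setequal(names(changed)[changed], c("g02", "g04", "g05"))
  expect_identical(ref[, c("g01", "g03", "g06")], out[, c("g01", "g03", "g06")])
  expect_true(all(ref >= 0 & ref <= 1))

  overlap <- identity_optimizer(c("g04", "g06"))
  expect_error(apply_local_optimizers(out, list(opt, overlap), lbl),
               "disjoint")
})

test_that("a refiner learns a constant shift and wins acceptance", {
  genes <- sprintf("g%02d", 1:5)
  n <- 120
  with_seed(8, {
    lbl <- matrix(0L, n, 16)
    lbl[, 2] <- 1L; lbl[, 6] <- 1L; lbl[, 11] <- 1L; lbl[, 12] <- 1L
    truth <- matrix(0.8 + rnorm(n * 5, 0, 0.02), n, 5,
                    dimnames = list(NULL, genes))
    out <- matrix(0.5, n, 5, dimnames = list(NULL, genes))
  })
  truth[truth > 1] <- 1
  tr <- 1:80; va <- 81:120
  opt <- train_local_optimizer(genes, out[tr, ], truth[tr, ], lbl[tr, ],
                               epochs = 200, seed = 2)
  init_mse <- mean((out[va, ] - truth[va, ])^2)
  ref <- aivive:::refine_module(opt, out[va, ], lbl[va, ])
  expect_lt(mean((ref - truth[va, ])^2), 0.5 * init_mse)

  acc <- accept_modules(list(opt), out[va, ], truth[va, ], lbl[va, ])
  expect_true(acc$table$accepted)
  expect_lt(acc$table$rmse_refined, acc$table$rmse_translator)
  expect_length(acc$accepted, 1)
})

test_that("an already-perfect translator leaves nothing to improve", {
  genes <- sprintf("g%02d", 1:4)
  with_seed(5, {
    truth <- matrix(runif(200, 0.2, 0.8), 50, 4, dimnames = list(NULL, genes))
    lbl <- matrix(rbinom(800, 1, 0.25), 50, 16)
  })
  # translator output equals truth: training cannot be worse than doing
  # nothing, and the identity refiner is rejected on the strict-improvement
  # rule (a tie is not an improvement)
  opt <- train_local_optimizer(genes, truth, truth, lbl, epochs = 150,
                               seed = 3)
  expect_lte(opt$history[length(opt$history)], opt$history[1])

  ident <- identity_optimizer(genes)
  acc <- accept_modules(list(ident), truth, truth, lbl)
  expect_false(acc$table$accepted)
  expect_length(acc$accepted, 0)
  expect_error(accept_modules(list(ident), truth[0, , drop = FALSE],
                              truth[0, , drop = FALSE], lbl[0, , drop = FALSE]),
               "empty validation")
})
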