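FULL_GEN_WIDTHS <- c(8192, 7168, 7168, 4096, 4096)
FULL_DISC_WIDTHS <- c(256, 64)

#' Generator and discriminator architecture specifications
#'
#' The generator is a fully connected network that receives the scaled in
#' vitro profile (G values), two 16-bit label vectors (source and target
#' experiment/dose/time/replicate) and a G-dimensional standard Gaussian
#' noise vector: input dimension `2G + 2L`. It has five hidden layers of
#' 8192/7168/7168/4096/4096 units (scaled by `width_factor` and rounded up),
#' LeakyReLU(0.2) activations, dropout 0.8/0.8/0.8/0.4 after hidden layers
#' 1-4, and a sigmoid output of width G. The discriminator consumes a
#' G-dimensional profile through 256/64-unit ReLU layers with dropout 0.5
#' and a single sigmoid unit, and is trained with SGD (lr 1e-4, momentum
#' 0.9) under binary cross-entropy.
#'
#' @param G Gene-panel size.
#' @param L Label length (16).
#' @param width_factor Multiplier in (0, 1] applied to the hidden widths;
#'   1/64 gives the scaled-down desk profile.
#' @return A spec list with `input_dim`, `hidden`, `dropout`, `output_dim`.
#' @export
build_generator <- function(G, L = 16, width_factor = 1) {
  stopifnot(G >= 1, width_factor > 0, width_factor <= 1)
  hidden <- ceiling(width_factor * FULL_GEN_WIDTHS)
  structure(list(input_dim = 2L * G + 2L * L,
                 hidden = hidden,
                 activation = "lrelu", alpha = 0.2,
                 dropout = c(0.8, 0.8, 0.8, 0.4, 0),
                 output_dim = G, output_activation = "sigmoid",
                 G = G, L = L, width_factor = width_factor),
            class = "generator_spec")
}

#' @rdname build_generator
#' @export
build_discriminator <- function(G, width_factor = 1) {
  stopifnot(G >= 1, width_factor > 0, width_factor <= 1)
  structure(list(input_dim = G,
                 hidden = ceiling(width_factor * FULL_DISC_WIDTHS),
                 activation = "relu", dropout = c(0.5, 0.5),
                 output_dim = 1L, output_activation = "sigmoid",
                 optimizer = list(kind = "sgd", lr = 1e-4, momentum = 0.9),
                 G = G, width_factor = width_factor),
            class = "discriminator_spec")
}

spec_to_mlp <- function(spec) {
  sizes <- c(spec$input_dim, spec$hidden, spec$output_dim)
  acts <- c(rep(spec$activation, length(spec$hidden)), spec$output_activation)
  dropout <- c(spec$dropout, 0)[seq_along(acts)]
  mlp_new(sizes, acts, dropout, alpha = spec$alpha %||% 0.2)
}

#' Assemble a generator input vector/batch
#'
#' Concatenates `[scaled profile | source label | target label | noise]`
#' with `noise ~ N(0, 1)` per coordinate, drawn reproducibly from
#' `noise_seed`.
#'
#' @param profile_scaled Matrix (examples x G) or vector of scaled profiles.
#' @param source_label,target_label Matrix (examples x L) or length-L
#'   vector.
#' @param noise_seed Integer seed for the noise block, or `NULL` to draw
#'   from the current RNG stream (used inside training).
#' @return Matrix examples x (2G + 2L).
#' @export
make_generator_input <- function(profile_scaled, source_label, target_label,
                                 noise_seed = NULL) {
  if (is.null(dim(profile_scaled))) profile_scaled <- matrix(profile_scaled, 1)
  if (is.null(dim(source_label))) source_label <- matrix(source_label, 1)
  if (is.null(dim(target_label))) target_label <- matrix(target_label, 1)
  n <- nrow(profile_scaled); G <- ncol(profile_scaled)
  if (nrow(source_label) != n || nrow(target_label) != n)
    stop("label row counts do not match the profile batch")
  if (ncol(source_label) != ncol(target_label))
    stop("source and target labels must have equal length")
  draw <- function() matrix(rnorm(n * G), n, G)
  noise <- if (is.null(noise_seed)) draw() else with_seed(noise_seed, draw())
  cbind(profile_scaled, source_label, target_label, noise)
}

#' Train the cycle-consistent in vitro to in vivo translator
#'
#' Alternates discriminator and generator updates. Two discriminators (one
#' per domain) are trained with binary cross-entropy under SGD with
#' momentum; the two generators (forward vitro-to-vivo and reverse
#' vivo-to-vitro) are trained jointly with Adam on the adversarial loss plus
#' `cycle_weight` times the L1 cycle-reconstruction loss in both directions.
#' All profile inputs must be scaled to `[0, 1]`.
#'
#' @param pairs A scaled `pair_set` (see [scale_pairs()]).
#' @param gen_spec,disc_spec Specs from [build_generator()] /
#'   [build_discriminator()].
#' @param epochs Training epochs (0 returns the untrained state).
#' @param batch_size Minibatch size.
#' @param cycle_weight Weight of the L1 cycle loss.
#' @param gen_lr Adam learning rate for both generators.
#' @param disc_lr SGD learning rate for both discriminators (defaults to
#'   the rate declared in `disc_spec`).
#' @param seed Seed controlling initialization, shuffling, dropout and
#'   noise; training is fully deterministic given it.
#' @param checkpoint_window,checkpoint_tol Passed to [select_checkpoint()].
#' @return A `translator_state` with the four networks, per-epoch loss
#'   history, and the selected `best_epoch`.
#' @export
train_translator <- function(pairs, gen_spec, disc_spec, epochs,
                             batch_size = 128, cycle_weight = 10,
                             gen_lr = 1e-4, disc_lr = NULL, seed = 1,
                             checkpoint_window = 25, checkpoint_tol = 0.05) {
  G <- gen_spec$G
  stopifnot(ncol(pairs$vitro) == G, ncol(pairs$vivo) == G)
  if (n_pairs(pairs) == 0) stop("empty paired training set")
  if (max(pairs$vitro) > 1 + 1e-9 || min(pairs$vitro) < -1e-9)
    stop("pair profiles must be scaled to [0, 1]; see scale_pairs()")
  disc_lr <- disc_lr %||% disc_spec$optimizer$lr

  with_seed(seed, {
    gen_f <- spec_to_mlp(gen_spec)
    gen_r <- spec_to_mlp(gen_spec)
    d_vivo <- spec_to_mlp(disc_spec)
    d_vitro <- spec_to_mlp(disc_spec)
    opt_f <- opt_adam(gen_f, lr = gen_lr)
    opt_r <- opt_adam(gen_r, lr = gen_lr)
    opt_dvo <- opt_sgd_momentum(d_vivo, lr = disc_lr,
                                momentum = disc_spec$optimizer$momentum)
    opt_dvi <- opt_sgd_momentum(d_vitro, lr = disc_lr,
                                momentum = disc_spec$optimizer$momentum)

    n <- n_pairs(pairs)
    hist <- data.frame(epoch = integer(0), d_vivo = numeric(0),
                       d_vitro = numeric(0), adversarial = numeric(0),
                       cycle = numeric(0), generator = numeric(0))
    if (epochs > 0) for (ep in seq_len(epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = batch_size)
      acc <- c(d_vivo = 0, d_vitro = 0, adv = 0, cyc = 0)
      for (st in starts) {
        idx <- ord[st:min(st + batch_size - 1, n)]
        x <- pairs$vitro[idx, , drop = FALSE]
        y <- pairs$vivo[idx, , drop = FALSE]
        s <- pairs$source_label[idx, , drop = FALSE]
        t <- pairs$target_label[idx, , drop = FALSE]
        m <- length(idx)

        fw <- mlp_forward(gen_f, make_generator_input(x, s, t), training = TRUE)
        rv <- mlp_forward(gen_r, make_generator_input(y, t, s), training = TRUE)
        yhat <- fw$out; xhat <- rv$out

        # --- discriminators (generated profiles treated as constants) ---
        upd <- function(net, opt, real, fake) {
          inp <- rbind(real, fake)
          lab <- matrix(c(rep(1, nrow(real)), rep(0, nrow(fake))), ncol = 1)
          f <- mlp_forward(net, inp, training = TRUE)
          loss <- bce_loss(f$out, lab)
          bk <- mlp_backward(net, f$cache, dZ_out = bce_dz(f$out, lab))
          stp <- opt_sgd_step(net, bk$grads, opt)
          list(net = stp$net, opt = stp$state, loss = loss)
        }
        u1 <- upd(d_vivo, opt_dvo, y, yhat)
        d_vivo <- u1$net; opt_dvo <- u1$opt
        u2 <- upd(d_vitro, opt_dvi, x, xhat)
        d_vitro <- u2$net; opt_dvi <- u2$opt

        # --- generators: adversarial + cycle ---
        ones <- matrix(1, m, 1)
        adv_grad <- function(dnet, fake) {
          f <- mlp_forward(dnet, fake, training = TRUE)
          bk <- mlp_backward(dnet, f$cache, dZ_out = bce_dz(f$out, ones))
          list(loss = bce_loss(f$out, ones), dFake = bk$dX)
        }
        av <- adv_grad(d_vivo, yhat)
        ai <- adv_grad(d_vitro, xhat)

        cyc_x <- mlp_forward(gen_r, make_generator_input(yhat, t, s),
                             training = TRUE)
        cyc_y <- mlp_forward(gen_f, make_generator_input(xhat, s, t),
                             training = TRUE)
        l1_x <- mean(abs(cyc_x$out - x))
        l1_y <- mean(abs(cyc_y$out - y))
        dcx <- cycle_weight * sign(cyc_x$out - x) / length(x)
        dcy <- cycle_weight * sign(cyc_y$out - y) / length(y)
        bk_cx <- mlp_backward(gen_r, cyc_x$cache, dOut = dcx)
        bk_cy <- mlp_backward(gen_f, cyc_y$cache, dOut = dcy)

        dyhat <- av$dFake + bk_cx$dX[, seq_len(G), drop = FALSE]
        dxhat <- ai$dFake + bk_cy$dX[, seq_len(G), drop = FALSE]
        bk_f <- mlp_backward(gen_f, fw$cache, dOut = dyhat)
        bk_r <- mlp_backward(gen_r, rv$cache, dOut = dxhat)

        gf <- sum_grads(bk_f$grads, bk_cy$grads)
        gr <- sum_grads(bk_r$grads, bk_cx$grads)
        stp <- opt_adam_step(gen_f, gf, opt_f); gen_f <- stp$net; opt_f <- stp$state
        stp <- opt_adam_step(gen_r, gr, opt_r); gen_r <- stp$net; opt_r <- stp$state

        w <- m / n
        acc <- acc + w * c(u1$loss, u2$loss, av$loss + ai$loss,
                           cycle_weight * (l1_x + l1_y))
      }
      if (!all(is.finite(acc))) stop("NaN/Inf loss at epoch ", ep,
                                     "; lower the learning rates")
      hist[nrow(hist) + 1, ] <- c(ep, acc[1], acc[2], acc[3], acc[4],
                                  acc[3] + acc[4])
    }

    best <- if (nrow(hist)) select_checkpoint(hist$generator,
                                              window = checkpoint_window,
                                              tolerance = checkpoint_tol)
            else NA_integer_
    structure(list(gen_f = gen_f, gen_r = gen_r,
                   d_vivo = d_vivo, d_vitro = d_vitro,
                   gen_spec = gen_spec, disc_spec = disc_spec,
                   history = hist, best_epoch = best, seed = seed,
                   hyper = list(epochs = epochs, batch_size = batch_size,
                                cycle_weight = cycle_weight,
                                gen_lr = gen_lr, disc_lr = disc_lr)),
              class = "translator_state")
  })
}

#' @export
print.translator_state <- function(x, ...) {
  cat("translator_state: G =", x$gen_spec$G,
      "| width factor", x$gen_spec$width_factor,
      "| epochs trained", nrow(x$history),
      "| best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Select a stabilized training epoch from a loss history
#'
#' Returns the first epoch whose trailing window of generator losses has a
#' relative range (max minus min over the window mean) below `tolerance`;
#' when no window stabilizes, falls back to the epoch minimizing the
#' window-smoothed loss.
#'
#' @param loss_history Numeric vector of per-epoch generator losses.
#' @param window Trailing window length (epochs).
#' @param tolerance Relative-range threshold.
#' @return Integer epoch index.
#' @export
select_checkpoint <- function(loss_history, window = 25, tolerance = 0.05) {
  n <- length(loss_history)
  if (n == 0) stop("empty loss history")
  if (!all(is.finite(loss_history))) stop("non-finite losses in history")
  window <- min(window, n)
  for (i in window:n) {
    w <- loss_history[(i - window + 1):i]
    if ((max(w) - min(w)) < tolerance * mean(abs(w))) return(i)
  }
  sm <- stats::filter(loss_history, rep(1 / window, window), sides = 1)
  which.min(as.numeric(sm))
}

#' Translate in vitro profiles into synthetic in vivo profiles
#'
#' Scales the input with the bundle's in vitro scaler, runs the forward
#' generator (dropout off, noise fixed by `noise_seed`), optionally applies
#' the accepted per-module local optimizers, and inverts the in vivo scaler
#' so outputs are on the log2 scale. By construction every output lies
#' within the per-gene training min/max of the in vivo data.
#'
#' @param bundle An `aivive_bundle` from [make_bundle()].
#' @param vitro Matrix genes x samples (or named per-gene vector) of log2
#'   in vitro profiles.
#' @param source_label,target_label Length-16 labels, or matrices with one
#'   row per sample.
#' @param noise_seed Integer seed fixing the Gaussian noise block.
#' @param apply_optimizers Whether to apply the bundle's accepted local
#'   optimizers.
#' @return Matrix genes x samples of synthetic in vivo log2 profiles.
#' @export
translate <- function(bundle, vitro, source_label, target_label,
                      noise_seed = 1, apply_optimizers = TRUE) {
  stopifnot(inherits(bundle, "aivive_bundle"))
  vec <- is.null(dim(vitro))
  if (vec) vitro <- matrix(vitro, ncol = 1, dimnames = list(names(vitro), NULL))
  xs <- t(scale_expr(vitro, bundle$scaler_vitro))
  n <- nrow(xs)
  if (is.null(dim(source_label))) source_label <-
    matrix(source_label, n, length(source_label), byrow = TRUE)
  if (is.null(dim(target_label))) target_label <-
    matrix(target_label, n, length(target_label), byrow = TRUE)
  inp <- make_generator_input(xs, source_label, target_label, noise_seed)
  out <- mlp_forward(bundle$state$gen_f, inp, training = FALSE)$out
  if (apply_optimizers && length(bundle$optimizers))
    out <- apply_local_optimizers(out, bundle$optimizers, target_label,
                                  bundle$genes)
  res <- unscale_expr(t(out), bundle$scaler_vivo)
  rownames(res) <- bundle$genes
  colnames(res) <- colnames(vitro)
  if (vec) res[, 1] else res
}

#' Bundle a trained translator with its scalers and optimizers
#'
#' @param state A `translator_state`.
#' @param scaler_vitro,scaler_vivo Per-gene scalers fitted on training data.
#' @param genes Gene identifiers (panel order).
#' @param optimizers Accepted local optimizers (possibly empty list).
#' @param time_vocab Per-system time vocabularies used for labels.
#' @return An `aivive_bundle`.
#' @export
make_bundle <- function(state, scaler_vitro, scaler_vivo, genes,
                        optimizers = list(),
                        time_vocab = default_time_vocab()) {
  structure(list(state = state, scaler_vitro = scaler_vitro,
                 scaler_vivo = scaler_vivo, genes = genes,
                 optimizers = optimizers, time_vocab = time_vocab),
            class = "aivive_bundle")
}

#' @rdname make_bundle
#' @param bundle An `aivive_bundle`.
#' @param path File path for the serialized bundle.
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname make_bundle
#' @export
load_bundle <- function(path) {
  b <- readRDS(path)
  stopifnot(inherits(b, "aivive_bundle"))
  b
}

#' Translate every pair of a pair set in batch
#'
#' Convenience wrapper over [translate()] operating on a raw (unscaled)
#' `pair_set`: each in vitro profile is translated toward its pair's target
#' label.
#'
#' @param bundle An `aivive_bundle`.
#' @param pairs A `pair_set` on the log2 scale.
#' @param noise_seed Seed for the noise block.
#' @param apply_optimizers Whether to apply accepted local optimizers.
#' @return Matrix pairs x genes of synthetic in vivo log2 profiles.
#' @export
translate_pairs <- function(bundle, pairs, noise_seed = 1,
                            apply_optimizers = TRUE) {
  out <- translate(bundle, t(pairs$vitro), pairs$source_label,
                   pairs$target_label, noise_seed = noise_seed,
                   apply_optimizers = apply_optimizers)
  t(out)
}
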