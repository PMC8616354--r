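#' Encoder-decoder network configuration
#'
#' Desk-scale configuration of the U-net-style segmenter: a contracting path
#' of 3x3 conv + ReLU blocks with 2x2 max-pooling, a bottleneck, and an
#' expanding path with nearest-neighbour upsampling and skip connections at
#' every resolution level, closed by a 1x1 convolution and a sigmoid. The
#' full-scale instrument-resolution variant (2048 x 2048 input) is the same
#' architecture with a larger `input_size`/`depth`; training it is a compute
#' concern, not a code path.
#'
#' @param input_size square input side in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param depth number of resolution levels (2 or 3 at desk scale).
#' @param base_filters channels of the first level (doubled per level).
#' @param max_epochs training epoch budget; the returned model is the
#'   snapshot with minimum validation loss within this budget.
#' @param learning_rate Adam step size.
#' @param augment named logical toggles `rotation`, `flipping`, `resizing`.
#' @param val_fraction fraction of pairs held out for validation (by image).
#' @param seed integer; controls initialization, the train/validation split,
#'   shuffling and augmentation draws, making training reproducible
#'   (single-threaded deterministic kernels).
#' @return A `net_config` object.
#' @export
net_config <- function(input_size = 64, depth = 2, base_filters = 8,
                       max_epochs = 30, learning_rate = 1e-3,
                       augment = c(rotation = TRUE, flipping = TRUE,
                                   resizing = FALSE),
                       val_fraction = 0.2, seed = 1L) {
  if (base_filters < 1) stop("config error: base_filters must be >= 1")
  if (depth < 2) stop("config error: depth must be >= 2")
  if (input_size %% 2^(depth - 1) != 0)
    stop("config error: input_size must be divisible by 2^(depth-1)")
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, augment = augment,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "net_config")
}

he_init <- function(fan_in, n_out) {
  matrix(rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out)
}

# weight structure for the generic-depth U-net; consumes the RNG stream
unet_init <- function(cfg) {
  L <- cfg$depth - 1
  base <- cfg$base_filters
  enc <- vector("list", L)
  for (l in 1:L) {
    cin <- if (l == 1) 1 else base * 2^(l - 2)
    cout <- base * 2^(l - 1)
    enc[[l]] <- list(Wa = he_init(9 * cin, cout), ba = rep(0, cout),
                     Wb = he_init(9 * cout, cout), bb = rep(0, cout))
  }
  cb <- base * 2^(L - 1)
  bott <- list(Wa = he_init(9 * cb, 2 * cb), ba = rep(0, 2 * cb),
               Wb = he_init(9 * 2 * cb, 2 * cb), bb = rep(0, 2 * cb))
  dec <- vector("list", L)
  for (l in 1:L) {
    cskip <- base * 2^(l - 1)
    cin <- cskip + base * 2^l
    dec[[l]] <- list(Wa = he_init(9 * cin, cskip), ba = rep(0, cskip),
                     Wb = he_init(9 * cskip, cskip), bb = rep(0, cskip))
  }
  out <- list(W = he_init(base, 1), b = 0)
  list(enc = enc, bott = bott, dec = dec, out = out)
}

relu_mask <- function(d, out) d * (out > 0)

conv_relu <- function(a, W, b) {
  out <- cpp_conv2d(a, W, b, 3L)
  out[out < 0] <- 0
  out
}

# forward pass; x is an H x W x 1 array with H, W divisible by 2^(depth-1)
unet_forward <- function(wts, x, keep_cache = FALSE) {
  L <- length(wts$enc)
  cc <- list(enc = vector("list", L), dec = vector("list", L))
  a <- x
  for (l in 1:L) {
    o1 <- conv_relu(a, wts$enc[[l]]$Wa, wts$enc[[l]]$ba)
    o2 <- conv_relu(o1, wts$enc[[l]]$Wb, wts$enc[[l]]$bb)
    pm <- cpp_maxpool2(o2)
    if (keep_cache)
      cc$enc[[l]] <- list(in1 = a, out1 = o1, out2 = o2, idx = pm$idx)
    else cc$enc[[l]] <- list(out2 = o2)
    a <- pm$out
  }
  b1 <- conv_relu(a, wts$bott$Wa, wts$bott$ba)
  b2 <- conv_relu(b1, wts$bott$Wb, wts$bott$bb)
  if (keep_cache) cc$bott <- list(in1 = a, out1 = b1, out2 = b2)
  a <- b2
  for (l in L:1) {
    up <- cpp_upsample2(a)
    skip <- cc$enc[[l]]$out2
    d <- dim(skip)
    cat_in <- array(c(skip, up), dim = c(d[1], d[2], d[3] + dim(up)[3]))
    o1 <- conv_relu(cat_in, wts$dec[[l]]$Wa, wts$dec[[l]]$ba)
    o2 <- conv_relu(o1, wts$dec[[l]]$Wb, wts$dec[[l]]$bb)
    if (keep_cache)
      cc$dec[[l]] <- list(in1 = cat_in, out1 = o1, out2 = o2, nskip = d[3])
    a <- o2
  }
  logits <- cpp_conv2d(a, wts$out$W, wts$out$b, 1L)
  if (keep_cache) cc$final_in <- a
  prob <- 1 / (1 + exp(-logits[, , 1]))
  list(prob = prob, cache = if (keep_cache) cc else NULL)
}

# mean pixel-wise binary cross-entropy and its logit gradient
bce_loss <- function(prob, y) {
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# backward pass given the logit gradient (H x W matrix)
unet_backward <- function(wts, cc, dlogit) {
  L <- length(wts$enc)
  grads <- list(enc = vector("list", L), dec = vector("list", L))
  dl <- array(dlogit, dim = c(dim(dlogit), 1))
  g <- cpp_conv2d_backward(cc$final_in, wts$out$W, dl, 1L)
  grads$out <- list(W = g$dW, b = as.numeric(g$db))
  da <- g$dx
  dskip <- vector("list", L)
  for (l in 1:L) {
    e <- cc$dec[[l]]
    d2 <- relu_mask(da, e$out2)
    g2 <- cpp_conv2d_backward(e$out1, wts$dec[[l]]$Wb, d2, 3L)
    d1 <- relu_mask(g2$dx, e$out1)
    g1 <- cpp_conv2d_backward(e$in1, wts$dec[[l]]$Wa, d1, 3L)
    grads$dec[[l]] <- list(Wa = g1$dW, ba = as.numeric(g1$db),
                           Wb = g2$dW, bb = as.numeric(g2$db))
    dcat <- g1$dx
    ns <- e$nskip
    dskip[[l]] <- dcat[, , seq_len(ns), drop = FALSE]
    dup <- dcat[, , (ns + 1):dim(dcat)[3], drop = FALSE]
    da <- cpp_upsample2_backward(dup)
  }
  b <- cc$bott
  d2 <- relu_mask(da, b$out2)
  g2 <- cpp_conv2d_backward(b$out1, wts$bott$Wb, d2, 3L)
  d1 <- relu_mask(g2$dx, b$out1)
  g1 <- cpp_conv2d_backward(b$in1, wts$bott$Wa, d1, 3L)
  grads$bott <- list(Wa = g1$dW, ba = as.numeric(g1$db),
                     Wb = g2$dW, bb = as.numeric(g2$db))
  da <- g1$dx
  for (l in L:1) {
    e <- cc$enc[[l]]
    d2 <- cpp_maxpool2_backward(da, e$idx) + dskip[[l]]
    d2 <- relu_mask(d2, e$out2)
    g2 <- cpp_conv2d_backward(e$out1, wts$enc[[l]]$Wb, d2, 3L)
    d1 <- relu_mask(g2$dx, e$out1)
    g1 <- cpp_conv2d_backward(e$in1, wts$enc[[l]]$Wa, d1, 3L)
    grads$enc[[l]] <- list(Wa = g1$dW, ba = as.numeric(g1$db),
                           Wb = g2$dW, bb = as.numeric(g2$db))
    da <- g1$dx
  }
  grads
}

zero_like <- function(w) rapply(w, function(x) x * 0, how = "replace")

adam_step <- function(w, g, m, v, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.list(w)) {
    keys <- if (!is.null(names(w))) names(w) else seq_along(w)
    r <- lapply(keys, function(k)
      adam_step(w[[k]], g[[k]], m[[k]], v[[k]], lr, t, beta1, beta2, eps))
    names(r) <- names(w)
    list(w = lapply(r, `[[`, "w"), m = lapply(r, `[[`, "m"),
         v = lapply(r, `[[`, "v"))
  } else {
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mh <- m2 / (1 - beta1^t)
    vh <- v2 / (1 - beta2^t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
}

# square reflect-pad image and mask to a side divisible by 2^(depth-1)
net_target_side <- function(dims, cfg) {
  f <- 2^(cfg$depth - 1)
  as.integer(f * ceiling(max(dims, cfg$input_size) / f))
}

pair_to_arrays <- function(pair, cfg) {
  px <- normalize_minmax(as_pixels(pair$phase))
  mk <- as_pixels(pair$truth)
  if (!identical(dim(px), dim(mk)))
    stop("training pair image and mask dimensions differ")
  side <- net_target_side(dim(px), cfg)
  orig <- dim(px)
  px <- as_pixels(pad_reflect(px, side))
  mkp <- as_pixels(pad_reflect(mk * 1, side)) > 0.5
  list(x = array(px, dim = c(side, side, 1)), y = mkp * 1, orig = orig)
}

#' Build and train the encoder-decoder segmenter
#'
#' Trains on phase-contrast/ground-truth pairs with pixel-wise binary
#' cross-entropy and Adam (one image per update), using a seeded 80/20
#' train/validation split by image, per-image augmentation draws, and
#' early-model selection: the returned model is the weight snapshot at the
#' epoch of minimum validation loss.
#'
#' @param pairs list of training pairs, each `list(phase =, truth =)` with a
#'   [gray_image()] (or matrix) and a [binary_mask()] (or logical matrix) of
#'   identical dimensions. At least 2 pairs.
#' @param cfg a [net_config()].
#' @param verbose print per-epoch losses.
#' @return A `platelet_unet` object: `weights`, `cfg`, `history` (data frame
#'   with `epoch`, `train_loss`, `val_loss`), `best_epoch`.
#' @export
build_and_train <- function(pairs, cfg = net_config(), verbose = FALSE) {
  if (length(pairs) < 2)
    stop("need at least 2 training pairs for a train/validation split")
  with_local_seed(cfg$seed, {
    wts <- unet_init(cfg)
    data <- lapply(pairs, pair_to_arrays, cfg = cfg)
    n <- length(data)
    n_val <- max(1, round(cfg$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(train_idx) == 0) stop("validation split left no training pairs")
    m <- zero_like(wts); v <- zero_like(wts)
    t <- 0L
    best <- list(loss = Inf, wts = wts, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    any_aug <- any(unlist(cfg$augment))
    for (epoch in seq_len(cfg$max_epochs)) {
      tr_losses <- numeric(0)
      for (i in sample(train_idx)) {
        d <- data[[i]]
        if (any_aug) {
          ap <- augment_pair(list(phase = d$x[, , 1], truth = d$y > 0.5),
                             toggles = cfg$augment)
          d <- list(x = array(ap$phase, dim = dim(d$x)), y = ap$truth * 1)
        }
        fw <- unet_forward(wts, d$x, keep_cache = TRUE)
        tr_losses <- c(tr_losses, bce_loss(fw$prob, d$y))
        dlogit <- (fw$prob - d$y) / length(d$y)
        grads <- unet_backward(wts, fw$cache, dlogit)
        t <- t + 1L
        st <- adam_step(wts, grads, m, v, cfg$learning_rate, t)
        wts <- st$w; m <- st$m; v <- st$v
      }
      val_loss <- mean(vapply(val_idx, function(i) {
        fw <- unet_forward(wts, data[[i]]$x)
        bce_loss(fw$prob, data[[i]]$y)
      }, numeric(1)))
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(tr_losses),
                                     val_loss = val_loss))
      if (val_loss < best$loss)
        best <- list(loss = val_loss, wts = wts, epoch = epoch)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        mean(tr_losses), val_loss))
    }
    structure(list(weights = best$wts, cfg = cfg, history = hist,
                   best_epoch = best$epoch),
              class = "platelet_unet")
  })
}

#' @export
print.platelet_unet <- function(x, ...) {
  cat(sprintf(
    "<platelet_unet depth %d, %d base filters, best epoch %d (val loss %.5f)>\n",
    x$cfg$depth, x$cfg$base_filters, x$best_epoch,
    min(x$history$val_loss)))
  invisible(x)
}

#' Segment an image with a trained model
#'
#' Applies the prediction contract: min-max normalize, reflection-pad to a
#' compatible square, forward pass, crop back to native resolution, and
#' threshold the foreground probability at 0.5.
#'
#' @param object a trained `platelet_unet`.
#' @param img a [gray_image()] or numeric matrix.
#' @param ... unused.
#' @return A [binary_mask()] at the native resolution of `img`.
#' @export
predict.platelet_unet <- function(object, img, ...) {
  px <- as_pixels(img)
  side <- net_target_side(dim(px), object$cfg)
  padded <- as_pixels(pad_reflect(normalize_minmax(px), side))
  x <- array(padded, dim = c(side, side, 1))
  fw <- unet_forward(object$weights, x)
  prob <- crop_back(fw$prob, dim(px))
  ps <- if (inherits(img, "gray_image")) img$pixel_size else 1
  binary_mask(prob > 0.5, ps)
}
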