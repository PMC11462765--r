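# Compact two-block convolutional classifier:
#   [Conv2D -> BatchNorm -> ReLU -> MaxPool] x 2 -> Flatten
#   -> FullyConnected(fc_units) -> ReLU -> FullyConnected(2) -> Softmax
# trained with Adam on the cross-entropy, early-stopped on validation loss.

#' Model configuration for the two-block convolutional classifier
#'
#' @param input_dims `c(width, height)` of the input montages in pixels.
#'   The study standard is 1200 x 900; a reduced-resolution mode (montages
#'   downscaled after standardization, e.g. 300 x 225) is supported for
#'   CPU-bound runs.
#' @param blocks List of exactly two conv blocks, each
#'   `c(filters, kernel_size, stride, pool_size)`. Kernels must be odd
#'   ("same" padding is used).
#' @param fc_units Width of the fully connected layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation loss (epochs).
#' @param warmup_steps Linear learning-rate warmup length in optimizer steps;
#'   guards the high-fan-in flatten-to-dense layer against early ReLU death.
#' @param clip_norm Global gradient-norm clipping threshold.
#' @param class_weights Optional `c(non_case, case)` loss weights (default
#'   unweighted, so class imbalance is reflected in the fit).
#' @param seed Integer seed fixing initialization and data order.
#' @return A validated list of class `dcnn_config`.
#' @export
dcnn_config <- function(input_dims = c(1200, 900),
                        blocks = list(c(8, 3, 1, 2), c(16, 3, 1, 2)),
                        fc_units = 32, learning_rate = 1e-3, batch_size = 16,
                        epochs = 50, patience = 5, warmup_steps = 25,
                        clip_norm = 5, class_weights = NULL, seed = 1) {
  if (length(blocks) != 2L)
    em_stop("em_config_error", "the architecture has exactly two principal blocks, got %d",
            length(blocks))
  for (b in blocks) {
    if (length(b) != 4L || any(b < 1) || any(b != floor(b)))
      em_stop("em_config_error", "each block must be c(filters, kernel, stride, pool) of positive integers")
    if (b[2] %% 2 == 0)
      em_stop("em_config_error", "kernel sizes must be odd (same-padding convolution)")
  }
  cfg <- structure(
    list(input_dims = input_dims, blocks = blocks, fc_units = fc_units,
         learning_rate = learning_rate, batch_size = batch_size,
         epochs = epochs, patience = patience, warmup_steps = warmup_steps,
         clip_norm = clip_norm, class_weights = class_weights, seed = seed),
    class = "dcnn_config"
  )
  cfg$shapes <- dcnn_shapes(cfg)  # validates feasibility
  cfg
}

# Spatial dimensions through the network; errors when a stage collapses.
dcnn_shapes <- function(config) {
  h <- config$input_dims[2]; w <- config$input_dims[1]
  cin <- 1L
  shapes <- list()
  for (i in 1:2) {
    b <- config$blocks[[i]]
    f <- b[1]; k <- b[2]; s <- b[3]; p <- b[4]
    pad <- (k - 1) / 2
    if (k > h + 2 * pad || k > w + 2 * pad)
      em_stop("em_config_error", "kernel %d too large for input %dx%d", k, w, h)
    hc <- floor((h + 2 * pad - k) / s) + 1
    wc <- floor((w + 2 * pad - k) / s) + 1
    hp <- floor(hc / p); wp <- floor(wc / p)
    if (hp < 1 || wp < 1)
      em_stop("em_config_error", "block %d reduces the %dx%d input below 1 pixel", i, w, h)
    shapes[[i]] <- list(cin = cin, filters = f, kernel = k, stride = s,
                        pool = p, pad = pad, conv = c(hc, wc), out = c(hp, wp))
    h <- hp; w <- wp; cin <- f
  }
  shapes$flat <- h * w * cin
  shapes
}

#' Closed-form trainable parameter count
#'
#' Conv block: `k^2 * c_in * f + f` weights plus `2 f` batch-norm scale/shift
#' terms; fully connected: `(flat + 1) * fc_units`; output: `(fc_units + 1) * 2`.
#'
#' @param config A [dcnn_config()].
#' @return Integer parameter count.
#' @export
dcnn_param_count <- function(config) {
  sh <- config$shapes %||% dcnn_shapes(config)
  total <- 0
  for (i in 1:2) {
    s <- sh[[i]]
    total <- total + s$kernel^2 * s$cin * s$filters + s$filters + 2 * s$filters
  }
  total + (sh$flat + 1) * config$fc_units + (config$fc_units + 1) * 2
}

he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)

#' Build an untrained classifier from a configuration
#'
#' Initializes weights (He-normal), batch-norm parameters, and running
#' statistics. The returned model predicts (uninformatively) before
#' training.
#'
#' @param config A [dcnn_config()].
#' @return An object of class `echo_dcnn` with `trained = FALSE`.
#' @export
dcnn_build <- function(config) {
  stopifnot(inherits(config, "dcnn_config"))
  sh <- config$shapes
  params <- with_seed(config$seed, {
    p <- list()
    for (i in 1:2) {
      s <- sh[[i]]
      p[[paste0("W", i)]] <- he_init(c(s$kernel, s$kernel, s$cin, s$filters),
                                     s$kernel^2 * s$cin)
      p[[paste0("b", i)]] <- numeric(s$filters)
      p[[paste0("gamma", i)]] <- rep(1, s$filters)
      p[[paste0("beta", i)]] <- numeric(s$filters)
    }
    p$Wfc <- matrix(stats::rnorm(config$fc_units * sh$flat, 0, sqrt(2 / sh$flat)),
                    config$fc_units, sh$flat)
    p$bfc <- numeric(config$fc_units)
    p$Wout <- matrix(stats::rnorm(2 * config$fc_units, 0, sqrt(2 / config$fc_units)),
                     2, config$fc_units)
    p$bout <- numeric(2)
    p
  })
  running <- list(mean1 = numeric(sh[[1]]$filters), var1 = rep(1, sh[[1]]$filters),
                  mean2 = numeric(sh[[2]]$filters), var2 = rep(1, sh[[2]]$filters))
  structure(
    list(config = config, params = params, running = running,
         n_params = dcnn_param_count(config), trained = FALSE, history = NULL),
    class = "echo_dcnn"
  )
}

BN_EPS <- 1e-5

bn_stats <- function(z) {
  d <- dim(z); hw <- d[1] * d[2]; f <- d[3]; n <- d[4]
  cm <- .colMeans(z, hw, f * n)
  cm2 <- .colMeans(z * z, hw, f * n)
  mu <- rowMeans(matrix(cm, f, n))
  list(mu = mu, var = pmax(0, rowMeans(matrix(cm2, f, n)) - mu^2))
}

dcnn_forward <- function(model, x4, train = FALSE) {
  cfg <- model$config; sh <- cfg$shapes; p <- model$params
  cache <- list(x = x4)
  a <- x4
  for (i in 1:2) {
    s <- sh[[i]]
    z <- conv_fwd(a, p[[paste0("W", i)]], p[[paste0("b", i)]], s$stride, s$pad)
    if (train) {
      st <- bn_stats(z)
    } else {
      st <- list(mu = model$running[[paste0("mean", i)]],
                 var = model$running[[paste0("var", i)]])
    }
    gamma <- p[[paste0("gamma", i)]]
    scale <- gamma / sqrt(st$var + BN_EPS)
    r <- bn_fwd_relu(z, scale, p[[paste0("beta", i)]] - st$mu * scale)
    pl <- pool_fwd(r, s$pool)
    cache[[paste0("conv_in", i)]] <- a
    cache[[paste0("z", i)]] <- z
    cache[[paste0("bn_stats", i)]] <- st
    cache[[paste0("relu_out", i)]] <- r
    cache[[paste0("pool_arg", i)]] <- pl$argmax
    cache[[paste0("pool_in_dim", i)]] <- dim(r)
    a <- pl$y
  }
  n <- dim(x4)[4]
  xf <- matrix(a, nrow = sh$flat, ncol = n)
  afc <- p$Wfc %*% xf + p$bfc
  rfc <- pmax(afc, 0)
  logits <- p$Wout %*% rfc + p$bout
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  prob <- sweep(e, 2, colSums(e), "/")
  cache$xf <- xf; cache$afc <- afc; cache$rfc <- rfc; cache$prob <- prob
  cache$pool_out_dim <- dim(a)
  cache
}

# y: logical is-case; returns loss and parameter gradients
dcnn_backward <- function(model, cache, y, class_weights = NULL) {
  cfg <- model$config; sh <- cfg$shapes; p <- model$params
  n <- length(y)
  prob <- cache$prob
  cls <- ifelse(y, 2L, 1L)
  wts <- if (is.null(class_weights)) rep(1, n) else class_weights[cls]
  py <- prob[cbind(cls, seq_len(n))]
  loss <- -sum(wts * log(pmax(py, 1e-12))) / n

  onehot <- matrix(0, 2, n)
  onehot[cbind(cls, seq_len(n))] <- 1
  dlogits <- sweep(prob - onehot, 2, wts / n, "*")

  g <- list()
  g$Wout <- dlogits %*% t(cache$rfc)
  g$bout <- rowSums(dlogits)
  drfc <- t(p$Wout) %*% dlogits
  dafc <- drfc * (cache$afc > 0)
  g$Wfc <- dafc %*% t(cache$xf)
  g$bfc <- rowSums(dafc)
  dxf <- t(p$Wfc) %*% dafc
  da <- array(dxf, dim = cache$pool_out_dim)

  for (i in 2:1) {
    s <- sh[[i]]
    dr <- pool_bwd(cache[[paste0("pool_arg", i)]], da,
                   as.integer(cache[[paste0("pool_in_dim", i)]]))
    dzn <- relu_mask_mul(dr, cache[[paste0("relu_out", i)]])
    st <- cache[[paste0("bn_stats", i)]]
    bb <- bn_bwd(dzn, cache[[paste0("z", i)]], st$mu,
                 1 / sqrt(st$var + BN_EPS), p[[paste0("gamma", i)]])
    g[[paste0("gamma", i)]] <- bb$dgamma
    g[[paste0("beta", i)]] <- bb$dbeta
    cb <- conv_bwd(cache[[paste0("conv_in", i)]], p[[paste0("W", i)]], bb$dz,
                   s$stride, s$pad)
    g[[paste0("W", i)]] <- cb$dw
    g[[paste0("b", i)]] <- cb$db
    da <- cb$dx
  }
  list(loss = loss, grads = g)
}

adam_step <- function(state, params, grads, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gr * 0
      state$v[[nm]] <- gr * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    mh <- state$m[[nm]] / (1 - b1^t)
    vh <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

as_x4 <- function(x) {
  if (is.list(x) && !is.array(x)) x <- simplify2array(x)
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) == 3L) {
    x <- array(x, dim = c(d[1], d[2], 1L, d[3]))
  } else if (length(d) != 4L) {
    em_stop("em_input_error", "montage input must be h x w [x n] array or list of matrices")
  }
  x
}

index_images <- function(x, idx) {
  x <- as_x4(x)
  x[, , , idx, drop = FALSE]
}

eval_loss <- function(model, x4, y, batch_size) {
  n <- dim(x4)[4]
  total <- 0
  for (st in seq(1, n, by = batch_size)) {
    en <- min(st + batch_size - 1, n)
    cache <- dcnn_forward(model, x4[, , , st:en, drop = FALSE], train = FALSE)
    cls <- ifelse(y[st:en], 2L, 1L)
    py <- cache$prob[cbind(cls, seq_along(st:en))]
    total <- total + sum(-log(pmax(py, 1e-12)))
  }
  total / n
}

#' Fit the two-block convolutional cardiomyopathy classifier
#'
#' Trains on grayscale montages (pixel values are scaled to `[0, 1]`
#' internally) by minimizing the cross-entropy with Adam. Validation loss is
#' monitored every epoch and the weights of the best-validation epoch are
#' returned (early stopping with the configured patience). When no
#' validation set is supplied, a stratified 15% of the training data is
#' held out for monitoring.
#'
#' @param x Training montages: `h x w x n` array (or list of matrices).
#' @param y Labels (case/non-case in any accepted coding).
#' @param x_val,y_val Optional validation set in the same formats.
#' @param config A [dcnn_config()]; its `input_dims` must match the montage
#'   dimensions.
#' @param verbose Print per-epoch losses.
#' @return An `echo_dcnn` model with `trained = TRUE` and a `history`
#'   data.frame of per-epoch train/validation loss.
#' @export
dcnn_fit <- function(x, y, x_val = NULL, y_val = NULL, config = dcnn_config(),
                     verbose = FALSE) {
  x4 <- as_x4(x)
  y <- as_case(y)
  if (dim(x4)[4] != length(y))
    em_stop("em_input_error", "number of montages and labels disagree")
  if (dim(x4)[1] != config$input_dims[2] || dim(x4)[2] != config$input_dims[1])
    em_stop("em_input_error", "montages are %dx%d but config expects %dx%d",
            dim(x4)[2], dim(x4)[1], config$input_dims[1], config$input_dims[2])
  if (length(unique(y)) < 2L)
    em_stop("em_degenerate_data_error", "training set contains a single class")
  # dataset-level input standardization (stored with the model, applied at
  # inference): zero-mean unit-variance inputs keep the first Adam steps on
  # a sensible scale regardless of how dark the masked montages are
  norm <- list(mean = mean(x4), sd = max(stats::sd(x4), 1e-6))
  x4 <- (x4 - norm$mean) / norm$sd

  with_seed(config$seed + 1L, {
    if (is.null(x_val)) {
      hold <- unlist(lapply(c(TRUE, FALSE), function(lv) {
        ids <- which(y == lv)
        sample(ids, max(1, round(0.15 * length(ids))))
      }))
      x_val4 <- x4[, , , hold, drop = FALSE]; y_val <- y[hold]
      x4 <- x4[, , , -hold, drop = FALSE]; y <- y[-hold]
    } else {
      x_val4 <- (as_x4(x_val) - norm$mean) / norm$sd
      y_val <- as_case(y_val)
    }
    if (length(unique(y)) < 2L)
      em_stop("em_degenerate_data_error", "training set contains a single class after validation holdout")

    model <- dcnn_build(config)
    state <- list(m = list(), v = list())
    n <- dim(x4)[4]
    best <- list(val = Inf, params = model$params, running = model$running, epoch = 0)
    hist <- NULL
    t_step <- 0
    wait <- 0
    momentum <- 0.9

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batch <- 0
      for (st in seq(1, n, by = config$batch_size)) {
        en <- min(st + config$batch_size - 1, n)
        ids <- ord[st:en]
        xb <- x4[, , , ids, drop = FALSE]
        cache <- dcnn_forward(model, xb, train = TRUE)
        for (i in 1:2) {
          bs <- cache[[paste0("bn_stats", i)]]
          model$running[[paste0("mean", i)]] <-
            momentum * model$running[[paste0("mean", i)]] + (1 - momentum) * bs$mu
          model$running[[paste0("var", i)]] <-
            momentum * model$running[[paste0("var", i)]] + (1 - momentum) * bs$var
        }
        bk <- dcnn_backward(model, cache, y[ids], config$class_weights)
        t_step <- t_step + 1
        gn <- sqrt(sum(vapply(bk$grads, function(g) sum(g^2), 0)))
        if (is.finite(gn) && gn > config$clip_norm)
          bk$grads <- lapply(bk$grads, function(g) g * (config$clip_norm / gn))
        lr_t <- config$learning_rate *
          min(1, t_step / max(1, config$warmup_steps))
        up <- adam_step(state, model$params, bk$grads, lr_t, t_step)
        state <- up$state; model$params <- up$params
        ep_loss <- ep_loss + bk$loss; n_batch <- n_batch + 1
      }
      val_loss <- eval_loss(model, x_val4, y_val, config$batch_size)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n_batch,
                                     val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch, ep_loss / n_batch, val_loss))
      if (val_loss < best$val - 1e-6) {
        best <- list(val = val_loss, params = model$params,
                     running = model$running, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= config$patience) break
      }
    }
    model$params <- best$params
    model$running <- best$running
    model$norm <- norm
    model$trained <- TRUE
    model$history <- hist
    model$best_epoch <- best$epoch
    model
  })
}

#' Predict case probabilities for montages
#'
#' @param object A fitted (or freshly built) `echo_dcnn`.
#' @param newdata Montages: `h x w x n` array or list of matrices
#'   (0-255 grayscale).
#' @param type `"prob"` for an `n x 2` probability matrix (columns
#'   `non_case`, `case`), `"class"` for thresholded labels
#'   (case iff `p_case >= 0.5`).
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return Probability matrix or character vector of labels.
#' @export
predict.echo_dcnn <- function(object, newdata, type = c("prob", "class"),
                              batch_size = 32, ...) {
  type <- match.arg(type)
  x4 <- as_x4(newdata)
  norm <- object$norm %||% list(mean = 127.5, sd = 73.9)  # nominal 0-255 scale
  x4 <- (x4 - norm$mean) / norm$sd
  if (dim(x4)[1] != object$config$input_dims[2] ||
      dim(x4)[2] != object$config$input_dims[1])
    em_stop("em_input_error", "montage dims %dx%d do not match model input %dx%d",
            dim(x4)[2], dim(x4)[1],
            object$config$input_dims[1], object$config$input_dims[2])
  n <- dim(x4)[4]
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("non_case", "case")))
  for (st in seq(1, n, by = batch_size)) {
    en <- min(st + batch_size - 1, n)
    cache <- dcnn_forward(object, x4[, , , st:en, drop = FALSE], train = FALSE)
    out[st:en, ] <- t(cache$prob)
  }
  if (type == "class") {
    ifelse(out[, "case"] >= 0.5, "CASE", "NON_CASE")
  } else {
    out
  }
}

#' @export
print.echo_dcnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<echo_dcnn> input %dx%d, blocks %s, fc %d | %s parameters | %s\n",
              cfg$input_dims[1], cfg$input_dims[2],
              paste(vapply(cfg$blocks, function(b) sprintf("%df k%d", b[1], b[2]),
                           character(1)), collapse = " + "),
              cfg$fc_units, format(x$n_params, big.mark = ","),
              if (x$trained) sprintf("trained (best epoch %d)", x$best_epoch)
              else "untrained"))
  invisible(x)
}

#' @export
summary.echo_dcnn <- function(object, ...) {
  print(object)
  sh <- object$config$shapes
  for (i in 1:2)
    cat(sprintf("  block %d: conv %dx%d -> %dx%dx%d, pool -> %dx%dx%d\n", i,
                sh[[i]]$kernel, sh[[i]]$kernel,
                sh[[i]]$conv[2], sh[[i]]$conv[1], sh[[i]]$filters,
                sh[[i]]$out[2], sh[[i]]$out[1], sh[[i]]$filters))
  cat(sprintf("  flatten: %d -> fc %d -> 2 (softmax)\n", sh$flat, object$config$fc_units))
  if (!is.null(object$history)) {
    cat(sprintf("  history: %d epochs, final val loss %.4f\n",
                nrow(object$history), object$history$val_loss[nrow(object$history)]))
  }
  invisible(object)
}

#' @export
coef.echo_dcnn <- function(object, ...) object$params

#' @export
plot.echo_dcnn <- function(x, ...) {
  if (is.null(x$history)) em_stop("em_input_error", "model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
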