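#' Clipped binary cross-entropy between probability sequences
#'
#' The supervision objective for heartbeat-probability maps. For soft labels
#' the raw cross-entropy never reaches zero, so the constant entropy of the
#' label is subtracted (equivalently, this is the binary KL divergence);
#' the loss is then 0 exactly when `y == y_hat` and strictly positive
#' otherwise, and the constant does not affect gradients. Each per-sample
#' log argument is floored at `exp(-clip)`, bounding every element's
#' contribution (and hence the loss) at `clip`: a maximally wrong sample
#' (`y = 1`, `y_hat -> 0`) contributes exactly `clip`.
#'
#' @param y True probabilities in `[0, 1]` (an [hbp_map()] or numeric vector).
#' @param y_hat Predicted probabilities in `[0, 1]`, same length.
#' @param clip Upper bound on each element's loss (default 10).
#'
#' @return Mean clipped loss (scalar >= 0, <= `clip`).
#' @export
#' @examples
#' bce_loss(c(1, 0.5), c(1, 0.5))   # 0
#' bce_loss(1, 0)                   # exactly 10
#' bce_loss(1, 0.5)                 # log(2)
bce_loss <- function(y, y_hat, clip = 10) {
  y <- hbp_values(y)
  y_hat <- hbp_values(y_hat)
  if (length(y) != length(y_hat)) {
    stop_invalid("label (%d) and prediction (%d) lengths differ", length(y), length(y_hat))
  }
  if (any(y < 0 | y > 1) || any(y_hat < 0 | y_hat > 1)) {
    stop_invalid("probabilities must lie in [0, 1]")
  }
  if (clip <= 0) stop_invalid("`clip` must be positive")
  eps <- exp(-clip)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  term <- xlogx(y) - y * log(pmax(y_hat, eps)) +
    xlogx(1 - y) - (1 - y) * log(pmax(1 - y_hat, eps))
  mean(pmin(term, clip))
}

# Gradient of the clipped BCE with respect to y_hat (the label-entropy terms
# are constant). Flooring zeroes the gradient where the clip is active.
bce_grad <- function(y, y_hat, clip = 10) {
  eps <- exp(-clip)
  g <- numeric(length(y))
  ok1 <- y_hat > eps
  ok2 <- (1 - y_hat) > eps
  g[ok1] <- g[ok1] - y[ok1] / y_hat[ok1]
  g[ok2] <- g[ok2] + (1 - y[ok2]) / (1 - y_hat[ok2])
  g / length(y)
}

#' Alternative training losses
#'
#' The losses used by the signal-reconstruction baselines: mean squared
#' error, negative Pearson correlation (`1 - r`), and a weighted hybrid of
#' clipped BCE and negative Pearson.
#'
#' @param name `"mse"`, `"neg_pearson"`, or `"hybrid"`.
#' @param y,y_hat Equal-length numeric sequences (or [hbp_map()]s).
#' @param hybrid_weights Two weights for `c(bce, neg_pearson)` in the hybrid
#'   loss (default `c(0.5, 0.5)`).
#'
#' @return Scalar loss.
#' @export
alt_loss <- function(name = c("mse", "neg_pearson", "hybrid"), y, y_hat,
                     hybrid_weights = c(0.5, 0.5)) {
  name <- match.arg(name)
  y <- hbp_values(y)
  y_hat <- hbp_values(y_hat)
  if (length(y) != length(y_hat)) {
    stop_invalid("label (%d) and prediction (%d) lengths differ", length(y), length(y_hat))
  }
  neg_pearson <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) {
      stop_invalid("negative-Pearson loss undefined for a constant sequence")
    }
    1 - cor(a, b)
  }
  switch(name,
    mse = mean((y - y_hat)^2),
    neg_pearson = neg_pearson(y, y_hat),
    hybrid = hybrid_weights[1] * bce_loss(y, y_hat) +
      hybrid_weights[2] * neg_pearson(y, y_hat)
  )
}

#' Training configuration
#'
#' Defaults follow the reference protocol: AdamW (learning rate 1e-4, betas
#' 0.9/0.999, weight decay 1e-4), cosine annealing with a 5-epoch linear
#' warm-up, 30 epochs, batch size 8, clipped BCE loss.
#'
#' @param lr Peak learning rate.
#' @param betas AdamW moment decay rates.
#' @param weight_decay Decoupled weight decay (applied to convolution
#'   kernels only).
#' @param epochs,batch_size Training schedule.
#' @param warmup_epochs Linear warm-up duration (from learning rate 0).
#' @param loss `"bce"`, `"mse"`, `"neg_pearson"` or `"hybrid"`.
#' @param loss_clip Clip bound for the BCE loss.
#' @param seed Seed consumed by shuffling (initialisation is seeded in
#'   [hbp_net()]).
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, betas = c(0.9, 0.999), weight_decay = 1e-4,
                         epochs = 30, batch_size = 8, warmup_epochs = 5,
                         loss = c("bce", "mse", "neg_pearson", "hybrid"),
                         loss_clip = 10, seed = 1) {
  loss <- match.arg(loss)
  if (lr <= 0 || epochs < 1 || batch_size < 1 || loss_clip <= 0) {
    stop_invalid("rates, epochs, batch size and clip must be positive")
  }
  structure(
    list(lr = lr, betas = betas, weight_decay = weight_decay,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         warmup_epochs = warmup_epochs, loss = loss, loss_clip = loss_clip,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning-rate schedule: linear warm-up then cosine annealing
#'
#' @param step 0-based optimisation step.
#' @param steps_per_epoch Steps in one epoch.
#' @param config A [train_config()].
#' @return Learning rate at `step`; 0 at step 0, the configured peak at the
#'   end of warm-up, decaying to ~0 at the final step.
#' @export
lr_schedule <- function(step, steps_per_epoch, config) {
  warm <- config$warmup_epochs * steps_per_epoch
  total <- config$epochs * steps_per_epoch
  if (warm > 0 && step < warm) return(config$lr * step / warm)
  denom <- max(1, total - warm)
  config$lr * 0.5 * (1 + cos(pi * (step - warm) / denom))
}

flatten_grads <- function(x) {
  out <- list()
  for (nm in names(x)) for (f in names(x[[nm]])) out[[paste(nm, f, sep = ".")]] <- x[[nm]][[f]]
  out
}

loss_and_grad <- function(y, y_hat, config) {
  clip <- config$loss_clip
  switch(config$loss,
    bce = list(loss = bce_loss(y, y_hat, clip), grad = bce_grad(y, y_hat, clip)),
    mse = list(loss = mean((y - y_hat)^2), grad = 2 * (y_hat - y) / length(y)),
    neg_pearson = {
      n <- length(y)
      sy <- sd(y); sh <- sd(y_hat)
      if (sy == 0 || sh == 0) stop_invalid("negative-Pearson loss undefined for constant sequences")
      r <- cor(y, y_hat)
      yc <- y - mean(y); hc <- y_hat - mean(y_hat)
      g <- -(yc / (sy * sh) - r * hc / sh^2) / (n - 1)
      list(loss = 1 - r, grad = g)
    },
    hybrid = {
      b <- list(loss = bce_loss(y, y_hat, clip), grad = bce_grad(y, y_hat, clip))
      n <- length(y)
      sy <- sd(y); sh <- sd(y_hat)
      if (sy == 0 || sh == 0) stop_invalid("negative-Pearson loss undefined for constant sequences")
      r <- cor(y, y_hat)
      yc <- y - mean(y); hc <- y_hat - mean(y_hat)
      g <- -(yc / (sy * sh) - r * hc / sh^2) / (n - 1)
      list(loss = 0.5 * b$loss + 0.5 * (1 - r), grad = 0.5 * b$grad + 0.5 * g)
    }
  )
}

#' Train a heartbeat-probability network
#'
#' Mini-batch AdamW on the configured loss with linear warm-up and cosine
#' annealing. Shuffling is driven by the configuration seed, so runs are
#' reproducible given identical thread settings. The returned fit contains
#' the parameters with the best validation loss (or final-epoch parameters
#' when no validation set is given) plus the full per-epoch log.
#'
#' @param model An [hbp_net()].
#' @param clips List of `3 x T x H x W` clip arrays.
#' @param labels List of length-`T` numeric label vectors (or [hbp_map()]s).
#' @param val_clips,val_labels Optional validation clips/labels.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#'
#' @return An object of class `hbp_fit`: `model` (best weights),
#'   `final_model`, `log` (tibble), `config`, `best_epoch`.
#' @export
train_hbp <- function(model, clips, labels, val_clips = NULL, val_labels = NULL,
                      config = train_config(), verbose = FALSE) {
  if (!length(clips)) stop_invalid("empty training set")
  if (length(clips) != length(labels)) {
    stop_invalid("got %d clips but %d labels", length(clips), length(labels))
  }
  labels <- lapply(labels, hbp_values)
  for (i in seq_along(clips)) {
    if (dim(clips[[i]])[2] != length(labels[[i]])) {
      stop_invalid("clip %d has T = %d frames but its label has length %d",
                   i, dim(clips[[i]])[2], length(labels[[i]]))
    }
  }
  if (!is.null(val_labels)) val_labels <- lapply(val_labels, hbp_values)

  params <- model$params
  adam_m <- list(); adam_v <- list()
  n <- length(clips)
  bs <- min(config$batch_size, n)
  steps_per_epoch <- ceiling(n / bs)
  step <- 0L
  decay_field <- function(nm) grepl("\\.w$", nm)  # weight decay on kernels only
  log_rows <- list()
  best_val <- Inf
  best_params <- params
  best_buffers <- model$buffers
  best_epoch <- NA_integer_

  eval_loss <- function(m, cl, lb) {
    tot <- 0
    for (i in seq_along(cl)) {
      fw <- hbp_forward(m, cl[[i]], training = FALSE, keep_cache = FALSE)
      tot <- tot + loss_and_grad(lb[[i]], as.numeric(fw$pred), config)$loss
    }
    tot / length(cl)
  }

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs) - 1L) {
      t0 <- proc.time()[["elapsed"]]
      ord <- sample.int(n)
      ep_loss <- 0; ep_batches <- 0
      for (b0 in seq(1, n, by = bs)) {
        idx <- ord[b0:min(b0 + bs - 1, n)]
        xb <- array(0, dim = c(dim(clips[[idx[1]]]), length(idx)))
        for (k in seq_along(idx)) xb[, , , , k] <- clips[[idx[k]]]
        yb <- unlist(labels[idx])
        model$params <- params
        fwd <- hbp_forward(model, xb, training = TRUE)
        model$buffers <- fwd$buffers
        lg <- loss_and_grad(yb, as.numeric(fwd$pred), config)
        dpred <- matrix(lg$grad, nrow = nrow(fwd$pred))
        grads <- hbp_backward(model, fwd, dpred)
        rm(fwd)
        gflat <- flatten_grads(grads)
        lr_t <- lr_schedule(step, steps_per_epoch, config)
        b1 <- config$betas[1]; b2 <- config$betas[2]
        for (nm in names(gflat)) {
          g <- gflat[[nm]]
          if (is.null(adam_m[[nm]])) { adam_m[[nm]] <- g * 0; adam_v[[nm]] <- g * 0 }
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g * g
          mhat <- adam_m[[nm]] / (1 - b1^(step + 1))
          vhat <- adam_v[[nm]] / (1 - b2^(step + 1))
          parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
          cur <- params[[parts[1]]][[parts[2]]]
          upd <- cur - lr_t * mhat / (sqrt(vhat) + 1e-8)
          if (decay_field(nm)) upd <- upd - lr_t * config$weight_decay * cur
          params[[parts[1]]][[parts[2]]] <- upd
        }
        step <- step + 1L
        ep_loss <- ep_loss + lg$loss
        ep_batches <- ep_batches + 1
      }
      model$params <- params
      vl <- if (!is.null(val_clips)) eval_loss(model, val_clips, val_labels) else NA_real_
      if (!is.na(vl) && vl < best_val) {
        best_val <- vl
        best_params <- params
        best_buffers <- model$buffers
        best_epoch <- epoch
      }
      log_rows[[epoch + 1]] <- tibble(
        epoch = epoch,
        train_loss = ep_loss / ep_batches,
        val_loss = vl,
        lr = lr_schedule(step - 1L, steps_per_epoch, config),
        seconds = proc.time()[["elapsed"]] - t0
      )
      if (verbose) {
        cat(sprintf("epoch %3d  train %.4f  val %s\n", epoch,
                    ep_loss / ep_batches, ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
      }
    }
  })

  final_model <- model
  final_model$params <- params
  best_model <- model
  if (is.null(val_clips)) {
    best_params <- params
    best_buffers <- final_model$buffers
  }
  best_model$params <- best_params
  best_model$buffers <- best_buffers
  structure(
    list(model = best_model, final_model = final_model,
         log = dplyr::bind_rows(log_rows), config = config,
         best_epoch = best_epoch, best_val_loss = best_val),
    class = "hbp_fit"
  )
}

#' @export
print.hbp_fit <- function(x, ...) {
  cat(sprintf("<hbp_fit> %d epochs | final train loss %.4f | best val loss %s\n",
              nrow(x$log), x$log$train_loss[nrow(x$log)],
              ifelse(is.finite(x$best_val_loss), sprintf("%.4f (epoch %d)", x$best_val_loss, x$best_epoch), "-")))
  invisible(x)
}

#' Per-epoch training log
#' @param x An `hbp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch.
#' @export
tidy.hbp_fit <- function(x, ...) x$log

#' One-row fit summary
#' @param x An `hbp_fit`.
#' @param ... Unused.
#' @export
glance.hbp_fit <- function(x, ...) {
  tibble(
    epochs = nrow(x$log),
    final_train_loss = x$log$train_loss[nrow(x$log)],
    best_val_loss = ifelse(is.finite(x$best_val_loss), x$best_val_loss, NA_real_),
    best_epoch = x$best_epoch,
    params = count_parameters(x$model$config),
    loss = x$config$loss
  )
}

#' Training-curve plot
#' @param object An `hbp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hbp_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log[, c("epoch", "train_loss", "val_loss")],
                            -"epoch", names_to = "split", values_to = "loss")
  df <- df[is.finite(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
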