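#' Network configuration
#'
#' Describes the heartbeat-probability network: a four-stage 3D convolutional
#' encoder, a mirrored transposed-convolution decoder with skip concatenation
#' whose sigmoid output is the spatiotemporal attention map, and a
#' convolutional head that consumes the attention-weighted clip and pools it
#' to one probability per frame.
#'
#' All 3D convolutions use 3x3x3 kernels with padding 1 and omit the bias
#' when batch normalisation follows; transposed convolutions use kernel 4 and
#' stride 2 along every upsampled axis (kernel 1 / stride 1 along a preserved
#' axis) with padding matching, so printed stage dimensions are met exactly.
#' The head downsamples spatially with one strided stem convolution followed
#' by two convolution + max-pool stages, then projects through two 1x1x1
#' convolutions before spatial global average pooling. This reconciled
#' configuration carries 0.536 million learnable parameters at the default
#' widths.
#'
#' @param t_len,height,width Input clip dimensions (`T` divisible by 4 — the
#'   product of the encoder's temporal pooling factors; `height`/`width`
#'   divisible by 16).
#' @param stage_widths Encoder channel widths (default `c(12, 24, 48, 96)`).
#' @param head_widths Head channel widths (default `c(12, 24, 48, 24, 1)`).
#' @param in_channels Input channels (RGB = 3).
#' @param bn_eps,bn_momentum Batch-normalisation constants.
#'
#' @return A list of class `net_config`.
#' @export
net_config <- function(t_len = 160, height = 128, width = 128,
                       stage_widths = c(12, 24, 48, 96),
                       head_widths = c(12, 24, 48, 24, 1),
                       in_channels = 3,
                       bn_eps = 1e-5, bn_momentum = 0.1) {
  if (length(stage_widths) != 4 || any(stage_widths <= 0)) {
    stop_invalid("`stage_widths` must be 4 positive widths")
  }
  if (length(head_widths) != 5 || head_widths[5] != 1) {
    stop_invalid("`head_widths` must be 5 widths ending in 1")
  }
  if (t_len %% 4 != 0) {
    stop_invalid("clip length T = %d must be divisible by 4 (temporal pooling 1*2*2*1)", t_len)
  }
  if (height %% 16 != 0 || width %% 16 != 0 || height < 16 || width < 16) {
    stop_invalid("height/width must be multiples of 16 (spatial pooling 2^4)")
  }
  structure(
    list(
      t_len = as.integer(t_len), height = as.integer(height), width = as.integer(width),
      in_channels = as.integer(in_channels),
      stage_widths = as.integer(stage_widths),
      head_widths = as.integer(head_widths),
      pool_schedule = list(c(1L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 2L), c(1L, 2L, 2L)),
      bn_eps = bn_eps, bn_momentum = bn_momentum
    ),
    class = "net_config"
  )
}

# Transposed-convolution geometry paired with a pooling factor: kernel 4 /
# stride 2 / pad 1 along upsampled axes, kernel 1 along preserved axes.
tconv_geom <- function(pool) {
  list(
    kernel = ifelse(pool == 1L, 1L, 4L),
    stride = pool,
    pad = ifelse(pool == 1L, 0L, 1L)
  )
}

# Full per-layer description of the architecture: channels, kernels, strides,
# output dimensions, parameter and multiply-accumulate counts. Both the
# parameter initialiser and the analytic counters derive from this single
# table, so the analytic counts match the instantiated model by construction.
net_layers <- function(config, t_len = NULL, height = NULL, width = NULL) {
  tl <- t_len %||% config$t_len
  hh <- height %||% config$height
  ww <- width %||% config$width
  sw <- config$stage_widths
  hw <- config$head_widths
  cin <- config$in_channels
  pools <- config$pool_schedule

  rows <- list()
  add <- function(name, stage, type, ci, co, kernel, stride, pad, bias, bn, act,
                  dims_out, pool_after = NULL) {
    rows[[length(rows) + 1]] <<- list(
      name = name, stage = stage, type = type, ci = ci, co = co,
      kernel = list(as.integer(kernel)), stride = list(as.integer(stride)),
      pad = list(as.integer(pad)), bias = bias, bn = bn, act = act,
      dims_out = list(as.integer(dims_out)),
      pool_after = list(if (is.null(pool_after)) NULL else as.integer(pool_after))
    )
  }

  # ---- encoder ----
  d <- c(tl, hh, ww)
  enc_ci <- c(cin, sw[-4])
  for (i in 1:4) {
    add(paste0("enc", i), paste0("Enc", i), "conv", enc_ci[i], sw[i],
        c(3, 3, 3), c(1, 1, 1), c(1, 1, 1), FALSE, TRUE, "relu",
        c(sw[i], d), pool_after = pools[[i]])
    d <- d %/% pools[[i]]
  }
  # after the loop d = bottleneck dims (T/4, H/16, W/16)

  # ---- decoder (mirrored, skip concatenation) ----
  dec_pool <- list(pools[[4]], pools[[3]], pools[[2]], pools[[1]])
  up_ci <- c(sw[4], sw[3], sw[2], sw[1])
  up_co <- c(sw[3], sw[2], sw[1], cin)
  skip_ch <- c(sw[3], sw[2], sw[1], cin)
  for (j in 1:4) {
    g <- tconv_geom(dec_pool[[j]])
    d <- d * dec_pool[[j]]
    add(paste0("dec", 5 - j, "t"), paste0("Dec", 5 - j), "tconv", up_ci[j], up_co[j],
        g$kernel, g$stride, g$pad, TRUE, FALSE, "none", c(up_co[j], d))
    act <- if (j == 4) "sigmoid" else "relu"
    add(paste0("dec", 5 - j, "c"), paste0("Dec", 5 - j), "conv",
        up_co[j] + skip_ch[j], up_co[j], c(3, 3, 3), c(1, 1, 1), c(1, 1, 1),
        FALSE, TRUE, act, c(up_co[j], d))
  }

  # ---- head on the attention-weighted clip ----
  d <- c(tl, hh %/% 2, ww %/% 2)
  add("head1", "Out3", "conv", cin, hw[1], c(3, 3, 3), c(1, 2, 2), c(1, 1, 1),
      FALSE, TRUE, "relu", c(hw[1], d))
  add("head2", "Out2", "conv", hw[1], hw[2], c(3, 3, 3), c(1, 1, 1), c(1, 1, 1),
      FALSE, TRUE, "relu", c(hw[2], d), pool_after = c(1, 2, 2))
  d <- d %/% c(1, 2, 2)
  add("head3", "Out1", "conv", hw[2], hw[3], c(3, 3, 3), c(1, 1, 1), c(1, 1, 1),
      FALSE, TRUE, "relu", c(hw[3], d), pool_after = c(1, 2, 2))
  d <- d %/% c(1, 2, 2)
  add("head4", "Out1", "conv", hw[3], hw[4], c(1, 1, 1), c(1, 1, 1), c(0, 0, 0),
      TRUE, FALSE, "none", c(hw[4], d))
  add("head5", "Out1", "conv", hw[4], hw[5], c(1, 1, 1), c(1, 1, 1), c(0, 0, 0),
      TRUE, FALSE, "none", c(hw[5], d))

  tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  kv <- vapply(tab$kernel, prod, numeric(1))
  out_el <- vapply(tab$dims_out, prod, numeric(1))
  tab$params <- tab$co * tab$ci * kv + ifelse(tab$bias, tab$co, 0) + ifelse(tab$bn, 2 * tab$co, 0)
  # MAC convention: output-elements x input-channels x kernel-volume for both
  # convolution types (the convention used by common profilers on which the
  # reference complexity figures in this field are reported)
  tab$macs <- out_el * tab$ci * kv
  tab$elementwise_ops <- ifelse(tab$bn, 2, 0) * out_el +
    ifelse(tab$act != "none", 2, 0) * out_el
  tab
}

#' Count learnable parameters analytically
#'
#' Sums convolution and transposed-convolution kernels, their biases where
#' present, and batch-normalisation scale/offset pairs, from the architecture
#' description alone. The count is independent of the input dimensions and
#' equals the instantiated model's parameter count exactly.
#'
#' @param config A [net_config()] (or an `hbp_net` model).
#' @return Integer parameter count.
#' @export
#' @examples
#' count_parameters(net_config(160, 128, 128)) # 536356, i.e. 0.536 M
count_parameters <- function(config) {
  if (inherits(config, "hbp_net")) config <- config$config
  sum(net_layers(config)$params)
}

#' Count multiply-accumulate operations analytically
#'
#' Per-clip forward-pass MACs. Each convolution contributes
#' `output_elements * input_channels * kernel_volume`; transposed convolutions
#' are counted with the same output-element convention. With
#' `include_elementwise = TRUE` (default) batch-normalisation and activation
#' layers add 2 operations per element each and the final global average pool
#' adds its input elements, matching the counting convention of common
#' network profilers; max-pooling is free under either setting. The count is
#' linear in `T` and in `H * W`.
#'
#' @param config A [net_config()] (or an `hbp_net` model).
#' @param t_len,height,width Input dimensions to count at (default: the
#'   configured dimensions).
#' @param include_elementwise Include normalisation/activation/average-pool
#'   element operations (default `TRUE`).
#' @return Total MAC count (numeric, exact integer value).
#' @export
count_macs <- function(config, t_len = NULL, height = NULL, width = NULL,
                       include_elementwise = TRUE) {
  if (inherits(config, "hbp_net")) config <- config$config
  tab <- net_layers(config, t_len, height, width)
  total <- sum(tab$macs)
  if (include_elementwise) {
    hw3 <- tab$dims_out[[nrow(tab)]]
    total <- total + sum(tab$elementwise_ops) +
      prod(hw3) +                       # global average pool reads its input once
      2 * hw3[2]                        # final per-frame sigmoid
  }
  total
}

init_conv <- function(ci, co, kernel, bias) {
  fan_in <- ci * prod(kernel)
  bound <- sqrt(1 / fan_in)
  w <- array(runif(co * ci * prod(kernel), -bound, bound),
             dim = c(co, ci, kernel[1], kernel[2], kernel[3]))
  out <- list(w = w)
  if (bias) out$b <- runif(co, -bound, bound)
  out
}

#' Build a heartbeat-probability network
#'
#' Instantiates the architecture described by a [net_config()] with
#' deterministic, seeded fan-in-scaled uniform initialisation for
#' convolutions and ones/zeros for batch-normalisation scales/offsets.
#'
#' @param config A [net_config()].
#' @param seed Integer seed fixing the initialisation.
#' @return An object of class `hbp_net`: list with `config`, `params`
#'   (named layer parameter arrays) and `buffers` (batch-norm running
#'   statistics).
#' @export
hbp_net <- function(config = net_config(), seed = 1) {
  tab <- net_layers(config)
  params <- list()
  buffers <- list()
  with_local_seed(seed, {
    for (i in seq_len(nrow(tab))) {
      nm <- tab$name[i]
      params[[nm]] <- init_conv(tab$ci[i], tab$co[i], tab$kernel[[i]], tab$bias[i])
      if (tab$bn[i]) {
        params[[nm]]$gamma <- rep(1, tab$co[i])
        params[[nm]]$beta <- rep(0, tab$co[i])
        buffers[[nm]] <- list(mean = rep(0, tab$co[i]), var = rep(1, tab$co[i]))
      }
    }
  })
  structure(list(config = config, params = params, buffers = buffers),
            class = "hbp_net")
}

#' Apply a spatiotemporal attention map to a clip
#'
#' The attention-enhanced clip is the elementwise product of the input and
#' the attention weights.
#'
#' @param x,a Arrays of identical dimension.
#' @return The elementwise product.
#' @export
apply_attention <- function(x, a) {
  if (!identical(dim(x), dim(a))) {
    stop_invalid("attention map dimensions (%s) do not match input (%s)",
                 paste(dim(a), collapse = "x"), paste(dim(x), collapse = "x"))
  }
  x * a
}

# ---- internal layer math -------------------------------------------------

bn_forward <- function(x, gamma, beta, buf, training, eps, momentum) {
  d <- dim(x)
  co <- d[1]
  m <- matrix(x, nrow = co)
  if (training) {
    mu <- rowMeans(m)
    v <- rowMeans(m * m) - mu^2
    v[v < 0] <- 0
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * v
  } else {
    mu <- buf$mean
    v <- buf$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * invstd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, xhat = xhat, invstd = invstd, buf = buf, dims = d)
}

bn_backward <- function(dy, cache, gamma) {
  co <- cache$dims[1]
  dm <- matrix(dy, nrow = co)
  dgamma <- rowSums(dm * cache$xhat)
  dbeta <- rowSums(dm)
  dxhat <- dm * gamma
  n <- ncol(dm)
  dx <- cache$invstd * (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  dim(dx) <- cache$dims
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[-1]))
  n_rest <- prod(da[-1])
  am <- matrix(a, nrow = da[1]); bm <- matrix(b, nrow = db[1])
  om <- rbind(am, bm)
  dim(om) <- dim(out)
  om
}

# Forward pass. Returns predictions (T x B matrix), the attention output and,
# when `training`/`keep_cache`, everything needed for the backward pass.
hbp_forward <- function(model, x, training = FALSE, keep_cache = training) {
  cfg <- model$config
  p <- model$params
  buf <- model$buffers
  tab <- net_layers(cfg, t_len = dim(x)[2], height = dim(x)[3], width = dim(x)[4])
  d <- dim(x)
  if (length(d) == 4) dim(x) <- c(d, 1)
  d <- dim(x)
  if (d[1] != cfg$in_channels) {
    stop_invalid("clip has %d channels; config expects %d", d[1], cfg$in_channels)
  }
  if (d[2] %% 4 != 0) stop_invalid("clip length T = %d must be divisible by 4", d[2])
  if (d[3] %% 16 != 0 || d[4] %% 16 != 0) {
    stop_invalid("clip spatial size %dx%d must be a multiple of 16", d[3], d[4])
  }
  layer <- function(nm) tab[tab$name == nm, ]
  cache <- if (keep_cache) list() else NULL

  run_conv_bn_act <- function(nm, input, act, pool = NULL) {
    L <- layer(nm)
    z <- cpp_conv3d_fwd(input, dim(input), p[[nm]]$w, dim(p[[nm]]$w),
                        p[[nm]]$b %||% numeric(0), L$stride[[1]], L$pad[[1]])
    if (L$bn) {
      bnres <- bn_forward(z, p[[nm]]$gamma, p[[nm]]$beta, buf[[nm]], training,
                          cfg$bn_eps, cfg$bn_momentum)
      buf[[nm]] <<- bnres$buf
      z <- bnres$y
    } else bnres <- NULL
    a <- switch(act, relu = pmax(z, 0), sigmoid = 1 / (1 + exp(-z)), none = z)
    pl <- NULL
    out <- a
    if (!is.null(pool)) {
      pl <- cpp_maxpool3d_fwd(a, dim(a), pool)
      out <- pl$y
    }
    if (keep_cache) {
      cache[[nm]] <<- list(input = input, in_dim = dim(input),
                           bn = if (!is.null(bnres)) bnres[c("xhat", "invstd", "dims")],
                           act = act, act_out = a, pool_idx = pl$idx,
                           pre_pool_dim = dim(a))
    }
    out
  }

  shapes <- list()

  # encoder
  enc_out <- vector("list", 4)
  h <- x
  for (i in 1:4) {
    h <- run_conv_bn_act(paste0("enc", i), h, "relu", cfg$pool_schedule[[i]])
    enc_out[[i]] <- h
    shapes[[paste0("Enc", i)]] <- dim(h)[1:4]
  }

  # decoder with skip concatenation
  skips <- list(enc_out[[3]], enc_out[[2]], enc_out[[1]], x)
  dcur <- enc_out[[4]]
  for (j in 1:4) {
    tn <- paste0("dec", 5 - j, "t")
    cn <- paste0("dec", 5 - j, "c")
    L <- layer(tn)
    u <- cpp_convt3d_fwd(dcur, dim(dcur), p[[tn]]$w, dim(p[[tn]]$w),
                         p[[tn]]$b %||% numeric(0), L$stride[[1]], L$pad[[1]])
    if (keep_cache) cache[[tn]] <- list(input = dcur, in_dim = dim(dcur), up_dim = dim(u))
    cat_in <- concat_channels(u, skips[[j]])
    rm(u)
    dcur <- run_conv_bn_act(cn, cat_in, if (j == 4) "sigmoid" else "relu")
    rm(cat_in)
    shapes[[paste0("Dec", 5 - j)]] <- dim(dcur)[1:4]
  }
  a_st <- dcur
  x_star <- x * a_st

  # head
  h <- run_conv_bn_act("head1", x_star, "relu")
  shapes[["Out3"]] <- dim(h)[1:4]
  h <- run_conv_bn_act("head2", h, "relu", c(1L, 2L, 2L))
  shapes[["Out2"]] <- dim(h)[1:4]
  h <- run_conv_bn_act("head3", h, "relu", c(1L, 2L, 2L))
  shapes[["Out1_in"]] <- dim(h)[1:4]
  h <- run_conv_bn_act("head4", h, "none")
  h <- run_conv_bn_act("head5", h, "none")
  shapes[["Out1"]] <- dim(h)[1:4]
  hd <- dim(h)                                   # (1, T, h, w, B)
  pooled <- colMeans(matrix(aperm(h, c(3, 4, 1, 2, 5)), nrow = hd[3] * hd[4]))
  z_t <- matrix(pooled, nrow = hd[2])            # T x B
  pred <- 1 / (1 + exp(-z_t))

  shapes[["Out"]] <- nrow(pred)
  out <- list(pred = pred, a_st = a_st, x_star = x_star, buffers = buf,
              shapes = shapes)
  if (keep_cache) {
    out$cache <- cache
    out$head_dim <- hd
    out$x <- x
  }
  out
}

# Backward pass: gradient of the scalar loss with respect to every parameter,
# given d(loss)/d(pred). Mirrors hbp_forward exactly.
hbp_backward <- function(model, fwd, dpred) {
  cfg <- model$config
  p <- model$params
  cache <- fwd$cache
  tab <- net_layers(cfg, t_len = dim(fwd$x)[2], height = dim(fwd$x)[3],
                    width = dim(fwd$x)[4])
  layer <- function(nm) tab[tab$name == nm, ]
  grads <- list()

  back_conv_bn_act <- function(nm, dout, need_dx = TRUE) {
    cc <- cache[[nm]]
    L <- layer(nm)
    if (!is.null(cc$pool_idx)) {
      dout <- cpp_maxpool3d_bwd(dout, cc$pool_idx, cc$pre_pool_dim)
    }
    dout <- switch(cc$act,
      relu = dout * (cc$act_out > 0),
      sigmoid = dout * cc$act_out * (1 - cc$act_out),
      none = dout
    )
    g <- list()
    if (!is.null(cc$bn)) {
      bb <- bn_backward(dout, cc$bn, p[[nm]]$gamma)
      dout <- bb$dx
      g$gamma <- bb$dgamma
      g$beta <- bb$dbeta
    }
    cb <- cpp_conv3d_bwd(cc$input, cc$in_dim, p[[nm]]$w, dim(p[[nm]]$w), dout,
                         L$stride[[1]], L$pad[[1]], need_dx)
    g$w <- cb$dw
    if (!is.null(p[[nm]]$b)) g$b <- cb$db
    grads[[nm]] <<- g
    if (need_dx) cb$dx else NULL
  }

  hd <- fwd$head_dim
  n_sp <- hd[3] * hd[4]
  dz_t <- dpred * fwd$pred * (1 - fwd$pred)       # T x B
  # undo spatial average pooling: each spatial site gets dz / (h*w)
  per <- as.numeric(dz_t) / n_sp
  dh_perm <- array(rep(per, each = n_sp), dim = c(hd[3], hd[4], hd[1], hd[2], hd[5]))
  dh <- aperm(dh_perm, c(3, 4, 1, 2, 5))

  dh <- back_conv_bn_act("head5", dh)
  dh <- back_conv_bn_act("head4", dh)
  dh <- back_conv_bn_act("head3", dh)
  dh <- back_conv_bn_act("head2", dh)
  dx_star <- back_conv_bn_act("head1", dh)

  da <- dx_star * fwd$x                           # product rule; dL/dx itself unused

  # decoder backward (Dec1 .. Dec4), accumulating skip gradients
  dskip <- vector("list", 4)                      # -> enc3, enc2, enc1, x
  dcur <- da
  for (j in 4:1) {
    tn <- paste0("dec", 5 - j, "t")
    cn <- paste0("dec", 5 - j, "c")
    dcat <- back_conv_bn_act(cn, dcur)
    up_ch <- cache[[tn]]$up_dim[1]
    dc <- dim(dcat)
    dm <- matrix(dcat, nrow = dc[1])
    du <- dm[seq_len(up_ch), , drop = FALSE]
    ds <- dm[-seq_len(up_ch), , drop = FALSE]
    dim(du) <- c(up_ch, dc[-1])
    dim(ds) <- c(dc[1] - up_ch, dc[-1])
    dskip[[j]] <- ds
    L <- layer(tn)
    tb <- cpp_convt3d_bwd(cache[[tn]]$input, cache[[tn]]$in_dim, p[[tn]]$w,
                          dim(p[[tn]]$w), du, L$stride[[1]], L$pad[[1]], TRUE)
    grads[[tn]] <- list(w = tb$dw, b = tb$db)
    dcur <- tb$dx
  }

  # encoder backward; dcur is the gradient w.r.t. Enc4's pooled output
  denc <- list(dskip[[3]], dskip[[2]], dskip[[1]], dcur)  # grads wrt enc_out 1..4
  g <- denc[[4]]
  for (i in 4:1) {
    if (i < 4) g <- g + denc[[i]]
    g <- back_conv_bn_act(paste0("enc", i), g, need_dx = i > 1)
  }
  grads
}

#' Forward a clip through the network
#'
#' Evaluation-mode forward pass: deterministic for fixed parameters, using
#' batch-normalisation running statistics.
#'
#' @param object An [hbp_net()].
#' @param clip A `3 x T x H x W` array (a `ClipTensor`), or `3 x T x H x W x B`.
#' @param fps Frames per second attached to the returned probability map.
#' @param ... Unused.
#'
#' @return A list of class `hbp_forward`: `hbp` (an [hbp_map()], or `T x B`
#'   matrix for batches), `a_st` (attention weights in `[0, 1]`) and
#'   `x_star` (attention-weighted clip).
#' @export
predict.hbp_net <- function(object, clip, fps = 30, ...) {
  fwd <- hbp_forward(object, clip, training = FALSE, keep_cache = FALSE)
  hbp <- if (ncol(fwd$pred) == 1) hbp_map(as.numeric(fwd$pred), fps) else fwd$pred
  structure(list(hbp = hbp, a_st = fwd$a_st, x_star = fwd$x_star),
            class = "hbp_forward")
}

#' Stage-by-stage architecture summary
#'
#' One row per parameterised layer with output dimensions, parameter count
#' and MACs, mirroring the printed architecture table.
#'
#' @param x An `hbp_net` or `net_config`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hbp_net <- function(x, ...) tidy.net_config(x$config, ...)

#' @rdname tidy.hbp_net
#' @export
tidy.net_config <- function(x, ...) {
  tab <- net_layers(x)
  tibble(
    layer = tab$name, stage = tab$stage, type = tab$type,
    in_channels = tab$ci, out_channels = tab$co,
    kernel = vapply(tab$kernel, paste, character(1), collapse = "x"),
    output = vapply(tab$dims_out, paste, character(1), collapse = "x"),
    params = as.integer(tab$params), macs = tab$macs
  )
}

#' @rdname tidy.hbp_net
#' @export
glance.hbp_net <- function(x, ...) glance.net_config(x$config, ...)

#' @rdname tidy.hbp_net
#' @export
glance.net_config <- function(x, ...) {
  tibble(
    params = count_parameters(x),
    params_m = round(count_parameters(x) / 1e6, 3),
    macs = count_macs(x),
    macs_g = round(count_macs(x) / 1e9, 3),
    t_len = x$t_len, height = x$height, width = x$width
  )
}

#' @export
print.hbp_net <- function(x, ...) {
  g <- glance.hbp_net(x)
  cat(sprintf(
    "<hbp_net> input (%d,%d,%d,%d) | %.3f M parameters | %.3f G MACs\n",
    x$config$in_channels, g$t_len, g$height, g$width, g$params_m, g$macs_g
  ))
  invisible(x)
}

#' Save / load model checkpoints
#'
#' Checkpoints serialise the configuration, parameters and batch-norm
#' buffers; loading restores them bit-exactly.
#'
#' @param model An `hbp_net`.
#' @param path File path.
#' @return `load_checkpoint()` returns the restored `hbp_net`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               buffers = model$buffers), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(config = structure(obj$config, class = "net_config"),
                 params = obj$params, buffers = obj$buffers),
            class = "hbp_net")
}
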