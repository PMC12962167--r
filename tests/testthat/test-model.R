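# Direct-summation oracle for a 3D convolution (channel-first layout).
naive_conv3d <- function(x, w, b, stride, pad) {
  dx <- dim(x); dw <- dim(w)
  Ci <- dx[1]; Ti <- dx[2]; Hi <- dx[3]; Wi <- dx[4]
  Co <- dw[1]; kT <- dw[3]; kH <- dw[4]; kW <- dw[5]
  To <- (Ti + 2 * pad[1] - kT) %/% stride[1] + 1
  Ho <- (Hi + 2 * pad[2] - kH) %/% stride[2] + 1
  Wo <- (Wi + 2 * pad[3] - kW) %/% stride[3] + 1
  y <- array(0, dim = c(Co, To, Ho, Wo))
  for (co in 1:Co) for (to in 1:To) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- if (length(b)) b[co] else 0
    for (ci in 1:Ci) for (kt in 1:kT) for (kh in 1:kH) for (kw in 1:kW) {
      it <- (to - 1) * stride[1] - pad[1] + kt
      ih <- (ho - 1) * stride[2] - pad[2] + kh
      iw <- (wo - 1) * stride[3] - pad[3] + kw
      if (it >= 1 && it <= Ti && ih >= 1 && ih <= Hi && iw >= 1 && iw <= Wi) {
        acc <- acc + x[ci, it, ih, iw] * w[co, ci, kt, kh, kw]
      }
    }
    y[co, to, ho, wo] <- acc
  }
  y
}

# Scatter-definition oracle for a transposed 3D convolution.
naive_convt3d <- function(x, w, b, stride, pad) {
  dx <- dim(x); dw <- dim(w)
  Ci <- dx[1]; Ti <- dx[2]; Hi <- dx[3]; Wi <- dx[4]
  Co <- dw[1]; kT <- dw[3]; kH <- dw[4]; kW <- dw[5]
  To <- (Ti - 1) * stride[1] - 2 * pad[1] + kT
  Ho <- (Hi - 1) * stride[2] - 2 * pad[2] + kH
  Wo <- (Wi - 1) * stride[3] - 2 * pad[3] + kW
  y <- array(0, dim = c(Co, To, Ho, Wo))
  for (ci in 1:Ci) for (it in 1:Ti) for (ih in 1:Hi) for (iw in 1:Wi) {
    for (co in 1:Co) for (kt in 1:kT) for (kh in 1:kH) for (kw in 1:kW) {
      ot <- (it - 1) * stride[1] - pad[1] + kt
      oh <- (ih - 1) * stride[2] - pad[2] + kh
      ow <- (iw - 1) * stride[3] - pad[3] + kw
      if (ot >= 1 && ot <= To && oh >= 1 && oh <= Ho && ow >= 1 && ow <= Wo) {
        y[co, ot, oh, ow] <- y[co, ot, oh, ow] + x[ci, it, ih, iw] * w[co, ci, kt, kh, kw]
      }
    }
  }
  if (length(b)) for (co in 1:Co) y[co, , , ] <- y[co, , , ] + b[co]
  y
}

test_that("the GEMM convolution matches direct summation", {
  set.seed(1)
  x <- array(rnorm(3 * 6 * 7 * 5), dim = c(3, 6, 7, 5))
  w <- array(rnorm(4 * 3 * 3 * 3 * 3), dim = c(4, 3, 3, 3, 3))
  b <- rnorm(4)
  for (stride in list(c(1L, 1L, 1L), c(1L, 2L, 2L))) {
    got <- hbpnet:::cpp_conv3d_fwd(x, c(dim(x), 1L), w, dim(w), b, stride, c(1L, 1L, 1L))
    want <- naive_conv3d(x, w, b, stride, c(1, 1, 1))
    expect_equal(array(got, dim(got)[1:4]), want, tolerance = 1e-12)
  }
})

test_that("the transposed convolution matches its scatter definition", {
  set.seed(2)
  x <- array(rnorm(4 * 3 * 4 * 4), dim = c(4, 3, 4, 4))
  w <- array(rnorm(2 * 4 * 1 * 4 * 4), dim = c(2, 4, 1, 4, 4))
  b <- rnorm(2)
  got <- hbpnet:::cpp_convt3d_fwd(x, c(dim(x), 1L), w, dim(w), b,
                                  c(1L, 2L, 2L), c(0L, 1L, 1L))
  want <- naive_convt3d(x, w, b, c(1, 2, 2), c(0, 1, 1))
  expect_equal(array(got, dim(got)[1:4]), want, tolerance = 1e-12)

  w2 <- array(rnorm(2 * 4 * 4 * 4 * 4), dim = c(2, 4, 4, 4, 4))
  got2 <- hbpnet:::cpp_convt3d_fwd(x, c(dim(x), 1L), w2, dim(w2), numeric(0),
                                   c(2L, 2L, 2L), c(1L, 1L, 1L))
  want2 <- naive_convt3d(x, w2, numeric(0), c(2, 2, 2), c(1, 1, 1))
  expect_equal(array(got2, dim(got2)[1:4]), want2, tolerance = 1e-12)
})

test_that("the default architecture carries 0.536 M parameters, matching instantiation", {
  cfg <- net_config(160, 128, 128)
  expect_equal(count_parameters(cfg), 536356)
  m_small <- hbp_net(tiny_config(), seed = 1)
  inst <- sum(unlist(lapply(m_small$params, function(l) vapply(l, length, integer(1)))))
  expect_identical(as.integer(count_parameters(tiny_config())), as.integer(inst))
  # invariant to input dims
  expect_equal(count_parameters(net_config(64, 32, 32)), count_parameters(cfg))
})

test_that("parameter counting matches an independent layer-by-layer enumeration", {
  # widths (2, 4, 8, 16), head (2, 4, 8, 4, 1): every layer enumerated by hand
  oracle <- sum(
    2 * 3 * 27 + 2 * 2,        # enc1 conv 3->2 + BN
    4 * 2 * 27 + 2 * 4,        # enc2
    8 * 4 * 27 + 2 * 8,        # enc3
    16 * 8 * 27 + 2 * 16,      # enc4
    16 * 8 * 16 + 8,           # dec4 transpose 16->8, kernel (1,4,4)
    8 * 16 * 27 + 2 * 8,       # dec4 conv on concat(8 + 8)
    8 * 4 * 64 + 4,            # dec3 transpose, kernel (4,4,4)
    4 * 8 * 27 + 2 * 4,        # dec3 conv
    4 * 2 * 64 + 2,            # dec2 transpose
    2 * 4 * 27 + 2 * 2,        # dec2 conv
    2 * 3 * 16 + 3,            # dec1 transpose 2->3, kernel (1,4,4)
    3 * 6 * 27 + 2 * 3,        # dec1 conv on concat(3 + 3), BN + sigmoid
    2 * 3 * 27 + 2 * 2,        # head stem 3->2
    4 * 2 * 27 + 2 * 4,        # head 2->4
    8 * 4 * 27 + 2 * 8,        # head 4->8
    4 * 8 + 4,                 # head 1x1x1 8->4 with bias
    1 * 4 + 1                  # head 1x1x1 4->1 with bias
  )
  expect_equal(oracle, 15846)
  cfg <- net_config(16, 32, 32, stage_widths = c(2, 4, 8, 16),
                    head_widths = c(2, 4, 8, 4, 1))
  expect_equal(count_parameters(cfg), oracle)
})

test_that("MAC accounting is linear in T with the exact 160/128 ratio", {
  cfg <- net_config(160, 128, 128)
  m128 <- count_macs(cfg, t_len = 128)
  m160 <- count_macs(cfg, t_len = 160)
  expect_equal(m160 / m128, 160 / 128, tolerance = 1e-12)
  expect_equal(count_macs(cfg, t_len = 128, include_elementwise = FALSE) * 160 / 128,
               count_macs(cfg, t_len = 160, include_elementwise = FALSE))
  # scales with H*W on the convolution terms
  conv64 <- count_macs(cfg, t_len = 128, height = 64, width = 64,
                       include_elementwise = FALSE)
  conv128 <- count_macs(cfg, t_len = 128, include_elementwise = FALSE)
  expect_equal(conv128 / conv64, 4, tolerance = 1e-12)
})

test_that("forward output is a length-T probability sequence, deterministic in eval mode", {
  cfg <- tiny_config(t_len = 8, hw = 16)
  m <- hbp_net(cfg, seed = 3)
  x <- array(runif(3 * 8 * 16 * 16), dim = c(3, 8, 16, 16))
  out1 <- predict(m, x, fps = 30)
  out2 <- predict(m, x, fps = 30)
  expect_equal(nrow(out1$hbp), 8)
  expect_true(all(out1$hbp$probability >= 0 & out1$hbp$probability <= 1))
  expect_identical(out1$hbp$probability, out2$hbp$probability)
  expect_true(all(out1$a_st >= 0 & out1$a_st <= 1))
  expect_equal(out1$x_star, array(x, c(dim(x), 1)) * out1$a_st)

  zero <- predict(m, array(0, dim = c(3, 8, 16, 16)))
  expect_true(all(zero$x_star == 0))

  expect_error(net_config(130, 128, 128), class = "hbpnet_invalid_parameter")
  expect_error(predict(m, array(0, dim = c(2, 8, 16, 16))),
               class = "hbpnet_invalid_parameter")
})

test_that("attention application is the elementwise product", {
  x <- array(0.5, dim = c(2, 3, 4, 4))
  expect_equal(apply_attention(x, array(1, dim(x))), x)
  expect_equal(apply_attention(x, array(0, dim(x))), x * 0)
  expect_equal(apply_attention(x, array(0.4, dim(x))), array(0.2, dim(x)))
  expect_error(apply_attention(x, array(1, dim = c(2, 3, 4, 5))),
               class = "hbpnet_invalid_parameter")
})

test_that("analytic gradients match finite differences across all layer types", {
  set.seed(42)
  cfg <- tiny_config(t_len = 8, hw = 16)
  m <- hbp_net(cfg, seed = 7)
  x <- array(runif(3 * 8 * 16 * 16 * 2), dim = c(3, 8, 16, 16, 2))
  y <- runif(8 * 2)
  lossfun <- function(model) {
    fw <- hbpnet:::hbp_forward(model, x, training = TRUE, keep_cache = FALSE)
    bce_loss(y, as.numeric(fw$pred))
  }
  fw <- hbpnet:::hbp_forward(m, x, training = TRUE)
  g <- hbpnet:::bce_grad(y, as.numeric(fw$pred))
  grads <- hbpnet:::hbp_backward(m, fw, matrix(g, nrow = nrow(fw$pred)))
  eps <- 1e-6
  spots <- list(
    c("enc1", "w"), c("enc3", "w"), c("enc2", "gamma"), c("enc4", "beta"),
    c("dec4t", "w"), c("dec2t", "b"), c("dec3c", "w"), c("dec1c", "w"),
    c("dec1c", "gamma"), c("head1", "w"), c("head3", "w"), c("head4", "w"),
    c("head5", "b")
  )
  for (sp in spots) {
    arr <- m$params[[sp[1]]][[sp[2]]]
    i <- min(2, length(arr))
    m_plus <- m; m_plus$params[[sp[1]]][[sp[2]]][i] <- arr[i] + eps
    m_minus <- m; m_minus$params[[sp[1]]][[sp[2]]][i] <- arr[i] - eps
    num <- (lossfun(m_plus) - lossfun(m_minus)) / (2 * eps)
    ana <- grads[[sp[1]]][[sp[2]]][i]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = sprintf("gradient of %s.%s", sp[1], sp[2]))
  }
})

test_that("no parameter group is dead at initialisation", {
  set.seed(9)
  cfg <- tiny_config(t_len = 8, hw = 16)
  m <- hbp_net(cfg, seed = 21)
  x <- array(runif(3 * 8 * 16 * 16), dim = c(3, 8, 16, 16, 1))
  y <- runif(8)
  fw <- hbpnet:::hbp_forward(m, x, training = TRUE)
  g <- hbpnet:::bce_grad(y, as.numeric(fw$pred))
  grads <- hbpnet:::hbp_backward(m, fw, matrix(g, nrow = nrow(fw$pred)))
  for (nm in names(grads)) {
    total <- sum(vapply(grads[[nm]], function(a) sum(abs(a)), numeric(1)))
    expect_gt(total, 0)
  }
})

test_that("checkpoints round-trip bit-exactly", {
  m <- hbp_net(tiny_config(), seed = 5)
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_identical(back$buffers, m$buffers)
  x <- array(runif(3 * 8 * 16 * 16), dim = c(3, 8, 16, 16))
  expect_identical(predict(m, x)$hbp$probability, predict(back, x)$hbp$probability)
})

test_that("the architecture summary mirrors the stage table", {
  tab <- tidy(net_config(128, 128, 128))
  expect_equal(sum(tab$params), 536356)
  expect_equal(tab$output[tab$layer == "enc4"], "96x32x16x16")
  expect_equal(tab$output[tab$layer == "dec1c"], "3x128x128x128")
  expect_equal(tab$output[tab$layer == "head5"], "1x128x16x16")
  g <- glance(net_config(160, 128, 128))
  expect_equal(g$params_m, 0.536)
})
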