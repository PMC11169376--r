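test_that("the conv front-end preserves spatial shape and counts parameters", {
  cf <- model_config(C = 8, n_classes = 2)
  pp <- init_params(cf)
  x <- array(rnorm(8 * 81), c(8, 9, 9))
  y <- conv_frontend(x, pp, cf)
  expect_equal(dim(y), c(8, 9, 9))

  # zero weights and biases give an identically zero output (ReLU(0) = 0)
  p0 <- pp
  p0$conv <- lapply(p0$conv, function(w) w * 0)
  expect_equal(conv_frontend(x, p0, cf), array(0, c(8, 9, 9)))

  # layer parameter counts from Table-style closed forms
  expect_equal(length(pp$conv$W1) + length(pp$conv$b1), 32 * 8 * 3 * 3 + 32)
  expect_equal(sum(lengths(pp$conv)), 2336 + (8 * 32 * 3 * 3 + 8))

  expect_error(conv_frontend(array(0, c(4, 9, 9)), pp, cf), "tensor")
})

test_that("token reshaping is row-major and invertible", {
  x <- array(rnorm(8 * 81), c(8, 9, 9))
  z <- reshape_tokens(x)
  expect_equal(dim(z), c(8, 81))
  expect_equal(z[3, ], as.vector(t(x[3, , ])))  # row-major flatten
  expect_equal(unreshape_tokens(z, 9, 9), x)
  xk <- array(7, c(2, 3, 3))
  expect_true(all(reshape_tokens(xk) == 7))
})

test_that("token augmentation prepends two seeded trainable rows", {
  cf <- model_config(C = 8, n_classes = 2, seed = 5)
  pp <- init_params(cf)
  z0 <- matrix(rnorm(8 * 81), 8, 81)
  z <- token_augment(z0, pp)
  expect_equal(dim(z), c(10, 81))
  expect_equal(z[3:10, ], z0)
  expect_identical(pp$tokens, init_params(cf)$tokens)  # same seed, same tokens
  expect_false(identical(pp$tokens,
                         init_params(model_config(C = 8, n_classes = 2,
                                                  seed = 6))$tokens))
})

test_that("learned tokens receive gradient on a toy loss", {
  cf <- tiny_config()
  pp <- init_params(cf)
  X4 <- eegemotion:::stack_tensors(random_tensors(4))
  fw <- eegemotion:::net_fwd(X4, pp, cf)
  ce <- eegemotion:::cross_entropy(fw$logits, c(1L, 2L, 3L, 1L))
  gr <- eegemotion:::net_bwd(ce$dlogits, fw, pp, cf)
  expect_gt(max(abs(gr$tokens)), 0)
})

test_that("vectorised ISA matches the literal loop-based oracle", {
  withr::with_seed(17, {
    for (sh in list(c(2, 4), c(10, 81), c(32, 81), c(2, 81), c(10, 4))) {
      n <- sh[1]; d <- sh[2]
      for (r in 1:5) {
        p <- random_isa_params(n, d)
        z <- matrix(rnorm(n * d), n)
        expect_lt(max(abs(isa_attention(z, p) - loop_isa(z, p))), 1e-5)
      }
    }
  })
})

test_that("a zero scaling matrix D annihilates the ISA output exactly", {
  withr::with_seed(2, {
    p <- random_isa_params(10, 81)
    p$D <- matrix(0, 10, 81)
    z <- matrix(rnorm(10 * 81), 10)
    expect_equal(isa_attention(z, p), matrix(0, 10, 81))
  })
})

test_that("encoder blocks preserve shape and honour the printed residual", {
  cf <- model_config(C = 8, n_classes = 2, seed = 3)
  pp <- init_params(cf)
  z <- matrix(rnorm(10 * 81), 10, 81)

  for (variant in c("isa", "original")) {
    cfv <- model_config(C = 8, n_classes = 2, seed = 3, variant = variant)
    bp <- init_params(cfv)$blocks[[1]]
    out <- encoder_block(z, bp, variant)
    expect_equal(dim(out), c(10, 81))

    # with FFN weights and biases zeroed the block returns LN(z') exactly
    bp0 <- bp
    bp0$W1[] <- 0; bp0$b1[] <- 0; bp0$W2[] <- 0; bp0$b2[] <- 0
    l1 <- eegemotion:::ln_fwd(z, bp0$ln1_g, bp0$ln1_b)
    att <- if (variant == "isa") {
      eegemotion:::isa_fwd(l1$out, bp0$attn, 1L, 10, 81, 1e-6)$out
    } else {
      eegemotion:::orig_fwd(l1$out, bp0$attn, 1L, 10, 81, 1e-6)$out
    }
    zp <- att + z
    lnzp <- eegemotion:::ln_fwd(zp, bp0$ln2_g, bp0$ln2_b)$out
    expect_equal(encoder_block(z, bp0, variant), lnzp)
  }

  # an L = 15 stack composes without shape change
  zz <- z
  for (l in seq_len(15)) {
    zz <- encoder_block(zz, init_params(cf)$blocks[[(l - 1) %% cf$L + 1]], "isa")
  }
  expect_equal(dim(zz), c(10, 81))
})

test_that("the classification head produces proper class distributions", {
  for (k in c(8, 5)) {
    cf <- model_config(C = 8, n_classes = k)
    pp <- init_params(cf)
    pr <- classify(matrix(rnorm(10 * 81), 10), pp$head)
    expect_length(pr, k)
    expect_true(all(pr > 0))
    expect_equal(sum(pr), 1)
  }
  withr::with_seed(4, {
    for (i in 1:20) {
      P <- eegemotion:::softmax_rows(matrix(rnorm(12, sd = 5), 3, 4))
      expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-6)
    }
  })
})

test_that("backprop matches finite differences on small shapes", {
  cf <- tiny_config()
  pp <- init_params(cf)
  X4 <- eegemotion:::stack_tensors(random_tensors(4))
  y <- c(1L, 2L, 3L, 1L)
  lossfn <- function(par) {
    fw <- eegemotion:::net_fwd(X4, par, cf, keep_cache = FALSE)
    eegemotion:::cross_entropy(fw$logits, y)$loss
  }
  fw <- eegemotion:::net_fwd(X4, pp, cf)
  ce <- eegemotion:::cross_entropy(fw$logits, y)
  gr <- eegemotion:::net_bwd(ce$dlogits, fw, pp, cf)

  check <- function(get, set, g) {
    ix <- withr::with_seed(1, sample(length(get(pp)), min(5, length(get(pp)))))
    for (i in ix) {
      e <- 1e-5
      p1 <- set(pp, i, e); p2 <- set(pp, i, -e)
      num <- (lossfn(p1) - lossfn(p2)) / (2 * e)
      expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-6), 1e-3)
    }
  }
  check(function(p) p$blocks[[1]]$attn$D,
        function(p, i, e) { p$blocks[[1]]$attn$D[i] <- p$blocks[[1]]$attn$D[i] + e; p },
        gr$blocks[[1]]$attn$D)
  check(function(p) p$blocks[[2]]$attn$Usum,
        function(p, i, e) { p$blocks[[2]]$attn$Usum[i] <- p$blocks[[2]]$attn$Usum[i] + e; p },
        gr$blocks[[2]]$attn$Usum)
  check(function(p) p$blocks[[1]]$attn$Ucopy,
        function(p, i, e) { p$blocks[[1]]$attn$Ucopy[i] <- p$blocks[[1]]$attn$Ucopy[i] + e; p },
        gr$blocks[[1]]$attn$Ucopy)
  check(function(p) p$tokens,
        function(p, i, e) { p$tokens[i] <- p$tokens[i] + e; p },
        gr$tokens)
  check(function(p) p$conv$W1,
        function(p, i, e) { p$conv$W1[i] <- p$conv$W1[i] + e; p },
        gr$conv$W1)
})

test_that("the compiled fast path reproduces the reference implementation", {
  cf <- model_config(C = 4, H = 9, W = 9, L = 3, n_classes = 3,
                     conv_hidden = 5, ffn_hidden = 10, seed = 11)
  pp <- init_params(cf)
  X4 <- eegemotion:::stack_tensors(random_tensors(7, C = 4, H = 9, W = 9))
  y <- c(1L, 2L, 3L, 1L, 2L, 3L, 1L)
  fw <- eegemotion:::net_fwd(X4, pp, cf)
  ce <- eegemotion:::cross_entropy(fw$logits, y)
  gr <- eegemotion:::net_bwd(ce$dlogits, fw, pp, cf)
  res <- eegemotion:::.cpp_net_grad(X4, pp, cf, y)
  expect_lt(max(abs(fw$logits - res$logits)), 1e-10)
  expect_lt(abs(ce$loss - res$loss), 1e-12)
  cmp <- function(a, b) {
    if (is.list(a)) return(max(mapply(cmp, a, b)))
    max(abs(as.numeric(a) - as.numeric(b)))
  }
  expect_lt(cmp(gr, res$grads), 1e-10)
})

test_that("forward passes are deterministic and end-to-end shapes hold", {
  for (variant in c("isa", "original")) {
    cf <- model_config(C = 8, n_classes = 5, variant = variant, L = 2)
    pp <- init_params(cf)
    X4 <- eegemotion:::stack_tensors(random_tensors(2, C = 8, H = 9, W = 9))
    l1 <- eegemotion:::net_fwd(X4, pp, cf, keep_cache = FALSE)$logits
    l2 <- eegemotion:::net_fwd(X4, pp, cf, keep_cache = FALSE)$logits
    expect_identical(l1, l2)
    expect_equal(dim(l1), c(2, 5))
  }
})
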