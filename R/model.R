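#' Model architecture configuration
#'
#' Describes the classifier: a two-layer 3x3 convolutional front-end
#' (C -> `conv_hidden` -> C channels, stride 1, padding 1), plane-to-token
#' reshape (token width `d = H * W`), two learned tokens prepended
#' (`n_tokens = C + 2`), a stack of `L` pre-norm transformer encoder
#' blocks, and a token-mixing + linear + softmax head. The encoder's
#' attention is either the efficient linear-algebraic attention
#' (`variant = "isa"`; norm-scaled key-value Hadamard products with
#' trainable mixing matrices) or standard single-head scaled-dot-product
#' self-attention (`variant = "original"`).
#'
#' @param C Input feature planes (8 for the combined DE + enhanced-DE
#'   tensor, 4 for a single feature set).
#' @param H,W Grid dimensions (9 x 9).
#' @param L Encoder depth (default 15).
#' @param n_classes Number of output classes.
#' @param conv_hidden Hidden channel count of the front-end (default 32).
#' @param ffn_hidden Feed-forward width (default `4 * d`, the usual
#'   transformer convention).
#' @param variant `"isa"` or `"original"`.
#' @param seed Seed for parameter initialisation.
#' @param eps_scale Guard added to the per-token key/value L2 norms.
#' @return A list of class `model_config`.
#' @export
model_config <- function(C = 8, H = 9, W = 9, L = 15, n_classes = 2,
                         conv_hidden = 32, ffn_hidden = NULL,
                         variant = c("isa", "original"), seed = 42,
                         eps_scale = 1e-6) {
  variant <- match.arg(variant)
  stopifnot(L >= 1, n_classes >= 2, C >= 1, H >= 3, W >= 3)
  d <- as.integer(H * W)
  if (is.null(ffn_hidden)) ffn_hidden <- 4L * d
  structure(
    list(C = as.integer(C), H = as.integer(H), W = as.integer(W), d = d,
         n_tokens = as.integer(C + 2L), L = as.integer(L),
         conv_hidden = as.integer(conv_hidden),
         ffn_hidden = as.integer(ffn_hidden),
         n_classes = as.integer(n_classes), variant = variant,
         seed = as.integer(seed), eps_scale = eps_scale),
    class = "model_config"
  )
}

#' Initialise model parameters
#'
#' Draws all trainable parameters under the config's seed, in a fixed
#' order, so initialisation is reproducible. Weight matrices are Gaussian
#' with fan-based scales; the learned tokens are N(0, 0.02^2); the dynamic
#' scaling matrix D starts at all ones; the token-mixing matrix U_copy
#' starts uniform at 1/n (aggregate-and-broadcast); layer-norm gains start
#' at 1; all biases at 0; the head's token weights at 1/n.
#'
#' @param config A [model_config()].
#' @return A nested list of parameter arrays.
#' @export
init_params <- function(config) {
  cf <- config
  rmat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)
  withr::with_seed(cf$seed, {
    list(
      conv = list(
        W1 = rmat(9L * cf$C, cf$conv_hidden, sqrt(2 / (9 * cf$C))),
        b1 = numeric(cf$conv_hidden),
        W2 = rmat(9L * cf$conv_hidden, cf$C, sqrt(2 / (9 * cf$conv_hidden))),
        b2 = numeric(cf$C)
      ),
      tokens = rmat(2L, cf$d, 0.02),
      blocks = lapply(seq_len(cf$L), function(l) {
        attn <- if (cf$variant == "isa") {
          list(Uqkv = rmat(cf$d, 3L * cf$d, 1 / sqrt(cf$d)),
               D = matrix(1, cf$n_tokens, cf$d),
               Ucopy = matrix(1 / cf$n_tokens, cf$n_tokens, cf$n_tokens),
               Usum = rmat(cf$d, cf$d, 1 / sqrt(cf$d)),
               Uproj = rmat(cf$d, cf$d, 1 / sqrt(cf$d)))
        } else {
          list(Uqkv = rmat(cf$d, 3L * cf$d, 1 / sqrt(cf$d)),
               Uproj = rmat(cf$d, cf$d, 1 / sqrt(cf$d)))
        }
        list(ln1_g = rep(1, cf$d), ln1_b = numeric(cf$d), attn = attn,
             ln2_g = rep(1, cf$d), ln2_b = numeric(cf$d),
             W1 = rmat(cf$d, cf$ffn_hidden, sqrt(2 / (cf$d + cf$ffn_hidden))),
             b1 = numeric(cf$ffn_hidden),
             W2 = rmat(cf$ffn_hidden, cf$d, sqrt(2 / (cf$d + cf$ffn_hidden))),
             b2 = numeric(cf$d))
      }),
      head = list(w = rep(1 / cf$n_tokens, cf$n_tokens),
                  Wc = rmat(cf$d, cf$n_classes, sqrt(2 / (cf$d + cf$n_classes))),
                  bc = numeric(cf$n_classes))
    )
  })
}

# ---- small dense helpers (column-wise broadcast without sweep()) -----------

add_cols <- function(M, v) M + rep(v, rep.int(nrow(M), length(v)))
scale_cols <- function(M, v) M * rep(v, rep.int(nrow(M), length(v)))

# sigmoid approximation of GELU (Hendrycks & Gimpel): x * sigmoid(1.702 x).
# One transcendental per element; the sigmoid is cached so the derivative
# sig + 1.702 x sig (1 - sig) costs no further exp calls in the backward pass.
gelu_sig <- function(x) 1 / (1 + exp(-1.702 * x))
gelu <- function(x) x * gelu_sig(x)
gelu_prime_from_sig <- function(x, sig) sig + 1.702 * x * sig * (1 - sig)

# ---- convolution via im2col over the (H, W, C, B) batch layout -------------

pad_hw <- function(A) {
  d <- dim(A)
  P <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  P[1L + seq_len(d[1]), 1L + seq_len(d[2]), , ] <- A
  P
}

# padded (H+2, W+2, C, B) -> (H*W*B) x (9*C); row order: col-within-row
# (row-major grid positions) fastest, then sample; column blocks ordered by
# kernel offset (ki outer, kj inner), channels contiguous within a block
im2col3 <- function(P) {
  d <- dim(P); H <- d[1] - 2L; W <- d[2] - 2L; C <- d[3]; B <- d[4]
  out <- matrix(0, H * W * B, 9L * C)
  o <- 0L
  for (ki in 0:2) for (kj in 0:2) {
    slab <- P[ki + seq_len(H), kj + seq_len(W), , , drop = FALSE]
    slab <- aperm(slab, c(2L, 1L, 4L, 3L))
    dim(slab) <- c(H * W * B, C)
    out[, o + seq_len(C)] <- slab
    o <- o + C
  }
  out
}

col2im3 <- function(dcols, H, W, C, B) {
  G <- array(0, dim = c(H + 2L, W + 2L, C, B))
  o <- 0L
  for (ki in 0:2) for (kj in 0:2) {
    blk <- dcols[, o + seq_len(C), drop = FALSE]
    dim(blk) <- c(W, H, B, C)
    G[ki + seq_len(H), kj + seq_len(W), , ] <-
      G[ki + seq_len(H), kj + seq_len(W), , ] + aperm(blk, c(2L, 1L, 4L, 3L))
    o <- o + C
  }
  G
}

conv_fwd <- function(X4, cp) {
  d <- dim(X4); H <- d[1]; W <- d[2]; B <- d[4]
  C1cols <- im2col3(pad_hw(X4))
  O1 <- add_cols(C1cols %*% cp$W1, cp$b1)
  R1 <- pmax(O1, 0)
  ch1 <- ncol(cp$W1)
  A1 <- R1; dim(A1) <- c(W, H, B, ch1)
  A1 <- aperm(A1, c(2L, 1L, 4L, 3L))
  C2cols <- im2col3(pad_hw(A1))
  O2 <- add_cols(C2cols %*% cp$W2, cp$b2)
  R2 <- pmax(O2, 0)
  list(out = R2, C1cols = C1cols, O1 = O1, C2cols = C2cols, O2 = O2,
       H = H, W = W, B = B, ch1 = ch1)
}

conv_bwd <- function(dR2, cache, cp) {
  dO2 <- dR2 * (cache$O2 > 0)
  gW2 <- crossprod(cache$C2cols, dO2)
  gb2 <- colSums(dO2)
  dC2 <- tcrossprod(dO2, cp$W2)
  dP2 <- col2im3(dC2, cache$H, cache$W, cache$ch1, cache$B)
  dA1 <- dP2[1L + seq_len(cache$H), 1L + seq_len(cache$W), , , drop = FALSE]
  dR1 <- aperm(dA1, c(2L, 1L, 4L, 3L))
  dim(dR1) <- c(cache$H * cache$W * cache$B, cache$ch1)
  dO1 <- dR1 * (cache$O1 > 0)
  list(conv = list(W1 = crossprod(cache$C1cols, dO1), b1 = colSums(dO1),
                   W2 = gW2, b2 = gb2))
}

# ---- layer norm ------------------------------------------------------------

ln_fwd <- function(Z, g, b, eps = 1e-5) {
  mu <- rowMeans(Z)
  Zc <- Z - mu
  inv <- 1 / sqrt(rowMeans(Zc * Zc) + eps)
  xhat <- Zc * inv
  list(out = add_cols(scale_cols(xhat, g), b), xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dxhat <- scale_cols(dY, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  list(dZ = (dxhat - m1 - cache$xhat * m2) * cache$inv, dg = dg, db = db)
}

# ---- attention -------------------------------------------------------------

# apply an n x n token-mixing matrix per sample to a (B*n) x d stack
# (rows grouped per sample, token index fastest)
tokmix <- function(M, U, n) {
  dm <- dim(M)
  dim(M) <- c(n, prod(dm) / n)
  R <- U %*% M
  dim(R) <- dm
  R
}

isa_fwd <- function(Ain, p, B, n, d, eps) {
  QKV <- Ain %*% p$Uqkv
  Q <- QKV[, seq_len(d), drop = FALSE]
  K <- QKV[, d + seq_len(d), drop = FALSE]
  V <- QKV[, 2L * d + seq_len(d), drop = FALSE]
  nK <- sqrt(rowSums(K * K)); sK <- pmax(nK, eps)
  nV <- sqrt(rowSums(V * V)); sV <- pmax(nV, eps)
  Kn <- K / sK
  Vn <- V / sV
  A0 <- Kn * Vn
  A1 <- tokmix(A0, p$Ucopy, n)
  A2 <- A1 %*% p$Usum
  Dt <- p$D[rep(seq_len(n), B), , drop = FALSE]
  G <- Dt * Q * A2
  out <- G %*% p$Uproj
  list(out = out, Ain = Ain, Q = Q, K = K, V = V, sK = sK, sV = sV,
       actK = nK > eps, actV = nV > eps, Kn = Kn, Vn = Vn,
       A0 = A0, A1 = A1, A2 = A2, Dt = Dt, G = G)
}

isa_bwd <- function(dOut, cc, p, B, n, d) {
  dG <- tcrossprod(dOut, p$Uproj)
  gUproj <- crossprod(cc$G, dOut)
  gD <- unname(rowsum(dG * cc$Q * cc$A2, group = rep(seq_len(n), B)))
  dQ <- dG * cc$Dt * cc$A2
  dA2 <- dG * cc$Dt * cc$Q
  dA1 <- tcrossprod(dA2, p$Usum)
  gUsum <- crossprod(cc$A1, dA2)
  dA1T <- dA1; dim(dA1T) <- c(n, B * d)
  A0T <- cc$A0; dim(A0T) <- c(n, B * d)
  gUcopy <- tcrossprod(dA1T, A0T)
  dA0 <- crossprod(p$Ucopy, dA1T)
  dim(dA0) <- c(B * n, d)
  dKn <- dA0 * cc$Vn
  dVn <- dA0 * cc$Kn
  dK <- dKn / cc$sK - cc$K * (rowSums(dKn * cc$K) / cc$sK^3 * cc$actK)
  dV <- dVn / cc$sV - cc$V * (rowSums(dVn * cc$V) / cc$sV^3 * cc$actV)
  dQKV <- cbind(dQ, dK, dV)
  list(dAin = tcrossprod(dQKV, p$Uqkv),
       grads = list(Uqkv = crossprod(cc$Ain, dQKV), D = gD,
                    Ucopy = gUcopy, Usum = gUsum, Uproj = gUproj))
}

orig_fwd <- function(Ain, p, B, n, d, eps) {
  QKV <- Ain %*% p$Uqkv
  Q <- QKV[, seq_len(d), drop = FALSE]
  K <- QKV[, d + seq_len(d), drop = FALSE]
  V <- QKV[, 2L * d + seq_len(d), drop = FALSE]
  PV <- matrix(0, B * n, d)
  Plist <- vector("list", B)
  for (s in seq_len(B)) {
    r <- (s - 1L) * n + seq_len(n)
    S <- tcrossprod(Q[r, , drop = FALSE], K[r, , drop = FALSE]) / sqrt(d)
    S <- S - apply(S, 1, max)
    P <- exp(S); P <- P / rowSums(P)
    Plist[[s]] <- P
    PV[r, ] <- P %*% V[r, , drop = FALSE]
  }
  list(out = PV %*% p$Uproj, Ain = Ain, Q = Q, K = K, V = V,
       PV = PV, Plist = Plist)
}

orig_bwd <- function(dOut, cc, p, B, n, d) {
  dPV <- tcrossprod(dOut, p$Uproj)
  gUproj <- crossprod(cc$PV, dOut)
  dQ <- matrix(0, B * n, d); dK <- dQ; dV <- dQ
  for (s in seq_len(B)) {
    r <- (s - 1L) * n + seq_len(n)
    P <- cc$Plist[[s]]
    dA <- dPV[r, , drop = FALSE]
    dP <- tcrossprod(dA, cc$V[r, , drop = FALSE])
    dV[r, ] <- crossprod(P, dA)
    dS <- P * (dP - rowSums(dP * P))
    dQ[r, ] <- dS %*% cc$K[r, , drop = FALSE] / sqrt(d)
    dK[r, ] <- crossprod(dS, cc$Q[r, , drop = FALSE]) / sqrt(d)
  }
  dQKV <- cbind(dQ, dK, dV)
  list(dAin = tcrossprod(dQKV, p$Uqkv),
       grads = list(Uqkv = crossprod(cc$Ain, dQKV), Uproj = gUproj))
}

attn_fwd <- function(Ain, p, cf, B) {
  if (cf$variant == "isa") isa_fwd(Ain, p, B, cf$n_tokens, cf$d, cf$eps_scale)
  else orig_fwd(Ain, p, B, cf$n_tokens, cf$d, cf$eps_scale)
}

attn_bwd <- function(dOut, cc, p, cf, B) {
  if (cf$variant == "isa") isa_bwd(dOut, cc, p, B, cf$n_tokens, cf$d)
  else orig_bwd(dOut, cc, p, B, cf$n_tokens, cf$d)
}

# ---- encoder block ---------------------------------------------------------
# z' = ATTN(LN(z)) + z ;  z_next = Linear(GELU(Linear(LN(z')))) + LN(z')
# (second residual adds the *normalised* z', as the model is specified)

block_fwd <- function(Z, bp, cf, B) {
  l1 <- ln_fwd(Z, bp$ln1_g, bp$ln1_b)
  at <- attn_fwd(l1$out, bp$attn, cf, B)
  Zp <- at$out + Z
  l2 <- ln_fwd(Zp, bp$ln2_g, bp$ln2_b)
  B1 <- add_cols(l2$out %*% bp$W1, bp$b1)
  sig <- gelu_sig(B1)
  Hh <- B1 * sig
  O <- add_cols(Hh %*% bp$W2, bp$b2)
  list(out = O + l2$out, l1 = l1, at = at, l2 = l2, B1 = B1, sig = sig, Hh = Hh)
}

block_bwd <- function(dZnext, cc, bp, cf, B) {
  dO <- dZnext
  dHh <- tcrossprod(dO, bp$W2)
  gW2 <- crossprod(cc$Hh, dO)
  gb2 <- colSums(dO)
  dB1 <- dHh * gelu_prime_from_sig(cc$B1, cc$sig)
  gW1 <- crossprod(cc$l2$out, dB1)
  gb1 <- colSums(dB1)
  dl2out <- dZnext + tcrossprod(dB1, bp$W1)
  l2b <- ln_bwd(dl2out, cc$l2, bp$ln2_g)
  dZp <- l2b$dZ
  ab <- attn_bwd(dZp, cc$at, bp$attn, cf, B)
  l1b <- ln_bwd(ab$dAin, cc$l1, bp$ln1_g)
  list(dZ = dZp + l1b$dZ,
       grads = list(ln1_g = l1b$dg, ln1_b = l1b$db, attn = ab$grads,
                    ln2_g = l2b$dg, ln2_b = l2b$db,
                    W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

# ---- token plumbing and head ----------------------------------------------

# conv output ((H*W*B) x C, grid positions row-major) -> (B*C) x d token stack
planes_to_tokens <- function(R2, H, W, B, C) {
  A <- R2; dim(A) <- c(H * W, B, C)
  A <- aperm(A, c(3L, 2L, 1L))
  dim(A) <- c(C * B, H * W)
  A
}

tokens_to_planes <- function(dZ0, H, W, B, C) {
  A <- dZ0; dim(A) <- c(C, B, H * W)
  A <- aperm(A, c(3L, 2L, 1L))
  dim(A) <- c(H * W * B, C)
  A
}

augment_rows <- function(n, B) {
  tok <- as.vector(outer(1:2, (seq_len(B) - 1L) * n, `+`))
  dat <- as.vector(outer(3:n, (seq_len(B) - 1L) * n, `+`))
  list(tok = tok, dat = dat)
}

head_fwd <- function(ZL, hp, B, n, d) {
  A3 <- ZL; dim(A3) <- c(n, B * d)
  zD <- matrix(crossprod(A3, hp$w), B, d)
  list(logits = add_cols(zD %*% hp$Wc, hp$bc), A3 = A3, zD = zD)
}

head_bwd <- function(dlogits, cc, hp, B, n, d) {
  gWc <- crossprod(cc$zD, dlogits)
  gbc <- colSums(dlogits)
  dzD <- tcrossprod(dlogits, hp$Wc)
  gw <- as.vector(cc$A3 %*% as.vector(dzD))
  dZL <- hp$w %o% as.vector(dzD)
  dim(dZL) <- c(n * B, d)
  list(dZL = dZL, grads = list(w = gw, Wc = gWc, bc = gbc))
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  P <- exp(logits - m)
  P / rowSums(P)
}

# ---- full network ----------------------------------------------------------

# X4: (H, W, C, B) batch; returns logits and (optionally) all caches
net_fwd <- function(X4, params, cf, keep_cache = TRUE) {
  B <- dim(X4)[4]
  n <- cf$n_tokens
  cv <- conv_fwd(X4, params$conv)
  Z0 <- planes_to_tokens(cv$out, cf$H, cf$W, B, cf$C)
  rows <- augment_rows(n, B)
  Z <- matrix(0, B * n, cf$d)
  Z[rows$tok, ] <- params$tokens[rep(1:2, B), , drop = FALSE]
  Z[rows$dat, ] <- Z0
  bcaches <- if (keep_cache) vector("list", cf$L) else NULL
  for (l in seq_len(cf$L)) {
    bc <- block_fwd(Z, params$blocks[[l]], cf, B)
    Z <- bc$out
    if (keep_cache) { bc$out <- NULL; bcaches[[l]] <- bc }
  }
  hd <- head_fwd(Z, params$head, B, n, cf$d)
  list(logits = hd$logits, conv = if (keep_cache) cv else NULL,
       rows = rows, blocks = bcaches, head = hd, B = B)
}

net_bwd <- function(dlogits, fw, params, cf) {
  B <- fw$B; n <- cf$n_tokens
  hb <- head_bwd(dlogits, fw$head, params$head, B, n, cf$d)
  dZ <- hb$dZL
  bgrads <- vector("list", cf$L)
  for (l in rev(seq_len(cf$L))) {
    bb <- block_bwd(dZ, fw$blocks[[l]], params$blocks[[l]], cf, B)
    dZ <- bb$dZ
    bgrads[[l]] <- bb$grads
  }
  gtokens <- unname(rowsum(dZ[fw$rows$tok, , drop = FALSE], group = rep(1:2, B)))
  dZ0 <- dZ[fw$rows$dat, , drop = FALSE]
  dR2 <- tokens_to_planes(dZ0, cf$H, cf$W, B, cf$C)
  cg <- conv_bwd(dR2, fw$conv, params$conv)
  list(conv = cg$conv, tokens = gtokens, blocks = bgrads, head = hb$grads)
}

cross_entropy <- function(logits, y_idx) {
  B <- nrow(logits)
  P <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(B), y_idx)] + eps))
  dl <- P
  dl[cbind(seq_len(B), y_idx)] <- dl[cbind(seq_len(B), y_idx)] - 1
  list(loss = loss, dlogits = dl / B, probs = P)
}

# stack a list of (C, H, W) tensors into the internal (H, W, C, B) layout
stack_tensors <- function(tensors) {
  d <- dim(tensors[[1]])
  X <- array(unlist(tensors, use.names = FALSE), dim = c(d, length(tensors)))
  aperm(X, c(2L, 3L, 1L, 4L))
}
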