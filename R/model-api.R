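#' Convolutional front-end for one feature tensor
#'
#' Two 3x3 convolutions (C -> conv_hidden -> C channels, stride 1,
#' padding 1), each followed by a ReLU; spatial dimensions are preserved.
#'
#' @param x Array of shape (C, H, W).
#' @param params Parameters from [init_params()].
#' @param config The matching [model_config()].
#' @return Array of shape (C, H, W).
#' @export
conv_frontend <- function(x, params, config) {
  d <- dim(x)
  if (length(d) != 3 || any(d != c(config$C, config$H, config$W))) {
    abort(sprintf("expected a %d x %d x %d tensor", config$C, config$H, config$W))
  }
  X4 <- aperm(array(x, dim = c(d, 1L)), c(2L, 3L, 1L, 4L))
  R2 <- conv_fwd(X4, params$conv)$out          # (H*W) x C, positions row-major
  z <- t(R2)                                   # C x d token rows
  unreshape_tokens(z, config$H, config$W)
}

#' Flatten feature planes to token rows
#'
#' Row i of the result is plane i flattened row-major; the inverse
#' operation is [unreshape_tokens()].
#'
#' @param x Array of shape (C, H, W).
#' @return A C x (H*W) matrix.
#' @export
reshape_tokens <- function(x) {
  stopifnot(length(dim(x)) == 3)
  t(apply(x, 1, function(m) as.vector(t(m))))
}

#' @rdname reshape_tokens
#' @param z A C x (H*W) matrix of flattened planes.
#' @param H,W Grid dimensions.
#' @export
unreshape_tokens <- function(z, H, W) {
  stopifnot(ncol(z) == H * W)
  out <- array(0, dim = c(nrow(z), H, W))
  for (i in seq_len(nrow(z))) out[i, , ] <- matrix(z[i, ], H, W, byrow = TRUE)
  out
}

#' Prepend the learned tokens
#'
#' Adds the two trainable token rows (drawn N(0, 0.02^2) at initialisation
#' under the config seed) above the C plane tokens, giving the
#' (C+2) x (H*W) encoder input.
#'
#' @param z0 C x (H*W) matrix from [reshape_tokens()].
#' @param params Parameters from [init_params()].
#' @return A (C+2) x (H*W) matrix.
#' @export
token_augment <- function(z0, params) {
  rbind(params$tokens, z0)
}

#' Efficient linear-algebraic attention (single sample)
#'
#' Computes `[Q, K, V] = z U_qkv` (bias-free), normalises K and V per
#' token by their L2 norms over the feature axis (with a small guard
#' epsilon), forms the Hadamard interaction `(K/||K||) * (V/||V||)`,
#' mixes it across tokens by `U_copy` (n x n) and across features by
#' `U_sum` (d x d), gates with the trainable scaling matrix `D` and the
#' queries via Hadamard products, and projects with `U_proj` (bias-free):
#' `out = (D * Q * (U_copy ((K/s_K) * (V/s_V)) U_sum)) U_proj`.
#'
#' @param z n x d token matrix.
#' @param params List with `Uqkv` (d x 3d), `D` (n x d), `Ucopy` (n x n),
#'   `Usum` (d x d), `Uproj` (d x d).
#' @param eps Norm guard (default 1e-6).
#' @return n x d matrix.
#' @export
isa_attention <- function(z, params, eps = 1e-6) {
  n <- nrow(z); d <- ncol(z)
  if (!all(dim(params$Uqkv) == c(d, 3 * d))) abort("Uqkv must be d x 3d")
  if (!all(dim(params$D) == c(n, d))) abort("D must be n x d")
  if (!all(dim(params$Ucopy) == c(n, n))) abort("Ucopy must be n x n")
  if (!all(dim(params$Usum) == c(d, d)) || !all(dim(params$Uproj) == c(d, d))) {
    abort("Usum and Uproj must be d x d")
  }
  isa_fwd(z, params, 1L, n, d, eps)$out
}

#' One encoder block (single sample)
#'
#' Pre-norm block: `z' = ATTN(LN(z)) + z`, then
#' `z_next = Linear(GELU(Linear(LN(z')))) + LN(z')` — note the second
#' residual adds the *normalised* `z'`. `variant = "original"` swaps the
#' efficient attention for standard single-head scaled-dot-product
#' self-attention with the same projection layout.
#'
#' @param z n x d token matrix.
#' @param block_params One element of `params$blocks` from [init_params()].
#' @param variant `"isa"` or `"original"`.
#' @param eps_scale Norm guard for the efficient attention.
#' @return n x d matrix.
#' @export
encoder_block <- function(z, block_params, variant = c("isa", "original"),
                          eps_scale = 1e-6) {
  variant <- match.arg(variant)
  cf <- list(variant = variant, n_tokens = nrow(z), d = ncol(z),
             eps_scale = eps_scale)
  block_fwd(z, block_params, cf, 1L)$out
}

#' Classification head (single sample)
#'
#' Mixes the n token rows with trainable weights `w` into a single
#' d-vector `z_D = w' z_L`, applies an affine map to `n_classes` logits,
#' and returns softmax probabilities.
#'
#' @param zL n x d encoder output.
#' @param head_params `params$head` from [init_params()]: `w` (length n),
#'   `Wc` (d x n_classes), `bc` (length n_classes).
#' @return Probability vector of length `n_classes` (sums to 1).
#' @export
classify <- function(zL, head_params) {
  hd <- head_fwd(zL, head_params, 1L, nrow(zL), ncol(zL))
  drop(softmax_rows(hd$logits))
}
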