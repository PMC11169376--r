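# small, fast fixtures shared across tests; everything is generated in code

# a compact 4-class band-power recording (DEAP-style channel set)
small_recording <- function(n_trials = 8, trial_s = 4, seed = 101,
                            n_channels = 32) {
  generate_recording(synth_spec(n_channels = n_channels, n_trials = n_trials,
                                trial_s = trial_s, seed = seed))
}

# a model configuration small enough for exhaustive numeric checks
tiny_config <- function(n_classes = 3, ...) {
  model_config(C = 3, H = 3, W = 3, L = 2, n_classes = n_classes,
               conv_hidden = 4, ffn_hidden = 6, seed = 7, ...)
}

random_tensors <- function(n, C = 3, H = 3, W = 3, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    array(rnorm(C * H * W), c(C, H, W))
  }))
}

# literal, loop-based evaluation of the efficient attention, kept deliberately
# naive so it is an independent oracle for the vectorised implementation
loop_isa <- function(z, p, eps = 1e-6) {
  d <- ncol(z); n <- nrow(z)
  QKV <- z %*% p$Uqkv
  Q <- QKV[, 1:d, drop = FALSE]
  K <- QKV[, d + 1:d, drop = FALSE]
  V <- QKV[, 2 * d + 1:d, drop = FALSE]
  Kn <- K; Vn <- V
  for (i in 1:n) {
    Kn[i, ] <- K[i, ] / max(sqrt(sum(K[i, ]^2)), eps)
    Vn[i, ] <- V[i, ] / max(sqrt(sum(V[i, ]^2)), eps)
  }
  A <- Kn * Vn
  A <- p$Ucopy %*% A %*% p$Usum
  G <- matrix(0, n, d)
  for (i in 1:n) for (j in 1:d) G[i, j] <- p$D[i, j] * Q[i, j] * A[i, j]
  G %*% p$Uproj
}

random_isa_params <- function(n, d) {
  list(Uqkv = matrix(rnorm(d * 3 * d), d),
       D = matrix(rnorm(n * d), n),
       Ucopy = matrix(rnorm(n * n), n),
       Usum = matrix(rnorm(d * d), d),
       Uproj = matrix(rnorm(d * d), d))
}

# independent per-class arithmetic for macro metrics (the brute-force oracle)
oracle_macro <- function(cm) {
  n <- sum(cm); k <- nrow(cm)
  acc <- pre <- spe <- rec <- f1 <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- n - tp - fn - fp
    acc[c] <- (tp + tn) / n
    pre[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    spe[c] <- if (tn + fp > 0) tn / (tn + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (pre[c] + rec[c] > 0) 2 * pre[c] * rec[c] / (pre[c] + rec[c]) else 0
  }
  c(accuracy = mean(acc), precision = mean(pre), specificity = mean(spe),
    recall = mean(rec), f1 = mean(f1))
}

find_python_or_null <- function() {
  p <- Sys.which("python")
  if (nzchar(p)) p else NULL
}
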