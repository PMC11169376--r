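count_params <- function(x) sum(rapply(x, length, how = "unlist"))

# analytic matrix-multiply MAC counts for one forward pass at batch 1;
# elementwise work (activations, norms, Hadamard products) is O(n*d) per
# block and is not counted — the convention is documented and switchable
# between 1 MAC = 1 FLOP and 1 MAC = 2 FLOPs
flops_table <- function(cf, factor = 1) {
  n <- cf$n_tokens; d <- cf$d; hw <- cf$H * cf$W
  attn <- if (cf$variant == "isa") {
    n * d * 3 * d + n^2 * d + 2 * n * d * d        # qkv, token mix, Usum, Uproj
  } else {
    n * d * 3 * d + 2 * n^2 * d + n * d * d        # qkv, scores, attn*V, Uproj
  }
  tibble::tibble(
    component = c("conv1", "conv2", "attention", "ffn", "head"),
    layers = c(1L, 1L, cf$L, cf$L, 1L),
    flops_each = factor * c(hw * 9 * cf$C * cf$conv_hidden,
                            hw * 9 * cf$conv_hidden * cf$C,
                            attn,
                            2 * n * d * cf$ffn_hidden,
                            n * d + d * cf$n_classes),
    flops = layers * flops_each
  )
}

params_table <- function(cf) {
  p <- init_params(cf)
  blk <- p$blocks[[1]]
  tibble::tibble(
    component = c("conv1", "conv2", "tokens", "layer_norms", "attention",
                  "ffn", "head"),
    layers = c(1L, 1L, 1L, cf$L, cf$L, cf$L, 1L),
    params_each = c(count_params(p$conv[c("W1", "b1")]),
                    count_params(p$conv[c("W2", "b2")]),
                    length(p$tokens),
                    count_params(blk[c("ln1_g", "ln1_b", "ln2_g", "ln2_b")]),
                    count_params(blk$attn),
                    count_params(blk[c("W1", "b1", "W2", "b2")]),
                    count_params(p$head)),
    params = layers * params_each
  )
}

#' Parameter and FLOP audit of one model configuration
#'
#' Trainable parameters are counted exactly by enumerating the initialised
#' parameter tree; FLOPs are the matrix-multiply multiply-accumulate count
#' of one forward pass at batch size 1 (`flop_convention = "mac"` counts
#' 1 MAC as 1 FLOP; `"mult-add"` counts 2).
#'
#' @param config A [model_config()].
#' @param flop_convention `"mac"` or `"mult-add"`.
#' @return A tibble with one row per component and attributes
#'   `params_total`, `flops_total`.
#' @export
audit_model <- function(config, flop_convention = c("mac", "mult-add")) {
  flop_convention <- match.arg(flop_convention)
  fac <- if (flop_convention == "mac") 1 else 2
  pt <- params_table(config)
  ft <- flops_table(config, fac)
  tab <- dplyr::full_join(pt, ft, by = c("component", "layers"))
  tab$variant <- config$variant
  tab <- tab[, c("variant", "component", "layers", "params_each", "params",
                 "flops_each", "flops")]
  attr(tab, "params_total") <- sum(tab$params, na.rm = TRUE)
  attr(tab, "flops_total") <- sum(tab$flops, na.rm = TRUE)
  tab
}

#' Compare the efficient and original encoder variants
#'
#' Audits the same architecture under both encoder variants and reports
#' total trainable parameters (Params) and forward-pass FLOPs for each,
#' with the percentage change of the efficient variant relative to the
#' original (positive = reduction). With the package's chosen shapes for
#' the mixing matrices (`U_copy` n x n, `U_sum` d x d), the efficient
#' attention carries extra trainable state (`D`, `U_copy`, `U_sum`), so
#' the sign of the difference is an empirical property of the
#' configuration, not an assumption.
#'
#' @param config A [model_config()] (its `variant` field is ignored).
#' @param flop_convention Passed to [audit_model()].
#' @return A list of class `encoder_audit` with per-variant tables, a
#'   `totals` tibble, and `reduction_pct` (params, flops).
#' @export
audit_encoders <- function(config, flop_convention = c("mac", "mult-add")) {
  flop_convention <- match.arg(flop_convention)
  cfs <- lapply(c("isa", "original"), function(v) {
    cf <- config; cf$variant <- v; cf
  })
  tabs <- lapply(cfs, audit_model, flop_convention = flop_convention)
  totals <- tibble::tibble(
    variant = c("isa", "original"),
    params = vapply(tabs, attr, numeric(1), "params_total"),
    flops = vapply(tabs, attr, numeric(1), "flops_total")
  )
  red <- c(params = 100 * (totals$params[2] - totals$params[1]) / totals$params[2],
           flops = 100 * (totals$flops[2] - totals$flops[1]) / totals$flops[2])
  structure(list(tables = setNames(tabs, c("isa", "original")),
                 totals = totals, reduction_pct = red,
                 flop_convention = flop_convention),
            class = "encoder_audit")
}

#' @export
print.encoder_audit <- function(x, ...) {
  fmt_m <- function(v) sprintf("%.2fM", v / 1e6)
  t <- x$totals
  cat("encoder efficiency audit (", x$flop_convention, " convention):\n", sep = "")
  cat(sprintf("  improved encoder:  Params %s, FLOPs %s\n",
              fmt_m(t$params[1]), fmt_m(t$flops[1])))
  cat(sprintf("  original encoder:  Params %s, FLOPs %s\n",
              fmt_m(t$params[2]), fmt_m(t$flops[2])))
  verb <- function(p) if (p >= 0) "reducing" else "increasing"
  cat(sprintf("  %s Params by %.2f%% and %s FLOPs by %.2f%%\n",
              verb(x$reduction_pct["params"]), abs(x$reduction_pct["params"]),
              verb(x$reduction_pct["flops"]), abs(x$reduction_pct["flops"])))
  invisible(x)
}
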