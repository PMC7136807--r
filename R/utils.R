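# Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which does
# not match tabulated planning figures (e.g. 506.16 -> 506 but 54.5 -> 55).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Allocate `total` into shares `p` as whole numbers that sum exactly to
# `total` (largest-remainder method). Returns numeric to allow totals
# beyond integer range (e.g. cent amounts).
allocate_integer <- function(total, p) {
  stopifnot(total >= 0, all(p >= 0))
  p <- p / sum(p)
  raw <- total * p
  base_n <- floor(raw)
  short <- round(total - sum(base_n))
  if (short > 0) {
    idx <- order(raw - base_n, decreasing = TRUE)[seq_len(short)]
    base_n[idx] <- base_n[idx] + 1
  }
  base_n
}

stop_arg <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
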