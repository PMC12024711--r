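# internal helpers shared across modules

#' Treatment arms, in the fixed package-wide column order
#'
#' All reward matrices, propensity matrices and prescription factors use this
#' order: observation, angioembolization, splenectomy. The order doubles as the
#' tie-break preference (less invasive first).
#' @export
TREATMENTS <- c("OBS", "AE", "SPLENECTOMY")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# deterministic sub-seed derivation; keeps every derived seed < 2^31
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483629
  as.integer(s) + 1L
}

# row-wise minimum of an n x 3 matrix, vectorized
row_min3 <- function(m) pmin(m[, 1L], m[, 2L], m[, 3L])

# index of row-wise minimum with first-wins tie-break (arm order preference)
row_which_min <- function(m) {
  out <- rep.int(1L, nrow(m))
  best <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) {
    better <- m[, j] < best
    out[better] <- j
    best[better] <- m[better, j]
  }
  out
}

as_arm_factor <- function(x) {
  if (is.numeric(x)) x <- TREATMENTS[x]
  factor(as.character(x), levels = TREATMENTS)
}
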