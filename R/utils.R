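# Small shared helpers.

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, runs `expr`, then restores the caller's RNG state, so
#' seeded generators do not perturb the user's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round half away from zero (matches the 2-dp printing convention of the
# percentage tables this package reports)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# linear quantisation of an 8-bit gray patch to l levels in 0..l-1
quantize_gray <- function(patch, levels = 8L, max_gray = 255) {
  q <- floor(patch * levels / (max_gray + 1))
  q[q > levels - 1L] <- levels - 1L
  q[q < 0L] <- 0L
  storage.mode(q) <- "integer"
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
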