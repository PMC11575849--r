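#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `expr`, and restores the
#' previous state on exit, so seeded generators do not disturb user code.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Positive-truncated normal draws by rejection; means here sit several sd
# above zero so rejection is cheap.
rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp
# pipeline artifacts with a config fingerprint without extra dependencies.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # XOR on the low 16 bits only (byte input), keeping h a double in
    # [0, 2^32): bitwXor is limited to 32-bit signed integers
    lo <- h %% 65536
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # multiply by 16777619 mod 2^32 using 16-bit half products
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_domain <- function(...) stop(..., call. = FALSE)
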