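# internal helpers shared across modules

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
# All package randomness flows through this so no function touches global
# RNG state as a side effect.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a stage seed from a global seed
#'
#' Fans one global seed out to per-stage seeds via a deterministic string
#' hash, so pipeline stages are independently reproducible without seed
#' collisions. The result is always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer(h)
}

# Deterministic checksum of an R object (content fingerprint for manifests;
# not cryptographic).
content_checksum <- function(x) {
  b <- as.double(serialize(x, NULL, version = 2))
  m <- 2147483629
  w <- seq_along(b) %% 997 + 1
  s1 <- sum((b + 1) * w) %% m
  s2 <- sum((b + 7)^2 %% m) %% m
  sprintf("%08x%08x-%d", as.integer(s1), as.integer(s2), length(b))
}

# 2-D summed-area table with a zero top row/left column so that
# window sums are P[y2+1, x2+1] - P[y1, x2+1] - P[y2+1, x1] + P[y1, x1]
# (1-based, inclusive pixel ranges [y1, y2] x [x1, x2]).
integral_image <- function(m) {
  P <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  P[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  P
}

window_sum <- function(P, x, y, size) {
  # x, y are 0-based top-left corners; window covers pixels
  # rows y+1..y+size, cols x+1..x+size (1-based)
  P[cbind(y + size + 1L, x + size + 1L)] - P[cbind(y + 1L, x + size + 1L)] -
    P[cbind(y + size + 1L, x + 1L)] + P[cbind(y + 1L, x + 1L)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
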