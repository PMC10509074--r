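#' @importFrom rlang abort warn `%||%`
#' @importFrom stats cor dgamma runif setNames predict
#' @importFrom utils write.csv read.csv
NULL

# Stable 31-bit non-negative hash of character vectors. Used to derive
# sub-seeds and to fold structural identifiers into fingerprint bits; must be
# identical across platforms and sessions (digest2int is a pure C xxhash-style
# string hash with a fixed seed).
stable_hash <- function(x) {
  h <- digest::digest2int(as.character(x))
  h <- bitwAnd(h, 2147483647L) # clear the sign bit -> [0, 2^31)
  h
}

# Derive a stream of independent sub-seeds from one user seed. R integers are
# 32-bit, so everything stays below 2^31.
derive_seed <- function(seed, i, tag = "") {
  stable_hash(paste0("seed:", seed, ":", i, ":", tag))
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647), code)
}

# Euclidean distance matrix between two point sets (n x 3, m x 3).
cross_dist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
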