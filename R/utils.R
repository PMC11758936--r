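# Internal helpers shared across modules.

#' @useDynLib msconnectome, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor lm lm.fit median na.omit pchisq plogis pnorm
#'   predict pt qlogis qt quantile rbinom rnorm rpois runif sd var
#' @importFrom utils read.delim write.table
NULL

# Derive a reproducible 31-bit child seed from a base seed and a set of keys
# (subject id, visit, stream name ...).  Plain multiplicative hashing keeps
# subject-level streams independent of cohort size.
derive_seed <- function(seed, ...) {
  h <- 0
  for (k in c(list(seed), list(...))) {
    codes <- if (is.character(k)) {
      utf8ToInt(paste(k, collapse = "/")) # order-sensitive per character
    } else as.numeric(k)
    for (v in codes) {
      h <- (h * 48271 + (v %% 2147483647) + 11) %% 2147483647
    }
  }
  as.integer(h %% 2147483646) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round to the clinical 0.5-point grid, half-up.
round_half_up_05 <- function(x) floor(x * 2 + 0.5) / 2

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Upper-triangle (i, j) pairs in column-major order, matching `m[upper.tri(m)]`.
upper_tri_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
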