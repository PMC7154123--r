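#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ..., call. = FALSE) stop(sprintf(fmt, ...), call. = call.)

warnf <- function(fmt, ..., call. = FALSE) warning(sprintf(fmt, ...), call. = call.)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Digest of an ordered sample-identifier vector
#'
#' Polynomial rolling hash (mod 2^31 - 1) of the concatenated identifiers,
#' prefixed with the vector length. Used to guard genomic relationship
#' matrix caches and partial numerators against silent sample misalignment:
#' two runs agree on the digest only if they use the same individuals in
#' the same order.
#'
#' @param ids character vector of sample identifiers (order matters).
#' @return A single character string, e.g. `"12:183456201"`.
#' @export
#' @examples
#' sample_digest(c("ind1", "ind2"))
sample_digest <- function(ids) {
  ids <- as.character(ids)
  bytes <- utf8ToInt(paste(ids, collapse = "\x1f"))
  mod <- 2147483647
  h <- 0
  # h*31 + b stays < 2^53, so double arithmetic is exact
  for (b in bytes) h <- (h * 31 + b) %% mod
  sprintf("%d:%.0f", length(ids), h)
}

# deterministic, locale-independent character ordering
radix_order <- function(x, ...) order(x, ..., method = "radix")

# restore the caller's RNG stream after seeded work
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Moore-Penrose pseudo-inverse via SVD; used for (X'V^-1 X)^- and for the
# AI matrix when it is numerically singular at convergence.
pinv <- function(m, tol = 1e-12) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}
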