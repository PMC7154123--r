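# Genomic relationship matrices G = W W' / k with the trace
# normalization k = tr(W W')/n (the average diagonal of W W'), so that
# tr(G) = n and the attached variance component is the average individual
# variance. Also: partitioned construction (partial numerators over
# column chunks that sum to W W'), and a binary cache so relationship
# matrices are built once and reloaded across validation folds.

#' Trace-normalization constant of a model matrix
#'
#' `k = tr(W W') / n`, the average diagonal element of `W W'`; equals the
#' mean over individuals of the sum of squared coding values.
#'
#' @param W model matrix with n rows.
#' @return Positive scalar.
#' @export
k_constant <- function(W) {
  k <- sum(W^2) / nrow(W)
  if (k <= 0 || !is.finite(k))
    stopf("component has no variation (k = tr(WW')/n is zero); all markers monomorphic?")
  k
}

new_grm <- function(matrix, k, tag, digest) {
  structure(list(tag = tag, matrix = matrix, k = k, n = nrow(matrix),
                 sample_digest = digest), class = "hb_grm")
}

#' Build a genomic relationship matrix
#'
#' @param W model matrix (n individuals x coding columns) with sample ids
#'   as row names.
#' @param tag component tag: `"a"` (SNP additive), `"d"` (SNP dominance)
#'   or `"ah"` (haplotype additive).
#' @return An `hb_grm`: symmetric n x n `matrix` with `tr(matrix) = n`,
#'   the constant `k`, the `tag`, and a digest of the ordered sample ids.
#' @export
build_grm <- function(W, tag = c("a", "d", "ah")) {
  tag <- match.arg(tag)
  k <- k_constant(W)
  ids <- rownames(W) %||% as.character(seq_len(nrow(W)))
  M <- tcrossprod(W) / k
  dimnames(M) <- list(ids, ids)
  new_grm(M, k, tag, sample_digest(ids))
}

#' Partial numerator of a partitioned GRM construction
#'
#' Computes `W_chunk W_chunk'` and its trace for one column chunk, so that
#' independent processes can each handle a chunk and the full matrix is
#' recovered by [combine_partials()]. Chunks must respect block
#' boundaries (a haplotype block's columns are never split) and contain
#' all n individuals.
#'
#' @param W_chunk the chunk's columns (n rows; 0 columns is legal and
#'   yields a zero numerator).
#' @param tag component tag.
#' @param chunk_id integer index of this chunk, 1..n_chunks.
#' @param n_chunks total number of chunks in the partition.
#' @return A `partial_grm`: `numerator`, `partial_trace`, `chunk_id`,
#'   `n_chunks`, `n`, `tag`, `sample_digest`.
#' @export
partial_numerator <- function(W_chunk, tag = c("a", "d", "ah"), chunk_id,
                              n_chunks) {
  tag <- match.arg(tag)
  ids <- rownames(W_chunk) %||% as.character(seq_len(nrow(W_chunk)))
  structure(list(tag = tag, numerator = tcrossprod(W_chunk),
                 partial_trace = sum(W_chunk^2),
                 chunk_id = as.integer(chunk_id), n_chunks = as.integer(n_chunks),
                 n = nrow(W_chunk), sample_digest = sample_digest(ids),
                 sample_ids = ids),
            class = "partial_grm")
}

#' Combine partial numerators into a GRM
#'
#' `G = (sum_i W_i W_i') / k` with `k = (sum_i tr(W_i W_i')) / n`; the
#' result matches a single-pass [build_grm()] up to floating-point
#' summation order.
#'
#' @param partials list of `partial_grm` objects forming a complete
#'   partition (all chunk ids 1..n_chunks present, same tag, same
#'   individuals in the same order).
#' @return An `hb_grm`.
#' @export
combine_partials <- function(partials) {
  stopifnot(length(partials) > 0)
  tag <- partials[[1]]$tag
  dig <- partials[[1]]$sample_digest
  n <- partials[[1]]$n
  s <- partials[[1]]$n_chunks
  for (p in partials) {
    if (p$tag != tag) stopf("partials mix component tags '%s' and '%s'", tag, p$tag)
    if (p$sample_digest != dig)
      stopf("sample digest mismatch among partial numerators; different individual sets or orders")
    if (p$n != n || p$n_chunks != s) stopf("inconsistent partial numerator metadata")
  }
  ids <- sort(vapply(partials, function(p) p$chunk_id, 1L))
  if (!identical(ids, seq_len(s)))
    stopf("incomplete partition: expected chunks 1..%d, got {%s}",
          s, paste(ids, collapse = ","))
  num <- Reduce(`+`, lapply(partials, function(p) p$numerator))
  k <- sum(vapply(partials, function(p) p$partial_trace, 1.0)) / n
  if (k <= 0) stopf("component has no variation (combined k is zero)")
  sid <- partials[[1]]$sample_ids
  dimnames(num) <- list(sid, sid)
  new_grm(num / k, k, tag, dig)
}

#' Save a partial numerator as a binary file
#'
#' @param partial a `partial_grm`.
#' @param path output path (convention: `<tag>.part<i>.hgrm`).
#' @return `path`, invisibly.
#' @export
save_partial_grm <- function(partial, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write_hgrm_header(con, "HGRP", partial$tag, partial$n, partial$partial_trace,
                    partial$sample_digest, partial$sample_ids)
  writeBin(as.integer(c(partial$chunk_id, partial$n_chunks)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(partial$numerator), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a partial numerator saved by [save_partial_grm()]
#'
#' @param path file path.
#' @return A `partial_grm`.
#' @export
load_partial_grm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_hgrm_header(con, "HGRP", path)
  meta <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  num <- readBin(con, "numeric", hd$n^2, size = 8L, endian = "little")
  if (length(num) != hd$n^2) stopf("%s: truncated partial numerator file", path)
  structure(list(tag = hd$tag, numerator = matrix(num, hd$n, hd$n),
                 partial_trace = hd$k, chunk_id = meta[1], n_chunks = meta[2],
                 n = hd$n, sample_digest = hd$digest, sample_ids = hd$sample_ids),
            class = "partial_grm")
}

write_hgrm_header <- function(con, magic, tag, n, k, digest, sample_ids) {
  writeBin(charToRaw(magic), con)
  writeBin(1L, con, size = 4L, endian = "little")          # format version
  tagr <- charToRaw(tag)
  writeBin(length(tagr), con, size = 4L, endian = "little")
  writeBin(tagr, con)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  writeBin(as.numeric(k), con, size = 8L, endian = "little")
  digr <- charToRaw(digest)
  writeBin(length(digr), con, size = 4L, endian = "little")
  writeBin(digr, con)
  idr <- charToRaw(paste(sample_ids, collapse = "\n"))
  writeBin(length(idr), con, size = 4L, endian = "little")
  writeBin(idr, con)
}

read_hgrm_header <- function(con, magic, path) {
  mg <- readBin(con, "raw", 4L)
  if (length(mg) < 4 || rawToChar(mg) != magic)
    stopf("%s: not a %s file (bad magic)", path, magic)
  ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(ver, 1L)) stopf("%s: unsupported format version %s", path, ver)
  tl <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  tag <- rawToChar(readBin(con, "raw", tl))
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  k <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  dl <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  digest <- rawToChar(readBin(con, "raw", dl))
  il <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  idr <- readBin(con, "raw", il)
  if (length(n) != 1 || length(k) != 1 || length(idr) != il)
    stopf("%s: truncated header", path)
  list(tag = tag, n = n, k = k, digest = digest,
       sample_ids = strsplit(rawToChar(idr), "\n", fixed = TRUE)[[1]])
}

#' Save a genomic relationship matrix as a binary cache file
#'
#' Layout: magic `"HGRM"`, format version, component tag, n, k, a digest
#' of the ordered sample ids, the ids themselves, then the row-major
#' float64 matrix. The digest lets [load_grm_cache()] refuse matrices
#' computed for a different individual set or order — the dominant failure
#' mode when matrices are reused across validation runs.
#'
#' @param grm an `hb_grm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_grm_cache <- function(grm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  ids <- rownames(grm$matrix) %||% as.character(seq_len(grm$n))
  write_hgrm_header(con, "HGRM", grm$tag, grm$n, grm$k, grm$sample_digest, ids)
  writeBin(as.numeric(grm$matrix), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a genomic relationship matrix cache
#'
#' @param path a file written by [save_grm_cache()].
#' @param sample_ids optional expected sample ids (in order); loading
#'   fails if their digest does not match the cached one.
#' @return An `hb_grm` identical to the saved one.
#' @export
load_grm_cache <- function(path, sample_ids = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_hgrm_header(con, "HGRM", path)
  if (!is.null(sample_ids) && sample_digest(sample_ids) != hd$digest)
    stopf("%s: sample digest mismatch; cache was built for a different individual set or order",
          path)
  vals <- readBin(con, "numeric", hd$n^2, size = 8L, endian = "little")
  if (length(vals) != hd$n^2) stopf("%s: truncated matrix payload", path)
  M <- matrix(vals, hd$n, hd$n)
  dimnames(M) <- list(hd$sample_ids, hd$sample_ids)
  new_grm(M, hd$k, hd$tag, hd$digest)
}

#' Split model-matrix columns into block-respecting chunks
#'
#' Utility for partitioned GRM construction: divides columns into
#' `n_chunks` contiguous groups, never splitting a haplotype block's
#' columns across chunks when `block_spans` is given.
#'
#' @param n_cols number of columns of the model matrix.
#' @param n_chunks requested number of chunks.
#' @param block_spans optional 2-column matrix of half-open column spans.
#' @return List of integer column-index vectors (possibly fewer than
#'   `n_chunks` when blocks are large).
#' @export
chunk_columns <- function(n_cols, n_chunks, block_spans = NULL) {
  if (is.null(block_spans)) {
    groups <- split(seq_len(n_cols),
                    ceiling(seq_len(n_cols) / (n_cols / n_chunks)))
  } else {
    nonempty <- block_spans[block_spans[, 2] > block_spans[, 1], , drop = FALSE]
    nb <- nrow(nonempty)
    gid <- ceiling(seq_len(nb) / (nb / min(n_chunks, nb)))
    groups <- lapply(split(seq_len(nb), gid), function(bs)
      unlist(lapply(bs, function(b) seq(nonempty[b, 1], nonempty[b, 2] - 1L))))
  }
  unname(groups)
}

#' @export
print.hb_grm <- function(x, ...) {
  cat(sprintf("hb_grm '%s': %d x %d, k = %g, tr/n = %.6f\n", x$tag, x$n, x$n,
              x$k, sum(diag(x$matrix)) / x$n))
  invisible(x)
}
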