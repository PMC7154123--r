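# Quantitative-genetics codings of SNP and haplotype genotypes into the
# model matrices of the mixed model y = Xb + Z(W_a alpha_o + W_d delta_o +
# W_ah alpha_ho) + e. The haplotype coding for the column of allele k is
# the three-case substitution-effect coding
#   2 p_k            neither haplotype is k
#   -(1 - 2 p_k)     exactly one haplotype is k
#   -2 (1 - p_k)     both haplotypes are k
# which is identically w = 2 p_k - (copies of allele k); the SNP additive
# coding w = 2p - x is its biallelic specialization. Columns built with
# observed sample frequencies sum to exactly zero.

#' Per-SNP frequency of the "1" allele
#'
#' @param g an n x m SNP genotype matrix of allele-"1" counts.
#' @return Numeric vector `p` of length m, `p_j = sum(g[, j]) / (2n)`.
#' @export
snp_frequencies <- function(g) {
  if (nrow(g) == 0) stopf("genotype matrix has no individuals")
  colSums(g) / (2 * nrow(g))
}

#' Haplotype substitution-effect coding value
#'
#' The entry of the haplotype additive model matrix for an individual with
#' unordered allele pair \{i, j\} in the column of allele k (k >= 2;
#' allele 1 is the reference and contributes no column).
#'
#' @param i,j allele codes of the individual's two haplotypes (any order).
#' @param k the column's allele code, >= 2.
#' @param p_k frequency of allele k.
#' @return `2*p_k - (number of the pair's alleles equal to k)`; vectorized.
#' @export
#' @examples
#' haplotype_coding_value(1, 3, k = 2, p_k = 0.3)   #  0.6
#' haplotype_coding_value(2, 2, k = 2, p_k = 0.25)  # -1.5
haplotype_coding_value <- function(i, j, k, p_k) {
  if (any(k < 2)) stopf("k must be >= 2; allele 1 is the reference")
  if (any(i < 1) || any(j < 1)) stopf("invalid allele codes in pair")
  2 * p_k - ((i == k) + (j == k))
}

#' SNP additive model matrix
#'
#' `w_ij = 2 p_j - x_ij` with `x_ij` the allele-"1" count: the biallelic
#' specialization of the haplotype coding with k the "1" allele.
#' Monomorphic SNPs give all-zero columns.
#'
#' @param g n x m SNP genotype matrix.
#' @param p per-SNP allele-"1" frequencies; defaults to the observed
#'   sample frequencies, which centre every column exactly.
#' @return n x m numeric matrix with the same dimnames as `g`.
#' @export
build_W_alpha <- function(g, p = snp_frequencies(g)) {
  W <- matrix(2 * p, nrow(g), ncol(g), byrow = TRUE) - g
  dimnames(W) <- dimnames(g)
  W
}

#' SNP dominance model matrix
#'
#' With q = 1 - p: `-2q^2` for genotype 2, `2pq` for genotype 1, `-2p^2`
#' for genotype 0, per the single-SNP quantitative genetics model. Under
#' exact Hardy-Weinberg genotype proportions this coding has population
#' mean zero and is orthogonal to the additive coding.
#'
#' @inheritParams build_W_alpha
#' @return n x m numeric matrix.
#' @export
build_W_delta <- function(g, p = snp_frequencies(g)) {
  q <- 1 - p
  v2 <- matrix(-2 * q^2, nrow(g), ncol(g), byrow = TRUE)
  v1 <- matrix(2 * p * q, nrow(g), ncol(g), byrow = TRUE)
  v0 <- matrix(-2 * p^2, nrow(g), ncol(g), byrow = TRUE)
  W <- (g == 2L) * v2 + (g == 1L) * v1 + (g == 0L) * v0
  dimnames(W) <- dimnames(g)
  W
}

#' Haplotype additive model matrix
#'
#' One column per (block, allele k) for k = 2..h, filled by
#' [haplotype_coding_value()] using the block's observed haplotype
#' frequencies; blocks with a single allele contribute no column. Column
#' order is block order, then allele code.
#'
#' @param encoded a `block_genotypes` object.
#' @return A list: `W` (n x n_ah matrix, n_ah = sum over blocks of h - 1)
#'   and `block_spans` (per-block half-open column interval, 2-column
#'   matrix `first`,`last_excl`; empty span for single-allele blocks).
#' @export
build_W_alpha_h <- function(encoded) {
  n <- length(encoded$sample_ids)
  nb <- length(encoded$blocks)
  ncols <- vapply(encoded$blocks, function(b) b$h - 1L, 1L)
  spans <- cbind(first = cumsum(c(1L, ncols[-nb])), last_excl = cumsum(ncols) + 1L)
  if (nb == 0) spans <- matrix(integer(0), 0, 2)
  W <- matrix(0, n, sum(ncols))
  cn <- character(sum(ncols))
  for (b in seq_len(nb)) {
    blk <- encoded$blocks[[b]]
    if (blk$h < 2) next
    for (k in 2:blk$h) {
      col <- spans[b, 1] + (k - 2L)
      copies <- (blk$pairs[, 1] == k) + (blk$pairs[, 2] == k)
      W[, col] <- 2 * blk$freqs[k] - copies
      cn[col] <- paste0(blk$block_id, ".k", k)
    }
  }
  rownames(W) <- encoded$sample_ids
  colnames(W) <- cn
  rownames(spans) <- vapply(encoded$blocks, function(b) b$block_id, "")
  list(W = W, block_spans = spans)
}

#' Build all model matrices for a run
#'
#' Convenience wrapper assembling W_alpha, W_delta and W_alpha_h as
#' required by the configured model, with SNPs fitted as fixed covariates
#' removed from the random SNP coding to avoid double counting.
#'
#' @param config a `run_config`.
#' @param snp SNP genotype matrix (needed for components "a"/"d").
#' @param encoded `block_genotypes` (needed for component "ah").
#' @param map the `snp_map`, used to resolve SNP-as-fixed column names.
#' @return A list of class `model_matrices`: `W` (named list over included
#'   components), `block_spans`, `snp_ids` (SNPs kept in the random
#'   coding), `sample_ids`.
#' @export
build_model_matrices <- function(config, snp = NULL, encoded = NULL, map = NULL) {
  comps <- config$components
  W <- list()
  spans <- NULL
  snp_ids <- NULL
  sample_ids <- NULL
  if (any(c("a", "d") %in% comps)) {
    if (is.null(snp)) stopf("SNP genotypes required for components a/d")
    fixed_snps <- intersect(config$snp_fixed_cols, colnames(snp))
    if (length(fixed_snps) > 0) snp <- snp[, setdiff(colnames(snp), fixed_snps), drop = FALSE]
    p <- snp_frequencies(snp)
    snp_ids <- colnames(snp)
    sample_ids <- rownames(snp)
    if ("a" %in% comps) W$a <- build_W_alpha(snp, p)
    if ("d" %in% comps) W$d <- build_W_delta(snp, p)
  }
  if ("ah" %in% comps) {
    if (is.null(encoded)) stopf("encoded block genotypes required for component ah")
    wah <- build_W_alpha_h(encoded)
    if (ncol(wah$W) == 0)
      stopf("all haplotype blocks are monomorphic; haplotype component has no variation")
    W$ah <- wah$W
    spans <- wah$block_spans
    sample_ids <- sample_ids %||% encoded$sample_ids
    if (!identical(encoded$sample_ids, sample_ids))
      stopf("SNP and haplotype files list different individuals")
  }
  structure(list(W = W, block_spans = spans, snp_ids = snp_ids,
                 sample_ids = sample_ids),
            class = "model_matrices")
}
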