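# Haplotype blocking: divide mapped SNPs into blocks (fixed SNP count,
# fixed kb window, or user intervals) and encode each individual's pair of
# phased haplotypes within every block as a multi-allelic genotype. A
# block is a "locus"; each distinct phased SNP sequence inside it is an
# "allele", numbered by descending frequency (ties broken lexicographically
# on the allele string) so that allele 1 — the reference against which
# substitution effects are expressed — is fixed deterministically.

new_block_def <- function(block_id, chrom, first, last_excl, map) {
  df <- data.frame(block_id = block_id, chrom = chrom, first = as.integer(first),
                   last_excl = as.integer(last_excl), stringsAsFactors = FALSE)
  df$start_bp <- map$pos_bp[df$first]
  df$end_bp <- map$pos_bp[df$last_excl - 1L]
  df$n_snps <- df$last_excl - df$first
  class(df) <- c("block_def", "data.frame")
  df
}

block_ids <- function(chrom, idx_within) sprintf("%s_blk%d", chrom, idx_within)

#' Define haplotype blocks by a fixed number of SNPs
#'
#' Within each chromosome, consecutive runs of `snps_per_block` SNPs (in
#' map order) form the blocks; the final block of a chromosome may be
#' shorter. Blocks never span chromosomes.
#'
#' @param map a `snp_map`.
#' @param snps_per_block integer >= 1.
#' @return A `block_def` data frame: `block_id`, `chrom`, `first`,
#'   `last_excl` (half-open row interval into the map), `start_bp`,
#'   `end_bp`, `n_snps`.
#' @export
block_by_snp <- function(map, snps_per_block) {
  if (nrow(map) == 0) stopf("empty SNP map")
  snps_per_block <- as.integer(snps_per_block)
  if (is.na(snps_per_block) || snps_per_block < 1)
    stopf("snps_per_block must be an integer >= 1")
  pieces <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    starts <- seq(idx[1], idx[length(idx)], by = snps_per_block)
    ends <- pmin(starts + snps_per_block, idx[length(idx)] + 1L)
    new_block_def(block_ids(ch, seq_along(starts)), ch, starts, ends, map)
  })
  out <- do.call(rbind, pieces)
  class(out) <- c("block_def", "data.frame")
  out
}

#' Define haplotype blocks by a fixed kilobase window
#'
#' Windows of length `kb * 1000` bp are anchored at each chromosome's
#' first SNP position: window t covers `[first_pos + t*L, first_pos +
#' (t+1)*L)`. Every window containing at least one SNP becomes a block;
#' empty windows produce none. Anchoring at the first SNP makes the
#' partition invariant to a global shift of coordinates.
#'
#' @param map a `snp_map`.
#' @param kb window length in kilobases, > 0.
#' @return A `block_def` data frame.
#' @export
block_by_kb <- function(map, kb) {
  if (nrow(map) == 0) stopf("empty SNP map")
  if (!is.numeric(kb) || kb <= 0) stopf("kb must be > 0")
  L <- kb * 1000
  pieces <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    win <- floor((map$pos_bp[idx] - map$pos_bp[idx[1]]) / L)
    runs <- rle(win)
    last <- cumsum(runs$lengths)
    first <- c(1L, utils::head(last, -1) + 1L)
    new_block_def(block_ids(ch, seq_along(first)), ch, idx[first], idx[last] + 1L, map)
  })
  out <- do.call(rbind, pieces)
  class(out) <- c("block_def", "data.frame")
  out
}

#' Define haplotype blocks from user intervals
#'
#' Each interval (1-based, end-inclusive) containing at least one SNP
#' becomes a block of the SNPs with `start_bp <= pos <= end_bp`. SNPs not
#' covered by any interval are excluded from the haplotype model (they
#' remain in the SNP model); a warning reports how many.
#'
#' @param map a `snp_map`.
#' @param intervals data frame with `chrom`, `start_bp`, `end_bp`; sorted,
#'   non-overlapping within each chromosome.
#' @return A `block_def` data frame.
#' @export
block_by_pos <- function(map, intervals) {
  if (nrow(map) == 0) stopf("empty SNP map")
  if (is.null(intervals) || nrow(intervals) == 0) stopf("interval list is empty")
  if (any(intervals$start_bp > intervals$end_bp))
    stopf("interval with start_bp > end_bp")
  pieces <- list()
  covered <- logical(nrow(map))
  dropped <- 0L
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    iv <- iv[order(iv$start_bp), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start_bp[-1] <= iv$end_bp[-nrow(iv)]))
      stopf("overlapping intervals on chromosome %s", ch)
    idx <- which(map$chrom == ch)
    bnum <- 0L
    for (r in seq_len(nrow(iv))) {
      hit <- idx[map$pos_bp[idx] >= iv$start_bp[r] & map$pos_bp[idx] <= iv$end_bp[r]]
      if (length(hit) == 0) { dropped <- dropped + 1L; next }
      bnum <- bnum + 1L
      covered[hit] <- TRUE
      pieces[[length(pieces) + 1L]] <-
        new_block_def(block_ids(ch, bnum), ch, hit[1], hit[length(hit)] + 1L, map)
    }
  }
  if (dropped > 0)
    warnf("%d interval(s) contained no SNPs and were dropped", dropped)
  if (length(pieces) == 0) stopf("no interval contains any SNP")
  n_uncov <- sum(!covered)
  if (n_uncov > 0)
    warnf("%d SNP(s) not covered by any interval; excluded from the haplotype model",
          n_uncov)
  out <- do.call(rbind, pieces)
  class(out) <- c("block_def", "data.frame")
  out
}

#' Read a block-interval file
#'
#' Whitespace-separated columns `chrom`, `start_bp`, `end_bp` (1-based,
#' end-inclusive), with a header row.
#'
#' @param path path to the interval file.
#' @return A data frame usable by [block_by_pos()].
#' @export
read_block_intervals <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start_bp", "end_bp")
  if (!all(need %in% names(df)))
    stopf("%s: header must contain chrom, start_bp, end_bp", path)
  df$start_bp <- as.integer(df$start_bp)
  df$end_bp <- as.integer(df$end_bp)
  df
}

#' Encode per-individual haplotype genotypes within each block
#'
#' For every block, the distinct haplotype allele strings over its SNPs
#' are enumerated and coded 1..h by descending frequency among all 2n
#' phased haplotypes (ties broken lexicographically); each individual's
#' genotype is the unordered pair of its two allele codes. Frequencies are
#' exact counts over 2n, computed over all individuals (training and
#' validation) because the relationship matrices cover all of them.
#'
#' @param phased a `phased_haplotypes` object.
#' @param blocks a `block_def` data frame.
#' @return A list of class `block_genotypes`: `sample_ids`, and `blocks`,
#'   one entry per block with `block_id`, `alleles` (strings in code
#'   order), `counts`, `freqs`, `h`, and `pairs` (n x 2 integer matrix,
#'   column 1 <= column 2).
#' @export
encode_block_genotypes <- function(phased, blocks) {
  a <- phased$alleles
  n <- length(phased$sample_ids)
  enc <- lapply(seq_len(nrow(blocks)), function(b) {
    cols <- seq(blocks$first[b], blocks$last_excl[b] - 1L)
    strs <- do.call(paste0, as.data.frame(a[, cols, drop = FALSE]))
    cnt <- table(strs)
    allele <- names(cnt)
    cnt <- as.integer(cnt)
    ord <- radix_order(-cnt, allele)   # frequency desc, then lexicographic
    allele <- allele[ord]; cnt <- cnt[ord]
    code <- match(strs, allele)
    pairs <- cbind(code[seq(1, 2 * n, by = 2)], code[seq(2, 2 * n, by = 2)])
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    colnames(pairs) <- c("hap1", "hap2")
    list(block_id = blocks$block_id[b], alleles = allele, counts = cnt,
         freqs = cnt / (2 * n), h = length(allele), pairs = pairs)
  })
  structure(list(sample_ids = phased$sample_ids, blocks = enc),
            class = "block_genotypes")
}

#' Write haplotype genotypes with an allele-table sidecar
#'
#' The main file has one line per individual: id then one `i/j` pair per
#' block (`i <= j`). The sidecar (`<path>.alleles`) lists, per block, the
#' allele code, its haplotype string and its count over the 2n haplotypes,
#' so the encoding is auditable and the round trip is lossless.
#'
#' @param encoded a `block_genotypes` object.
#' @param path output path; sidecar written to `paste0(path, ".alleles")`.
#' @return `path`, invisibly.
#' @export
write_haplotype_genotypes <- function(encoded, path) {
  n <- length(encoded$sample_ids)
  pair_cols <- vapply(encoded$blocks, function(b)
    paste0(b$pairs[, 1], "/", b$pairs[, 2]), character(n))
  pair_cols <- matrix(pair_cols, nrow = n)
  writeLines(paste(encoded$sample_ids, apply(pair_cols, 1, paste, collapse = " ")),
             path)
  side <- unlist(lapply(encoded$blocks, function(b)
    paste(b$block_id, seq_len(b$h), b$alleles, b$counts)))
  writeLines(c("block_id code allele count", side), paste0(path, ".alleles"))
  invisible(path)
}

#' Read haplotype genotypes written by [write_haplotype_genotypes()]
#'
#' @param path main file path; the sidecar `paste0(path, ".alleles")` must
#'   exist alongside it.
#' @return A `block_genotypes` object identical to the one written.
#' @export
read_haplotype_genotypes <- function(path) {
  side <- utils::read.table(paste0(path, ".alleles"), header = TRUE,
                            colClasses = c("character", "integer", "character", "integer"))
  lines <- read_text_lines(path)
  toks <- split_ws(lines[nzchar(trimws(lines))])
  n <- length(toks)
  ids <- vapply(toks, `[`, "", 1)
  nb <- length(unique(side$block_id))
  block_order <- unique(side$block_id)
  pair_mat <- do.call(rbind, lapply(seq_len(n), function(i) {
    tk <- toks[[i]][-1]
    if (length(tk) != nb)
      stopf("%s: individual '%s' has %d genotype pairs, expected %d",
            path, ids[i], length(tk), nb)
    tk
  }))
  blocks <- lapply(seq_len(nb), function(b) {
    s <- side[side$block_id == block_order[b], , drop = FALSE]
    s <- s[order(s$code), , drop = FALSE]
    pr <- strsplit(pair_mat[, b], "/", fixed = TRUE)
    pairs <- cbind(as.integer(vapply(pr, `[`, "", 1)),
                   as.integer(vapply(pr, `[`, "", 2)))
    if (any(is.na(pairs)) || any(pairs < 1) || any(pairs > nrow(s)))
      stopf("%s: allele code out of range 1..%d in block %s",
            path, nrow(s), block_order[b])
    colnames(pairs) <- c("hap1", "hap2")
    list(block_id = block_order[b], alleles = s$allele, counts = s$count,
         freqs = s$count / (2 * n), h = nrow(s), pairs = pairs)
  })
  structure(list(sample_ids = ids, blocks = blocks), class = "block_genotypes")
}

#' Write a block definition table
#'
#' @param blocks a `block_def` data frame.
#' @param path output path; columns `block_id`, `chrom`, `first_snp`,
#'   `last_snp`, `n_snps` (1-based inclusive SNP indices).
#' @param encoded optional `block_genotypes` to add an `n_alleles` column.
#' @return `path`, invisibly.
#' @export
write_block_definitions <- function(blocks, path, encoded = NULL) {
  df <- data.frame(block_id = blocks$block_id, chrom = blocks$chrom,
                   first_snp = blocks$first, last_snp = blocks$last_excl - 1L,
                   n_snps = blocks$n_snps)
  if (!is.null(encoded))
    df$n_alleles <- vapply(encoded$blocks, function(b) b$h, 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
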