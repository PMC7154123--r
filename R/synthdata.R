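# Synthetic data with known variance components. Haplotypes follow a
# mosaic-of-founders model: a small founder panel per chromosome, each
# sample haplotype copying one founder and switching to a random founder
# with a fixed per-SNP probability. This creates linkage disequilibrium
# and, crucially, recurrent haplotypes within blocks, so haplotype blocks
# carry far fewer distinct alleles than 2n — the regime the multi-allelic
# coding is designed for. Phenotype components are simulated on the model
# codings themselves and rescaled so each component's sample variance
# equals its target exactly, giving parameter-recovery tests sharp truth.

#' Simulate phased haplotypes and a SNP map
#'
#' @param n number of individuals.
#' @param m total number of SNPs, split evenly across chromosomes and
#'   placed 1 kb apart.
#' @param n_chrom number of chromosomes (default 1).
#' @param f founders per chromosome (>= 2; default 6).
#' @param r per-SNP founder-switch probability in \[0, 1\] (default 0.02);
#'   0 copies founders verbatim, 1 gives free recombination.
#' @param maf_range range for the founder-panel allele-"1" frequencies,
#'   within (0, 0.5\] (default c(0.1, 0.5)).
#' @param seed integer seed; same seed, same output.
#' @return A list: `phased` (`phased_haplotypes`), `map` (`snp_map`).
#' @export
simulate_haplotypes <- function(n, m, n_chrom = 1L, f = 6L, r = 0.02,
                                maf_range = c(0.1, 0.5), seed = 1L) {
  if (f < 2) stopf("f must be >= 2")
  if (r < 0 || r > 1) stopf("r must be in [0, 1]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) stopf("maf_range must lie in (0, 0.5]")
  m_per <- diff(round(seq(0, m, length.out = n_chrom + 1)))
  ids <- sprintf("ind%d", seq_len(n))
  with_seed(seed, {
    chrom_alleles <- vector("list", n_chrom)
    for (ch in seq_len(n_chrom)) {
      mc <- m_per[ch]
      p <- stats::runif(mc, maf_range[1], maf_range[2])
      founders <- matrix(stats::rbinom(f * mc, 1L, rep(p, each = f)), f, mc)
      sw <- matrix(stats::runif(2 * n * mc) < r, 2 * n, mc)
      sw[, 1] <- TRUE                       # initial founder choice
      seg <- t(apply(sw, 1, cumsum))        # segment index per haplotype
      gid <- (row(seg) - 1L) * (mc + 1L) + seg
      founder_of_seg <- sample.int(f, 2 * n * (mc + 1L), replace = TRUE)
      fo <- matrix(founder_of_seg[gid], 2 * n, mc)
      chrom_alleles[[ch]] <- matrix(founders[cbind(as.vector(fo),
                                                   rep(seq_len(mc), each = 2 * n))],
                                    2 * n, mc)
    }
  })
  alleles <- do.call(cbind, chrom_alleles)
  storage.mode(alleles) <- "integer"
  map <- data.frame(snp_id = sprintf("snp%d", seq_len(m)),
                    chrom = rep(sprintf("chr%d", seq_len(n_chrom)), m_per),
                    pos_bp = unlist(lapply(m_per, function(mc) 1000L * seq_len(mc))),
                    stringsAsFactors = FALSE)
  class(map) <- c("snp_map", "data.frame")
  rownames(alleles) <- paste0(rep(ids, each = 2L), ".", rep(1:2, n))
  colnames(alleles) <- map$snp_id
  phased <- structure(list(sample_ids = ids, alleles = alleles),
                      class = "phased_haplotypes")
  list(phased = phased, map = map)
}

rescale_to_var <- function(v, target) {
  if (target == 0) return(numeric(length(v)))
  s <- stats::var(v)
  if (s == 0) stopf("simulated component has zero variance; cannot rescale")
  v * sqrt(target / s)
}

#' Simulate phenotypes with known variance components
#'
#' Draws standard-normal effects for `n_causal` SNPs (additive and,
#' where targeted, dominance, on their model codings) and for up to
#' `n_causal` polymorphic haplotype blocks (one effect per non-reference
#' allele), forms the component value vectors through the coding module,
#' and rescales each vector so its sample variance equals the target
#' exactly. The residual is likewise rescaled to `(1 - sum(h2)) *
#' sigma_P2`. A two-level class factor ("grp") is added as a fixed effect.
#'
#' @param phased a `phased_haplotypes`.
#' @param blocks a `block_def` table (needed when `h2_ah > 0`).
#' @param h2 named numeric targets, names among `c("a", "d", "ah")`;
#'   their sum must be < 1.
#' @param sigma_P2 total phenotypic variance (default 1).
#' @param n_causal number of causal SNPs / blocks (default 100).
#' @param seed integer seed.
#' @param mu intercept (default 10).
#' @param grp_effect additive effect of the second class level (default
#'   `0.5 * sqrt(sigma_P2)`).
#' @return A list: `pheno` (`pheno_table`, all individuals flagged "T")
#'   and `truth` (`sim_truth`: targets, component variances, component
#'   value vectors, total genetic values `g`, causal SNP/block ids,
#'   parameters).
#' @export
simulate_phenotypes <- function(phased, blocks = NULL,
                                h2 = c(a = 0.3, d = 0.1, ah = 0.2),
                                sigma_P2 = 1, n_causal = 100L, seed = 1L,
                                mu = 10, grp_effect = 0.5 * sqrt(sigma_P2)) {
  if (!all(names(h2) %in% c("a", "d", "ah")))
    stopf("h2 names must be among 'a', 'd', 'ah'")
  if (sum(h2) >= 1) stopf("target heritabilities must sum to < 1")
  n <- length(phased$sample_ids)
  geno <- haplotypes_to_genotypes(phased)
  m <- ncol(geno)
  target <- function(tag) if (tag %in% names(h2)) h2[[tag]] * sigma_P2 else 0
  comp <- list(a = numeric(n), d = numeric(n), ah = numeric(n))
  causal_snps <- character(0); causal_blocks <- character(0)
  with_seed(seed, {
    if (target("a") > 0 || target("d") > 0) {
      idx <- sort(sample.int(m, min(n_causal, m)))
      causal_snps <- colnames(geno)[idx]
      p <- snp_frequencies(geno)[idx]
      if (target("a") > 0) {
        Wa <- build_W_alpha(geno[, idx, drop = FALSE], p)
        comp$a <- rescale_to_var(drop(Wa %*% stats::rnorm(length(idx))), target("a"))
      }
      if (target("d") > 0) {
        Wd <- build_W_delta(geno[, idx, drop = FALSE], p)
        comp$d <- rescale_to_var(drop(Wd %*% stats::rnorm(length(idx))), target("d"))
      }
    }
    if (target("ah") > 0) {
      if (is.null(blocks)) stopf("blocks required when h2_ah > 0")
      encoded <- encode_block_genotypes(phased, blocks)
      wah <- build_W_alpha_h(encoded)
      spans <- wah$block_spans
      poly <- which(spans[, 2] > spans[, 1])
      if (length(poly) == 0) stopf("all blocks monomorphic; cannot simulate haplotype effects")
      bsel <- sort(sample(poly, min(n_causal, length(poly))))
      causal_blocks <- rownames(spans)[bsel]
      cols <- unlist(lapply(bsel, function(b) seq(spans[b, 1], spans[b, 2] - 1L)))
      comp$ah <- rescale_to_var(drop(wah$W[, cols, drop = FALSE] %*%
                                       stats::rnorm(length(cols))), target("ah"))
    }
    sigma_e2 <- (1 - sum(h2)) * sigma_P2
    e <- rescale_to_var(stats::rnorm(n), sigma_e2)
    grp <- factor(sample(c("g1", "g2"), n, replace = TRUE))
  })
  g <- comp$a + comp$d + comp$ah
  y <- mu + grp_effect * (as.integer(grp) - 1L) + g + e
  pheno <- data.frame(id = phased$sample_ids, flag = "T", trait = y,
                      grp = grp, stringsAsFactors = FALSE)
  pheno <- structure(pheno, class_cols = "grp", covariate_cols = character(0),
                     snp_fixed_cols = character(0), trait_col = "trait",
                     class = c("pheno_table", "data.frame"))
  truth <- structure(list(
    h2 = h2, sigma_P2 = sigma_P2,
    sigma = c(vapply(c("a", "d", "ah"), target, 1.0), e = (1 - sum(h2)) * sigma_P2),
    components = comp, e = e, g = g,
    causal_snps = causal_snps, causal_blocks = causal_blocks,
    mu = mu, grp_effect = grp_effect, seed = seed), class = "sim_truth")
  list(pheno = pheno, truth = truth)
}

#' Named simulation scenarios
#'
#' @return A named list of scenario parameter sets for
#'   [write_fixture_set()]: `null` (no genetic signal), `additive_only`
#'   (SNP additive model), `full_model` (all three components at
#'   h2 = 0.30/0.10/0.20, n = 1000, m = 2000, 5-SNP blocks),
#'   `rare_haplotypes` (low-frequency founder panel), `two_chrom`.
#' @export
scenario_registry <- function() {
  list(
    null = list(n = 500L, m = 1000L, n_chrom = 1L, f = 6L, r = 0.02,
                maf_range = c(0.1, 0.5), snps_per_block = 5L,
                h2 = c(a = 0, d = 0, ah = 0), components = c("a", "d", "ah")),
    additive_only = list(n = 1000L, m = 1000L, n_chrom = 1L, f = 6L, r = 0.02,
                         maf_range = c(0.1, 0.5), snps_per_block = 5L,
                         h2 = c(a = 0.5, d = 0, ah = 0), components = "a"),
    full_model = list(n = 1000L, m = 2000L, n_chrom = 1L, f = 6L, r = 0.02,
                      maf_range = c(0.1, 0.5), snps_per_block = 5L,
                      h2 = c(a = 0.30, d = 0.10, ah = 0.20),
                      components = c("a", "d", "ah")),
    rare_haplotypes = list(n = 500L, m = 1000L, n_chrom = 1L, f = 12L, r = 0.02,
                           maf_range = c(0.02, 0.2), snps_per_block = 5L,
                           h2 = c(a = 0.2, d = 0, ah = 0.3),
                           components = c("a", "ah")),
    two_chrom = list(n = 500L, m = 1000L, n_chrom = 2L, f = 6L, r = 0.02,
                     maf_range = c(0.1, 0.5), snps_per_block = 4L,
                     h2 = c(a = 0.3, d = 0, ah = 0.2),
                     components = c("a", "ah")))
}

#' Write a complete five-file input set with known truth
#'
#' Simulates a named scenario and writes the five pipeline input files
#' (SNP genotypes, phased haplotypes, phenotypes, map, parameter file)
#' plus a `truth.txt` sidecar. Ten percent of individuals have their
#' trait replaced by the missing token, flagging them as validation; the
#' sidecar records their held-out values. Starting variances in the
#' parameter file split the phenotypic variance equally over the active
#' components, so they carry no knowledge of the truth.
#'
#' @param dir output directory (created if needed).
#' @param scenario a name from [scenario_registry()].
#' @param seed integer seed.
#' @return Invisibly, a list with the simulated objects (`phased`, `map`,
#'   `blocks`, `pheno` as written, `truth`, `config_path`).
#' @export
write_fixture_set <- function(dir, scenario = "full_model", seed = 1L) {
  sc <- scenario_registry()[[scenario]]
  if (is.null(sc)) stopf("unknown scenario '%s'", scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_haplotypes(sc$n, sc$m, sc$n_chrom, sc$f, sc$r, sc$maf_range,
                             seed = seed)
  blocks <- block_by_snp(sim$map, sc$snps_per_block)
  ph <- simulate_phenotypes(sim$phased, blocks, h2 = sc$h2, seed = seed + 1L,
                            n_causal = max(50L, sc$m %/% 20L))
  pheno <- ph$pheno
  n <- nrow(pheno)
  n_val <- max(1L, round(0.1 * n))
  val <- with_seed(seed + 2L, sort(sample.int(n, n_val)))
  held <- data.frame(id = pheno$id[val], y = pheno$trait[val])
  geno <- haplotypes_to_genotypes(sim$phased)

  write_snp_map(sim$map, file.path(dir, "map.txt"))
  write_snp_genotypes(geno, file.path(dir, "snp.txt"))
  write_phased_haplotypes(sim$phased, file.path(dir, "hap.txt"))
  trait_chr <- sprintf("%.10g", pheno$trait)
  trait_chr[val] <- "NA"
  writeLines(c("id grp trait",
               paste(pheno$id, as.character(pheno$grp), trait_chr)),
             file.path(dir, "pheno.txt"))

  active <- sc$components
  start <- rep(1 / (length(active) + 1), length(active) + 1)
  vk <- c(a = "var_snp_a", d = "var_snp_d", ah = "var_hap_a")
  par_lines <- c(
    sprintf("# scenario %s (synthetic)", scenario),
    sprintf("snp_file %s", file.path(dir, "snp.txt")),
    sprintf("hap_file %s", file.path(dir, "hap.txt")),
    sprintf("map_file %s", file.path(dir, "map.txt")),
    sprintf("pheno_file %s", file.path(dir, "pheno.txt")),
    vapply(c("a", "d", "ah"), function(tag) {
      key <- vk[[tag]]
      if (tag %in% active) sprintf("%s %.6g", key, start[1]) else sprintf("#%s 0.1", key)
    }, ""),
    sprintf("var_snp_e %.6g", start[1]),
    sprintf("block_by_snp %d", sc$snps_per_block),
    "trait_col trait", "class_cols grp", "missing_token NA",
    sprintf("seed %d", seed), sprintf("output_prefix %s", file.path(dir, "run")))
  writeLines(par_lines, file.path(dir, "params.txt"))

  truth_lines <- c("component\ttarget_h2\trealized_h2\tseed",
                   vapply(c("a", "d", "ah"), function(tag) {
                     tg <- if (tag %in% names(sc$h2)) sc$h2[[tag]] else 0
                     re <- stats::var(ph$truth$components[[tag]]) / ph$truth$sigma_P2
                     sprintf("%s\t%g\t%g\t%d", tag, tg, re, seed)
                   }, ""))
  writeLines(truth_lines, file.path(dir, "truth.txt"))
  utils::write.table(held, file.path(dir, "held_out.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(phased = sim$phased, map = sim$map, blocks = blocks,
                 pheno = pheno, truth = ph$truth, held_out = held,
                 config_path = file.path(dir, "params.txt")))
}

#' Write a SNP map file
#' @param map a `snp_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_map <- function(map, path) {
  writeLines(c("snp_id chrom pos_bp",
               paste(map$snp_id, map$chrom, map$pos_bp)), path)
  invisible(path)
}

#' Write a SNP genotype file
#' @param geno n x m genotype matrix with sample row names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_genotypes <- function(geno, path) {
  writeLines(paste(rownames(geno), apply(geno, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Write a phased haplotype file
#' @param phased a `phased_haplotypes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_haplotypes <- function(phased, path) {
  n <- length(phased$sample_ids)
  writeLines(paste(rep(phased$sample_ids, each = 2L), rep(1:2, n),
                   apply(phased$alleles, 1, paste, collapse = " ")), path)
  invisible(path)
}
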