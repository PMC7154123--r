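# Shared fixtures and independent oracles, all built in code.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_map <- function() {
  read_snp_map(write_tmp(c("snp_id chrom pos_bp",
                           "s1 chr1 100", "s2 chr1 500", "s3 chr2 50")))
}

# Minimal config list accepted by read_phenotypes / build_model_matrices.
tiny_config <- function(trait_col = "trait", class_cols = character(0),
                        covariate_cols = character(0),
                        snp_fixed_cols = character(0), missing_token = "NA",
                        components = c("a", "d", "ah")) {
  list(trait_col = trait_col, class_cols = class_cols,
       covariate_cols = covariate_cols, snp_fixed_cols = snp_fixed_cols,
       missing_token = missing_token, components = components,
       snp_fixed = snp_fixed_cols)
}

# Simulated dataset with model matrices, GRMs, and assembled mixed-model
# data, at a size chosen per test.
sim_dataset <- function(n = 150, m = 120, h2 = c(a = 0.3, d = 0.1, ah = 0.2),
                        snps_per_block = 4, seed = 11, f = 6, r = 0.02,
                        n_chrom = 1, maf_range = c(0.1, 0.5),
                        val_frac = 0, n_causal = max(20, m %/% 10)) {
  sim <- simulate_haplotypes(n, m, n_chrom = n_chrom, f = f, r = r,
                             maf_range = maf_range, seed = seed)
  blocks <- block_by_snp(sim$map, snps_per_block)
  ph <- simulate_phenotypes(sim$phased, blocks, h2 = h2, seed = seed + 1,
                            n_causal = n_causal)
  pheno <- ph$pheno
  if (val_frac > 0) {
    idx <- with_seed_local(seed + 2, sort(sample.int(n, round(val_frac * n))))
    pheno$held_y <- NA_real_
    pheno$held_y[idx] <- pheno$trait[idx]
    pheno$trait[idx] <- NA_real_
    pheno$flag[idx] <- "V"
  }
  comps <- names(h2)[h2 > 0]
  if (length(comps) == 0) comps <- c("a", "d", "ah")
  geno <- haplotypes_to_genotypes(sim$phased)
  enc <- encode_block_genotypes(sim$phased, blocks)
  mm <- build_model_matrices(list(components = comps,
                                  snp_fixed_cols = character(0)),
                             snp = geno, encoded = enc)
  grms <- lapply(stats::setNames(comps, comps), function(t) build_grm(mm$W[[t]], t))
  data <- mixed_model_data(pheno, grms)
  list(sim = sim, blocks = blocks, pheno = pheno, truth = ph$truth,
       geno = geno, enc = enc, mm = mm, grms = grms, data = data,
       comps = comps)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# restrict an assembled mixed_model_data to a component subset
subset_components <- function(data, comps) {
  data$K <- data$K[comps]
  data$Kobs <- data$Kobs[comps]
  data$k <- data$k[comps]
  data
}

even_start <- function(comps, sigma_P = 1) {
  stats::setNames(rep(sigma_P / (length(comps) + 1), length(comps) + 1),
                  c(comps, "e"))
}

# ---- independent REML oracle ---------------------------------------------
# Straight-line restricted log-likelihood (no Cholesky shortcuts, no
# shared code with the fitting path) and direct numerical maximization.

oracle_reml_logL <- function(sig, y, X, Ks) {
  N <- length(y)
  V <- diag(sig[length(sig)], N)
  for (i in seq_along(Ks)) V <- V + sig[i] * Ks[[i]]
  Vi <- solve(V)
  if (ncol(X) > 0) {
    C <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(C) %*% t(X) %*% Vi
    ld <- as.numeric(determinant(V)$modulus + determinant(C)$modulus -
                       determinant(t(X) %*% X)$modulus)
  } else {
    P <- Vi
    ld <- as.numeric(determinant(V)$modulus)
  }
  -0.5 * (ld + drop(t(y) %*% P %*% y))
}

oracle_reml_fit <- function(y, X, Ks, n_starts = 6, seed = 99) {
  p <- length(Ks) + 1
  obj <- function(ls) -oracle_reml_logL(exp(ls), y, X, Ks)
  best <- NULL
  starts <- with_seed_local(seed, lapply(seq_len(n_starts), function(i)
    log(stats::runif(p, 0.05, 2) * stats::var(y))))
  for (s0 in starts) {
    o <- stats::optim(s0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(sigma = exp(best$par), logL = -best$value)
}
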