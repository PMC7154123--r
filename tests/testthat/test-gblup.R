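fake_fit <- function(sigma) structure(list(sigma = sigma), class = "greml_fit")

pheno_from <- function(ids, y, ...) {
  structure(data.frame(id = ids, flag = ifelse(is.na(y), "V", "T"), trait = y,
                       stringsAsFactors = FALSE),
            class_cols = character(0), covariate_cols = character(0),
            snp_fixed_cols = character(0), trait_col = "trait",
            class = c("pheno_table", "data.frame"))
}

grm_like <- function(M, k, tag = "a") {
  structure(list(tag = tag, matrix = M, k = k, n = nrow(M),
                 sample_digest = sample_digest(rownames(M))), class = "hb_grm")
}

test_that("single-record shrinkage and reliability follow the scalar closed form", {
  K <- matrix(1, 1, 1, dimnames = list("i1", "i1"))
  data <- mixed_model_data(pheno_from("i1", 2.4), list(a = grm_like(K, 1)),
                           intercept = FALSE)
  fit <- fake_fit(c(a = 1, e = 1))
  gb <- component_gblup(fit, data)
  expect_equal(unname(gb$u$a), 2.4 * 1 / (1 + 1))      # y * sg2/(sg2+se2)
  expect_equal(unname(reliability(fit, data, "a")), 0.5)
  fit2 <- fake_fit(c(a = 3, e = 1))
  expect_equal(unname(reliability(fit2, data, "a")), 0.75)
})

test_that("adding a constant to y shifts the intercept and leaves BLUPs unchanged", {
  ds <- sim_dataset(n = 60, m = 50, h2 = c(a = 0.4), seed = 91, val_frac = 0.1)
  fit <- fit_greml(ds$data, even_start("a"))
  b1 <- solve_fixed_effects(fit, ds$data)
  u1 <- component_gblup(fit, ds$data)$u$a
  pheno2 <- ds$pheno
  pheno2$trait <- pheno2$trait + 5
  data2 <- mixed_model_data(pheno2, ds$grms["a"])
  b2 <- solve_fixed_effects(fit, data2)
  u2 <- component_gblup(fit, data2)$u$a
  expect_equal(b2[["(Intercept)"]], b1[["(Intercept)"]] + 5, tolerance = 1e-8)
  expect_equal(b2[setdiff(names(b2), "(Intercept)")],
               b1[setdiff(names(b1), "(Intercept)")], tolerance = 1e-8)
  expect_equal(u2, u1, tolerance = 1e-8)
})

test_that("a validation individual unrelated to all training individuals gets BLUP 0", {
  n <- 12
  set.seed(3)
  W <- matrix(rnorm(n * 30), n, 30, dimnames = list(sprintf("i%d", 1:n), NULL))
  K <- build_grm(W, "a")$matrix
  K[n, ] <- 0; K[, n] <- 0          # sever individual n, keep PSD
  y <- c(rnorm(n - 1), NA)
  data <- mixed_model_data(pheno_from(sprintf("i%d", 1:n), y),
                           list(a = grm_like(K, 1)))
  fit <- fake_fit(c(a = 0.5, e = 0.5))
  gb <- component_gblup(fit, data)
  expect_equal(unname(gb$u$a[n]), 0)
  expect_warning(rel <- reliability(fit, data, "a"), "zero prior variance")
  expect_equal(unname(rel[n]), 0)
})

test_that("back-solved marker effects reconstruct the genomic values exactly", {
  ds <- sim_dataset(n = 80, m = 60, h2 = c(a = 0.3, d = 0.1, ah = 0.2),
                    seed = 93, val_frac = 0.1)
  fit <- fit_greml(ds$data, even_start(ds$comps))
  gb <- component_gblup(fit, ds$data)
  me <- marker_effects(fit, ds$data, ds$mm, ds$blocks)
  a_rebuilt <- drop(ds$mm$W$a %*% me$snp$alpha_hat)
  expect_equal(unname(a_rebuilt), unname(gb$u$a), tolerance = 1e-10)
  d_rebuilt <- drop(ds$mm$W$d %*% me$snp$delta_hat)
  expect_equal(unname(d_rebuilt), unname(gb$u$d), tolerance = 1e-10)
  # per-marker heritabilities are nonnegative and partition the component h2
  expect_true(all(me$snp$h2_snp_a >= 0))
  expect_true(all(me$block$h2_block >= 0))
  expect_equal(sum(me$snp$h2_snp_a), fit$h2[["a"]], tolerance = 1e-12)
  expect_equal(sum(me$snp$h2_snp_d), fit$h2[["d"]], tolerance = 1e-12)
  expect_equal(sum(me$block$h2_block), fit$h2[["ah"]], tolerance = 1e-12)
})

test_that("monomorphic SNPs get zero effect and zero heritability", {
  ds <- sim_dataset(n = 40, m = 30, h2 = c(a = 0.4), seed = 97)
  geno <- ds$geno
  geno[, 5] <- 0L                     # force monomorphic
  mm <- build_model_matrices(list(components = "a",
                                  snp_fixed_cols = character(0)), snp = geno)
  grms <- list(a = build_grm(mm$W$a, "a"))
  data <- mixed_model_data(ds$pheno, grms)
  fit <- fit_greml(data, even_start("a"))
  me <- marker_effects(fit, data, mm)
  expect_equal(me$snp$alpha_hat[5], 0)
  expect_equal(me$snp$h2_snp_a[5], 0)
})

test_that("total reliability equals the literal nine-term cross-component expansion", {
  ds <- sim_dataset(n = 50, m = 40, h2 = c(a = 0.25, d = 0.1, ah = 0.2),
                    seed = 101, val_frac = 0.1)
  fit <- fit_greml(ds$data, even_start(ds$comps))
  data <- ds$data
  rel <- reliability(fit, data)
  # brute-force expansion: sum over ordered component pairs of
  # (G_i Z'PZ G_j)_ii over the summed prior variance diagonal
  Pobj <- compute_P(fit$sigma, data)
  ZPZ <- matrix(0, data$n, data$n)
  agg <- rowsum(Pobj$P, data$obs_ind)
  agg <- rowsum(t(agg), data$obs_ind)
  idx <- as.integer(rownames(agg))
  ZPZ[idx, idx] <- agg
  G <- lapply(names(data$K), function(i) fit$sigma[[i]] * data$K[[i]])
  names(G) <- names(data$K)
  num <- 0
  for (i in names(G)) for (j in names(G))
    num <- num + diag(G[[i]] %*% ZPZ %*% G[[j]])
  den <- 0
  for (i in names(G)) den <- den + fit$sigma[[i]] * diag(data$K[[i]])
  expect_equal(unname(rel), unname(num / den), tolerance = 1e-10)
  expect_true(all(rel >= 0 & rel <= 1))
  # training individuals are on average at least as reliable as validation
  expect_gte(mean(rel[data$flag == "T"]), mean(rel[data$flag == "V"]))
})

test_that("reliabilities shrink to zero as residual variance inflates", {
  ds <- sim_dataset(n = 40, m = 30, h2 = c(a = 0.5), seed = 103)
  prev <- Inf
  for (se in c(1, 10, 100, 1000)) {
    rel <- reliability(fake_fit(c(a = 0.5, e = se)), ds$data, "a")
    expect_lt(mean(rel), prev)
    prev <- mean(rel)
  }
  expect_lt(prev, 0.01)
})

test_that("original-coding and normalized-GRM parameterizations give identical GBLUP and reliability", {
  ds <- sim_dataset(n = 50, m = 40, h2 = c(a = 0.4), seed = 107, val_frac = 0.1)
  Wa <- ds$mm$W$a
  ka <- k_constant(Wa)
  Ag <- build_grm(Wa, "a")                                    # WW'/k, sigma2_a
  WWt <- tcrossprod(Wa)
  dimnames(WWt) <- dimnames(Ag$matrix)
  raw <- grm_like(WWt, 1)                                     # WW', sigma2_ao
  sigma_a <- 0.45; sigma_e <- 0.55
  d1 <- mixed_model_data(ds$pheno, list(a = Ag))
  d2 <- mixed_model_data(ds$pheno, list(a = raw))
  f1 <- fake_fit(c(a = sigma_a, e = sigma_e))
  f2 <- fake_fit(c(a = sigma_a / ka, e = sigma_e))
  u1 <- component_gblup(f1, d1)$u$a
  u2 <- component_gblup(f2, d2)$u$a
  expect_equal(u1, u2, tolerance = 1e-12)
  expect_equal(reliability(f1, d1, "a"), reliability(f2, d2, "a"),
               tolerance = 1e-12)
})

test_that("GNG prediction composes fixed and genetic parts per model", {
  ds <- sim_dataset(n = 60, m = 40, h2 = c(a = 0.4), seed = 109, val_frac = 0.1)
  fit <- fit_greml(ds$data, even_start("a"))
  rep_df <- gblup_report(fit, ds$data)
  b <- attr(rep_df, "b_hat")
  expect_equal(rep_df$y_hat,
               unname(drop(ds$data$X_ind %*% b) + rep_df$a_hat),
               tolerance = 1e-12)
  # individual with zero genetic value predicts at the fixed-effect mean
  gb <- component_gblup(fit, ds$data)
  yh <- gng_predict(fit, ds$data, b, gb$g_hat * 0)
  expect_equal(unname(yh), unname(drop(ds$data$X_ind %*% b)))
  # training residuals have generalized-least-squares mean zero
  Pobj <- compute_P(fit$sigma, ds$data)
  expect_lt(abs(sum(Pobj$Vinv %*% (ds$data$y - ds$data$X %*% b))), 1e-6)
})

test_that("GNG refuses repeated observations per individual", {
  ids <- c("i1", "i1", "i2", "i3", "i4", "i5", "i6")
  set.seed(11)
  W <- matrix(rnorm(6 * 20), 6, 20, dimnames = list(sprintf("i%d", 1:6), NULL))
  K <- build_grm(W, "a")
  ph <- pheno_from(ids, rnorm(7))
  data <- mixed_model_data(ph, list(a = K))
  fit <- fake_fit(c(a = 0.5, e = 0.5))
  gb <- component_gblup(fit, data)
  b <- solve_fixed_effects(fit, data)
  expect_error(gng_predict(fit, data, b, gb$g_hat), "one observation per individual")
})

test_that("a SNP fitted as a fixed covariate moves to b_hat and out of the random coding", {
  ds <- sim_dataset(n = 80, m = 30, h2 = c(a = 0.4), seed = 113)
  snp_name <- "snp4"
  pheno <- ds$pheno
  pheno[[snp_name]] <- as.numeric(ds$geno[match(pheno$id, rownames(ds$geno)), snp_name])
  attr(pheno, "snp_fixed_cols") <- snp_name
  mm <- build_model_matrices(list(components = "a", snp_fixed_cols = snp_name),
                             snp = ds$geno)
  expect_false(snp_name %in% colnames(mm$W$a))
  data <- mixed_model_data(pheno, list(a = build_grm(mm$W$a, "a")))
  fit <- fit_greml(data, even_start("a"))
  b <- solve_fixed_effects(fit, data)
  expect_true(snp_name %in% names(b))
  me <- marker_effects(fit, data, mm)
  expect_false(snp_name %in% me$snp$snp_id)
})
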