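# Fixtures here are intentionally small (n <= 150): each REML iteration
# costs one Cholesky of the training-by-training V, so these run in
# seconds while still exercising every code path.

make_1comp_data <- function(n = 25, h2 = 0.5, seed = 1, m = 60) {
  set.seed(seed)
  W <- matrix(rnorm(n * m), n, m)
  rownames(W) <- sprintf("i%d", 1:n)
  K <- build_grm(W, "a")
  u <- drop(K$matrix %*% rnorm(n)) # smooth genetic signal
  u <- u / sd(u) * sqrt(h2)
  y <- 2 + u + rnorm(n, sd = sqrt(1 - h2))
  pheno <- structure(
    data.frame(id = rownames(W), flag = "T", trait = y, stringsAsFactors = FALSE),
    class_cols = character(0), covariate_cols = character(0),
    snp_fixed_cols = character(0), trait_col = "trait",
    class = c("pheno_table", "data.frame"))
  mixed_model_data(pheno, list(a = K))
}

test_that("the projection matrix annihilates X and is idempotent through V", {
  ds <- sim_dataset(n = 60, m = 50, h2 = c(a = 0.3, ah = 0.2), seed = 81,
                    val_frac = 0.1)
  data <- ds$data
  sig <- even_start(ds$comps)
  Pobj <- compute_P(sig, data)
  expect_lt(max(abs(Pobj$P %*% data$X)), 1e-10)
  V <- diag(sig[["e"]], data$N)
  for (i in ds$comps) V <- V + sig[[i]] * data$Kobs[[i]]
  expect_lt(max(abs(Pobj$P %*% V %*% Pobj$P - Pobj$P)), 1e-10)
})

test_that("the restricted likelihood is invariant to reparameterizing X", {
  ds <- sim_dataset(n = 50, m = 40, h2 = c(a = 0.4), seed = 83)
  data <- ds$data
  sig <- even_start("a")
  base <- compute_P(sig, data)$logL
  set.seed(9)
  A <- matrix(rnorm(data$c^2), data$c, data$c)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(data$c^2), data$c, data$c)
  data2 <- data
  data2$X <- data$X %*% A
  expect_equal(compute_P(sig, data2)$logL, base, tolerance = 1e-8)
})

test_that("EM updates never decrease the restricted likelihood", {
  for (seed in 1:20) {
    data <- make_1comp_data(n = 30, h2 = runif(1, 0.1, 0.8), seed = seed)
    sigma <- c(a = 0.4, e = 0.6)
    prev <- compute_P(sigma, data)$logL
    for (it in 1:12) {
      sigma <- em_update(sigma, data)
      cur <- compute_P(sigma, data)$logL
      expect_gte(cur, prev - 1e-8)
      prev <- cur
    }
  }
})

test_that("a REML stationary point is an EM fixed point", {
  data <- make_1comp_data(n = 40, h2 = 0.5, seed = 7)
  fit <- fit_greml(data, c(a = 0.5, e = 0.5),
                   greml_control(tolerance_var = 1e-12, tolerance_h2 = 0))
  stepped <- em_update(fit$sigma, data)
  expect_lt(max(abs(stepped - fit$sigma)), 1e-6)
  # AI proposal barely moves at the maximum
  ai <- ai_update(fit$sigma, data)
  if (ai$ok) expect_lt(max(abs(ai$sigma - fit$sigma)), 1e-6)
})

test_that("converged estimates match direct likelihood maximization (1 and 2 components)", {
  for (seed in 1:3) {
    data <- make_1comp_data(n = 25, h2 = 0.5, seed = seed)
    fit <- fit_greml(data, c(a = 0.3, e = 0.7),
                     greml_control(tolerance_var = 1e-12, tolerance_h2 = 1e-10))
    oracle <- oracle_reml_fit(data$y, data$X, data$Kobs, seed = seed + 100)
    expect_equal(unname(fit$sigma), unname(oracle$sigma), tolerance = 1e-4)
    expect_equal(fit$logL, oracle$logL, tolerance = 1e-6)
  }
  for (seed in 4:5) {
    ds <- sim_dataset(n = 25, m = 40, h2 = c(a = 0.3, ah = 0.3),
                      snps_per_block = 4, seed = seed)
    fit <- fit_greml(ds$data, even_start(ds$comps),
                     greml_control(tolerance_var = 1e-12, tolerance_h2 = 1e-10))
    oracle <- oracle_reml_fit(ds$data$y, ds$data$X, ds$data$Kobs, seed = seed + 100)
    expect_equal(unname(fit$sigma), unname(oracle$sigma), tolerance = 1e-4)
  }
})

test_that("AI failure on a near-zero component falls back to EM and still converges", {
  data <- make_1comp_data(n = 60, h2 = 0.001, seed = 13)
  # EM crawls near the boundary; give it the iterations it needs
  fit <- fit_greml(data, c(a = 0.5, e = 0.5),
                   greml_control(max_iterations = 10000))
  expect_true(fit$converged)
  expect_true(any(fit$trace$method == "AI-fail:EM") ||
                all(fit$trace$method[-(1:2)] %in% c("AI", "AI-fail:EM")))
  expect_lt(fit$h2[["a"]], 0.2)
})

test_that("AI reaches the variance tolerance in fewer iterations than EM alone", {
  data <- make_1comp_data(n = 80, h2 = 0.5, seed = 17)
  ctrl_v <- function(ai_start) greml_control(tolerance_var = 1e-10,
                                             tolerance_h2 = 0,
                                             ai_start_iteration = ai_start,
                                             max_iterations = 2000)
  hybrid <- fit_greml(data, c(a = 0.5, e = 0.5), ctrl_v(3))
  em_only <- fit_greml(data, c(a = 0.5, e = 0.5), ctrl_v(Inf))
  expect_true(hybrid$converged)
  expect_lt(hybrid$iterations, em_only$iterations)
})

test_that("scaling a relationship matrix rescales its variance estimate exactly", {
  data <- make_1comp_data(n = 40, h2 = 0.4, seed = 19)
  fit1 <- fit_greml(data, c(a = 0.4, e = 0.6))
  c_ <- 4
  data2 <- data
  data2$K$a <- data$K$a * c_
  data2$Kobs$a <- data$Kobs$a * c_
  fit2 <- fit_greml(data2, c(a = 0.4 / c_, e = 0.6))
  expect_equal(fit2$sigma[["a"]] * c_, fit1$sigma[["a"]], tolerance = 1e-8)
  expect_equal(fit2$sigma[["e"]], fit1$sigma[["e"]], tolerance = 1e-8)
  expect_equal(fit2$logL, fit1$logL, tolerance = 1e-8)
})

test_that("heritabilities lie in [0,1) with nonnegative standard deviations", {
  ds <- sim_dataset(n = 100, m = 80, h2 = c(a = 0.3, d = 0.1, ah = 0.2), seed = 23)
  fit <- fit_greml(ds$data, even_start(ds$comps))
  expect_true(all(fit$h2 >= 0 & fit$h2 < 1))
  expect_lte(sum(fit$h2), 1)
  expect_true(all(fit$h2_sd >= 0))
  expect_identical(fit$trace$method[1:2], c("EM", "EM"))
})

test_that("degenerate inputs are rejected with clear messages", {
  data <- make_1comp_data(n = 25)
  expect_error(fit_greml(data, c(a = -1, e = 1)), "> 0")
  expect_error(fit_greml(data, c(e = 1)), "must name every component")
  # all phenotypes missing
  pheno <- structure(
    data.frame(id = sprintf("i%d", 1:10), flag = "V", trait = NA_real_),
    class_cols = character(0), covariate_cols = character(0),
    snp_fixed_cols = character(0), trait_col = "trait",
    class = c("pheno_table", "data.frame"))
  W <- matrix(rnorm(100), 10, 10, dimnames = list(sprintf("i%d", 1:10), NULL))
  expect_error(mixed_model_data(pheno, list(a = build_grm(W, "a"))),
               "no training individuals")
})
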