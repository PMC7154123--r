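test_that("SNP map parsing validates structure and reports locations", {
  map <- tiny_map()
  expect_s3_class(map, "snp_map")
  expect_equal(nrow(map), 3)
  expect_equal(length(unique(map$chrom)), 2)
  expect_identical(map$snp_id, c("s1", "s2", "s3"))

  expect_error(read_snp_map(write_tmp(c("snp_id chrom pos_bp",
                                        "s2 chr1 500", "s1 chr1 100"))),
               "positions not increasing")
  expect_error(read_snp_map(write_tmp(c("snp_id chrom pos_bp",
                                        "s1 chr1 100", "s1 chr1 200"))),
               "duplicate snp_id")
  expect_error(read_snp_map(write_tmp(c("snp_id chrom pos_bp",
                                        "s1 chr1 1.5"))),
               "line 2.*not a positive integer")
  empty <- read_snp_map(write_tmp("snp_id chrom pos_bp"))
  expect_equal(nrow(empty), 0)
})

test_that("SNP genotype reader rejects missing values and dimension mismatches", {
  map <- tiny_map()
  g <- read_snp_genotypes(write_tmp(c("i1 2 1 0", "i2 0 1 2")), map)
  expect_equal(dim(g), c(2, 3))
  expect_equal(unname(g[1, ]), c(2L, 1L, 0L))
  expect_error(read_snp_genotypes(write_tmp("i1 2 NA 0"), map),
               "impute first")
  expect_error(read_snp_genotypes(write_tmp("i1 2 1 0 1"), map),
               "expected id \\+ 3 genotypes")
})

test_that("phased haplotype reader enforces pairing and cross-checks genotypes", {
  map <- tiny_map()
  hap <- read_phased_haplotypes(write_tmp(c("i1 1 0 0 1", "i1 2 0 1 1")), map)
  expect_equal(dim(hap$alleles), c(2, 3))
  expect_equal(hap$sample_ids, "i1")
  expect_error(read_phased_haplotypes(write_tmp("i1 1 0 0 1"), map),
               "odd number")
  expect_error(read_phased_haplotypes(write_tmp(c("i1 1 0 2 1", "i1 2 0 1 1")), map),
               "not in \\{0,1\\}")
  # allele sums must reproduce genotype counts
  g <- read_snp_genotypes(write_tmp("i1 0 1 2"), map)
  expect_true(check_phase_consistency(hap, g))
  g_bad <- read_snp_genotypes(write_tmp("i1 1 1 2"), map)
  expect_error(check_phase_consistency(hap, g_bad), "phase inconsistency")
})

test_that("phenotype flags are a pure function of the trait and missing token", {
  cfg <- tiny_config(class_cols = "sex")
  ph <- read_phenotypes(write_tmp(c("id sex trait", "i1 M 1.2", "i2 F NA",
                                    "i3 M 0.7")), cfg)
  expect_equal(ph$flag, c("T", "V", "T"))
  expect_equal(ph$trait, c(1.2, NA, 0.7))
  expect_s3_class(ph$sex, "factor")
  expect_equal(nlevels(ph$sex), 2)

  all_v <- read_phenotypes(write_tmp(c("id sex trait", "i1 M NA", "i2 F NA")), cfg)
  expect_true(all(all_v$flag == "V"))

  expect_error(read_phenotypes(write_tmp(c("id sex trait extra", "i1 M 1 2")), cfg),
               "not declared")
  cfg2 <- tiny_config(covariate_cols = "age")
  expect_error(read_phenotypes(write_tmp(c("id age trait", "i1 old 1")), cfg2),
               "non-numeric")
})

test_that("parameter-file activation patterns map bijectively to the seven models", {
  base <- c("var_snp_e 0.5", "trait_col trait")
  pat <- list(`1` = c("var_snp_a 0.1", "var_snp_d 0.1", "var_hap_a 0.1"),
              `2` = c("var_snp_a 0.1", "#var_snp_d 0.1", "var_hap_a 0.1"),
              `3` = c("#var_snp_a 0.1", "var_snp_d 0.1", "var_hap_a 0.1"),
              `4` = c("var_hap_a 0.1"),
              `5` = c("var_snp_a 0.1", "var_snp_d 0.1"),
              `6` = c("var_snp_a 0.1"),
              `7` = c("var_snp_d 0.1"))
  for (id in names(pat)) {
    cfg <- parse_parameter_file(write_tmp(c(pat[[id]], base)))
    expect_equal(cfg$model_id, as.integer(id), info = paste("pattern", id))
    expect_identical(cfg$components, model_components(cfg$model_id))
  }
  expect_error(parse_parameter_file(write_tmp(base)), "no genetic component")
  expect_error(parse_parameter_file(write_tmp(c("var_snp_a 0.1"))),
               "var_snp_e")
  expect_error(parse_parameter_file(write_tmp(c("var_snp_a -1", "var_snp_e 0.5"))),
               "must be > 0")
  # defaults
  cfg <- parse_parameter_file(write_tmp(c("var_snp_a 0.1", "var_snp_e 0.5")))
  expect_equal(cfg$tolerance_h2, 1e-6)
  expect_equal(cfg$tolerance_var, 1e-8)
  expect_equal(cfg$max_iterations, 1000L)
  expect_equal(cfg$ai_start_iteration, 3)
})

test_that("fill_counts records sizes and is idempotent", {
  map <- tiny_map()
  blocks <- block_by_snp(map, 2)
  cfg <- parse_parameter_file(write_tmp(c("var_snp_a 0.1", "var_snp_e 0.5")))
  cfg <- fill_counts(cfg, map, blocks)
  expect_equal(cfg$n_snps, 3L)
  expect_equal(cfg$n_blocks, 2L)
  expect_identical(fill_counts(cfg, map, blocks)[c("n_snps", "n_blocks")],
                   cfg[c("n_snps", "n_blocks")])
})

test_that("GBLUP report files round-trip at 12 significant digits with model-specific columns", {
  ds6 <- sim_dataset(n = 80, m = 40, h2 = c(a = 0.4), snps_per_block = 4, seed = 3)
  fit <- fit_greml(ds6$data, even_start(ds6$comps))
  rep6 <- gblup_report(fit, ds6$data)
  expect_identical(names(rep6), c("id", "flag", "a_hat", "rel_a", "y_hat"))
  path <- tempfile()
  write_gblup_report(rep6, path)
  back <- read_gblup_report(path)
  expect_equal(back$a_hat, rep6$a_hat, tolerance = 1e-11)
  expect_equal(back$rel_a, rep6$rel_a, tolerance = 1e-11)
  expect_identical(back$flag, rep6$flag)

  ds1 <- sim_dataset(n = 80, m = 40, h2 = c(a = 0.25, d = 0.1, ah = 0.2),
                     snps_per_block = 4, seed = 4)
  fit1 <- fit_greml(ds1$data, even_start(ds1$comps))
  rep1 <- gblup_report(fit1, ds1$data)
  expect_identical(names(rep1),
                   c("id", "flag", "a_hat", "rel_a", "d_hat", "rel_d",
                     "ah_hat", "rel_ah", "g_hat", "rel_g", "y_hat"))
})

test_that("merged visualization table interleaves block rows at midpoints, position-sorted", {
  map <- read_snp_map(write_tmp(c("snp_id chrom pos_bp", "s1 chr1 100",
                                  "s2 chr1 200", "s3 chr1 300")))
  snp_tab <- data.frame(snp_id = c("s1", "s2", "s3"),
                        h2_snp_a = c(0.01, 0.02, 0.03),
                        h2_snp_d = c(0.001, 0.002, 0.003))
  blk_tab <- data.frame(block_id = "chr1_blk1", chrom = "chr1",
                        start_bp = 100, end_bp = 300, h2_block = 0.1)
  merged <- merge_visualization_table(snp_tab, blk_tab, map)
  expect_equal(nrow(merged), 4)           # 3 SNP rows + 1 block row
  expect_false(is.unsorted(merged$pos_bp))
  brow <- merged[merged$id == "chr1_blk1", ]
  expect_equal(brow$pos_bp, 200)
  expect_true(is.na(brow$h2_snp_a))
  expect_equal(brow$h2_block, 0.1)
  # SNP-only variant has no block column
  m2 <- merge_visualization_table(snp_tab, NULL, map)
  expect_false("h2_block" %in% names(m2))
  expect_equal(nrow(m2), 3)
})
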