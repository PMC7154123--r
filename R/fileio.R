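# Readers and writers for the five pipeline input files (SNP genotypes,
# phased haplotypes, phenotypes, SNP map, parameter file) and the output
# report tables. All formats are whitespace-separated UTF-8 text, LF or
# CRLF. Malformed input is rejected with the offending line named; nothing
# is silently coerced.

split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

read_text_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", lines)
}

#' Read a SNP map file
#'
#' The map is whitespace-separated text with a header row and columns
#' `snp_id`, `chrom`, `pos_bp` (1-based physical position). Its row order
#' defines the column order of every genotype matrix in the pipeline.
#'
#' @param path path to the map file.
#' @return A data frame of class `snp_map` with columns `snp_id`, `chrom`,
#'   `pos_bp`.
#' @export
read_snp_map <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0) stopf("%s: empty file, expected a header row", path)
  header <- split_ws(lines[1])[[1]]
  need <- c("snp_id", "chrom", "pos_bp")
  if (!all(need %in% header))
    stopf("%s line 1: header must contain snp_id, chrom, pos_bp", path)
  body <- lines[-1]
  body_ln <- which(nzchar(trimws(body))) # keep original line numbers
  toks <- split_ws(body[body_ln])
  rows <- lapply(seq_along(toks), function(i) {
    tk <- toks[[i]]
    if (length(tk) != length(header))
      stopf("%s line %d: expected %d fields, found %d",
            path, body_ln[i] + 1L, length(header), length(tk))
    tk
  })
  m <- length(rows)
  get_col <- function(name) vapply(rows, function(r) r[match(name, header)], "")
  pos_chr <- get_col("pos_bp")
  bad <- which(!grepl("^[0-9]+$", pos_chr))
  if (length(bad) > 0)
    stopf("%s line %d: position '%s' is not a positive integer",
          path, body_ln[bad[1]] + 1L, pos_chr[bad[1]])
  map <- data.frame(snp_id = get_col("snp_id"), chrom = get_col("chrom"),
                    pos_bp = as.integer(pos_chr), stringsAsFactors = FALSE)
  validate_snp_map(map, path = path, lines = body_ln + 1L)
  class(map) <- c("snp_map", "data.frame")
  map
}

validate_snp_map <- function(map, path = "map", lines = seq_len(nrow(map)) + 1L) {
  dup <- duplicated(map$snp_id)
  if (any(dup))
    stopf("%s line %d: duplicate snp_id '%s'", path, lines[which(dup)[1]],
          map$snp_id[which(dup)[1]])
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    d <- diff(map$pos_bp[idx])
    if (any(d <= 0)) {
      at <- idx[which(d <= 0)[1] + 1L]
      stopf("%s line %d: positions not increasing within chromosome %s (snp '%s')",
            path, lines[at], ch, map$snp_id[at])
    }
  }
  if (any(map$pos_bp < 1)) stopf("%s: positions must be >= 1", path)
  invisible(map)
}

#' Read a SNP genotype file
#'
#' One row per individual: an identifier followed by one genotype per
#' mapped SNP, each the count (0, 1 or 2) of the file's "1" allele.
#' Missing genotypes are a hard error; impute before running the pipeline.
#'
#' @param path path to the genotype file (no header).
#' @param map a [read_snp_map()] result; defines the expected column count
#'   and the SNP column names.
#' @return An n x m integer matrix with sample ids as row names and SNP
#'   ids as column names.
#' @export
read_snp_genotypes <- function(path, map) {
  lines <- read_text_lines(path)
  keep <- which(nzchar(trimws(lines)))
  toks <- split_ws(lines[keep])
  m <- nrow(map)
  n <- length(toks)
  if (n == 0) stopf("%s: no genotype rows", path)
  counts <- matrix(0L, n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != m + 1L)
      stopf("%s line %d: expected id + %d genotypes, found %d fields",
            path, keep[i], m, length(tk))
    ids[i] <- tk[1]
    g <- tk[-1]
    bad <- which(!g %in% c("0", "1", "2"))
    if (length(bad) > 0)
      stopf(paste0("%s line %d: genotype '%s' for individual '%s' at SNP '%s'",
                   " is not in {0,1,2}; missing genotypes not supported; impute first"),
            path, keep[i], g[bad[1]], tk[1], map$snp_id[bad[1]])
    counts[i, ] <- as.integer(g)
  }
  if (anyDuplicated(ids))
    stopf("%s: duplicate individual id '%s'", path, ids[duplicated(ids)][1])
  dimnames(counts) <- list(ids, map$snp_id)
  counts
}

#' Read a phased haplotype file
#'
#' Two lines per individual: the identifier, the haplotype index (1 or 2),
#' then one allele (0 or 1) per mapped SNP. The two lines of an individual
#' must be adjacent. This file is the product of an external phasing or
#' imputation step; missing alleles are rejected.
#'
#' @param path path to the haplotype file (no header).
#' @param map a [read_snp_map()].
#' @param snp optional SNP genotype matrix from [read_snp_genotypes()]; if
#'   supplied, every individual's two alleles must sum to the genotype
#'   count at every SNP (phase-consistency cross-check).
#' @return A list of class `phased_haplotypes` with `sample_ids` (length n)
#'   and `alleles` (2n x m integer matrix, rows ordered id1.hap1, id1.hap2,
#'   id2.hap1, ...).
#' @export
read_phased_haplotypes <- function(path, map, snp = NULL) {
  lines <- read_text_lines(path)
  keep <- which(nzchar(trimws(lines)))
  toks <- split_ws(lines[keep])
  m <- nrow(map)
  if (length(toks) %% 2L != 0L)
    stopf("%s: odd number of haplotype rows (%d); two rows per individual required",
          path, length(toks))
  n <- length(toks) %/% 2L
  alleles <- matrix(0L, 2L * n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    for (h in 1:2) {
      r <- 2L * (i - 1L) + h
      tk <- toks[[r]]
      if (length(tk) != m + 2L)
        stopf("%s line %d: expected id + haplotype index + %d alleles, found %d fields",
              path, keep[r], m, length(tk))
      if (h == 1L) ids[i] <- tk[1]
      else if (tk[1] != ids[i])
        stopf("%s line %d: haplotype rows of '%s' and '%s' interleaved; the two rows of an individual must be adjacent",
              path, keep[r], ids[i], tk[1])
      if (!tk[2] %in% c("1", "2") || as.integer(tk[2]) != h)
        stopf("%s line %d: expected haplotype index %d, found '%s'",
              path, keep[r], h, tk[2])
      a <- tk[-(1:2)]
      bad <- which(!a %in% c("0", "1"))
      if (length(bad) > 0)
        stopf("%s line %d: allele '%s' for individual '%s' at SNP '%s' is not in {0,1}",
              path, keep[r], a[bad[1]], ids[i], map$snp_id[bad[1]])
      alleles[r, ] <- as.integer(a)
    }
  }
  if (anyDuplicated(ids))
    stopf("%s: duplicate individual id '%s'", path, ids[duplicated(ids)][1])
  rownames(alleles) <- paste0(rep(ids, each = 2L), ".", rep(1:2, n))
  colnames(alleles) <- map$snp_id
  out <- structure(list(sample_ids = ids, alleles = alleles),
                   class = "phased_haplotypes")
  if (!is.null(snp)) check_phase_consistency(out, snp)
  out
}

#' Check that phased haplotypes sum to SNP genotype counts
#'
#' @param phased a `phased_haplotypes` object.
#' @param snp a SNP genotype matrix over the same individuals and SNPs.
#' @return `TRUE` invisibly, or an error naming the first inconsistency.
#' @export
check_phase_consistency <- function(phased, snp) {
  if (!identical(phased$sample_ids, rownames(snp)))
    stopf("haplotype and SNP genotype files list different individuals")
  sums <- haplotypes_to_genotypes(phased)
  diff <- which(sums != snp, arr.ind = TRUE)
  if (nrow(diff) > 0)
    stopf("phase inconsistency: individual '%s' SNP '%s' has haplotype sum %d but genotype %d",
          rownames(snp)[diff[1, 1]], colnames(snp)[diff[1, 2]],
          sums[diff[1, , drop = FALSE]], snp[diff[1, , drop = FALSE]])
  invisible(TRUE)
}

#' Derive the SNP genotype matrix from phased haplotypes
#'
#' @param phased a `phased_haplotypes` object.
#' @return n x m integer matrix of allele-"1" counts.
#' @export
haplotypes_to_genotypes <- function(phased) {
  a <- phased$alleles
  n <- length(phased$sample_ids)
  g <- a[seq(1, 2 * n, by = 2), , drop = FALSE] +
    a[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(g) <- phased$sample_ids
  g
}

#' Read a phenotype file
#'
#' Whitespace-separated with a header; the first column is the individual
#' id, remaining columns must each be declared in the run configuration as
#' the trait, a class factor, a covariate, or a SNP-as-fixed column.
#' An observation whose trait equals the missing token marks its
#' individual as validation ("V"); all others are training ("T").
#'
#' @param path path to the phenotype file.
#' @param config a [parse_parameter_file()] result (or any list with
#'   `trait_col`, `class_cols`, `covariate_cols`, `snp_fixed_cols`,
#'   `missing_token`).
#' @return A data frame of class `pheno_table` with columns `id`, `flag`
#'   ("T"/"V"), `trait` (numeric, `NA` where missing) and the declared
#'   fixed-effect columns; declaration lists are kept as attributes.
#' @export
read_phenotypes <- function(path, config) {
  lines <- read_text_lines(path)
  if (length(lines) < 1) stopf("%s: empty phenotype file", path)
  header <- split_ws(lines[1])[[1]]
  id_col <- header[1]
  declared <- c(config$trait_col, config$class_cols, config$covariate_cols,
                config$snp_fixed_cols)
  extra <- setdiff(header[-1], declared)
  if (length(extra) > 0)
    stopf("%s: column '%s' is not declared as trait, class, covariate or SNP-fixed",
          path, extra[1])
  missing_declared <- setdiff(declared, header[-1])
  if (length(missing_declared) > 0)
    stopf("%s: declared column '%s' not present in file", path, missing_declared[1])
  keep <- which(nzchar(trimws(lines[-1]))) + 1L
  toks <- split_ws(lines[keep])
  bad_len <- which(lengths(toks) != length(header))
  if (length(bad_len) > 0)
    stopf("%s line %d: expected %d fields, found %d", path, keep[bad_len[1]],
          length(header), lengths(toks)[bad_len[1]])
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- header
  out <- data.frame(id = tab[[id_col]], stringsAsFactors = FALSE)
  trait_raw <- tab[[config$trait_col]]
  is_missing <- trait_raw == config$missing_token
  trait_num <- suppressWarnings(as.numeric(trait_raw))
  bad <- which(!is_missing & is.na(trait_num))
  if (length(bad) > 0)
    stopf("%s line %d: trait value '%s' is neither numeric nor the missing token '%s'",
          path, keep[bad[1]], trait_raw[bad[1]], config$missing_token)
  out$flag <- ifelse(is_missing, "V", "T")
  out$trait <- ifelse(is_missing, NA_real_, trait_num)
  for (cc in config$class_cols) out[[cc]] <- factor(tab[[cc]])
  for (cc in c(config$covariate_cols, config$snp_fixed_cols)) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stopf("%s line %d: covariate column '%s' has non-numeric value '%s'",
            path, keep[bad[1]], cc, tab[[cc]][bad[1]])
    out[[cc]] <- v
  }
  structure(out,
            class_cols = config$class_cols, covariate_cols = config$covariate_cols,
            snp_fixed_cols = config$snp_fixed_cols, trait_col = config$trait_col,
            class = c("pheno_table", "data.frame"))
}

# ---- parameter file -------------------------------------------------------

variance_keys <- c(a = "var_snp_a", d = "var_snp_d", ah = "var_hap_a",
                   e = "var_snp_e")

# Activation pattern of the three genetic starting variances -> model id.
model_table <- list(
  `1` = c("a", "d", "ah"), `2` = c("a", "ah"), `3` = c("d", "ah"),
  `4` = "ah", `5` = c("a", "d"), `6` = "a", `7` = "d")

#' Genetic components included in a prediction model
#'
#' @param model_id integer 1..7.
#' @return Character vector drawn from `c("a", "d", "ah")`: SNP additive,
#'   SNP dominance, haplotype additive.
#' @export
model_components <- function(model_id) {
  key <- as.character(model_id)
  if (!key %in% names(model_table)) stopf("no such model: %s", model_id)
  model_table[[key]]
}

#' Parse a run parameter file
#'
#' "key value" lines. A leading `#` disables a key: `#var_snp_d 0.1` means
#' the SNP dominance component is excluded from the model, exactly as if
#' the line were absent; `#` lines whose first token is not a known key are
#' ordinary comments. The prediction model (1..7) is derived from which of
#' the three genetic starting-variance keys (`var_snp_a`, `var_snp_d`,
#' `var_hap_a`) are active; `var_snp_e` is always required.
#'
#' @param path path to the parameter file.
#' @return A list of class `run_config`: `model_id`, `start` (named numeric
#'   vector over active components plus `"e"`), tolerances, iteration
#'   controls, file paths, fixed-effect declarations, counts, missing
#'   token, output prefix, seed.
#' @export
parse_parameter_file <- function(path) {
  lines <- read_text_lines(path)
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    disabled <- startsWith(ln, "#")
    if (disabled) ln <- trimws(sub("^#+", "", ln))
    if (!nzchar(ln)) next
    tk <- strsplit(ln, "[ \t]+")[[1]]
    key <- tk[1]
    if (disabled) next  # disabled key or plain comment: treated as absent
    if (length(tk) < 2)
      stopf("%s line %d: key '%s' has no value", path, i, key)
    kv[[key]] <- paste(tk[-1], collapse = " ")
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stopf("%s: key '%s' has non-numeric value '%s'", path, key, kv[[key]])
    v
  }
  chr <- function(key, default = NULL) kv[[key]] %||% default
  csv <- function(key) {
    v <- kv[[key]]
    if (is.null(v)) character(0) else strsplit(v, ",")[[1]]
  }
  start <- c(a = num("var_snp_a"), d = num("var_snp_d"),
             ah = num("var_hap_a"), e = num("var_snp_e"))
  if (!"e" %in% names(start))
    stopf("%s: var_snp_e (residual starting variance) is required", path)
  genetic <- intersect(c("a", "d", "ah"), names(start))
  if (length(genetic) == 0)
    stopf("%s: no genetic component active; at least one of var_snp_a, var_snp_d, var_hap_a must be set",
          path)
  if (any(start <= 0))
    stopf("%s: starting variance '%s' must be > 0",
          path, variance_keys[names(start)[which(start <= 0)[1]]])
  model_id <- as.integer(names(model_table)[vapply(model_table, identical, TRUE, y = genetic)])
  config <- list(
    model_id = model_id,
    components = genetic,
    start = start,
    tolerance_h2 = num("tolerance_h2", 1e-6),
    tolerance_var = num("tolerance_var", 1e-8),
    max_iterations = as.integer(num("max_iterations", 1000)),
    ai_start_iteration = num("ai_start_iteration", 3),
    files = list(snp = chr("snp_file"), hap = chr("hap_file"),
                 map = chr("map_file"), pheno = chr("pheno_file"),
                 blocks = chr("block_file")),
    n_snps = if (is.null(kv$n_snps)) NA_integer_ else as.integer(num("n_snps")),
    n_blocks = if (is.null(kv$n_blocks)) NA_integer_ else as.integer(num("n_blocks")),
    trait_col = chr("trait_col", "trait"),
    class_cols = csv("class_cols"),
    covariate_cols = csv("covariate_cols"),
    snp_fixed_cols = csv("snp_fixed_cols"),
    missing_token = chr("missing_token", "NA"),
    output_prefix = chr("output_prefix", "haploblup"),
    seed = if (is.null(kv$seed)) NULL else as.integer(num("seed")),
    blocking = list(by_snp = if (is.null(kv$block_by_snp)) NULL else as.integer(num("block_by_snp")),
                    by_kb = num("block_by_kb"))
  )
  class(config) <- "run_config"
  config
}

#' Fill SNP and block counts into a run configuration
#'
#' @param config a `run_config`.
#' @param map a `snp_map`.
#' @param blocks a block definition table ([block_by_snp()] etc.).
#' @return The configuration with `n_snps` and `n_blocks` set; idempotent.
#' @export
fill_counts <- function(config, map, blocks) {
  config$n_snps <- nrow(map)
  config$n_blocks <- if (is.null(blocks)) 0L else nrow(blocks)
  config
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: model %d (components: %s)\n", x$model_id,
              paste(x$components, collapse = ", ")))
  cat(sprintf("  starting variances: %s\n",
              paste(sprintf("%s=%g", names(x$start), x$start), collapse = ", ")))
  cat(sprintf("  tolerances: h2 %g, var %g; max %d iterations, AI from iteration %g\n",
              x$tolerance_h2, x$tolerance_var, x$max_iterations, x$ai_start_iteration))
  invisible(x)
}

# ---- output tables --------------------------------------------------------

report_columns <- function(components) {
  cols <- c("id", "flag")
  for (comp in c("a", "d", "ah"))
    if (comp %in% components) cols <- c(cols, paste0(comp, "_hat"), paste0("rel_", comp))
  if (length(components) >= 2) cols <- c(cols, "g_hat", "rel_g")
  c(cols, "y_hat")
}

#' Write a GBLUP report file
#'
#' Tab-separated, one row per individual: id, T/V flag, the BLUP and
#' reliability of each included genetic component, the total genetic value
#' and its reliability when the model has two or more components, and the
#' genomic + non-genetic phenotype prediction. Values carry 12 significant
#' digits so a read-back reproduces them.
#'
#' @param report a `gblup_report` ([gblup_report()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gblup_report <- function(report, path) {
  cols <- report_columns(attr(report, "components"))
  stopifnot(all(cols %in% names(report)))
  df <- as.data.frame(report)[, cols]
  fmt <- vapply(df, is.numeric, TRUE)
  for (j in which(fmt)) df[[j]] <- sprintf("%.12g", df[[j]])
  writeLines(c(paste(cols, collapse = "\t"),
               apply(df, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read back a GBLUP report file
#'
#' @param path a file written by [write_gblup_report()].
#' @return A `gblup_report` data frame.
#' @export
read_gblup_report <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  for (j in setdiff(names(df), c("id", "flag"))) df[[j]] <- as.numeric(df[[j]])
  comps <- c("a", "d", "ah")[c("a_hat", "d_hat", "ah_hat") %in% names(df)]
  structure(df, components = comps, class = c("gblup_report", "data.frame"))
}

#' Merge SNP and haplotype-block heritability tables for plotting
#'
#' Produces one position-sorted table suitable for Manhattan plots: each
#' SNP row carries the per-SNP additive (and, if fitted, dominance)
#' heritability; each block contributes one extra row at its midpoint
#' position carrying the block heritability, with the SNP columns empty.
#'
#' @param snp_table data frame with `snp_id`, `h2_snp_a` and optionally
#'   `h2_snp_d` (from [marker_effects()]).
#' @param block_table data frame with `block_id`, `chrom`, `start_bp`,
#'   `end_bp`, `h2_block`, or `NULL` for SNP-only models.
#' @param map the `snp_map`.
#' @param path optional output path (tab-separated, empty cells for `NA`).
#' @return The merged data frame, sorted by chromosome (map order) and
#'   position.
#' @export
merge_visualization_table <- function(snp_table, block_table, map, path = NULL) {
  if (!all(snp_table$snp_id %in% map$snp_id))
    stopf("snp_table contains ids absent from the map")
  idx <- match(snp_table$snp_id, map$snp_id)
  has_d <- "h2_snp_d" %in% names(snp_table)
  has_blocks <- !is.null(block_table) && nrow(block_table) > 0
  out <- data.frame(chrom = map$chrom[idx], pos_bp = map$pos_bp[idx],
                    id = snp_table$snp_id,
                    h2_snp_a = snp_table$h2_snp_a, stringsAsFactors = FALSE)
  if (has_d) out$h2_snp_d <- snp_table$h2_snp_d
  if (has_blocks) {
    out$h2_block <- NA_real_
    brow <- data.frame(chrom = block_table$chrom,
                       pos_bp = as.integer(floor((block_table$start_bp + block_table$end_bp) / 2)),
                       id = block_table$block_id,
                       h2_snp_a = NA_real_, stringsAsFactors = FALSE)
    if (has_d) brow$h2_snp_d <- NA_real_
    brow$h2_block <- block_table$h2_block
    out <- rbind(out, brow)
  }
  chrom_order <- match(out$chrom, unique(map$chrom))
  if (anyNA(chrom_order)) stopf("block_table chromosome absent from the map")
  out <- out[order(chrom_order, out$pos_bp), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    df <- out
    for (j in names(df)) if (is.numeric(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "", sprintf("%.12g", df[[j]]))
    }
    writeLines(c(paste(names(df), collapse = "\t"),
                 apply(df, 1, paste, collapse = "\t")), path)
  }
  out
}

#' Jointly validate the five pipeline input files
#'
#' Reads the map, SNP genotypes, phased haplotypes and phenotypes named in
#' a parameter file, cross-checks dimensions, individual lists and phase
#' consistency, and returns the parsed objects.
#'
#' @param config a `run_config` whose `files` entries are set.
#' @return Invisibly, a list with `config`, `map`, `snp`, `phased`,
#'   `pheno`.
#' @export
check_inputs <- function(config) {
  map <- read_snp_map(config$files$map)
  snp <- read_snp_genotypes(config$files$snp, map)
  phased <- read_phased_haplotypes(config$files$hap, map, snp = snp)
  pheno <- read_phenotypes(config$files$pheno, config)
  if (!all(pheno$id %in% rownames(snp)))
    stopf("phenotype file names individual '%s' absent from the genotype file",
          setdiff(pheno$id, rownames(snp))[1])
  invisible(list(config = config, map = map, snp = snp, phased = phased,
                 pheno = pheno))
}
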