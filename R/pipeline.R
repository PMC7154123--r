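# End-to-end driver: parameter file -> validated inputs -> blocks and
# codings -> relationship matrices (fresh or cached) -> GREML -> GBLUP
# reports and per-marker heritability tables.

#' Resolve haplotype blocks for a run configuration
#'
#' Uses, in order of precedence, `block_by_snp`, `block_by_kb`, or the
#' interval file named by `block_file`.
#'
#' @param config a `run_config`.
#' @param map the `snp_map`.
#' @return A `block_def` table, or `NULL` for SNP-only models.
#' @export
resolve_blocks <- function(config, map) {
  if (!"ah" %in% config$components) return(NULL)
  if (!is.null(config$blocking$by_snp)) return(block_by_snp(map, config$blocking$by_snp))
  if (!is.null(config$blocking$by_kb)) return(block_by_kb(map, config$blocking$by_kb))
  if (!is.null(config$files$blocks))
    return(block_by_pos(map, read_block_intervals(config$files$blocks)))
  stopf("haplotype model selected but no blocking specified (block_by_snp, block_by_kb or block_file)")
}

#' Build the genomic relationship matrices for a run
#'
#' @param config a `run_config`.
#' @param snp SNP genotype matrix.
#' @param encoded `block_genotypes` (or `NULL` for SNP-only models).
#' @param map the `snp_map`.
#' @param cache_dir optional directory: matrices found there (per-tag
#'   `<tag>.hgrm` files with matching sample digest) are loaded instead
#'   of rebuilt, and fresh builds are saved there.
#' @return Named list of `hb_grm` objects, plus the `model_matrices` as
#'   attribute `matrices`.
#' @export
build_run_grms <- function(config, snp, encoded, map, cache_dir = NULL) {
  mm <- build_model_matrices(config, snp = snp, encoded = encoded, map = map)
  grms <- list()
  for (tag in config$components) {
    path <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(tag, ".hgrm"))
    if (!is.null(path) && file.exists(path)) {
      grms[[tag]] <- load_grm_cache(path, sample_ids = mm$sample_ids)
    } else {
      grms[[tag]] <- build_grm(mm$W[[tag]], tag)
      if (!is.null(path)) {
        dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
        save_grm_cache(grms[[tag]], path)
      }
    }
  }
  attr(grms, "matrices") <- mm
  grms
}

#' Run the full analysis described by a parameter file
#'
#' Reads and validates the five input files, defines and encodes the
#' haplotype blocks, builds the genomic relationship matrices, fits the
#' variance components, and assembles the GBLUP report with per-marker
#' heritability tables. When `write_outputs` is `TRUE`, writes
#' `<prefix>.gblup`, `<prefix>.fixed`, `<prefix>.varcomp`,
#' `<prefix>.iter`, and (with marker tables available) `<prefix>.snpe`.
#'
#' @param config a `run_config` or path to a parameter file.
#' @param cache_dir optional GRM cache directory (see [build_run_grms()]).
#' @param write_outputs write the output files (default TRUE).
#' @return A list: `config`, `fit`, `report`, `markers`, `data`, `grms`,
#'   `blocks`, `map`.
#' @export
run_pipeline <- function(config, cache_dir = NULL, write_outputs = TRUE) {
  if (is.character(config)) config <- parse_parameter_file(config)
  inputs <- check_inputs(config)
  map <- inputs$map
  blocks <- resolve_blocks(config, map)
  encoded <- if (!is.null(blocks)) encode_block_genotypes(inputs$phased, blocks)
  config <- fill_counts(config, map, blocks)
  grms <- build_run_grms(config, inputs$snp, encoded, map, cache_dir = cache_dir)
  mm <- attr(grms, "matrices")
  data <- mixed_model_data(inputs$pheno, grms)
  control <- greml_control(config$tolerance_h2, config$tolerance_var,
                           config$max_iterations, config$ai_start_iteration)
  fit <- fit_greml(data, config$start, control)
  report <- gblup_report(fit, data)
  markers <- marker_effects(fit, data, mm, blocks = blocks)
  if (write_outputs) {
    prefix <- config$output_prefix
    write_gblup_report(report, paste0(prefix, ".gblup"))
    write_fixed_effects(attr(report, "b_hat"), paste0(prefix, ".fixed"))
    write_iteration_log(fit, paste0(prefix, ".iter"))
    vc <- data.frame(component = names(fit$sigma), sigma2 = fit$sigma,
                     h2 = c(fit$h2, NA)[match(names(fit$sigma), c(names(fit$h2), "e"))],
                     h2_sd = c(fit$h2_sd, NA)[match(names(fit$sigma), c(names(fit$h2_sd), "e"))])
    utils::write.table(vc, paste0(prefix, ".varcomp"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(markers$snp))
      merge_visualization_table(markers$snp, markers$block, map,
                                path = paste0(prefix, ".snpe"))
  }
  list(config = config, fit = fit, report = report, markers = markers,
       data = data, grms = grms, blocks = blocks, map = map)
}
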