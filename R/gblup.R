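# GBLUP at converged variance components: best linear unbiased estimates
# of fixed effects, per-component BLUPs with reliabilities for training
# and validation individuals, back-solved per-SNP effects with per-marker
# heritability partitioning, and genomic + non-genetic (GNG) phenotype
# prediction y_hat = X b_hat + g_hat.

#' BLUE of the fixed effects at converged variances
#'
#' `b_hat = (X' V^-1 X)^- X' V^-1 y`. Rank-deficient class codings were
#' reduced at data assembly by dropping redundant treatment-contrast
#' columns (first level of each factor is the reference), so the solution
#' is the documented identifiable parameterization.
#'
#' @param fit a `greml_fit`.
#' @param data the `mixed_model_data` it was fitted on.
#' @return Named numeric vector of fixed-effect estimates.
#' @export
solve_fixed_effects <- function(fit, data) {
  Pobj <- compute_P(fit$sigma, data)
  b <- drop(Pobj$Cinv %*% crossprod(data$X, Pobj$Vinv %*% data$y))
  stats::setNames(b, colnames(data$X))
}

#' GBLUP of each genetic component
#'
#' `u_hat_i = sigma2_i K_i Z' P y`, an n-vector covering training and
#' validation individuals: a validation individual is predicted entirely
#' through its relationship covariances with the training set (zero
#' relationships give a zero BLUP). The total genetic value is the
#' entrywise sum of the included components.
#'
#' @inheritParams solve_fixed_effects
#' @return A list: `u` (named list of n-vectors per component), `g_hat`
#'   (their sum), and `Py_ind` (`Z'Py`, reused by callers).
#' @export
component_gblup <- function(fit, data) {
  Pobj <- compute_P(fit$sigma, data)
  ZtPy <- numeric(data$n)
  agg <- rowsum(Pobj$Py, group = data$obs_ind)
  ZtPy[as.integer(rownames(agg))] <- agg[, 1]
  u <- lapply(names(data$K), function(i)
    stats::setNames(fit$sigma[[i]] * drop(data$K[[i]] %*% ZtPy), data$ids))
  names(u) <- names(data$K)
  list(u = u, g_hat = Reduce(`+`, u), Py_ind = ZtPy, Pobj = Pobj)
}

#' Reliability of component or total GBLUP
#'
#' For the component subset S, the per-individual reliability is the i-th
#' diagonal of `G_S Z'PZ G_S` over `sum_{j in S} K_j,ii sigma2_j`, with
#' `G_S = sum_{j in S} sigma2_j K_j`. With all included components this
#' reproduces the full cross-term expansion of the total-genetic-value
#' reliability (nine terms for a three-component model); a singleton S
#' gives the component reliability. Individuals with zero prior variance
#' (denominator 0) are reported with reliability 0 and a warning.
#'
#' @inheritParams solve_fixed_effects
#' @param components character subset of `names(data$K)`; default all.
#' @param Pobj optional precomputed [compute_P()] result.
#' @return Named n-vector of reliabilities in \[0, 1\].
#' @export
reliability <- function(fit, data, components = names(data$K), Pobj = NULL) {
  stopifnot(all(components %in% names(data$K)))
  if (is.null(Pobj)) Pobj <- compute_P(fit$sigma, data)
  ZPZ <- matrix(0, data$n, data$n)
  agg <- rowsum(Pobj$P, group = data$obs_ind)            # collapse rows
  agg <- rowsum(t(agg), group = data$obs_ind)            # collapse cols
  idx <- as.integer(rownames(agg))
  ZPZ[idx, idx] <- agg                                   # symmetric: P is
  G <- Reduce(`+`, lapply(components, function(j) fit$sigma[[j]] * data$K[[j]]))
  num <- rowSums((G %*% ZPZ) * G)   # diag(G ZPZ G), G symmetric
  den <- Reduce(`+`, lapply(components, function(j) fit$sigma[[j]] * diag(data$K[[j]])))
  rel <- numeric(data$n)
  zero <- den <= 0
  if (any(zero))
    warnf("%d individual(s) have zero prior variance; reliability reported as 0",
          sum(zero))
  rel[!zero] <- num[!zero] / den[!zero]
  rel <- pmin(pmax(rel, 0), 1)
  stats::setNames(rel, data$ids)
}

#' Back-solved marker effects and per-marker heritabilities
#'
#' SNP additive effects `alpha_hat_o = (sigma2_a / k_a) W_a' Z'Py` (the
#' original-scale effects whose coding reproduces the genomic values:
#' `W_a alpha_hat_o = a_hat`), SNP dominance effects analogously, and
#' per-marker heritabilities `(sigma2_o) * mean_i w_ij^2 / sigma2_P`,
#' defined so the per-SNP (or per-block) values are nonnegative and sum
#' exactly to the component heritability.
#'
#' @inheritParams solve_fixed_effects
#' @param matrices a `model_matrices` ([build_model_matrices()]) over the
#'   same individuals.
#' @param blocks optional `block_def` table for block annotation of the
#'   haplotype heritabilities.
#' @return A list: `snp` (data frame `snp_id`, `alpha_hat`, `h2_snp_a`
#'   and, if fitted, `delta_hat`, `h2_snp_d`), `block` (data frame
#'   `block_id`, `h2_block`, plus `chrom`/`start_bp`/`end_bp` when
#'   `blocks` is given), either `NULL` when the model lacks them.
#' @export
marker_effects <- function(fit, data, matrices, blocks = NULL) {
  gb <- component_gblup(fit, data)
  ZtPy <- gb$Py_ind
  sigma_P <- sum(fit$sigma)
  out <- list(snp = NULL, block = NULL)
  if ("a" %in% names(data$K)) {
    Wa <- matrices$W$a
    alpha_o <- drop(crossprod(Wa, ZtPy)) * fit$sigma[["a"]] / data$k[["a"]]
    h2a <- (fit$sigma[["a"]] / data$k[["a"]]) * colMeans(Wa^2) / sigma_P
    out$snp <- data.frame(snp_id = colnames(Wa), alpha_hat = alpha_o,
                          h2_snp_a = h2a, stringsAsFactors = FALSE, row.names = NULL)
  }
  if ("d" %in% names(data$K)) {
    Wd <- matrices$W$d
    delta_o <- drop(crossprod(Wd, ZtPy)) * fit$sigma[["d"]] / data$k[["d"]]
    h2d <- (fit$sigma[["d"]] / data$k[["d"]]) * colMeans(Wd^2) / sigma_P
    if (is.null(out$snp))
      out$snp <- data.frame(snp_id = colnames(Wd), stringsAsFactors = FALSE)
    out$snp$delta_hat <- delta_o
    out$snp$h2_snp_d <- h2d
  }
  if ("ah" %in% names(data$K)) {
    Wh <- matrices$W$ah
    spans <- matrices$block_spans
    colh2 <- (fit$sigma[["ah"]] / data$k[["ah"]]) * colMeans(Wh^2) / sigma_P
    h2b <- vapply(seq_len(nrow(spans)), function(b) {
      if (spans[b, 2] <= spans[b, 1]) return(0)
      sum(colh2[seq(spans[b, 1], spans[b, 2] - 1L)])
    }, 1.0)
    out$block <- data.frame(block_id = rownames(spans), h2_block = h2b,
                            stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(blocks)) {
      m <- match(out$block$block_id, blocks$block_id)
      out$block$chrom <- blocks$chrom[m]
      out$block$start_bp <- blocks$start_bp[m]
      out$block$end_bp <- blocks$end_bp[m]
    }
  }
  out
}

#' Genomic + non-genetic prediction of phenotypes
#'
#' `y_hat_i = x_i' b_hat + g_hat_i` for every individual, including
#' validation individuals; requires at most one phenotypic observation
#' per individual so that the individual-level fixed-effect row is
#' unambiguous.
#'
#' @inheritParams solve_fixed_effects
#' @param b_hat fixed-effect estimates from [solve_fixed_effects()].
#' @param g_hat total genetic values from [component_gblup()].
#' @return Named n-vector of predicted phenotypes.
#' @export
gng_predict <- function(fit, data, b_hat, g_hat) {
  if (any(data$n_obs > 1))
    stopf("GNG requires one observation per individual")
  if (anyNA(data$X_ind))
    stopf("GNG requires fixed-effect covariates for all individuals, including validation")
  stats::setNames(drop(data$X_ind %*% b_hat) + g_hat, data$ids)
}

#' Assemble the per-individual GBLUP report
#'
#' One row per individual: T/V flag, each included component's BLUP and
#' reliability, the total genetic value and its reliability when two or
#' more components are fitted, and the GNG phenotype prediction.
#'
#' @inheritParams solve_fixed_effects
#' @return A data frame of class `gblup_report` (see
#'   [write_gblup_report()] for the file layout).
#' @export
gblup_report <- function(fit, data) {
  gb <- component_gblup(fit, data)
  comps <- names(data$K)
  rep_df <- data.frame(id = data$ids, flag = data$flag, stringsAsFactors = FALSE)
  for (i in comps) {
    rep_df[[paste0(i, "_hat")]] <- gb$u[[i]]
    rep_df[[paste0("rel_", i)]] <- reliability(fit, data, i, Pobj = gb$Pobj)
  }
  if (length(comps) >= 2) {
    rep_df$g_hat <- gb$g_hat
    rep_df$rel_g <- reliability(fit, data, comps, Pobj = gb$Pobj)
  }
  b_hat <- solve_fixed_effects(fit, data)
  rep_df$y_hat <- gng_predict(fit, data, b_hat, gb$g_hat)
  rownames(rep_df) <- NULL
  structure(rep_df, components = comps, b_hat = b_hat,
            class = c("gblup_report", "data.frame"))
}

#' Write the fixed-effects file
#'
#' @param b_hat named fixed-effect estimates.
#' @param path output path; columns `term`, `estimate`.
#' @return `path`, invisibly.
#' @export
write_fixed_effects <- function(b_hat, path) {
  utils::write.table(data.frame(term = names(b_hat),
                                estimate = sprintf("%.12g", b_hat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
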