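# k-fold validation machinery and observed / expected prediction
# accuracies. Observed accuracy is the Pearson correlation between
# predicted genetic values and the held-out phenotypes of a validation
# fold; expected genetic accuracy is the mean square root of reliability
# over the fold's validation individuals; expected phenotypic accuracy
# multiplies that by the square root of heritability. The relationship
# matrices do not depend on which phenotypes are masked, so they are
# built once and reloaded from the binary cache for folds 2..k.

#' Randomly assign individuals to validation folds
#'
#' Seeded uniform partition with fold sizes differing by at most one;
#' deterministic given `(ids, k, seed)`.
#'
#' @param ids character vector of training-eligible individuals.
#' @param k number of folds, `2 <= k <= length(ids)`.
#' @param seed integer seed.
#' @return A list of class `fold_assignment`: `ids`, `fold` (named
#'   integer vector 1..k), `k`, `seed`.
#' @export
make_folds <- function(ids, k, seed) {
  n <- length(ids)
  if (k < 2 || k > n) stopf("k must satisfy 2 <= k <= %d", n)
  fold <- integer(n)
  with_seed(seed, {
    perm <- sample.int(n)
    fold[perm] <- rep_len(seq_len(k), n)
  })
  structure(list(ids = ids, fold = stats::setNames(fold, ids),
                 k = as.integer(k), seed = seed),
            class = "fold_assignment")
}

#' Run a k-fold validation study
#'
#' For each fold, the fold members' phenotypes are set missing (flagging
#' them "V"), the model is refitted and the GBLUP report computed. The
#' genomic relationship matrices are constructed exactly once — by
#' calling `grm_builder` during the first fold — cached as binary files
#' under `cache_dir`, and reloaded for the remaining folds.
#'
#' @param pheno a `pheno_table` covering all individuals (one observation
#'   each).
#' @param grm_builder zero-argument function returning the named list of
#'   `hb_grm` objects; called once.
#' @param folds a [make_folds()] assignment over the training-eligible
#'   individuals.
#' @param start named starting-variance vector (see [fit_greml()]).
#' @param control a [greml_control()].
#' @param cache_dir directory for the binary GRM cache (created if
#'   needed); defaults to a session temporary directory.
#' @return A list of class `validation_run` with one entry per fold:
#'   `fit` (`greml_fit`), `report` (`gblup_report`), `held_out` (ids and
#'   phenotypes masked in that fold).
#' @export
run_validation <- function(pheno, grm_builder, folds, start,
                           control = greml_control(),
                           cache_dir = file.path(tempdir(), "hb_grm_cache")) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  grms <- NULL
  cache_paths <- NULL
  runs <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    if (f == 1L) {
      grms <- grm_builder()
      cache_paths <- vapply(names(grms), function(tag) {
        p <- file.path(cache_dir, paste0(tag, ".hgrm"))
        save_grm_cache(grms[[tag]], p)
        p
      }, "")
    } else {
      ids <- rownames(grms[[1]]$matrix)  # kept only for the digest check
      grms <- lapply(cache_paths, load_grm_cache, sample_ids = ids)
      names(grms) <- names(cache_paths)
    }
    masked <- pheno
    hold <- names(folds$fold)[folds$fold == f]
    sel <- masked$id %in% hold
    held_out <- data.frame(id = masked$id[sel], y = masked$trait[sel],
                           stringsAsFactors = FALSE)
    masked$trait[sel] <- NA_real_
    masked$flag[sel] <- "V"
    data <- mixed_model_data(masked, grms)
    fit <- fit_greml(data, start, control)
    runs[[f]] <- list(fit = fit, report = gblup_report(fit, data),
                      held_out = held_out)
  }
  structure(list(folds = folds, runs = runs), class = "validation_run")
}

#' Observed prediction accuracy in a validation fold
#'
#' Pearson correlation between predicted genetic values and the held-out
#' phenotypes. Undefined (zero variance in either vector, or fewer than
#' 3 pairs) accuracies are reported as `NA` with a warning.
#'
#' @param g_hat0 predicted genetic values of the validation individuals
#'   (any single component or stated sum of components).
#' @param y0 their held-out phenotypic values.
#' @return Scalar correlation, or `NA`.
#' @export
observed_accuracy <- function(g_hat0, y0) {
  ok <- !is.na(g_hat0) & !is.na(y0)
  if (sum(ok) < 3) {
    warnf("fewer than 3 validation individuals with observed phenotypes; accuracy undefined")
    return(NA_real_)
  }
  if (stats::sd(g_hat0[ok]) == 0 || stats::sd(y0[ok]) == 0) {
    warnf("zero variance in predictions or phenotypes; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(g_hat0[ok], y0[ok])
}

#' Expected genetic prediction accuracies from reliabilities
#'
#' Per fold, the mean over its validation individuals of the square root
#' of reliability; overall, the mean over folds.
#'
#' @param rel_by_fold list (one entry per fold) of reliability vectors
#'   for that fold's validation individuals.
#' @return A list: `per_fold` (numeric vector) and `overall` (scalar).
#' @export
expected_accuracies <- function(rel_by_fold) {
  per_fold <- vapply(rel_by_fold, function(r) mean(sqrt(pmax(r, 0))), 1.0)
  list(per_fold = per_fold, overall = mean(per_fold))
}

#' Expected phenotypic prediction accuracy
#'
#' The expected genetic accuracy times the square root of heritability.
#'
#' @param R0g expected genetic accuracy (e.g. `expected_accuracies()$overall`).
#' @param h2 heritability of the predicted component sum, in \[0, 1\].
#' @return Scalar expected phenotypic accuracy.
#' @export
expected_phenotype_accuracy <- function(R0g, h2) {
  if (h2 < 0 || h2 > 1) stopf("h2 must be in [0, 1]")
  R0g * sqrt(h2)
}

#' Summarize a validation run into an accuracy report
#'
#' Computes, per fold, the observed accuracy of the total genetic value,
#' the expected genetic accuracy (mean root reliability of the fold's
#' validation individuals), and the expected phenotypic accuracy using
#' the training-fold heritability of the predicted component sum,
#' averaged over folds.
#'
#' @param vr a `validation_run`.
#' @param components which components' BLUP sum to evaluate; default all.
#' @param path optional output path for the tab-separated report (per
#'   fold plus a means row).
#' @return A data frame: `fold`, `n_validation`, `observed_r`,
#'   `expected_r_genetic`, `expected_r_phenotypic`, with attribute `means`.
#' @export
accuracy_report <- function(vr, components = NULL, path = NULL) {
  k <- vr$folds$k
  rel_col <- function(report, comps) {
    if (length(comps) == length(attr(report, "components")) && length(comps) >= 2)
      report$rel_g
    else if (length(comps) == 1) report[[paste0("rel_", comps)]]
    else report$rel_g
  }
  rows <- lapply(seq_len(k), function(f) {
    run <- vr$runs[[f]]
    comps <- components %||% attr(run$report, "components")
    rep_df <- run$report
    m <- match(run$held_out$id, rep_df$id)
    ghat_cols <- paste0(comps, "_hat")
    ghat <- rowSums(as.data.frame(rep_df)[m, ghat_cols, drop = FALSE])
    rel <- rel_col(rep_df, comps)[m]
    h2_fold <- sum(run$fit$h2[comps])
    data.frame(fold = f, n_validation = nrow(run$held_out),
               observed_r = observed_accuracy(ghat, run$held_out$y),
               expected_r_genetic = mean(sqrt(pmax(rel, 0))),
               h2_train = h2_fold)
  })
  out <- do.call(rbind, rows)
  R0g <- mean(out$expected_r_genetic)
  h2_bar <- mean(out$h2_train)
  out$expected_r_phenotypic <- out$expected_r_genetic * sqrt(out$h2_train)
  means <- data.frame(observed_r = mean(out$observed_r, na.rm = TRUE),
                      expected_r_genetic = R0g,
                      expected_r_phenotypic = expected_phenotype_accuracy(R0g, h2_bar))
  attr(out, "means") <- means
  if (!is.null(path)) {
    df <- out[, c("fold", "n_validation", "observed_r", "expected_r_genetic",
                  "expected_r_phenotypic")]
    mrow <- data.frame(fold = "mean", n_validation = sum(out$n_validation),
                       observed_r = means$observed_r,
                       expected_r_genetic = means$expected_r_genetic,
                       expected_r_phenotypic = means$expected_r_phenotypic)
    df$fold <- as.character(df$fold)
    utils::write.table(rbind(df, mrow), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
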