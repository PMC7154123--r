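# GREML: restricted maximum likelihood estimation of the variance
# components attached to the genomic relationship matrices, by a hybrid
# of EM-REML (slow, monotone, always available) and AI-REML (fast, can
# fail). The run starts with a minimum of two EM iterations, switches to
# AI at a configurable iteration (default 3), and falls back to EM for
# any iteration where AI fails: non-positive-definite average-information
# matrix, a non-positive proposed variance, or a likelihood decrease.
# Iteration stops when either of two tolerances is reached: the maximum
# relative variance-component change (default 1e-8) or the maximum
# absolute heritability change (default 1e-6).

#' Assemble mixed-model data for GREML and GBLUP
#'
#' Builds the observation-level quantities of the mixed model y = Xb +
#' Z u_a + Z u_d + Z u_ah + e from a phenotype table and the genomic
#' relationship matrices. Observations with a missing trait (validation
#' individuals) are excluded from y and X but their individuals remain in
#' the relationship matrices and receive predictions through relationship
#' covariances. The fixed-effect design is the intercept plus treatment
#' contrasts for each class factor, the covariates, and any SNP-as-fixed
#' columns; columns are dropped to full rank on the training rows.
#'
#' @param pheno a `pheno_table` ([read_phenotypes()] or built in code).
#' @param grms named list of `hb_grm` objects, names drawn from
#'   `c("a", "d", "ah")`; all must share the same individuals in the same
#'   order, and every phenotype id must be among them.
#' @param intercept include an intercept column (default TRUE).
#' @return A list of class `mixed_model_data`: `y` (N training
#'   observations), `X` (N x c), `obs_ind` (individual index per training
#'   observation, i.e. the incidence Z in index form), `K` and `Kobs`
#'   (relationship matrices at individual and observation level), `k`
#'   (trace constants), `ids`, `flag` (per-individual T/V), `X_ind`
#'   (individual-level design rows for phenotype prediction), `n_obs`
#'   (observations per individual).
#' @export
mixed_model_data <- function(pheno, grms, intercept = TRUE) {
  stopifnot(length(grms) > 0)
  tags <- names(grms)
  if (is.null(tags) || !all(tags %in% c("a", "d", "ah")))
    stopf("grms must be a named list with names among 'a', 'd', 'ah'")
  ids <- rownames(grms[[1]]$matrix)
  dig <- grms[[1]]$sample_digest
  for (g in grms) if (g$sample_digest != dig)
    stopf("relationship matrices were built over different individual sets or orders")
  if (!all(pheno$id %in% ids))
    stopf("phenotype individual '%s' absent from the relationship matrices",
          setdiff(pheno$id, ids)[1])
  n <- length(ids)
  obs_ind_all <- match(pheno$id, ids)
  train <- !is.na(pheno$trait)
  if (!any(train)) stopf("no training individuals: every trait value is missing")
  flag <- ifelse(ids %in% pheno$id[train], "T", "V")

  fixed_cols <- c(attr(pheno, "class_cols"), attr(pheno, "covariate_cols"),
                  attr(pheno, "snp_fixed_cols"))
  if (length(fixed_cols) > 0) {
    X_full <- stats::model.matrix(~ ., data = as.data.frame(pheno)[, fixed_cols, drop = FALSE])
    if (!intercept) X_full <- X_full[, -1, drop = FALSE]
  } else if (intercept) {
    X_full <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X_full <- matrix(0, nrow(pheno), 0)
  }
  X <- X_full[train, , drop = FALSE]
  if (ncol(X) > 0) {
    qrx <- qr(X)
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X_full)[setdiff(seq_len(ncol(X_full)), keep)]
    X <- X[, sort(keep), drop = FALSE]
    X_full <- X_full[, sort(keep), drop = FALSE]
  } else dropped <- character(0)
  y <- pheno$trait[train]
  N <- length(y)
  obs_ind <- obs_ind_all[train]
  Kobs <- lapply(grms, function(g) g$matrix[obs_ind, obs_ind, drop = FALSE])
  first_row <- match(ids, pheno$id)  # NA only if an individual lacks any pheno row
  X_ind <- X_full[first_row, , drop = FALSE]
  structure(list(
    y = y, X = X, obs_ind = obs_ind, N = N, n = n, c = ncol(X),
    K = lapply(grms, function(g) g$matrix), Kobs = Kobs,
    k = vapply(grms, function(g) g$k, 1.0),
    ids = ids, flag = flag, X_ind = X_ind,
    n_obs = tabulate(obs_ind_all, nbins = n),
    dropped_columns = dropped, train = train),
    class = "mixed_model_data")
}

#' Control parameters for [fit_greml()]
#'
#' @param tolerance_h2 absolute tolerance on the largest heritability
#'   change between iterations (default 1e-6).
#' @param tolerance_var relative tolerance on the largest variance
#'   component change, scaled by total phenotypic variance (default 1e-8).
#' @param max_iterations iteration cap (default 1000).
#' @param ai_start_iteration first iteration allowed to use AI-REML
#'   (default 3; at least two EM iterations always run first; `Inf` gives
#'   an EM-only schedule).
#' @return A list of class `greml_control`.
#' @export
greml_control <- function(tolerance_h2 = 1e-6, tolerance_var = 1e-8,
                          max_iterations = 1000L, ai_start_iteration = 3) {
  structure(list(tolerance_h2 = tolerance_h2, tolerance_var = tolerance_var,
                 max_iterations = as.integer(max_iterations),
                 ai_start_iteration = ai_start_iteration),
            class = "greml_control")
}

#' Projection matrix and restricted log-likelihood at given variances
#'
#' `V = sum_i sigma2_i Z K_i Z' + sigma2_e I`, `P = V^-1 - V^-1 X
#' (X' V^-1 X)^- X' V^-1`, and the restricted log-likelihood
#' `-(log|V| + log|X'V^-1X| - log|X'X| + y'Py)/2` (additive constant
#' omitted; the `log|X'X|` term makes the value invariant to the
#' fixed-effect parameterization).
#'
#' @param sigma named numeric vector of variance components: one entry
#'   per relationship matrix in `data` plus `"e"`; all > 0.
#' @param data a `mixed_model_data`.
#' @return A list: `P` (N x N), `Py`, `logL`, `Vinv`, and the pieces
#'   needed by the fixed-effect solver (`B = V^-1 X`, `Cinv`).
#' @export
compute_P <- function(sigma, data) {
  comps <- names(data$Kobs)
  stopifnot(all(c(comps, "e") %in% names(sigma)), all(sigma > 0))
  V <- diag(sigma[["e"]], data$N)
  for (i in comps) V <- V + sigma[[i]] * data$Kobs[[i]]
  R <- tryCatch(chol(V), error = function(e)
    stopf("V numerically singular at sigma = (%s): %s",
          paste(sprintf("%s=%g", names(sigma), sigma), collapse = ", "),
          conditionMessage(e)))
  Vinv <- chol2inv(R)
  B <- Vinv %*% data$X
  C <- crossprod(data$X, B)
  if (ncol(C) > 0) {
    Cinv <- tryCatch(solve(C), error = function(e) pinv(C))
    P <- Vinv - B %*% Cinv %*% t(B)
    P <- (P + t(P)) / 2
  } else {
    Cinv <- C
    P <- Vinv
  }
  Py <- drop(P %*% data$y)
  logdetV <- 2 * sum(log(diag(R)))
  logdetC <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  # + log|X'X| makes the value invariant to reparameterizing X (X -> XA)
  logdetXX <- if (ncol(data$X) > 0)
    as.numeric(determinant(crossprod(data$X), logarithm = TRUE)$modulus) else 0
  logL <- -0.5 * (logdetV + logdetC - logdetXX + sum(data$y * Py))
  list(P = P, Py = Py, logL = logL, Vinv = Vinv, B = B, Cinv = Cinv)
}

# per-component tr(PV_i) and y'PV_iPy (V_e = I for the residual)
reml_moments <- function(data, Pobj) {
  comps <- names(data$Kobs)
  t_ <- Pobj$Py
  trPV <- numeric(0); yPVPy <- numeric(0); q <- list()
  for (i in comps) {
    qi <- drop(data$Kobs[[i]] %*% t_)
    trPV[i] <- sum(Pobj$P * data$Kobs[[i]])  # tr(AB) for symmetric A, B
    yPVPy[i] <- sum(t_ * qi)
    q[[i]] <- qi
  }
  trPV["e"] <- sum(diag(Pobj$P))
  yPVPy["e"] <- sum(t_^2)
  q[["e"]] <- t_
  list(trPV = trPV, yPVPy = yPVPy, q = q)
}

variance_floor <- function(sigma) 1e-10 * sum(sigma)

#' One EM-REML update of the variance components
#'
#' For each genetic component, `sigma2_i <- sigma2_i + sigma2_i^2 *
#' (y'P V_i P y - tr(P V_i)) / n`; for the residual the divisor is N.
#' Results are floored at `1e-10` of total phenotypic variance to keep V
#' invertible. EM is monotone in the restricted likelihood and serves as
#' the fallback when AI-REML fails.
#'
#' @inheritParams compute_P
#' @param Pobj result of [compute_P()] at `sigma` (recomputed if omitted).
#' @return Updated named variance vector.
#' @export
em_update <- function(sigma, data, Pobj = compute_P(sigma, data)) {
  mom <- reml_moments(data, Pobj)
  out <- sigma
  for (i in names(data$Kobs))
    out[[i]] <- sigma[[i]] + sigma[[i]]^2 * (mom$yPVPy[[i]] - mom$trPV[[i]]) / data$n
  out[["e"]] <- sigma[["e"]] + sigma[["e"]]^2 * (mom$yPVPy[["e"]] - mom$trPV[["e"]]) / data$N
  pmax(out, variance_floor(out))
}

#' One AI-REML proposal for the variance components
#'
#' Scores `-(tr(P V_i) - y'P V_i P y)/2` and average-information matrix
#' `AI_ij = y'P V_i P V_j P y / 2` over all components including the
#' residual; the proposal is a Newton-type step `sigma + AI^-1 score`.
#' Failure — a signaled outcome, not an error — occurs when the AI matrix
#' is not positive definite, any proposed variance is non-positive, or
#' the restricted likelihood decreases; the caller then substitutes an EM
#' step for the iteration.
#'
#' @inheritParams em_update
#' @return A list: `ok` (logical), and on success `sigma` (updated
#'   vector) and `Pobj` (the projection at the new point, reusable by the
#'   caller); on failure `reason`.
#' @export
ai_update <- function(sigma, data, Pobj = compute_P(sigma, data)) {
  mom <- reml_moments(data, Pobj)
  comps <- c(names(data$Kobs), "e")
  score <- -0.5 * (mom$trPV[comps] - mom$yPVPy[comps])
  r <- lapply(mom$q, function(qi) drop(Pobj$P %*% qi))
  AI <- matrix(0, length(comps), length(comps), dimnames = list(comps, comps))
  for (i in seq_along(comps)) for (j in i:length(comps)) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(r[[comps[i]]] * mom$q[[comps[j]]])
  }
  ch <- tryCatch(chol(AI), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE, reason = "AI matrix not positive definite", AI = AI))
  prop <- sigma[comps] + drop(chol2inv(ch) %*% score)
  if (any(prop <= 0))
    return(list(ok = FALSE, reason = "non-positive proposed variance", AI = AI))
  newP <- compute_P(prop, data)
  if (newP$logL < Pobj$logL)
    return(list(ok = FALSE, reason = "likelihood decrease", AI = AI))
  list(ok = TRUE, sigma = prop, Pobj = newP, AI = AI)
}

ai_matrix <- function(sigma, data, Pobj = compute_P(sigma, data)) {
  mom <- reml_moments(data, Pobj)
  comps <- c(names(data$Kobs), "e")
  r <- lapply(mom$q, function(qi) drop(Pobj$P %*% qi))
  AI <- matrix(0, length(comps), length(comps), dimnames = list(comps, comps))
  for (i in seq_along(comps)) for (j in i:length(comps))
    AI[i, j] <- AI[j, i] <- 0.5 * sum(r[[comps[i]]] * mom$q[[comps[j]]])
  AI
}

#' Fit variance components by hybrid EM-REML/AI-REML
#'
#' Runs the hybrid schedule (two or more EM iterations, then AI with
#' automatic EM fallback) until the variance-component or heritability
#' tolerance is met or the iteration cap is reached. Heritabilities are
#' `h2_i = sigma2_i / sigma2_P` with `sigma2_P` the sum of all components;
#' their standard deviations come from the delta method with the inverse
#' average-information matrix at convergence as the asymptotic covariance
#' of the variance estimates.
#'
#' @param data a `mixed_model_data`.
#' @param start named numeric vector of starting variances (components of
#'   `data` plus `"e"`), all > 0; typically `config$start`.
#' @param control a [greml_control()].
#' @return A list of class `greml_fit`: `sigma`, `h2`, `h2_sd`,
#'   `sigma_cov`, `logL`, `converged`, `reason` (one of
#'   `"var-tolerance"`, `"h2-tolerance"`, `"max-iter"`), `iterations`,
#'   `trace` (per-iteration data frame with the method used), and
#'   `near_zero` (components pinned at the variance floor for 10
#'   consecutive iterations, candidates for removal from the model).
#' @export
fit_greml <- function(data, start, control = greml_control()) {
  comps <- names(data$Kobs)
  need <- c(comps, "e")
  if (!all(need %in% names(start)))
    stopf("start must name every component: %s", paste(need, collapse = ", "))
  sigma <- start[need]
  if (any(sigma <= 0)) stopf("starting variances must be > 0")
  if (data$N < data$c + length(comps) + 1)
    stopf("too few training observations (%d) for %d fixed-effect columns and %d variance components",
          data$N, data$c, length(comps) + 1)
  for (i in comps) if (sum(data$Kobs[[i]]^2) == 0)
    stopf("component '%s' has an all-zero relationship matrix", i)
  h2_of <- function(s) s[comps] / sum(s)
  Pobj <- compute_P(sigma, data)
  trace <- vector("list", control$max_iterations)
  reason <- "max-iter"; converged <- FALSE
  floor_run <- stats::setNames(integer(length(need)), need)
  near_zero <- character(0)
  it_done <- 0L
  for (it in seq_len(control$max_iterations)) {
    use_ai <- it >= max(3, control$ai_start_iteration)
    method <- "EM"
    if (use_ai) {
      step <- ai_update(sigma, data, Pobj)
      if (step$ok) {
        new_sigma <- step$sigma; new_P <- step$Pobj; method <- "AI"
      } else {
        new_sigma <- em_update(sigma, data, Pobj)
        new_P <- compute_P(new_sigma, data)
        method <- "AI-fail:EM"
      }
    } else {
      new_sigma <- em_update(sigma, data, Pobj)
      new_P <- compute_P(new_sigma, data)
    }
    d_var <- max(abs(new_sigma - sigma)) / sum(new_sigma)
    d_h2 <- max(abs(h2_of(new_sigma) - h2_of(sigma)))
    at_floor <- new_sigma <= variance_floor(new_sigma) * (1 + 1e-12)
    floor_run <- ifelse(at_floor, floor_run + 1L, 0L)
    near_zero <- union(near_zero, names(floor_run)[floor_run >= 10])
    sigma <- new_sigma; Pobj <- new_P; it_done <- it
    trace[[it]] <- data.frame(iteration = it, method = method,
                              t(sigma), t(h2_of(sigma)), logL = Pobj$logL,
                              delta_var = d_var, delta_h2 = d_h2,
                              check.names = FALSE)
    if (d_var < control$tolerance_var) { reason <- "var-tolerance"; converged <- TRUE; break }
    if (d_h2 < control$tolerance_h2) { reason <- "h2-tolerance"; converged <- TRUE; break }
  }
  trace <- do.call(rbind, trace[seq_len(it_done)])
  names(trace)[3:(2 + length(need))] <- paste0("sigma2_", need)
  names(trace)[(3 + length(need)):(2 + length(need) + length(comps))] <-
    paste0("h2_", comps)
  AI <- ai_matrix(sigma, data, Pobj)
  sigma_cov <- tryCatch(solve(AI), error = function(e) pinv(AI))
  S <- sum(sigma)
  h2 <- h2_of(sigma)
  h2_sd <- vapply(comps, function(i) {
    grad <- -sigma[[i]] / S^2 + (need == i) / S
    sqrt(max(0, drop(grad %*% sigma_cov %*% grad)))
  }, 1.0)
  structure(list(sigma = sigma, h2 = h2, h2_sd = h2_sd, sigma_cov = sigma_cov,
                 logL = Pobj$logL, converged = converged, reason = reason,
                 iterations = it_done, trace = trace, near_zero = near_zero,
                 control = control, k = data$k),
            class = "greml_fit")
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf("greml_fit: %d iterations, %s (%s)\n", x$iterations,
              if (x$converged) "converged" else "not converged", x$reason))
  comps <- setdiff(names(x$sigma), "e")
  for (i in comps)
    cat(sprintf("  sigma2_%-3s = %.6g   h2_%-3s = %.4f (SD %.4f)\n",
                i, x$sigma[[i]], i, x$h2[[i]], x$h2_sd[[i]]))
  cat(sprintf("  sigma2_e   = %.6g   logL = %.6f\n", x$sigma[["e"]], x$logL))
  if (length(x$near_zero) > 0)
    cat("  near-zero heritability components:", paste(x$near_zero, collapse = ", "),
        "- consider removing them from the model\n")
  invisible(x)
}

#' Write a GREML iteration log
#'
#' @param fit a `greml_fit`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_iteration_log <- function(fit, path) {
  utils::write.table(fit$trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
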