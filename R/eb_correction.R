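#' Fit the empirical Bayes batch-adjustment model
#'
#' Location/scale batch adjustment with empirical Bayes shrinkage, in the
#' ComBat tradition. Each CpG `g` in sample `j` of batch `i` is modeled
#' as
#' \deqn{y_{ijg} = \alpha_g + X_j \beta_g + \gamma_{ig} + \delta_{ig}
#'   \epsilon_{ijg},}
#' where `X` carries the biological covariates of interest (so biology is
#' protected from the adjustment), `gamma` is an additive and `delta^2` a
#' multiplicative batch effect. Per-CpG batch estimates are shrunk toward
#' batch-level priors (normal for `gamma`, inverse-gamma for `delta^2`)
#' whose hyperparameters are estimated from all CpGs by method of
#' moments; the coupled conditional posterior means are iterated to
#' convergence. Borrowing strength across CpGs stabilizes the per-batch
#' estimates when batches are small (a 12-sample chip).
#'
#' The grand location `alpha_g` is the batch-size-weighted mean of the
#' per-batch fits, so unbalanced chips do not bias it. CpGs with zero
#' pooled variance, or with missing values, are flagged and passed
#' through unadjusted.
#'
#' @param beta numeric beta matrix (probes x samples).
#' @param samples a [sample_sheet()] covering the columns of `beta`.
#' @param covariates character vector of sample-sheet column names to
#'   protect (e.g. the case/control outcome). May be empty.
#' @param shrink logical; `FALSE` disables EB shrinkage and uses the raw
#'   per-CpG batch location/scale estimates.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   shrunken parameters.
#' @param max_iter iteration cap for the EB fixed-point updates.
#' @return an object of class `eb_model`.
#' @export
fit_eb <- function(beta, samples, covariates = character(),
                   shrink = TRUE, tol = 1e-6, max_iter = 500L) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta must be a numeric matrix")
  sheet <- .align_sheet(samples, colnames(beta))
  batch <- factor(sheet$batch)
  nb <- nlevels(batch)
  if (nb < 2) stop("need at least 2 batches to estimate batch effects")
  n_i <- table(batch)
  if (any(n_i < 2))
    stop("every batch needs at least 2 samples (scale not estimable in: ",
         paste(names(n_i)[n_i < 2], collapse = ", "), ")")

  N <- ncol(beta)
  batch_des <- stats::model.matrix(~ 0 + batch)
  colnames(batch_des) <- levels(batch)
  cov_des <- .covariate_design(sheet, covariates)
  X <- cbind(batch_des, cov_des)
  if (qr(X)$rank < ncol(X)) {
    stop("covariates are confounded with batch; the design matrix ",
         "[batch | ", paste(covariates, collapse = ", "),
         "] is rank deficient, so batch and biological effects cannot ",
         "be separated")
  }

  usable <- rowSums(is.na(beta)) == 0
  Y <- beta[usable, , drop = FALSE]
  G <- nrow(Y)
  if (G == 0) stop("no CpG has complete data across samples")

  # per-CpG least squares on [batch indicators | covariates]
  B_hat <- solve(crossprod(X), crossprod(X, t(Y)))   # ncol(X) x G
  w <- as.numeric(n_i) / N
  grand <- as.numeric(w %*% B_hat[seq_len(nb), , drop = FALSE])
  fitted <- t(X %*% B_hat)
  var_pooled <- rowSums((Y - fitted)^2) / N

  zero_var <- var_pooled <= .Machine$double.eps
  stand_mean <- matrix(grand, G, N)
  if (!is.null(cov_des) && ncol(cov_des) > 0) {
    stand_mean <- stand_mean +
      t(cov_des %*% B_hat[-seq_len(nb), , drop = FALSE])
  }
  sd_pooled <- sqrt(var_pooled)
  sd_pooled[zero_var] <- 1  # placeholder; flagged rows are never adjusted
  Z <- (Y - stand_mean) / sd_pooled

  gamma_hat <- matrix(NA_real_, nb, G,
                      dimnames = list(levels(batch), rownames(Y)))
  delta2_hat <- gamma_hat
  for (i in seq_len(nb)) {
    zi <- Z[, batch == levels(batch)[i], drop = FALSE]
    gamma_hat[i, ] <- rowMeans(zi)
    delta2_hat[i, ] <- apply(zi, 1, stats::var)
    degen <- delta2_hat[i, ] <= 0 & !zero_var
    if (any(degen)) {
      pos <- delta2_hat[i, ][delta2_hat[i, ] > 0]
      if (length(pos) == 0) stop("all CpGs constant within batch ",
                                 levels(batch)[i])
      delta2_hat[i, degen] <- min(pos)
      warning(sum(degen), " CpG(s) constant within batch ",
              levels(batch)[i], "; scale floored to smallest observed")
    }
  }

  hyper <- data.frame(batch = levels(batch), n = as.integer(n_i),
                      gamma_bar = NA_real_, tau2 = NA_real_,
                      lambda = NA_real_, theta = NA_real_)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  if (shrink) {
    for (i in seq_len(nb)) {
      g <- gamma_hat[i, !zero_var]
      d <- delta2_hat[i, !zero_var]
      gbar <- mean(g); t2 <- stats::var(g)
      m <- mean(d); s2 <- stats::var(d)
      # inverse-gamma moment matching: mean = theta/(lambda-1),
      # var = theta^2 / ((lambda-1)^2 (lambda-2))
      lambda <- (2 * s2 + m^2) / s2
      theta <- (m * s2 + m^3) / s2
      hyper[i, c("gamma_bar", "tau2", "lambda", "theta")] <-
        c(gbar, t2, lambda, theta)
      zi <- Z[!zero_var, batch == levels(batch)[i], drop = FALSE]
      ni <- ncol(zi)
      g_old <- g; d_old <- d
      for (it in seq_len(max_iter)) {
        g_new <- (t2 * ni * g + d_old * gbar) / (t2 * ni + d_old)
        sum2 <- rowSums((zi - g_new)^2)
        d_new <- (0.5 * sum2 + theta) / (ni / 2 + lambda - 1)
        if (max(abs(g_new - g_old), abs(d_new - d_old)) < tol) {
          g_old <- g_new; d_old <- d_new
          break
        }
        g_old <- g_new; d_old <- d_new
      }
      gamma_star[i, !zero_var] <- g_old
      delta2_star[i, !zero_var] <- d_old
    }
  }

  structure(list(
    design = X, batch = batch, covariate_design = cov_des,
    probe_ids = rownames(Y), sample_ids = colnames(beta),
    usable = usable, zero_var = zero_var,
    coef = B_hat, alpha_g = grand, sigma2_g = var_pooled,
    stand_mean = stand_mean,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    hyper = hyper, shrink = shrink, tol = tol
  ), class = "eb_model")
}

.covariate_design <- function(sheet, covariates) {
  if (length(covariates) == 0) return(NULL)
  missing_cols <- setdiff(covariates, names(sheet))
  if (length(missing_cols))
    stop("covariate column(s) not in sample sheet: ",
         paste(missing_cols, collapse = ", "))
  df <- sheet[, covariates, drop = FALSE]
  for (k in seq_along(df))
    if (!is.numeric(df[[k]])) df[[k]] <- factor(df[[k]])
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]  # drop intercept; batch columns span it
}

#' @export
print.eb_model <- function(x, ...) {
  cat(sprintf(
    "eb_model: %d CpGs, %d samples, %d batches (%s shrinkage)\n",
    length(x$probe_ids), length(x$sample_ids), nlevels(x$batch),
    if (x$shrink) "parametric EB" else "no"))
  print(x$hyper, row.names = FALSE)
  invisible(x)
}

#' Apply a fitted EB model to a beta matrix
#'
#' Removes the shrunken batch location and scale from every CpG:
#' standardized residuals are recentred and rescaled per batch, then
#' returned to the original scale and the protected covariate fit is
#' added back. Under `clip_policy = "clip01"` the adjusted values are
#' clamped into `[0, 1]` (beta values are bounded and correction must
#' not push them outside); the number of clamped entries is attached as
#' attribute `n_clipped`.
#'
#' @param model an [fit_eb()] result.
#' @param beta the beta matrix the model was fitted on (same dimnames).
#' @param clip_policy `"clip01"` or `"none"`.
#' @return adjusted beta matrix.
#' @export
apply_eb <- function(model, beta, clip_policy = c("clip01", "none")) {
  clip_policy <- match.arg(clip_policy)
  stopifnot(inherits(model, "eb_model"))
  if (!identical(colnames(beta), model$sample_ids))
    stop("sample set differs from the fitted model")
  if (!all(model$probe_ids %in% rownames(beta)))
    stop("probe set differs from the fitted model")

  out <- beta
  rows <- model$probe_ids[!model$zero_var]
  keep <- !model$zero_var
  Y <- beta[rows, , drop = FALSE]
  sd_pooled <- sqrt(model$sigma2_g[keep])
  Z <- (Y - model$stand_mean[keep, , drop = FALSE]) / sd_pooled
  bi <- as.integer(model$batch)
  g <- model$gamma_star[, keep, drop = FALSE]
  d <- sqrt(model$delta2_star[, keep, drop = FALSE])
  for (j in seq_len(ncol(Y)))
    Z[, j] <- (Z[, j] - g[bi[j], ]) / d[bi[j], ]
  out[rows, ] <- Z * sd_pooled + model$stand_mean[keep, , drop = FALSE]

  n_clipped <- 0L
  if (clip_policy == "clip01") {
    lo <- !is.na(out) & out < 0
    hi <- !is.na(out) & out > 1
    n_clipped <- sum(lo) + sum(hi)
    out[lo] <- 0
    out[hi] <- 1
  }
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Fit and apply EB batch correction in one step
#'
#' Convenience composition of [fit_eb()] and [apply_eb()].
#'
#' @inheritParams fit_eb
#' @inheritParams apply_eb
#' @param method currently only `"eb-parametric"`.
#' @param transform `"none"` adjusts on the beta scale (default; clipped
#'   into bounds), `"logit"` adjusts on the logit scale (values squeezed
#'   away from 0/1 first, back-transformed after, never out of bounds).
#' @param verbose print the fitted hyperparameters.
#' @return list with elements `beta` (corrected matrix) and `model`.
#' @export
correct_batch <- function(beta, samples, covariates = character(),
                          method = "eb-parametric",
                          clip_policy = c("clip01", "none"),
                          transform = c("none", "logit"),
                          verbose = FALSE) {
  method <- match.arg(method)
  clip_policy <- match.arg(clip_policy)
  transform <- match.arg(transform)
  if (transform == "logit") {
    eps <- 1e-4
    y <- pmin(pmax(beta, eps), 1 - eps)
    y <- log2(y / (1 - y))
    model <- fit_eb(y, samples, covariates)
    adj <- apply_eb(model, y, clip_policy = "none")
    corrected <- 2^adj / (1 + 2^adj)
    dimnames(corrected) <- dimnames(beta)
    attr(corrected, "n_clipped") <- 0L
  } else {
    model <- fit_eb(beta, samples, covariates)
    corrected <- apply_eb(model, beta, clip_policy = clip_policy)
  }
  if (verbose) print(model)
  list(beta = corrected, model = model)
}
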