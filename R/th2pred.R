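# Deterministic interleaved fold assignment; "loo" gives leave-one-out.
make_folds <- function(n, k_folds) {
  if (identical(k_folds, "loo")) k_folds <- n
  k_folds <- as.integer(k_folds)
  stopifnot(k_folds >= 2L, k_folds <= n)
  rep_len(seq_len(k_folds), n)
}

scale_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv,
       X = sweep(sweep(X, 2L, mu), 2L, sdv, "/"))
}

apply_scale <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")

# OLS with intercept; ridge fallback (fixed small penalty) when the
# training design is rank-deficient or has more predictors than rows.
fit_linear <- function(X, Y, notify = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (p >= n) {
    if (notify) message("predictors >= training samples; ridge fallback ",
                        "(penalty 1e-3) used")
    XtX <- crossprod(X) + diag(1e-3, p)
    B <- solve(XtX, crossprod(X, sweep(Y, 2L, colMeans(Y))))
    a <- colMeans(Y) - drop(colMeans(X) %*% B)
    return(list(intercept = a, B = B))
  }
  fit <- stats::lm.fit(cbind(1, X), Y)
  cf <- as.matrix(fit$coefficients)
  list(intercept = cf[1L, ], B = cf[-1L, , drop = FALSE])
}

predict_linear <- function(model, X) {
  sweep(X %*% model$B, 2L, model$intercept, "+")
}

# One pass of k-fold CV: fold-wise standardization (scaler fit on the
# training rows only), OLS per fold, pooled PRESS / TSS contributions,
# with TSS taken about the training-fold means.
cv_press <- function(X, Y, folds) {
  Y <- as.matrix(Y)
  press <- matrix(0, ncol(Y), ncol(Y))
  tss <- matrix(0, ncol(Y), ncol(Y))
  for (f in unique(folds)) {
    test <- folds == f
    sc <- scale_train(X[!test, , drop = FALSE])
    model <- fit_linear(sc$X, Y[!test, , drop = FALSE], notify = FALSE)
    pred <- predict_linear(model, apply_scale(X[test, , drop = FALSE], sc))
    res <- Y[test, , drop = FALSE] - pred
    dev <- sweep(Y[test, , drop = FALSE], 2L,
                 colMeans(Y[!test, , drop = FALSE]))
    press <- press + crossprod(res)
    tss <- tss + crossprod(dev)
  }
  list(press = press, tss = tss)
}

#' Cross-validated predictive regression (Q2) of a single response
#'
#' Ordinary least squares of one response on a predictor matrix with
#' k-fold cross-validation: Q2 = 1 - PRESS/TSS, where PRESS pools the
#' squared out-of-fold prediction errors and TSS is taken about the
#' training-fold means.  Predictors are standardized inside each
#' training fold (no leakage).  The in-sample R2 and overall-F model
#' p-value come from the full fit; `q2_p` is the add-one-corrected
#' fraction of `n_perm` response-permuted runs reaching the observed Q2.
#' Training folds with predictors >= samples fall back to ridge with a
#' fixed small penalty (logged).
#'
#' @param X Numeric predictor matrix (samples x predictors).
#' @param y Numeric response vector.
#' @param k_folds Number of folds (default 7) or `"loo"`.
#' @param n_perm Response permutations for `q2_p` (0 to skip).
#' @return Object of class `regression_report`: r2_y, q2_y, model_p,
#'   q2_p, coefficients (standardized, response x predictor), folds.
#' @export
crossval_q2_regression <- function(X, y, k_folds = 7, n_perm = 0L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  folds <- make_folds(nrow(X), k_folds)

  q2_of <- function(yy) {
    cv <- cv_press(X, yy, folds)
    1 - drop(cv$press) / drop(cv$tss)
  }
  q2 <- q2_of(y)

  sc <- scale_train(X)
  ys <- (y - mean(y)) / stats::sd(y)
  full <- fit_linear(sc$X, ys)
  fitted <- drop(predict_linear(full, sc$X))
  rss <- sum((ys - fitted)^2)
  tss <- sum((ys - mean(ys))^2)
  r2 <- 1 - rss / tss
  p_pred <- ncol(X); n <- nrow(X)
  model_p <- if (n - p_pred - 1 > 0) {
    fstat <- (r2 / p_pred) / ((1 - r2) / (n - p_pred - 1))
    stats::pf(fstat, p_pred, n - p_pred - 1, lower.tail = FALSE)
  } else NA_real_

  q2_p <- NA_real_
  if (n_perm > 0L) {
    b <- sum(vapply(seq_len(n_perm),
                    function(i) q2_of(sample(y)) >= q2, logical(1)))
    q2_p <- perm_pvalue(b, n_perm)
  }
  coef <- matrix(drop(full$B), nrow = 1,
                 dimnames = list("response", colnames(X)))
  structure(list(responses = "response", r2_y = r2, q2_y = q2,
                 model_p = model_p, q2_p = q2_p, coefficients = coef,
                 folds = length(unique(folds)), n_perm = n_perm),
            class = "regression_report")
}

# Wilks lambda and Rao's F approximation for the overall regression of
# a multivariate response on q predictors.
wilks_rao <- function(E, T, n, p_resp, q_pred) {
  dT <- det(T)
  if (!is.finite(dT) || dT <= 0)
    stop("singular response covariance; use fewer responses or regularize")
  lambda <- det(E) / dT
  t_s <- if (p_resp^2 + q_pred^2 - 5 > 0)
    sqrt((p_resp^2 * q_pred^2 - 4) / (p_resp^2 + q_pred^2 - 5)) else 1
  w <- n - 1 - (p_resp + q_pred + 1) / 2
  df1 <- p_resp * q_pred
  df2 <- w * t_s - (p_resp * q_pred - 2) / 2
  lam_t <- lambda^(1 / t_s)
  fstat <- (1 - lam_t) / lam_t * df2 / df1
  list(lambda = lambda,
       p = stats::pf(fstat, df1, df2, lower.tail = FALSE),
       fstat = fstat, df1 = df1, df2 = df2)
}

#' Multivariate regression with Wilks lambda and out-of-sample 1 - lambda
#'
#' Fits the multivariate linear model Y ~ X and reports Wilks
#' Lambda = det(E)/det(E + H) with 1 - Lambda as the multivariate R2
#' analogue, the Rao F approximation p-value, and an out-of-sample
#' 1 - Lambda computed from cross-validated residual and total SSCP
#' matrices (fold-wise standardization as in
#' [crossval_q2_regression()]).  With `n_perm > 0`, rows of Y are
#' permuted jointly to give permutation p-values for both the in-sample
#' statistic (`model_p_perm`, the cross-check on Rao's F) and the
#' out-of-sample statistic (`q2_p`).
#'
#' @param X Predictor matrix (samples x predictors).
#' @param Y Response matrix (samples x responses, >= 2 responses,
#'   samples > responses).
#' @param k_folds Folds (default 7) or `"loo"`.
#' @param n_perm Response permutations (0 to skip).
#' @return Object of class `regression_report`: r2_y (1 - Lambda),
#'   q2_y (out-of-sample 1 - Lambda), model_p (Rao F), model_p_perm,
#'   q2_p, lambda, coefficients (standardized, response x predictor).
#' @export
multivariate_wilks <- function(X, Y, k_folds = 7, n_perm = 0L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(Y) >= 2L, nrow(Y) > ncol(Y))
  n <- nrow(X)
  folds <- make_folds(n, k_folds)

  sc <- scale_train(X)
  Ys <- scale_train(Y)$X
  full <- fit_linear(sc$X, Ys)
  res <- Ys - predict_linear(full, sc$X)
  E <- crossprod(res)
  T <- crossprod(sweep(Ys, 2L, colMeans(Ys)))
  rao <- wilks_rao(E, T, n, ncol(Y), ncol(X))

  lambda_out_of <- function(YY) {
    cv <- cv_press(X, YY, folds)
    dT <- det(cv$tss)
    if (!is.finite(dT) || dT <= 0)
      stop("singular cross-validated response covariance")
    det(cv$press) / dT
  }
  lambda_out <- lambda_out_of(Y)

  model_p_perm <- q2_p <- NA_real_
  if (n_perm > 0L) {
    b_in <- 0L; b_out <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n)
      Yp <- Y[idx, , drop = FALSE]
      Yps <- scale_train(Yp)$X
      res_p <- Yps - predict_linear(fit_linear(sc$X, Yps, notify = FALSE),
                                    sc$X)
      Ep <- crossprod(res_p)
      Tp <- crossprod(sweep(Yps, 2L, colMeans(Yps)))
      b_in <- b_in + ((1 - det(Ep) / det(Tp)) >= (1 - rao$lambda))
      b_out <- b_out + ((1 - lambda_out_of(Yp)) >= (1 - lambda_out))
    }
    model_p_perm <- perm_pvalue(b_in, n_perm)
    q2_p <- perm_pvalue(b_out, n_perm)
  }
  structure(list(responses = colnames(Y) %||% paste0("y", seq_len(ncol(Y))),
                 r2_y = 1 - rao$lambda, q2_y = 1 - lambda_out,
                 lambda = rao$lambda, lambda_out = lambda_out,
                 model_p = rao$p, model_p_perm = model_p_perm,
                 q2_p = q2_p,
                 coefficients = t(full$B),
                 folds = length(unique(folds)), n_perm = n_perm),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  multi <- length(x$responses) > 1L
  cat(if (multi) "Multivariate regression (Wilks lambda)\n"
      else "Cross-validated regression\n")
  cat(sprintf("  in-sample %s  = %.3f\n",
              if (multi) "1 - lambda" else "R2_y", x$r2_y))
  cat(sprintf("  out-of-sample %s = %.3f  (%d folds)\n",
              if (multi) "1 - lambda" else "Q2_y", x$q2_y, x$folds))
  cat(sprintf("  model p = %s", format.pval(x$model_p)))
  if (!is.na(x$q2_p)) cat(sprintf(",  out-of-sample permutation p = %s",
                                  format.pval(x$q2_p)))
  cat("\n")
  invisible(x)
}

# Member sets of all internal nodes of an hclust tree (sizes 2..k-1).
hclust_clades <- function(h, labels) {
  k <- length(labels)
  members <- vector("list", k - 1L)
  for (i in seq_len(k - 1L)) {
    m <- h$merge[i, ]
    members[[i]] <- c(if (m[1] < 0) labels[-m[1]] else members[[m[1]]],
                      if (m[2] < 0) labels[-m[2]] else members[[m[2]]])
  }
  members <- lapply(members, sort)
  members[lengths(members) < k]
}

cluster_tree <- function(M) {
  d <- 1 - suppressWarnings(stats::cor(t(M)))
  d[is.na(d)] <- 1
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Bootstrap-supported clustering of standardized regression coefficients
#'
#' Fits the standardized multivariate regression of `Y` on `X`,
#' clusters the coefficient matrix by rows (responses) and by columns
#' (predictors) with correlation distance and average linkage, and
#' assesses cluster stability by refitting on `n_boot` bootstrap
#' resamples of the samples: a cluster's support is the fraction of
#' refits in which the same member set reappears as a clade.  Clusters
#' with support >= 0.95 are flagged significant.  Skipped (with a
#' message) when fewer than 3 rows or columns are available.
#'
#' @param X,Y Predictor and response matrices (samples x variables).
#' @param n_boot Bootstrap refits.
#' @return List of class `coefficient_clustering`: coefficients,
#'   response_tree / predictor_tree (hclust), response_support /
#'   predictor_support (data.frames: members, support, significant).
#' @export
coefficient_clustering <- function(X, Y, n_boot = 200L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  fit_coef <- function(rows) {
    sc <- scale_train(X[rows, , drop = FALSE])
    Ys <- scale_train(Y[rows, , drop = FALSE])$X
    t(fit_linear(sc$X, Ys, notify = FALSE)$B)  # response x predictor
  }
  coef <- fit_coef(seq_len(nrow(X)))
  dimnames(coef) <- list(colnames(Y) %||% paste0("y", seq_len(ncol(Y))),
                         colnames(X) %||% paste0("x", seq_len(ncol(X))))
  out <- list(coefficients = coef)
  for (side in c("response", "predictor")) {
    M <- if (side == "response") coef else t(coef)
    if (nrow(M) < 3L) {
      message("fewer than 3 ", side, "s; clustering skipped")
      next
    }
    tree <- cluster_tree(M)
    clades <- hclust_clades(tree, rownames(M))
    hits <- integer(length(clades))
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nrow(X), replace = TRUE)
      cb <- fit_coef(rows)
      Mb <- if (side == "response") cb else t(cb)
      rownames(Mb) <- rownames(M)
      boot_clades <- hclust_clades(cluster_tree(Mb), rownames(Mb))
      keys <- vapply(boot_clades, paste, "", collapse = "|")
      hits <- hits + (vapply(clades, paste, "", collapse = "|") %in% keys)
    }
    support <- hits / n_boot
    out[[paste0(side, "_tree")]] <- tree
    out[[paste0(side, "_support")]] <-
      data.frame(members = vapply(clades, paste, "", collapse = ","),
                 size = lengths(clades), support = support,
                 significant = support >= 0.95, stringsAsFactors = FALSE)
  }
  class(out) <- "coefficient_clustering"
  out
}
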