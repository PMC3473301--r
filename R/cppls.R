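# Canonical Powered Partial Least Squares discriminant.
#
# Two-class regression of the +1/-1 response on the word-frequency matrix.
# Components are extracted sequentially; the loading-weight vector of each
# component re-balances column standard deviations against column-response
# correlations through a power parameter gamma in [0, 1]:
#
#   w_j(gamma) = sign(r_j) * |r_j|^(gamma/(1-gamma)) * s_j^((1-gamma)/gamma)
#
# (r_j, s_j normalized by their maxima; gamma = 0 and 1 keep only the
# maximum-s and maximum-|r| columns). At gamma = 0.5 both exponents are 1
# and w is proportional to the covariance of column j with the response —
# the classical PLS loading weight. gamma is chosen per component by
# maximizing the canonical correlation between the candidate score t = X w
# and the response space, which for a single +/-1 response reduces to the
# squared Pearson correlation with the centered response.

powered_weights <- function(corr, sds, gamma) {
  w <- numeric(length(corr))
  ok <- sds > 0 & !is.na(corr)
  if (!any(ok)) stop("all predictor columns are constant")
  if (gamma <= 0) {
    sel <- ok & sds >= max(sds[ok]) * (1 - 1e-12)
    w[sel] <- sds[sel]
  } else if (gamma >= 1) {
    ac <- abs(corr)
    sel <- ok & ac >= max(ac[ok]) * (1 - 1e-12)
    w[sel] <- sign(corr[sel]) * ac[sel]
  } else {
    cn <- abs(corr[ok]) / max(abs(corr[ok]))
    sn <- sds[ok] / max(sds[ok])
    w[ok] <- sign(corr[ok]) * cn^(gamma / (1 - gamma)) * sn^((1 - gamma) / gamma)
  }
  w
}

# one CPPLS fit at fixed number of components; X, y already validated
cppls_core <- function(X, y, A, gamma_grid) {
  n <- nrow(X)
  p <- ncol(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xd <- sweep(X, 2L, xbar)
  yc <- y - ybar
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  q <- numeric(A)
  gammas <- numeric(A)
  for (a in seq_len(A)) {
    sds <- sqrt(pmax(0, colMeans(Xd^2)))  # deflated columns are centered
    covs <- as.vector(crossprod(Xd, yc)) / n
    corr <- ifelse(sds > 0, covs / (sds * stats::sd(yc)), NA_real_)
    best <- NULL
    for (g in gamma_grid) {
      w <- powered_weights(corr, sds, g)
      nw <- sqrt(sum(w^2))
      if (nw == 0) next
      t_cand <- Xd %*% (w / nw)
      r2 <- suppressWarnings(stats::cor(t_cand, yc)^2)
      if (is.na(r2)) next
      if (is.null(best) || r2 > best$r2 + 1e-12)
        best <- list(w = w / nw, t = t_cand, r2 = r2, gamma = g)
    }
    if (is.null(best)) {
      # deflated matrix carries no signal; stop early
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      gammas <- gammas[seq_len(a - 1L)]
      break
    }
    tt <- sum(best$t^2)
    if (tt < .Machine$double.eps) break
    W[, a] <- best$w
    P[, a] <- as.vector(crossprod(Xd, best$t)) / tt
    q[a] <- sum(yc * best$t) / tt
    gammas[a] <- best$gamma
    Xd <- Xd - best$t %*% t(P[, a])
  }
  A_eff <- ncol(W)
  beta <- if (A_eff == 0L) numeric(p) else
    as.vector(W %*% solve(crossprod(P, W), q))
  list(coefficients = beta, intercept = ybar - sum(xbar * beta),
       column_means = xbar, n_components = A_eff, power_parameters = gammas)
}

#' Fit a CPPLS two-class discriminant
#'
#' Regresses the +1/-1 class response on mean-centered word frequencies,
#' extracting up to \code{A_max} latent components; the per-component power
#' parameter gamma is picked from \code{gamma_grid} (see the file-level
#' notes: gamma = 0.5 recovers classical PLS). The number of components is
#' selected by an inner stratified cross-validation on the training data,
#' minimizing misclassification (ties favor fewer components), after which
#' the model is refitted on all rows.
#'
#' @param X Numeric predictor matrix (rows = sequences, columns = word
#'   frequencies), e.g. from [word_feature_matrix()].
#' @param y Response vector: +1 (Positive) / -1 (Negative) for the
#'   discriminant. A continuous response is also accepted (CPPLS is at heart
#'   a regression method); the inner cross-validation then minimizes squared
#'   error instead of misclassification.
#' @param A_max Maximum number of components (default 10; capped at
#'   \code{min(n - 1, p)}).
#' @param gamma_grid Candidate power parameters; default \{0.5\} plus ten
#'   evenly spaced interior points.
#' @param inner_folds Folds of the component-selection cross-validation
#'   (default 5); set to 0 to skip selection and use \code{A_max} components.
#' @param seed Seed for the inner fold split.
#' @return A \code{cppls_model}: \code{coefficients}, \code{intercept},
#'   \code{column_means}, \code{n_components}, \code{power_parameters},
#'   \code{cv_misclassification} (per candidate A, when selected).
#' @export
cppls_fit <- function(X, y, A_max = 10L,
                      gamma_grid = sort(unique(c(0.5, (1:10) / 11))),
                      inner_folds = 5L, seed = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  two_class <- all(y %in% c(-1, 1))
  if (length(unique(y)) < 2L)
    stop(if (two_class) "both classes must be present in y"
         else "y is constant")
  if (nrow(X) < 4L) stop("need at least 4 training rows")
  if (!any(colMeans(X^2) - colMeans(X)^2 > 0))
    stop("all predictor columns are constant")
  A_cap <- min(A_max, nrow(X) - 1L, ncol(X))
  cv_err <- NULL
  A_best <- A_cap
  if (inner_folds >= 2L && A_cap > 1L) {
    fold <- if (two_class) {
      split_folds(y, folds = inner_folds, seed = seed)
    } else {
      with_seed(seed, sample(rep_len(seq_len(inner_folds), length(y))))
    }
    err <- numeric(A_cap)
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      A_f <- min(A_cap, sum(tr) - 1L)
      # held-out loss for each truncated component count
      scores <- cppls_path_scores(X[!tr, , drop = FALSE], X[tr, , drop = FALSE],
                                  y[tr], A_f, gamma_grid)
      for (a in seq_len(A_cap)) {
        s <- scores[, min(a, ncol(scores))]
        err[a] <- err[a] + if (two_class)
          sum(ifelse(s > 0, 1, -1) != y[!tr]) else sum((s - y[!tr])^2)
      }
    }
    A_best <- which.min(err)  # which.min takes the first (smallest A) on ties
    cv_err <- err / length(y)
  }
  fit <- cppls_core(X, y, A_best, gamma_grid)
  structure(
    c(fit, list(cv_misclassification = cv_err, word_index = colnames(X),
                gamma_grid = gamma_grid)),
    class = "cppls_model"
  )
}

# test-set score for every component count 1..A in one pass
cppls_path_scores <- function(X_test, X_train, y_train, A, gamma_grid) {
  n <- nrow(X_train)
  xbar <- colMeans(X_train)
  ybar <- mean(y_train)
  Xd <- sweep(X_train, 2L, xbar)
  yc <- y_train - ybar
  p <- ncol(X_train)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  out <- matrix(ybar, nrow(X_test), 0L)
  Xt <- sweep(X_test, 2L, xbar)
  for (a in seq_len(A)) {
    sds <- sqrt(pmax(0, colMeans(Xd^2)))
    covs <- as.vector(crossprod(Xd, yc)) / n
    corr <- ifelse(sds > 0, covs / (sds * stats::sd(yc)), NA_real_)
    best <- NULL
    for (g in gamma_grid) {
      w <- powered_weights(corr, sds, g)
      nw <- sqrt(sum(w^2))
      if (nw == 0) next
      t_cand <- Xd %*% (w / nw)
      r2 <- suppressWarnings(stats::cor(t_cand, yc)^2)
      if (is.na(r2)) next
      if (is.null(best) || r2 > best$r2 + 1e-12)
        best <- list(w = w / nw, t = t_cand, r2 = r2)
    }
    if (is.null(best)) break
    tt <- sum(best$t^2)
    if (tt < .Machine$double.eps) break
    W[, a] <- best$w
    P[, a] <- as.vector(crossprod(Xd, best$t)) / tt
    q[a] <- sum(yc * best$t) / tt
    Xd <- Xd - best$t %*% t(P[, a])
    beta_a <- as.vector(W[, 1:a, drop = FALSE] %*%
                          solve(crossprod(P[, 1:a, drop = FALSE],
                                          W[, 1:a, drop = FALSE]),
                                q[1:a]))
    out <- cbind(out, ybar + Xt %*% beta_a)
  }
  if (ncol(out) == 0L) out <- matrix(ybar, nrow(X_test), 1L)
  out
}

#' @export
print.cppls_model <- function(x, ...) {
  cat(sprintf("<cppls_model> %d component(s), p = %d, gamma = %s\n",
              x$n_components, length(x$coefficients),
              paste(signif(x$power_parameters, 3), collapse = ", ")))
  invisible(x)
}

#' Predicted CPPLS score
#'
#' \code{intercept + x \%*\% coefficients}: an affine map of the word
#' frequencies whose sign carries the classification.
#'
#' @param model A \code{cppls_model}.
#' @param X Feature row(s) with the model's columns.
#' @return Numeric score vector.
#' @export
cppls_predict_score <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(model$coefficients))
    stop(sprintf("feature dimension %d does not match model p = %d",
                 ncol(X), length(model$coefficients)))
  as.vector(model$intercept + X %*% model$coefficients)
}

#' Classify with a CPPLS discriminant
#'
#' +1 (Positive) when the predicted score is above 0, the midpoint of the
#' +1/-1 response coding; -1 otherwise.
#'
#' @inheritParams cppls_predict_score
#' @return Integer vector of +1 / -1 labels.
#' @export
cppls_classify <- function(model, X) {
  s <- cppls_predict_score(model, X)
  ifelse(s > 0, 1L, -1L)
}

#' Serialize / restore a CPPLS model as JSON text
#'
#' @param model A \code{cppls_model}.
#' @param path File path.
#' @return \code{path} (write) or the restored model (read).
#' @export
write_cppls <- function(model, path) {
  obj <- list(
    format = "orfclass-cppls", version = 1L,
    coefficients = model$coefficients, intercept = model$intercept,
    column_means = model$column_means, n_components = model$n_components,
    power_parameters = model$power_parameters,
    word_index = model$word_index
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cppls
#' @export
read_cppls <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "orfclass-cppls"))
    stop("not an orfclass CPPLS model file")
  structure(
    list(coefficients = obj$coefficients, intercept = obj$intercept,
         column_means = obj$column_means,
         n_components = as.integer(obj$n_components),
         power_parameters = obj$power_parameters,
         cv_misclassification = NULL, word_index = obj$word_index,
         gamma_grid = NULL),
    class = "cppls_model"
  )
}
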