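#' PLS-DA configuration
#'
#' @param n_lv Number of latent variables (default 6).
#' @param cv_splits Number of Venetian-blinds data splits (default 10).
#' @param class_order Optional character vector fixing the class column
#'   order; defaults to order of first appearance in the labels.
#' @param block_by Optional vector (e.g. subject ids) assigning all
#'   replicates of one subject to the same fold. Default `NULL`
#'   reproduces plain Venetian blinds on the sample index, which can put
#'   replicates of one subject in different folds — supply spectra in
#'   acquisition order and use `block_by` if that leakage is a concern.
#' @return A list of class `praman_plsda_config`.
#' @export
plsda_config <- function(n_lv = 6, cv_splits = 10, class_order = NULL,
                         block_by = NULL) {
  if (n_lv < 1) stop("n_lv must be >= 1")
  if (cv_splits < 2) stop("cv_splits must be >= 2")
  structure(list(n_lv = n_lv, cv_splits = cv_splits,
                 class_order = class_order, block_by = block_by),
            class = "praman_plsda_config")
}

#' Fit a PLS2 regression model (NIPALS)
#'
#' Fits partial least squares regression of a one-hot class indicator
#' matrix on the spectra by the NIPALS algorithm with per-component
#' deflation of both blocks. `X` and `Y` are mean-centred internally and
#' the means stored, so prediction is `(X - x_mean) B + y_mean`. With
#' `n_lv` equal to the rank of the centred `X`, the fitted values
#' coincide with ordinary least squares. The algorithm is deterministic
#' given the input order.
#'
#' @param X Numeric matrix, samples x channels.
#' @param Y Numeric matrix, samples x classes (one-hot indicator).
#' @param n_lv Number of latent variables; must not exceed the rank of
#'   the centred `X`.
#' @param class_order Character vector naming the columns of `Y`.
#' @return An object of class `praman_plsda` with fields `x_mean`,
#'   `y_mean`, `W` (weights), `P` (x-loadings), `Q` (y-loadings), `B`
#'   (channels x classes regression coefficients), `R`
#'   (`W (P'W)^{-1}`, the score projection), `n_lv` and `class_order`.
#' @export
fit_pls <- function(X, Y, n_lv, class_order = colnames(Y)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (any(apply(Y, 2, stats::var) == 0))
    stop("Y has a zero-variance column (single class present?)")
  if (n < n_lv + 1) stop("need at least n_lv + 1 samples")
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  r <- qr(Xc)$rank
  if (n_lv > r)
    stop(sprintf("n_lv (%d) exceeds the achievable rank %d of centred X",
                 n_lv, r))
  p_ch <- ncol(X); p_cl <- ncol(Y)
  W <- matrix(0, p_ch, n_lv); P <- matrix(0, p_ch, n_lv)
  Q <- matrix(0, p_cl, n_lv); TT <- matrix(0, n, n_lv)
  for (a in seq_len(n_lv)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- rep(0, n)
    for (it in seq_len(500L)) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) stop("degenerate component: X deflated to zero")
      w <- w / nw
      tt <- as.numeric(Xc %*% w)
      q <- as.numeric(crossprod(Yc, tt)) / sum(tt^2)
      u <- as.numeric(Yc %*% q) / sum(q^2)
      if (sum((tt - t_old)^2) <= 1e-24 * sum(tt^2)) break
      t_old <- tt
    }
    p <- as.numeric(crossprod(Xc, tt)) / sum(tt^2)
    W[, a] <- w; P[, a] <- p; Q[, a] <- q; TT[, a] <- tt
    Xc <- Xc - tcrossprod(tt, p)
    Yc <- Yc - tcrossprod(tt, q)
  }
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  structure(list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, Q = Q,
                 B = B, R = R, scores = TT, n_lv = n_lv,
                 class_order = class_order %||% paste0("class", seq_len(p_cl))),
            class = "praman_plsda")
}

#' Predict class membership from a fitted PLS-DA model
#'
#' @param m A [fit_pls()] model.
#' @param X Numeric matrix, samples x channels (channel count must match
#'   the model).
#' @return A list with `yhat` (`(X - x_mean) B + y_mean`) and `labels`
#'   (`class_order[argmax yhat]`, ties broken towards the lowest class
#'   index).
#' @export
predict_plsda <- function(m, X) {
  stopifnot(inherits(m, "praman_plsda"))
  X <- as.matrix(X)
  if (ncol(X) != length(m$x_mean))
    stop(sprintf("channel mismatch: model has %d channels, input has %d",
                 length(m$x_mean), ncol(X)))
  yhat <- sweep(X, 2, m$x_mean) %*% m$B
  yhat <- sweep(yhat, 2, m$y_mean, `+`)
  colnames(yhat) <- m$class_order
  labels <- m$class_order[max.col(yhat, ties.method = "first")]
  list(labels = labels, yhat = yhat)
}

#' Venetian-blinds fold assignment
#'
#' Sample `i` (1-based input order) goes to fold `((i - 1) mod splits) + 1`,
#' interleaving consecutive samples across folds.
#'
#' @param n Number of samples.
#' @param splits Number of folds; must not exceed `n`.
#' @return Integer vector of fold ids in `1:splits`.
#' @export
venetian_blinds_folds <- function(n, splits) {
  if (splits < 2) stop("splits must be >= 2")
  if (n < splits) stop("need at least as many samples as splits")
  as.integer((seq_len(n) - 1L) %% splits + 1L)
}

#' Cross-validated PLS-DA classification
#'
#' Runs Venetian-blinds cross-validation: for each fold the model is
#' fitted on the remaining samples (mean-centring computed on the
#' training fold only) and the held-out samples are predicted. The
#' reported accuracy and confusion matrix cover every held-out
#' prediction. Latent scores from a final full-data fit are returned for
#' visualisation. The whole procedure is deterministic given the input
#' order.
#'
#' @param X Numeric matrix, samples x channels.
#' @param labels Character vector of class labels (>= 2 classes).
#' @param cfg A [plsda_config()].
#' @return An object of class `praman_cv` with fields `fold_of`,
#'   `predicted`, `confusion` (true class in rows), `accuracy`, `scores`
#'   and `model` (the full-data fit).
#' @export
cross_validate <- function(X, labels, cfg = plsda_config()) {
  stopifnot(inherits(cfg, "praman_plsda_config"))
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("one label per row of X required")
  class_order <- cfg$class_order %||% unique(labels)
  if (!all(labels %in% class_order)) stop("labels outside class_order")
  if (length(class_order) < 2) stop("need at least 2 classes")
  n <- nrow(X)
  Y <- outer(labels, class_order, `==`) * 1
  colnames(Y) <- class_order
  folds <- if (!is.null(cfg$block_by)) {
    blocks <- as.character(cfg$block_by)
    if (length(blocks) != n) stop("block_by must have one entry per sample")
    ids <- unique(blocks)
    bf <- venetian_blinds_folds(length(ids), cfg$cv_splits)
    bf[match(blocks, ids)]
  } else {
    venetian_blinds_folds(n, cfg$cv_splits)
  }
  predicted <- character(n)
  for (k in sort(unique(folds))) {
    test <- folds == k
    if (length(unique(labels[!test])) < length(class_order))
      stop(paste("a training fold lacks a class;",
                 "reorder samples so classes interleave across folds"))
    m <- fit_pls(X[!test, , drop = FALSE], Y[!test, , drop = FALSE],
                 cfg$n_lv, class_order)
    predicted[test] <- predict_plsda(m, X[test, , drop = FALSE])$labels
  }
  confusion <- table(factor(labels, levels = class_order),
                     factor(predicted, levels = class_order))
  accuracy <- sum(diag(confusion)) / n
  full <- fit_pls(X, Y, cfg$n_lv, class_order)
  scores <- sweep(X, 2, full$x_mean) %*% full$R
  colnames(scores) <- paste0("LV", seq_len(cfg$n_lv))
  structure(list(fold_of = folds, predicted = predicted,
                 confusion = confusion, accuracy = accuracy,
                 scores = scores, model = full,
                 class_order = class_order),
            class = "praman_cv")
}

#' @export
print.praman_cv <- function(x, ...) {
  cat(sprintf("<praman_cv> accuracy %.3f over %d samples, %d folds\n",
              x$accuracy, length(x$fold_of), length(unique(x$fold_of))))
  print(x$confusion)
  invisible(x)
}
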