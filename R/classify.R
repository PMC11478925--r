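#' Train the standardized-feature linear discriminant classifier
#'
#' Features are standardized by the training mean and SD; a linear
#' discriminant model with pooled within-class covariance (optionally shrunk
#' toward its diagonal) is fitted; canonical discriminant-function (DF) axes
#' are the leading eigenvectors of the within/between eigenproblem, scaled
#' so the within-class covariance of the DF scores is the identity. With
#' three classes there are two DF axes.
#'
#' The discriminant for class k at standardized vector z is
#' `g_k(z) = z' S^-1 m_k - m_k' S^-1 m_k / 2 + log pi_k`, and posterior
#' probabilities are the softmax of the `g_k` (exact for a shared-covariance
#' Gaussian model).
#'
#' @param data Data frame with one row per training case.
#' @param label Name of the class-label column (character).
#' @param features Character vector of feature columns; default: all numeric
#'   columns except `label`.
#' @param prior `"uniform"` (default), `"frequency"`, or a named numeric
#'   vector summing to 1.
#' @param lambda Shrinkage weight toward the diagonal of the pooled
#'   covariance, in `[0, 1]`; `lambda = 0` is classical LDA.
#' @return An object of class `mrs_lda`.
#' @export
train_lda <- function(data, label = "tumour_type", features = NULL,
                      prior = "uniform", lambda = 0.1) {
  stopifnot(label %in% names(data), lambda >= 0, lambda <= 1)
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, TRUE)]
    features <- setdiff(features, label)
  }
  X <- as.matrix(data[, features, drop = FALSE])
  if (any(!is.finite(X))) abort("non-finite feature values")
  y <- as.character(data[[label]])
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) abort("need at least 2 classes")
  n <- nrow(X)
  p <- ncol(X)

  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  if (any(sigma <= 0)) {
    abort(paste0("zero training SD for: ",
                 paste(features[sigma <= 0], collapse = ", ")))
  }
  Z <- scale(X, center = mu, scale = sigma)

  counts <- table(factor(y, levels = classes))
  if (any(counts < 2)) {
    warn(paste0("class(es) with < 2 training cases: ",
                paste(classes[counts < 2], collapse = ", ")))
  }
  m_k <- t(vapply(classes, function(cl) colMeans(Z[y == cl, , drop = FALSE]),
                  numeric(p)))
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    Zi <- Z[y == cl, , drop = FALSE]
    if (nrow(Zi) >= 2) Sw <- Sw + crossprod(sweep(Zi, 2, colMeans(Zi)))
  }
  Sw <- Sw / max(n - K, 1)
  Sigma <- (1 - lambda) * Sw + lambda * diag(diag(Sw), p)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    abort("pooled covariance is singular; increase lambda")
  }
  Sigma_inv <- chol2inv(R)

  if (identical(prior, "uniform")) {
    priors <- stats::setNames(rep(1 / K, K), classes)
  } else if (identical(prior, "frequency")) {
    priors <- as.numeric(counts) / n
    names(priors) <- classes
  } else {
    stopifnot(abs(sum(prior) - 1) < 1e-8, all(classes %in% names(prior)))
    priors <- prior[classes]
  }

  W <- Sigma_inv %*% t(m_k)                       # p x K
  b <- -0.5 * colSums(t(m_k) * W) + log(priors)   # K

  # canonical axes: eigenvectors of R^-T Sb R^-1, mapped back by R^-1
  mbar <- colSums(m_k * as.numeric(counts)) / n
  Sb <- matrix(0, p, p)
  for (k in seq_len(K)) {
    d <- m_k[k, ] - mbar
    Sb <- Sb + counts[[k]] * tcrossprod(d)
  }
  ncomp <- min(K - 1, p)
  Rinv <- backsolve(R, diag(p))
  Msym <- t(Rinv) %*% Sb %*% Rinv
  ev <- eigen((Msym + t(Msym)) / 2, symmetric = TRUE)
  proj <- Rinv %*% ev$vectors[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(proj[, j]))
    if (proj[i, j] < 0) proj[, j] <- -proj[, j]
  }
  colnames(proj) <- paste0("DF", seq_len(ncomp))

  scores <- Z %*% proj
  train_scores <- tibble(
    subject = if ("subject" %in% names(data)) as.character(data$subject) else
      sprintf("T%03d", seq_len(n)),
    label = y
  )
  for (j in seq_len(ncomp)) train_scores[[paste0("DF", j)]] <- scores[, j]

  structure(list(
    features = features, mu = mu, sigma = sigma,
    classes = classes, class_means = m_k, Sigma = Sigma,
    Sigma_inv = Sigma_inv, priors = priors, W = W, b = b,
    proj = proj, df_class_means = m_k %*% proj,
    lambda = lambda, n = n, counts = as.numeric(counts),
    train_scores = train_scores
  ), class = "mrs_lda")
}

#' @export
print.mrs_lda <- function(x, ...) {
  cat(sprintf(
    "<mrs_lda> %d classes (%s), %d features, n = %d, lambda = %g\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    length(x$features), x$n, x$lambda
  ))
  invisible(x)
}

#' Standardize feature vectors with the training statistics
#'
#' @param model An `mrs_lda`.
#' @param data Data frame (or named numeric vector) containing the model's
#'   feature columns.
#' @return Numeric matrix of standardized values, one row per case.
#' @export
standardize_features <- function(model, data) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- as.data.frame(as.list(data))
  }
  missing <- setdiff(model$features, names(data))
  if (length(missing)) {
    abort(paste0("missing feature(s): ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[, model$features, drop = FALSE])
  scale(X, center = model$mu, scale = model$sigma)[, , drop = FALSE]
}

#' Classify cases with a fitted discriminant model
#'
#' Returns, per case, the predicted class (maximum posterior; exact ties
#' break in lexicographic class order), the posterior probability of each
#' class, the canonical DF scores, and the Mahalanobis-scaled distance to
#' the decision boundary between the two highest-posterior classes.
#'
#' @param model An `mrs_lda`.
#' @param data Data frame of cases (or a single named numeric vector).
#' @return A tibble: `subject` (if present in `data`), `predicted`,
#'   `post_<class>` columns, `DF1`, `DF2`, `boundary_distance`.
#' @export
apply_lda <- function(model, data) {
  Z <- standardize_features(model, data)
  G <- Z %*% model$W + matrix(model$b, nrow(Z), length(model$b), byrow = TRUE)
  Gs <- G - apply(G, 1, max)
  post <- exp(Gs) / rowSums(exp(Gs))
  colnames(post) <- model$classes
  pred <- model$classes[apply(post, 1, which.max)]
  scores <- Z %*% model$proj

  bdist <- vapply(seq_len(nrow(Z)), function(i) {
    top2 <- order(post[i, ], decreasing = TRUE)[1:2]
    j <- top2[1]; k <- top2[2]
    dvec <- model$Sigma_inv %*% (model$class_means[j, ] - model$class_means[k, ])
    abs(G[i, j] - G[i, k]) / sqrt(sum(dvec^2))
  }, numeric(1))

  out <- tibble(.rows = nrow(Z))
  if (is.data.frame(data) && "subject" %in% names(data)) {
    out$subject <- as.character(data$subject)
  }
  out$predicted <- pred
  for (cl in model$classes) out[[paste0("post_", cl)]] <- as.numeric(post[, cl])
  for (j in seq_len(ncol(scores))) out[[paste0("DF", j)]] <- as.numeric(scores[, j])
  out$boundary_distance <- bdist
  out
}

#' @export
#' @rdname apply_lda
#' @param object,newdata,... S3 `predict` interface equivalent to
#'   `apply_lda(object, newdata)`.
predict.mrs_lda <- function(object, newdata, ...) apply_lda(object, newdata)

#' Decision boundaries in the DF-score plane
#'
#' For a linear discriminant model the locus where the two highest
#' posteriors are equal is piecewise linear. For each class pair the
#' bisecting line in DF space is sampled and points kept where that pair
#' are the top two classes.
#'
#' @param model An `mrs_lda` (3 classes, 2 DF axes).
#' @param xlim,ylim Ranges of the DF plane to cover; default: training score
#'   range expanded by 50%.
#' @param n Number of samples per boundary line.
#' @return Tibble: `pair`, `DF1`, `DF2`.
#' @export
decision_boundaries <- function(model, xlim = NULL, ylim = NULL, n = 400) {
  stopifnot(ncol(model$proj) == 2)
  ts <- model$train_scores
  if (is.null(xlim)) xlim <- grDevices::extendrange(ts$DF1, f = 0.5)
  if (is.null(ylim)) ylim <- grDevices::extendrange(ts$DF2, f = 0.5)
  dm <- model$df_class_means
  K <- length(model$classes)
  post_df <- function(pts) {
    # posteriors as a function of DF coordinates (within-cov = identity)
    g <- pts %*% t(dm) -
      matrix(0.5 * rowSums(dm^2) - log(model$priors), nrow(pts), K, byrow = TRUE)
    gs <- g - apply(g, 1, max)
    exp(gs) / rowSums(exp(gs))
  }
  out <- list()
  for (j in seq_len(K - 1)) {
    for (k in (j + 1):K) {
      u <- dm[j, ] - dm[k, ]
      c0 <- 0.5 * (sum(dm[j, ]^2) - sum(dm[k, ]^2)) -
        (log(model$priors[j]) - log(model$priors[k]))
      # line: d . u = c0; param along the perpendicular direction
      base <- c0 * u / sum(u^2)
      v <- c(-u[2], u[1]) / sqrt(sum(u^2))
      tmax <- sqrt(diff(xlim)^2 + diff(ylim)^2)
      tt <- seq(-tmax, tmax, length.out = n)
      pts <- cbind(base[1] + tt * v[1], base[2] + tt * v[2])
      keep <- pts[, 1] >= xlim[1] & pts[, 1] <= xlim[2] &
        pts[, 2] >= ylim[1] & pts[, 2] <= ylim[2]
      pts <- pts[keep, , drop = FALSE]
      if (!nrow(pts)) next
      post <- post_df(pts)
      top2 <- t(apply(post, 1, function(p) sort(order(p, decreasing = TRUE)[1:2])))
      on_pair <- top2[, 1] == j & top2[, 2] == k
      pts <- pts[on_pair, , drop = FALSE]
      if (!nrow(pts)) next
      out[[length(out) + 1]] <- tibble(
        pair = paste(model$classes[j], model$classes[k], sep = "-"),
        DF1 = pts[, 1], DF2 = pts[, 2]
      )
    }
  }
  bind_rows(out)
}

round_half_up <- function(x) floor(x + 0.5)

#' Accuracy and confusion matrix from truth and predicted labels
#'
#' Accuracy is the percentage of cases with a correct diagnosis, reported
#' rounded half-up to the nearest integer alongside the exact fraction.
#'
#' @param truth,predicted Character vectors of equal length.
#' @return A list: `accuracy_pct` (integer-rounded), `accuracy_exact`,
#'   `n_correct`, `n_total`, `confusion` (matrix, rows = truth).
#' @export
classification_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  labs <- sort(unique(c(truth, predicted)))
  conf <- table(
    truth = factor(truth, levels = labs),
    predicted = factor(predicted, levels = labs)
  )
  n_correct <- sum(truth == predicted)
  n_total <- length(truth)
  list(
    accuracy_pct = round_half_up(100 * n_correct / n_total),
    accuracy_exact = 100 * n_correct / n_total,
    n_correct = n_correct,
    n_total = n_total,
    confusion = unclass(conf)
  )
}

#' Evaluate a frozen classifier on a labelled test set
#'
#' Applies the model prospectively (test data never update the training
#' statistics) and tallies the confusion matrix and accuracy.
#'
#' @param model An `mrs_lda`.
#' @param data Test data frame containing the feature columns and the truth
#'   label column.
#' @param label Truth column name.
#' @return A list of class `mrs_lda_eval`: elements of
#'   [classification_accuracy()] plus `predictions` (per-case tibble with
#'   posteriors and truth).
#' @export
evaluate_classifier <- function(model, data, label = "tumour_type") {
  stopifnot(label %in% names(data), nrow(data) > 0)
  preds <- apply_lda(model, data)
  preds$truth <- as.character(data[[label]])
  acc <- classification_accuracy(preds$truth, preds$predicted)
  structure(c(acc, list(predictions = preds)), class = "mrs_lda_eval")
}

#' @export
print.mrs_lda_eval <- function(x, ...) {
  cat(sprintf("<mrs_lda_eval> accuracy %d%% (%d/%d)\n",
              x$accuracy_pct, x$n_correct, x$n_total))
  print(x$confusion)
  invisible(x)
}

#' @export
glance.mrs_lda_eval <- function(x, ...) {
  tibble(
    accuracy_pct = x$accuracy_pct, accuracy_exact = x$accuracy_exact,
    n_correct = x$n_correct, n_total = x$n_total
  )
}

#' @export
tidy.mrs_lda <- function(x, ...) {
  out <- as_tibble(x$class_means, .name_repair = "minimal")
  names(out) <- x$features
  out <- mutate(out, class = x$classes, prior = as.numeric(x$priors), .before = 1)
  tidyr::pivot_longer(out, cols = -c("class", "prior"),
                      names_to = "feature", values_to = "standardized_mean")
}

#' @export
glance.mrs_lda <- function(x, ...) {
  tibble(
    n = x$n, n_features = length(x$features),
    n_classes = length(x$classes), lambda = x$lambda,
    n_df_axes = ncol(x$proj)
  )
}
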