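test_that("standardization uses training statistics exactly", {
  coh <- gaussian_cohort(20, list(c(0, 0, 0), c(3, 0, 1), c(0, 3, 2)), seed = 2)
  model <- train_lda(coh, lambda = 0)
  mu_row <- as.data.frame(as.list(model$mu))
  expect_equal(as.numeric(standardize_features(model, mu_row)),
               rep(0, 3))
  one_row <- as.data.frame(as.list(model$mu + model$sigma))
  expect_equal(as.numeric(standardize_features(model, one_row)),
               rep(1, 3))
  Z <- standardize_features(model, coh)
  expect_equal(colMeans(Z), setNames(rep(0, 3), model$features),
               tolerance = 1e-12)
  expect_equal(apply(Z, 2, sd), setNames(rep(1, 3), model$features),
               tolerance = 1e-12)
})

test_that("well-separated spherical classes are learnt perfectly", {
  means <- list(c(0, 0, 0, 0), c(10, 0, 0, 0), c(0, 10, 0, 0))
  coh <- gaussian_cohort(50, means, sd = 1, seed = 3)
  model <- train_lda(coh, lambda = 0)
  ev <- evaluate_classifier(model, coh)
  expect_equal(ev$accuracy_pct, 100)
})

test_that("equal class means give posteriors equal to the priors", {
  coh <- gaussian_cohort(30, list(c(0, 0), c(0, 0), c(0, 0)), seed = 4)
  model <- train_lda(coh, prior = c(EP = 0.5, MB = 0.3, PA = 0.2),
                     lambda = 0.1)
  model$class_means[] <- 0   # exact equality of standardized class means
  model$W <- model$Sigma_inv %*% t(model$class_means)
  model$b <- -0.5 * colSums(t(model$class_means) * model$W) + log(model$priors)
  pred <- apply_lda(model, coh[1:5, ])
  for (i in 1:5) {
    expect_equal(as.numeric(pred[i, c("post_EP", "post_MB", "post_PA")]),
                 c(0.5, 0.3, 0.2), tolerance = 1e-12)
  }
})

test_that("three classes span exactly two canonical axes", {
  coh <- gaussian_cohort(20, list(c(0, 0, 0, 0, 0), c(3, 1, 0, 0, 0),
                                  c(0, 0, 2, 1, 0)), seed = 5)
  model <- train_lda(coh)
  expect_equal(ncol(model$proj), 2)
  expect_named(model$train_scores, c("subject", "label", "DF1", "DF2"))
})

test_that("posteriors match brute-force Gaussian class densities", {
  coh <- gaussian_cohort(40, list(c(0, 0, 0), c(2.5, 1, 0), c(0, 2, 1.5)),
                         seed = 6)
  model <- train_lda(coh, lambda = 0.1)
  set.seed(7)
  X <- matrix(rnorm(100 * 3, sd = 2), 100, 3)
  newdata <- as.data.frame(X)
  names(newdata) <- model$features
  pred <- apply_lda(model, newdata)
  Z <- standardize_features(model, newdata)
  Sigma <- model$Sigma
  dens <- sapply(seq_along(model$classes), function(k) {
    m <- model$class_means[k, ]
    apply(Z, 1, function(z) {
      exp(-0.5 * t(z - m) %*% solve(Sigma) %*% (z - m)) *
        model$priors[k] / sqrt(det(2 * pi * Sigma))
    })
  })
  post_bf <- dens / rowSums(dens)
  for (k in seq_along(model$classes)) {
    expect_equal(pred[[paste0("post_", model$classes[k])]], post_bf[, k],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("a Mahalanobis-equidistant point gets posteriors of one third", {
  # symmetric simplex of class means around the origin, identity covariance
  coh <- gaussian_cohort(25, list(c(1, 0), c(-0.5, sqrt(3) / 2),
                                  c(-0.5, -sqrt(3) / 2)), seed = 8)
  model <- train_lda(coh, lambda = 0)
  # force the exactly symmetric configuration
  model$class_means <- rbind(c(1, 0), c(-0.5, sqrt(3) / 2),
                             c(-0.5, -sqrt(3) / 2))
  model$Sigma <- diag(2)
  model$Sigma_inv <- diag(2)
  model$W <- model$Sigma_inv %*% t(model$class_means)
  model$b <- -0.5 * colSums(t(model$class_means) * model$W) + log(model$priors)
  origin <- as.data.frame(as.list(model$mu))  # standardizes to (0, 0)
  pred <- apply_lda(model, origin)
  expect_equal(as.numeric(pred[, c("post_EP", "post_MB", "post_PA")]),
               rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("posteriors always sum to one", {
  coh <- gaussian_cohort(15, list(c(0, 0, 0), c(4, 1, 0), c(1, 3, 2)),
                         seed = 9)
  model <- train_lda(coh)
  set.seed(10)
  X <- as.data.frame(matrix(rnorm(200 * 3, sd = 5), 200, 3))
  names(X) <- model$features
  pred <- apply_lda(model, X)
  sums <- pred$post_EP + pred$post_MB + pred$post_PA
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("decision boundaries sit where the top-two posteriors are equal", {
  coh <- gaussian_cohort(30, list(c(0, 0, 0), c(3, 1, 0), c(0, 3, 1)),
                         seed = 11)
  model <- train_lda(coh)
  bnd <- decision_boundaries(model, n = 150)
  expect_gt(nrow(bnd), 0)
  dm <- model$df_class_means
  for (i in sample(nrow(bnd), min(25, nrow(bnd)))) {
    d <- as.numeric(bnd[i, c("DF1", "DF2")])
    g <- as.numeric(dm %*% d - 0.5 * rowSums(dm^2) + log(model$priors))
    p <- exp(g - max(g)); p <- p / sum(p)
    top2 <- sort(p, decreasing = TRUE)[1:2]
    expect_lt(abs(top2[1] - top2[2]), 1e-6)
  }
})

test_that("two-class boundary with equal priors bisects the projected means", {
  coh <- gaussian_cohort(40, list(c(0, 0), c(4, 0), c(0, 4)), seed = 12)
  model <- train_lda(coh, lambda = 0)
  bnd <- decision_boundaries(model, n = 400)
  dm <- model$df_class_means
  for (pr in unique(bnd$pair)) {
    ix <- match(strsplit(pr, "-")[[1]], model$classes)
    mid <- colMeans(dm[ix, ])
    u <- dm[ix[1], ] - dm[ix[2], ]
    pts <- as.matrix(bnd[bnd$pair == pr, c("DF1", "DF2")])
    # all boundary points are equidistant from the two projected means
    along <- (pts - matrix(mid, nrow(pts), 2, byrow = TRUE)) %*% u
    expect_lt(max(abs(along)), 1e-8)
  }
})

test_that("changing priors shifts the boundary by the log-odds offset", {
  coh <- gaussian_cohort(40, list(c(0, 0), c(4, 0), c(0, 4)), seed = 13)
  m_eq <- train_lda(coh, lambda = 0, prior = "uniform")
  pri <- c(EP = 0.7, MB = 0.2, PA = 0.1)
  m_sk <- train_lda(coh, lambda = 0, prior = pri)
  dm <- m_eq$df_class_means
  u <- dm[1, ] - dm[2, ]   # EP vs MB direction in DF space
  # boundary: d.u = c; with priors, c shifts by -log(pi_EP/pi_MB)
  c_eq <- 0.5 * (sum(dm[1, ]^2) - sum(dm[2, ]^2))
  c_sk <- c_eq - (log(pri[["EP"]]) - log(pri[["MB"]]))
  b_eq <- decision_boundaries(m_eq, n = 500)
  b_sk <- decision_boundaries(m_sk, n = 500)
  p_eq <- as.matrix(b_eq[b_eq$pair == "EP-MB", c("DF1", "DF2")])
  p_sk <- as.matrix(b_sk[b_sk$pair == "EP-MB", c("DF1", "DF2")])
  expect_lt(max(abs(p_eq %*% u - c_eq)), 1e-8)
  expect_lt(max(abs(p_sk %*% u - c_sk)), 1e-8)
})

test_that("accuracy reporting matches the printed worked examples", {
  # 30 of 33 correct rounds (half-up) to 91%
  truth <- rep("A", 33)
  pred <- c(rep("A", 30), rep("B", 3))
  acc <- classification_accuracy(truth, pred)
  expect_equal(acc$accuracy_pct, 91)
  expect_equal(acc$accuracy_exact, 100 * 30 / 33)
  # all correct
  expect_equal(classification_accuracy(truth, truth)$accuracy_pct, 100)
})

test_that("the confusion matrix equals a brute-force tally", {
  set.seed(14)
  labs <- c("EP", "MB", "PA")
  truth <- sample(labs, 60, replace = TRUE)
  pred <- sample(labs, 60, replace = TRUE)
  conf <- classification_accuracy(truth, pred)$confusion
  for (a in labs) {
    for (b in labs) {
      expect_equal(conf[a, b], sum(truth == a & pred == b))
    }
  }
})

test_that("prospective evaluation never mutates the frozen model", {
  coh <- gaussian_cohort(20, list(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                         seed = 15)
  model <- train_lda(coh)
  snapshot <- unserialize(serialize(model, NULL))
  test_set <- gaussian_cohort(50, list(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                              seed = 16)
  invisible(evaluate_classifier(model, test_set))
  invisible(apply_lda(model, test_set))
  expect_identical(model, snapshot)
})

test_that("the in-package LDA agrees with an independent reference fit", {
  coh <- gaussian_cohort(30, list(c(0, 0, 0), c(2, 1, 0), c(0, 2, 1)),
                         seed = 17)
  model <- train_lda(coh, lambda = 0)
  ref <- MASS::lda(tumour_type ~ ., data = coh, prior = rep(1 / 3, 3))
  test_set <- gaussian_cohort(40, list(c(0, 0, 0), c(2, 1, 0), c(0, 2, 1)),
                              seed = 18)
  ours <- apply_lda(model, test_set)
  theirs <- predict(ref, test_set)
  expect_equal(ours$predicted, as.character(theirs$class))
  expect_equal(unname(as.matrix(ours[, c("post_EP", "post_MB", "post_PA")])),
               unname(theirs$posterior), tolerance = 1e-8)
})

test_that("held-out accuracy on model-consistent cohorts reaches the Bayes rate", {
  p <- 6
  means <- list(rep(0, p), c(2.2, 1.2, rep(0, p - 2)), c(0, 0, 2.0, 1.0, 0, 0))
  train <- gaussian_cohort(150, means, sd = 1, seed = 19)
  test <- gaussian_cohort(2000, means, sd = 1, seed = 20)
  model <- train_lda(train, lambda = 0)
  acc <- evaluate_classifier(model, test)$accuracy_exact
  # Monte-Carlo Bayes rate: classify with the true generative parameters
  X <- as.matrix(test[, 1:p])
  g <- sapply(means, function(m) {
    -0.5 * rowSums(sweep(X, 2, m)^2)
  })
  bayes_pred <- c("EP", "MB", "PA")[max.col(g)]
  bayes_acc <- 100 * mean(bayes_pred == test$tumour_type)
  expect_lt(abs(acc - bayes_acc), 3)
})

test_that("lipid-shifted test ependymomas lose recall (directional)", {
  # grade-3-like EPs have higher lipids; shifting the EP test mean toward
  # the lipid axis must reduce EP recall relative to unshifted EPs
  cps <- default_class_params()
  train <- sample_cohort(cps, c(PA = 30, EP = 30, MB = 30), seed = 21,
                         simulate_fids = FALSE)
  feat <- function(coh) {
    wide <- as.data.frame(do.call(rbind, coh$profile))
    wide$tumour_type <- coh$tumour_type
    wide
  }
  model <- train_lda(feat(train), label = "tumour_type", lambda = 0.1)
  ep_only <- sample_cohort(cps["EP"], c(EP = 120), seed = 22,
                           simulate_fids = FALSE)
  base <- feat(ep_only)
  shifted <- base
  shifted$Lip13a <- shifted$Lip13a + 3
  shifted$Lip13b <- shifted$Lip13b + 2
  shifted$MM14 <- shifted$MM14 + 1
  recall <- function(df) {
    mean(apply_lda(model, df)$predicted == "EP")
  }
  expect_lt(recall(shifted), recall(base))
})
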