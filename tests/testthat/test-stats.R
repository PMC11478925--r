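cert_row <- function(rater, case, stage, pa, ep, mb, truth) {
  tibble::tibble(rater = rater, case = case, stage = stage,
                 cert_PA = pa, cert_EP = ep, cert_MB = mb, truth = truth)
}

# table with a known number of >50% correct answers for one rater/stage
make_acc_table <- function(n_correct, n_total, stage = "imaging",
                           rater = "rad1") {
  rows <- lapply(seq_len(n_total), function(i) {
    if (i <= n_correct) {
      cert_row(rater, sprintf("C%02d", i), stage, 70, 20, 10, "PA")
    } else {
      cert_row(rater, sprintf("C%02d", i), stage, 30, 60, 10, "PA")
    }
  })
  dplyr::bind_rows(rows)
}

test_that("accuracy reproduces the printed worked examples", {
  expect_equal(diagnostic_accuracy(make_acc_table(14, 33))$accuracy_pct, 42)
  expect_equal(diagnostic_accuracy(make_acc_table(29, 33))$accuracy_pct, 88)
  expect_equal(diagnostic_accuracy(make_acc_table(30, 33))$accuracy_pct, 91)
})

test_that("a certainty of exactly 50 is counted incorrect (strict rule)", {
  tbl <- cert_row("r", "c1", "imaging", 50, 25, 25, "PA")
  expect_equal(diagnostic_accuracy(tbl)$n_correct, 0)
  tbl2 <- cert_row("r", "c1", "imaging", 50.5, 24.5, 25, "PA")
  expect_equal(diagnostic_accuracy(tbl2)$n_correct, 1)
})

test_that("accuracy counting matches a brute-force loop on random tables", {
  set.seed(30)
  for (rep in 1:5) {
    n <- 40
    raw <- matrix(runif(3 * n), n)
    certs <- 100 * raw / rowSums(raw)
    truth <- sample(c("PA", "EP", "MB"), n, replace = TRUE)
    tbl <- tibble::tibble(
      rater = "r", case = sprintf("C%02d", 1:n), stage = "imaging",
      cert_PA = certs[, 1], cert_EP = certs[, 2], cert_MB = certs[, 3],
      truth = truth
    )
    acc <- diagnostic_accuracy(tbl)
    brute <- 0
    for (i in 1:n) {
      ct <- certs[i, match(truth[i], c("PA", "EP", "MB"))]
      if (ct > 50) brute <- brute + 1
    }
    expect_equal(acc$n_correct, brute)
  }
})

test_that("certainty-when-correct uses the highest-certainty predicate", {
  tbl <- dplyr::bind_rows(
    cert_row("r", "c1", "imaging", 40, 35, 25, "PA"),  # correct, <= 50
    cert_row("r", "c2", "imaging", 80, 10, 10, "PA"),  # correct
    cert_row("r", "c3", "imaging", 20, 60, 20, "PA"),  # incorrect
    cert_row("r", "c4", "imaging", 40, 40, 20, "PA")   # tie -> incorrect
  )
  cs <- certainty_summary(tbl)
  corr <- cs[cs$correct, ]
  inc <- cs[!cs$correct, ]
  expect_equal(corr$n, 2)
  expect_equal(corr$mean_certainty, 60)  # mean of 40 and 80
  expect_equal(inc$n, 2)
  expect_equal(inc$mean_certainty, 30)   # truth-class certainties 20 and 40
  # a single correct case at 80 has mean 80 and SD 0
  single <- certainty_summary(cert_row("r", "c1", "imaging", 80, 15, 5, "PA"))
  expect_equal(single$mean_certainty, 80)
  expect_true(is.na(single$sd_certainty) || single$sd_certainty == 0)
})

test_that("the two correctness predicates differ exactly on truth-max <= 50 cases", {
  set.seed(31)
  n <- 200
  raw <- matrix(runif(3 * n), n)
  certs <- 100 * raw / rowSums(raw)
  truth <- sample(c("PA", "EP", "MB"), n, replace = TRUE)
  tbl <- tibble::tibble(
    rater = "r", case = sprintf("C%03d", 1:n), stage = "imaging",
    cert_PA = certs[, 1], cert_EP = certs[, 2], cert_MB = certs[, 3],
    truth = truth
  )
  ct <- certs[cbind(1:n, match(truth, c("PA", "EP", "MB")))]
  other_max <- sapply(1:n, function(i) max(certs[i, -match(truth[i], c("PA", "EP", "MB"))]))
  strict50 <- ct > 50
  truthmax <- ct > other_max
  # the predicates disagree precisely when the truth class is ranked first
  # with 50% or less
  disagree <- truthmax & !strict50
  expect_equal(sum(truthmax) - sum(strict50 & truthmax), sum(disagree))
  expect_true(all(strict50 == (truthmax & ct > 50))
              || sum(strict50 & !truthmax) == 0)
})

test_that("certainty changes are paired by case with deltas in range", {
  truth <- rep(c("PA", "EP", "MB"), 5)
  tbl <- sample_certainty_table(truth, seed = 32)
  d <- certainty_change(tbl, "imaging", "imaging+MRS+DSS")
  expect_equal(nrow(d), length(truth) * 3)  # 3 raters
  expect_true(all(d$delta >= -100 & d$delta <= 100))
  d0 <- certainty_change(tbl, "imaging", "imaging")
  expect_true(all(d0$delta == 0))
  # a constructed shift is returned exactly
  t2 <- dplyr::bind_rows(
    cert_row("r", "c1", "imaging", 40, 30, 30, "PA"),
    cert_row("r", "c1", "imaging+MRS", 55, 20, 25, "PA")
  )
  expect_equal(certainty_change(t2, "imaging", "imaging+MRS")$delta, 15)
  # unpaired cases error
  t3 <- dplyr::bind_rows(t2, cert_row("r", "c2", "imaging", 50, 25, 25, "EP"))
  expect_error(certainty_change(t3, "imaging", "imaging+MRS"), "unpaired")
})

test_that("six positive distinct deltas give the exact sign-test p-values", {
  d <- c(3, 7, 12, 18, 25, 40)
  res <- wilcoxon_signed_rank(d, mode = "exact")
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 2 / 64)
})

test_that("exactly symmetric deltas give a two-sided p of 1", {
  d <- c(5, -5, 11, -11, 23, -23)
  res <- wilcoxon_signed_rank(d, mode = "exact")
  expect_equal(res$p_value, 1)
})

test_that("exact and normal-approximation p agree at n = 15", {
  set.seed(33)
  d <- round(rnorm(15, mean = 4, sd = 10))
  d <- d[d != 0]
  pe <- wilcoxon_signed_rank(d, mode = "exact")$p_value
  pn <- wilcoxon_signed_rank(d, mode = "normal")$p_value
  expect_lt(abs(pe - pn), 0.02)
})

test_that("exact enumeration matches the reference signed-rank test", {
  set.seed(34)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n, mean = 2, sd = 6), 1)
    d <- d[d != 0]
    if (length(d) < 3 || length(unique(abs(d))) < length(d)) next
    ours <- wilcoxon_signed_rank(d, mode = "exact")
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("the Hodges-Lehmann estimate matches the reference implementation", {
  set.seed(35)
  d <- rnorm(20, 3, 5)
  ours <- wilcoxon_signed_rank(d)
  ref <- suppressWarnings(stats::wilcox.test(d, conf.int = TRUE))
  expect_equal(ours$median, unname(ref$estimate), tolerance = 1e-9)
})

test_that("Pratt zero handling keeps zeros in the ranking", {
  d <- c(0, 0, 1, 2, 3)
  res <- wilcoxon_signed_rank(d, zero_policy = "pratt", mode = "exact")
  # ranks of |deltas| incl. zeros: zeros get 1.5, others 3, 4, 5
  expect_equal(res$statistic, 12)
  expect_equal(res$n_used, 3)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
})

test_that("identical groups give a Levene statistic of 0 and p of 1", {
  g <- rep(c("a", "b"), each = 6)
  x <- rep(c(1, 5, 9, 2, 4, 8), 2)
  res <- levene_test(x, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("a 4/4 two-group Levene example matches the direct formula", {
  x <- c(1, 2, 6, 9, 2, 4, 4, 11)
  g <- rep(c("a", "b"), each = 4)
  res <- levene_test(x, g, center = "median")
  # Brown-Forsythe by hand: deviations from group medians, one-way ANOVA F
  dev <- abs(x - ave(x, g, FUN = median))
  n <- 8; k <- 2
  gm <- mean(dev)
  mg <- tapply(dev, g, mean)
  ssb <- sum(4 * (mg - gm)^2)
  ssw <- sum((dev - ave(dev, g))^2)
  f_hand <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$statistic, f_hand, tolerance = 1e-12)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 6)
})

test_that("inflating one group's spread strictly increases the Levene statistic", {
  set.seed(36)
  x1 <- rnorm(10); x2 <- rnorm(10)
  g <- rep(c("a", "b"), each = 10)
  f1 <- levene_test(c(x1, x2), g)$statistic
  f2 <- levene_test(c(x1, 5 * x2), g)$statistic
  expect_gt(f2, f1)
})

test_that("Kruskal-Wallis on {1,2,3} vs {4,5,6} matches the closed form", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # tie-free H = 12/(N(N+1)) * sum n_i rbar_i^2 - 3(N+1)
  h_hand <- 12 / (6 * 7) * (3 * 2^2 + 3 * 5^2) - 3 * 7
  expect_equal(res$statistic, h_hand, tolerance = 1e-12)
  expect_equal(h_hand, 27 / 7, tolerance = 1e-12)
})

test_that("identically distributed group contents give H of 0", {
  res <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_error(kruskal_wallis(rep(1, 6), rep(c("a", "b"), each = 3)),
               "identical")
})

test_that("the exact Kruskal-Wallis p matches a permutation oracle at n = 10", {
  set.seed(37)
  diffs <- numeric(0)
  for (rep in 1:5) {
    x <- rnorm(10)
    g <- rep(c("a", "b", "c"), c(3, 3, 4))  # three groups, as in the cohort
    res <- kruskal_wallis(x, g, exact = TRUE)
    expect_false(is.na(res$p_exact))
    # independent Monte-Carlo permutation oracle
    h_obs <- res$statistic
    hs <- replicate(4000, stats::kruskal.test(x, factor(sample(g)))$statistic)
    p_mc <- mean(hs >= h_obs - 1e-12)
    expect_lt(abs(res$p_exact - p_mc), 0.03)
    diffs <- c(diffs, abs(res$p_exact - res$p_value))
  }
  # the chi-square approximation tracks the exact p at this sample size
  expect_lt(median(diffs), 0.05)
})

test_that("identical groups give ANOVA F near 0 and adjusted p of 1", {
  df <- tibble::tibble(
    m1 = rep(c(1, 2, 3, 4), 3),
    tumour_type = rep(c("PA", "EP", "MB"), each = 4)
  )
  res <- metabolite_group_comparison(df)
  expect_lt(res$anova$f_statistic, 1e-20)
  expect_true(all(res$pairwise$p_adjusted == 1))
})

test_that("a 3-sigma group separation is detected with high power", {
  hits <- 0
  for (rep in 1:100) {
    set.seed(500 + rep)
    df <- tibble::tibble(
      m = c(rnorm(20, 0, 1), rnorm(20, 3, 1)),
      tumour_type = rep(c("PA", "MB"), each = 20)
    )
    p <- metabolite_group_comparison(df)$anova$p_value
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("the ANOVA F matches a long-hand mean-square ratio", {
  x1 <- c(3, 5, 7); x2 <- c(2, 4, 9); x3 <- c(10, 12, 11)
  df <- tibble::tibble(m = c(x1, x2, x3),
                       tumour_type = rep(c("A", "B", "C"), each = 3))
  res <- metabolite_group_comparison(df)$anova
  gm <- mean(c(x1, x2, x3))
  ssb <- 3 * ((mean(x1) - gm)^2 + (mean(x2) - gm)^2 + (mean(x3) - gm)^2)
  ssw <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2) + sum((x3 - mean(x3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$f_statistic, f_hand, tolerance = 1e-12)
})

test_that("reader-study statistics are invariant under case reordering", {
  truth <- rep(c("PA", "EP", "MB"), 6)
  tbl <- sample_certainty_table(truth, seed = 38)
  perm <- sample(nrow(tbl))
  tblp <- tbl[perm, ]
  expect_equal(diagnostic_accuracy(tbl), diagnostic_accuracy(tblp))
  expect_equal(certainty_summary(tbl), certainty_summary(tblp))
  d1 <- dplyr::arrange(certainty_change(tbl, "imaging", "imaging+MRS"),
                       rater, case)
  d2 <- dplyr::arrange(certainty_change(tblp, "imaging", "imaging+MRS"),
                       rater, case)
  expect_equal(d1, d2)
})

test_that("a reader study in the published regime yields p < 0.001 reliably", {
  hits <- 0
  for (rep in 1:20) {
    tbl <- sample_certainty_table(
      rep(c("PA", "EP", "MB"), length.out = 33),
      stage_effects = c(0, 8, 7), n_raters = 1, seed = 900 + rep
    )
    d <- certainty_change(tbl, "imaging", "imaging+MRS+DSS")
    p <- wilcoxon_signed_rank(d$delta)$p_value
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the reader-study summary has the accuracy/certainty shape", {
  truth <- rep(c("PA", "EP", "MB"), 11)
  tbl <- sample_certainty_table(truth, seed = 39)
  s <- reader_study_summary(tbl)
  expect_equal(nrow(s), 9)  # 3 raters x 3 stages
  expect_true(all(c("accuracy_pct", "mean_certainty_correct",
                    "mean_certainty_incorrect") %in% names(s)))
})
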