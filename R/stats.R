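cert_col <- function(class) paste0("cert_", class)

check_certainty_table <- function(tbl) {
  need <- c("rater", "case", "stage", "cert_PA", "cert_EP", "cert_MB", "truth")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(paste0("certainty table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  sums <- tbl$cert_PA + tbl$cert_EP + tbl$cert_MB
  if (any(abs(sums - 100) > 1e-6)) abort("certainty triples must sum to 100")
  invisible(tbl)
}

truth_certainty <- function(tbl) {
  m <- as.matrix(tbl[, cert_col(TUMOUR_TYPES)])
  m[cbind(seq_len(nrow(tbl)), match(tbl$truth, TUMOUR_TYPES))]
}

#' Diagnostic accuracy under the strict >50% certainty rule
#'
#' A diagnosis counts as correct only when the certainty assigned to the
#' true class is strictly greater than 50% (a certainty of exactly 50 is
#' incorrect). Accuracy is the percentage of correct diagnoses, rounded
#' half-up, with the exact fraction retained.
#'
#' @param tbl Certainty table: columns `rater`, `case`, `stage`, `cert_PA`,
#'   `cert_EP`, `cert_MB`, `truth`.
#' @param raters,stages Optional filters; default: all present, summarised
#'   per rater x stage.
#' @return Tibble: `rater`, `stage`, `n_correct`, `n_total`, `accuracy_pct`,
#'   `accuracy_exact`.
#' @export
diagnostic_accuracy <- function(tbl, raters = NULL, stages = NULL) {
  check_certainty_table(tbl)
  if (!is.null(raters)) tbl <- filter(tbl, .data$rater %in% raters)
  if (!is.null(stages)) tbl <- filter(tbl, .data$stage %in% stages)
  if (!nrow(tbl)) abort("no rows for the requested rater/stage")
  tbl$..ct <- truth_certainty(tbl)
  tbl |>
    group_by(.data$rater, .data$stage) |>
    summarise(
      n_correct = sum(.data$..ct > 50),
      n_total = n(),
      .groups = "drop"
    ) |>
    mutate(
      accuracy_pct = round_half_up(100 * .data$n_correct / .data$n_total),
      accuracy_exact = 100 * .data$n_correct / .data$n_total
    )
}

#' Mean certainty when the diagnosis was correct / incorrect
#'
#' Here "correct" means the truth class received the strictly highest
#' certainty — even when that certainty was 50% or less — which is a
#' deliberately different predicate from the strict >50% accuracy rule;
#' ties count as incorrect. Summaries are the mean and SD of the
#' truth-class certainty within each stratum.
#'
#' @inheritParams diagnostic_accuracy
#' @return Tibble: `rater`, `stage`, `correct` (logical stratum), `n`,
#'   `mean_certainty`, `sd_certainty` (NA when the stratum is empty or has
#'   a single case for SD).
#' @export
certainty_summary <- function(tbl, raters = NULL, stages = NULL) {
  check_certainty_table(tbl)
  if (!is.null(raters)) tbl <- filter(tbl, .data$rater %in% raters)
  if (!is.null(stages)) tbl <- filter(tbl, .data$stage %in% stages)
  m <- as.matrix(tbl[, cert_col(TUMOUR_TYPES)])
  ct <- truth_certainty(tbl)
  other_max <- vapply(seq_len(nrow(tbl)), function(i) {
    max(m[i, -match(tbl$truth[i], TUMOUR_TYPES)])
  }, numeric(1))
  tbl$..correct <- ct > other_max   # strict maximum; ties -> incorrect
  tbl$..ct <- ct
  tbl |>
    group_by(.data$rater, .data$stage, correct = .data$..correct) |>
    summarise(
      n = n(),
      mean_certainty = mean(.data$..ct),
      sd_certainty = sd(.data$..ct),
      .groups = "drop"
    )
}

#' Per-case change in truth-class certainty between two stages
#'
#' @param tbl Certainty table.
#' @param from_stage,to_stage Stage labels; the delta is
#'   `certainty_truth(to) - certainty_truth(from)`, paired by rater and
#'   case id.
#' @return Tibble: `rater`, `case`, `truth`, `delta` (in percentage points,
#'   necessarily within \[-100, 100\]).
#' @export
certainty_change <- function(tbl, from_stage, to_stage) {
  check_certainty_table(tbl)
  a <- filter(tbl, .data$stage == from_stage)
  b <- filter(tbl, .data$stage == to_stage)
  a$..ct <- truth_certainty(a)
  b$..ct <- truth_certainty(b)
  j <- dplyr::inner_join(
    select(a, "rater", "case", "truth", from = "..ct"),
    select(b, "rater", "case", to = "..ct"),
    by = c("rater", "case")
  )
  if (nrow(j) != nrow(a) || nrow(j) != nrow(b)) {
    abort("unpaired case(s) between the two stages")
  }
  mutate(j, delta = .data$to - .data$from) |>
    select("rater", "case", "truth", "delta")
}

# exact two-sided signed-rank p by full 2^n sign enumeration (handles ties
# in the ranks); W = sum of ranks of positive values
signed_rank_enumeration_p <- function(ranks, w_obs) {
  n <- length(ranks)
  mu <- sum(ranks) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% ranks)
  mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Wilcoxon signed-rank test for paired certainty changes
#'
#' Tests whether the median change differs from zero. Zeros are dropped
#' (Wilcoxon's rule) or retained in the ranking (Pratt) according to
#' `zero_policy`. The null distribution is computed by exact enumeration of
#' all `2^n` sign assignments (valid under ties) when the effective n is at
#' most `exact_limit`, and by the normal approximation with tie correction
#' and continuity correction otherwise. The Hodges-Lehmann pseudo-median of
#' the deltas and its Walsh-average confidence interval are reported.
#'
#' @param deltas Numeric vector of paired differences.
#' @param zero_policy `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit Largest effective n for which `"auto"` enumerates.
#' @param conf_level Confidence level for the Hodges-Lehmann interval.
#' @return Tibble: `statistic` (V, sum of positive ranks), `p_value`,
#'   `method`, `n_used`, `median` (Hodges-Lehmann), `conf_low`, `conf_high`.
#' @export
wilcoxon_signed_rank <- function(deltas, zero_policy = c("wilcoxon", "pratt"),
                                 mode = c("auto", "exact", "normal"),
                                 exact_limit = 15, conf_level = 0.95) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  deltas <- deltas[!is.na(deltas)]
  nonzero <- deltas != 0
  if (!any(nonzero)) abort("all deltas are zero")

  if (zero_policy == "wilcoxon") {
    d <- deltas[nonzero]
    r <- rank(abs(d))
  } else {
    d <- deltas
    r_all <- rank(abs(d))
    keep <- d != 0
    d <- d[keep]
    r <- r_all[keep]
  }
  n <- length(d)
  V <- sum(r[d > 0])
  mu <- sum(r) / 2

  use_exact <- mode == "exact" || (mode == "auto" && n <= exact_limit)
  if (use_exact && n > 20) abort("exact enumeration limited to n <= 20")
  if (use_exact) {
    p <- signed_rank_enumeration_p(r, V)
    method <- "exact enumeration"
  } else {
    sig2 <- sum(r^2) / 4
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    p <- min(p, 1)
    method <- "normal approximation"
  }

  # Hodges-Lehmann pseudo-median and Walsh-average CI (on all deltas)
  walsh <- outer(deltas, deltas, "+")[upper.tri(diag(length(deltas)), diag = TRUE)] / 2
  walsh <- sort(walsh)
  hl <- median(walsh)
  nn <- length(deltas)
  alpha <- 1 - conf_level
  k <- stats::qsignrank(alpha / 2, nn)
  lo <- if (k + 1 >= 1 && k + 1 <= length(walsh)) walsh[k + 1] else min(walsh)
  hi <- if (length(walsh) - k >= 1) walsh[length(walsh) - k] else max(walsh)
  tibble(
    statistic = V, p_value = p, method = method, n_used = n,
    median = hl, conf_low = lo, conf_high = hi
  )
}

#' Levene's test for equality of variability across groups
#'
#' Brown-Forsythe variant by default: absolute deviations from the group
#' median are compared by one-way ANOVA. The classical mean-centred variant
#' is available via `center = "mean"`.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (coerced to factor), same length.
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"`.
#' @return Tibble: `statistic` (F), `df1`, `df2`, `p_value`, `center`.
#' @export
levene_test <- function(values, group, center = c("median", "mean")) {
  center <- match.arg(center)
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (nlevels(group) < 2) abort("need at least 2 groups")
  if (any(table(group) < 2)) abort("each group needs at least 2 values")
  centre_fun <- if (center == "median") median else mean
  dev <- abs(values - ave(values, group, FUN = centre_fun))
  if (all(dev == 0)) {
    return(tibble(
      statistic = 0, df1 = nlevels(group) - 1,
      df2 = length(values) - nlevels(group), p_value = 1, center = center
    ))
  }
  fit <- anova(lm(dev ~ group))
  tibble(
    statistic = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
    p_value = fit$`Pr(>F)`[1], center = center
  )
}

# all distinct assignments of n items to groups of given sizes
enumerate_group_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  recurse <- function(remaining, labels_so_far, gi) {
    if (gi > length(sizes)) {
      out[[length(out) + 1]] <<- labels_so_far
      return(invisible())
    }
    if (gi == length(sizes)) {
      lab <- labels_so_far
      lab[remaining] <- gi
      out[[length(out) + 1]] <<- lab
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (pk in picks) {
      lab <- labels_so_far
      lab[pk] <- gi
      recurse(setdiff(remaining, pk), lab, gi + 1)
    }
  }
  recurse(seq_len(n), integer(n), 1)
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' The tie-corrected H statistic and chi-square p-value come from
#' [stats::kruskal.test()]. For small samples (total n at most
#' `exact_limit`) an exact permutation p-value can be computed by
#' enumerating all assignments of the observed values to groups of the
#' observed sizes.
#'
#' @param values Numeric vector.
#' @param group Grouping vector, same length.
#' @param exact Logical; also compute the exact enumeration p-value.
#' @param exact_limit Maximum total n for enumeration (default 10).
#' @return Tibble: `statistic` (H), `df`, `p_value` (chi-square),
#'   `p_exact` (NA unless requested).
#' @export
kruskal_wallis <- function(values, group, exact = FALSE, exact_limit = 10) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (nlevels(group) < 2) abort("need at least 2 groups")
  if (length(unique(values)) == 1) abort("all values identical")
  kt <- stats::kruskal.test(values, group)
  p_exact <- NA_real_
  if (exact) {
    if (length(values) > exact_limit) {
      abort(sprintf("exact enumeration limited to total n <= %d", exact_limit))
    }
    sizes <- as.integer(table(group))
    h_of <- function(lab) {
      stats::kruskal.test(values, factor(lab))$statistic
    }
    h_obs <- kt$statistic
    assigns <- enumerate_group_assignments(sizes)
    hs <- vapply(assigns, h_of, numeric(1))
    p_exact <- mean(hs >= h_obs - 1e-12)
  }
  tibble(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, p_exact = p_exact
  )
}

#' Compare metabolite concentrations between groups
#'
#' Per metabolite: one-way ANOVA across groups, plus pairwise two-sample
#' t-tests with Bonferroni adjustment. Metabolites with zero variance are
#' reported as NA.
#'
#' @param data Data frame with one row per subject.
#' @param metabolites Character vector of metabolite columns; default: all
#'   numeric columns except the grouping column.
#' @param group Name of the grouping column.
#' @param p_adjust Adjustment method for the pairwise tests
#'   (default `"bonferroni"`).
#' @return A list of two tibbles: `anova` (`metabolite`, `f_statistic`,
#'   `df1`, `df2`, `p_value`) and `pairwise` (`metabolite`, `group1`,
#'   `group2`, `p_adjusted`).
#' @export
metabolite_group_comparison <- function(data, metabolites = NULL,
                                        group = "tumour_type",
                                        p_adjust = "bonferroni") {
  stopifnot(group %in% names(data))
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("each group needs at least 2 subjects")
  if (is.null(metabolites)) {
    metabolites <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], group)
  }
  anova_rows <- list()
  pw_rows <- list()
  for (m in metabolites) {
    v <- data[[m]]
    if (sd(v) == 0) {
      anova_rows[[m]] <- tibble(
        metabolite = m, f_statistic = NA_real_, df1 = NA_real_,
        df2 = NA_real_, p_value = NA_real_
      )
      next
    }
    ft <- anova(lm(v ~ g))
    anova_rows[[m]] <- tibble(
      metabolite = m, f_statistic = ft$`F value`[1],
      df1 = ft$Df[1], df2 = ft$Df[2], p_value = ft$`Pr(>F)`[1]
    )
    pt_ <- stats::pairwise.t.test(v, g, p.adjust.method = p_adjust,
                                  pool.sd = FALSE)
    pm <- pt_$p.value
    for (i in seq_len(nrow(pm))) {
      for (j in seq_len(ncol(pm))) {
        if (!is.na(pm[i, j])) {
          pw_rows[[length(pw_rows) + 1]] <- tibble(
            metabolite = m, group1 = colnames(pm)[j], group2 = rownames(pm)[i],
            p_adjusted = pm[i, j]
          )
        }
      }
    }
  }
  list(anova = bind_rows(anova_rows), pairwise = bind_rows(pw_rows))
}

#' Table-2-shaped summary of a reader study
#'
#' Combines [diagnostic_accuracy()] and [certainty_summary()] into one
#' accuracy-and-certainty table per rater and stage.
#'
#' @param tbl Certainty table.
#' @return Tibble with one row per rater x stage: accuracy, and mean (SD)
#'   truth-class certainty when correct and when incorrect.
#' @export
reader_study_summary <- function(tbl) {
  acc <- diagnostic_accuracy(tbl)
  cs <- certainty_summary(tbl)
  wide <- cs |>
    mutate(stratum = ifelse(.data$correct, "correct", "incorrect")) |>
    select("rater", "stage", "stratum", "mean_certainty", "sd_certainty") |>
    tidyr::pivot_wider(
      names_from = "stratum",
      values_from = c("mean_certainty", "sd_certainty")
    )
  left_join(acc, wide, by = c("rater", "stage"))
}
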