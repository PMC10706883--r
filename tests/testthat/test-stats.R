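test_that("group comparison gates on normality and behaves symmetrically", {
  x <- c(1, 2, 3, 4, 5)
  res <- compare_groups(x, x)
  expect_equal(res$p_value, 1)             # identical groups, mid-rank U
  set.seed(20)
  a <- rnorm(50); b <- rnorm(50, 2)
  r1 <- compare_groups(a, b)
  expect_lt(r1$p_value, 1e-4)
  expect_equal(r1$test, "t-test")
  r2 <- compare_groups(b, a)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  # heavy-tailed data fail the gate and fall to Mann-Whitney
  skew <- exp(rnorm(50, 0, 1.5))
  expect_equal(compare_groups(skew, skew + 0.1)$test, "mann-whitney")
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("Mann-Whitney p agrees with a permutation oracle", {
  set.seed(22)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  p_mw <- compare_groups(exp(a), exp(b))$p_value   # forced non-normal
  # permutation oracle on the rank-sum statistic
  pooled <- c(exp(a), exp(b))
  r <- rank(pooled)
  obs <- sum(r[1:30])
  n_perm <- 2e4
  perms <- replicate(n_perm, sum(r[sample(60, 30)]))
  p_perm <- mean(abs(perms - mean(r) * 30) >= abs(obs - mean(r) * 30))
  expect_lt(abs(p_mw - p_perm), max(0.01, 3 * sqrt(p_perm * (1 - p_perm) / n_perm)))
})

test_that("ROC AUC equals the exhaustive ordered-pair fraction and anti-symmetry holds", {
  set.seed(23)
  for (r in 1:30) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    scores <- sample(1:4, n1 + n0, replace = TRUE)   # heavy ties
    pos <- c(rep(TRUE, n1), rep(FALSE, n0))
    expected <- auc_pairs_oracle(scores, pos)
    got <- roc_auc(scores, pos, direction = ">", n_boot = 10, seed = 1)$auc
    expect_equal(got, expected, tolerance = 1e-12)
    neg <- roc_auc(-scores, pos, direction = ">", n_boot = 10, seed = 1)$auc
    expect_equal(neg, 1 - expected, tolerance = 1e-12)
  }
  perfect <- roc_auc(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     n_boot = 50, seed = 1)
  expect_equal(perfect$auc, 1)
})

test_that("ROC bootstrap CI brackets the estimate and the run is seed-reproducible", {
  set.seed(24)
  scores <- c(rnorm(20, 1), rnorm(25))
  labels <- c(rep(TRUE, 20), rep(FALSE, 25))
  r1 <- roc_auc(scores, labels, n_boot = 500, seed = 42)
  r2 <- roc_auc(scores, labels, n_boot = 500, seed = 42)
  expect_identical(glance(r1), glance(r2))
  expect_lte(r1$ci_lo, r1$auc); expect_gte(r1$ci_hi, r1$auc)
  expect_gte(r1$ci_lo, 0); expect_lte(r1$ci_hi, 1)
  # auto orientation flips an anti-predictive score
  flip <- roc_auc(-scores, labels, n_boot = 50, seed = 1)
  expect_equal(flip$direction, "<")
  expect_gte(flip$auc, 0.5)
  # independent cross-check against pROC
  pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(r1$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("Spearman equals Pearson on mid-ranks; correlation matrix is coherent", {
  set.seed(25)
  for (r in 1:100) {
    x <- sample(1:8, 30, replace = TRUE)   # ties
    y <- rnorm(30)
    expect_equal(cor(x, y, method = "spearman"),
                 cor(rank(x), rank(y), method = "pearson"), tolerance = 1e-12)
  }
  d <- tibble::tibble(x = rnorm(40))
  d$y <- 2 * d$x + 1
  d$z <- exp(rnorm(40, 0, 2))
  cm <- correlation_matrix(d)
  expect_equal(cm$estimate["x", "y"], 1, tolerance = 1e-12)
  expect_equal(cm$method["x", "y"], "pearson")
  expect_equal(cm$method["x", "z"], "spearman")   # z fails the normality gate
  td <- tidy(cm)
  expect_true(all(c("var1", "var2", "estimate", "p_value") %in% names(td)))
  expect_equal(nrow(td), 6)
})

test_that("slope correlations are Spearman, flag constants, and resist monotone transforms", {
  set.seed(26)
  d <- tibble::tibble(slope = rnorm(25),
                      m1 = rnorm(25),
                      const = 1)
  d$m2 <- exp(d$m1)   # monotone transform of m1
  sc <- slope_correlation(d)
  expect_true(is.na(sc$rho[sc$measure == "const"]))
  expect_equal(sc$rho[sc$measure == "m1"], sc$rho[sc$measure == "m2"],
               tolerance = 1e-12)
})

test_that("percentage changes, CV gating and polarity classification work cellwise", {
  labels <- tibble::tibble(subject_id = sprintf("S%d", 1:6),
                           label = rep(c("progressor", "stable"), each = 3))
  mk <- function(values) tidyr::expand_grid(subject_id = sprintf("S%d", 1:6),
                                            visit_year = 0:2) |>
    dplyr::mutate(measure = "t1_cortex", value = values)
  # baseline 100, year1 90 is a -10% change
  v <- rep(c(100, 90, 80), 6)
  rep1 <- pct_change_report(mk(v), labels)
  expect_s3_class(rep1, "change_report")
  y1 <- rep1[rep1$visit_year == 1, ]
  expect_true(all(y1$mean_pct == -10))
  # zero change everywhere is always no-change
  rep0 <- pct_change_report(mk(rep(100, 18)), labels)
  expect_true(all(rep0$category == "no-change"))
  # a T1 rise beyond the CV band is a decline (polarity +1), and the
  # category is invariant to unit rescaling
  set.seed(27)
  vals <- as.vector(replicate(6, 100 * c(1, 1.10, 1.20) *
                                (1 + rnorm(3, 0, 0.005))))
  repr <- pct_change_report(mk(vals), labels)
  expect_true(all(repr$category == "decline"))
  reps <- pct_change_report(mk(vals * 1e3), labels)
  expect_equal(repr$category, reps$category)
})

test_that("subjects missing a visit are excluded from the change report only", {
  labels <- tibble::tibble(subject_id = sprintf("S%d", 1:6),
                           label = rep(c("progressor", "stable"), each = 3))
  summ <- tidyr::expand_grid(subject_id = sprintf("S%d", 1:6),
                             visit_year = 0:2, measure = "tkv") |>
    dplyr::mutate(value = 100)
  drop_y2 <- summ[!(summ$subject_id == "S1" & summ$visit_year == 2), ]
  rep2 <- pct_change_report(drop_y2, labels)
  expect_true(all(rep2$n[rep2$label == "progressor"] == 2))
  rep_full <- pct_change_report(summ, labels)
  expect_true(all(rep_full$n[rep_full$label == "progressor"] == 3))
})

test_that("an injected progressive T1 drift is classified as decline in nearly all replicates", {
  set.seed(28)
  labels <- tibble::tibble(subject_id = sprintf("S%d", 1:9), label = "progressor")
  hits <- replicate(200, {
    base <- rnorm(9, 1500, 60)
    vals <- vapply(0:2, function(y) base * 1.08^y *
                     (1 + rnorm(9, 0, 0.03)), numeric(9))
    summ <- tidyr::expand_grid(subject_id = sprintf("S%d", 1:9),
                               visit_year = 0:2) |>
      dplyr::mutate(measure = "t1_cortex",
                    value = vals[cbind(match(subject_id, labels$subject_id),
                                       visit_year + 1)])
    rep <- pct_change_report(summ, labels)
    rep$category[rep$visit_year == 2] == "decline"
  })
  expect_gte(mean(hits), 0.95)
})
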