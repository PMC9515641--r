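# small helper: Gaussian two-class feature table in the standard columns
gauss_features <- function(n1, n2, shift, seed = 1, sd = 1) {
  set.seed(seed)
  data.frame(
    D_um = c(rnorm(n1, 10, sd), rnorm(n2, 10 + shift, sd)),
    nc_ratio = c(rnorm(n1, 0.8, sd * 0.01), rnorm(n2, 0.8, sd * 0.01)),
    ri_n = rnorm(n1 + n2, 1.42, sd * 0.005),
    ri_c = rnorm(n1 + n2, 1.38, sd * 0.005),
    label = rep(c("A", "B"), c(n1, n2)), stringsAsFactors = FALSE)
}

test_that("perfectly separated classes classify at 100% with zero cost", {
  feats <- gauss_features(100, 100, shift = 100)
  for (kind in c("quadratic_svm", "linear_svm", "fine_knn", "cosine_knn",
                 "medium_tree")) {
    r <- cross_validate(feats, classifier_config(kind, seed = 5))
    expect_equal(r$mean_accuracy, 100, info = kind)
    expect_identical(r$cost, 0, info = kind)
  }
})

test_that("1-NN prediction equals the hand-enumerated nearest neighbour", {
  Xtr <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  ytr <- factor(c("a", "a", "b", "b"))
  Xte <- matrix(c(0.1, 0.1, 0.9, 0.8, 0.6, 0.1, 0.1, 0.9), ncol = 2,
                byrow = TRUE)
  # nearest rows by inspection: (0,0)->a, (1,1)->b, (1,0)->a, (0,1)->b
  got <- cytoscatter:::.knn_predict(Xtr, ytr, Xte, k = 1, "euclidean")
  expect_identical(as.character(got), c("a", "b", "a", "b"))

  # cosine metric ranks by direction, not magnitude
  Xtr2 <- matrix(c(10, 0, 0, 10), ncol = 2, byrow = TRUE)
  got2 <- cytoscatter:::.knn_predict(Xtr2, factor(c("x", "y")),
                                     matrix(c(0.9, 0.1, 0.1, 2), ncol = 2,
                                            byrow = TRUE), 1, "cosine")
  expect_identical(as.character(got2), c("x", "y"))

  # vote ties break to the lowest class index
  ytie <- factor(c("a", "b"))
  gtie <- cytoscatter:::.knn_predict(matrix(c(0, 0, 2, 0), ncol = 2,
                                            byrow = TRUE),
                                     ytie, matrix(c(1, 0), ncol = 2), 2,
                                     "euclidean")
  expect_identical(as.character(gtie), "a")
})

test_that("confusion statistics follow their definitions", {
  cm <- matrix(c(10, 0, 0, 10), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  s <- confusion_stats(cm)
  expect_equal(unname(s$ppv), c(100, 100))
  expect_equal(unname(s$fdr), c(0, 0))
  expect_identical(s$cost, 0)

  cm2 <- matrix(c(8, 3, 2, 7), 2, dimnames = list(c("c1", "c2"),
                                                  c("c1", "c2")))
  s2 <- confusion_stats(cm2)
  expect_equal(unname(s2$ppv[1]), 100 * 8 / 11, tolerance = 1e-12)
  expect_identical(s2$cost, 5)
  expect_equal(unname(s2$ppv + s2$fdr), c(100, 100))
  expect_equal(s2$accuracy, 100 * 15 / 20)

  # never-predicted class has undefined PPV
  cm3 <- matrix(c(5, 5, 0, 0), 2)
  expect_true(is.na(confusion_stats(cm3)$ppv[2]))
  expect_error(confusion_stats(matrix(1:6, 2)), "square")
})

test_that("cost equals the accuracy complement on every CV run", {
  feats <- gauss_features(60, 60, shift = 1.5, seed = 8)
  r <- cross_validate(feats, classifier_config("quadratic_svm", seed = 2))
  n <- r$n
  for (i in seq_along(r$confusions)) {
    cm <- r$confusions[[i]]
    expect_identical(sum(cm), n)          # mass conservation
    expect_equal(r$cost_per_repeat[i],
                 (1 - r$accuracy_per_repeat[i] / 100) * n)
  }
  expect_equal(unname(r$ppv + r$fdr), rep(100, 2))
})

test_that("reports are reproducible and paired comparisons share splits", {
  feats <- gauss_features(50, 50, shift = 2, seed = 3)
  cfg <- classifier_config("cosine_knn", seed = 77)
  expect_identical(cross_validate(feats, cfg), cross_validate(feats, cfg))

  cmp <- compare_classifiers(feats, c("fine_knn", "fine_knn"), seed = 9)
  expect_equal(cmp$mean_accuracy[1], cmp$mean_accuracy[2])
})

test_that("label shuffling drives accuracy to the majority rate", {
  feats <- gauss_features(1000, 1000, shift = 50, seed = 10)
  set.seed(21)
  feats$label <- sample(feats$label)
  r <- cross_validate(feats, classifier_config("linear_svm", seed = 22))
  expect_lt(abs(r$mean_accuracy - 50), 3)
})

test_that("one-way ANOVA matches direct sum-of-squares computation", {
  # classic three-group teaching example, recomputed from first principles
  v <- c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 8, 7, 13, 9, 11, 8, 12, 13)
  g <- rep(c("g1", "g2", "g3"), each = 6)
  res <- anova_tukey(v, g)

  means <- tapply(v, g, mean)
  ssb <- sum(6 * (means - mean(v))^2)
  ssw <- sum((v - means[g])^2)
  f_ref <- (ssb / 2) / (ssw / 15)
  expect_equal(res$F, f_ref, tolerance = 1e-12)
  expect_equal(res$p, pf(f_ref, 2, 15, lower.tail = FALSE),
               tolerance = 1e-12)

  # Tukey adjusted p recomputed from the studentized range distribution
  mse <- ssw / 15
  q12 <- abs(unname(means["g2"] - means["g1"])) / sqrt(mse / 6)
  p12_ref <- ptukey(q12, 3, 15, lower.tail = FALSE)
  expect_equal(res$tukey$p_adj[res$tukey$pair == "g2-g1"], p12_ref,
               tolerance = 1e-9)
  expect_identical(res$tukey$code[res$tukey$pair == "g2-g1"],
                   cytoscatter:::.sig_code(p12_ref))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(6)
  x <- rnorm(12, 0, 1); y <- rnorm(15, 0.8, 1)
  res <- anova_tukey(c(x, y), rep(c("x", "y"), c(12, 15)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA behaves correctly under the null and degenerate input", {
  set.seed(31)
  fs <- replicate(300, {
    anova_tukey(rnorm(30), rep(c("a", "b", "c"), each = 10))$F
  })
  # E[F] = df2 / (df2 - 2) = 27/25 under H0
  expect_lt(abs(mean(fs) - 27 / 25), 0.15)
  ps <- pf(fs, 2, 27, lower.tail = FALSE)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)

  deg <- anova_tukey(rep(c(1, 2), each = 5), rep(c("a", "b"), each = 5))
  expect_true(deg$degenerate)
  expect_identical(deg$F, Inf)
  expect_identical(deg$p, 0)

  expect_error(anova_tukey(1:3, c("a", "a", "b")), "at least two values")
})
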