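test_that("risk scores are exact linear arithmetic on the preset coefficients", {
  ircg <- score_preset("iRCG_PFS")
  vars0 <- list(cluDiss = 0, age = 0, CNB = 0)
  expect_equal(evaluate_score(ircg, vars0)$score, 0)
  vars1 <- list(cluDiss = 1, age = 1, CNB = 1)
  expect_equal(evaluate_score(ircg, vars1)$score, 10.27)

  ccg <- score_preset("CCG_PFS")
  expect_equal(evaluate_score(ccg, list(age = 1, sites = 1, CNB = 1,
                                        resection = 1))$score, 6.115)

  arcg <- score_preset("aRCG_PFS")
  u <- as.list(setNames(rep(1, length(arcg)), names(arcg)))
  expect_equal(evaluate_score(arcg, u)$score, 11.61)

  # cohort-median magnitudes reproduce the hand-derived value
  v <- list(cluDiss = 68.62, age = 59, CNB = 0.546)
  expect_equal(evaluate_score(ircg, v)$score, 525.30, tolerance = 0.01 / 525)
})

test_that("score evaluation is linear and the cutoff boundary is high risk", {
  ircg <- score_preset("iRCG_PFS")
  v <- list(cluDiss = 3.2, age = 61, CNB = 0.4)
  s1 <- evaluate_score(ircg, v)$score
  s2 <- evaluate_score(ircg, lapply(v, `*`, 2.5))$score
  expect_equal(s2, 2.5 * s1, tolerance = 1e-12)
  # additivity in variables
  va <- list(cluDiss = 1.1, age = 0, CNB = 0)
  vb <- list(cluDiss = 0, age = 40, CNB = 0.2)
  expect_equal(evaluate_score(ircg, Map(`+`, va, vb))$score,
               evaluate_score(ircg, va)$score + evaluate_score(ircg, vb)$score,
               tolerance = 1e-12)
  # boundary rule: score exactly at cutoff dichotomizes high
  r <- evaluate_score(ircg, v, cutoff = s1)
  expect_equal(r$risk_group, "high")
  r2 <- evaluate_score(ircg, v, cutoff = s1 + 1e-9)
  expect_equal(r2$risk_group, "low")
  expect_error(evaluate_score(ircg, list(age = 1, CNB = 1)),
               "cluDiss")
})

test_that("Youden cut point handles separable, null, and reversed labels", {
  sep <- find_cutpoint(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_gt(sep$cutoff, 3)
  expect_lte(sep$cutoff, 10)
  expect_equal(sep$youden, 1)

  set.seed(11)
  null <- find_cutpoint(rnorm(200), sample(c(TRUE, FALSE), 200, TRUE))
  expect_lte(null$youden, 0.25)

  rev <- find_cutpoint(c(1, 2, 3, 10, 11), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(rev$youden, 1)
  expect_equal(rev$direction, "<")

  expect_error(find_cutpoint(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("elastic net recovers planted support and shrinks fully at huge lambda", {
  hits <- 0
  for (r in 1:25) {
    set.seed(100 + r)
    X <- matrix(rnorm(60 * 10), 60, dimnames = list(NULL, paste0("f", 1:10)))
    y <- 2 * X[, 1] + rnorm(60, 0, 0.5)
    co <- fit_linear_risk_score(X, y, alpha = 1, seed = 100 + r)
    if ("f1" %in% names(co) && sum(paste0("f", 2:10) %in% names(co)) <= 2)
      hits <- hits + 1
  }
  expect_gte(hits / 25, 0.9)

  set.seed(1)
  X <- matrix(rnorm(30 * 5), 30)
  y <- rnorm(30)
  co_inf <- fit_linear_risk_score(X, y, alpha = 1, lambda = 1e6, seed = 1)
  expect_length(co_inf, 0L)

  # duplicated feature: lasso keeps at most one of the pair
  set.seed(2)
  Xd <- matrix(rnorm(80 * 3), 80, dimnames = list(NULL, c("a", "b", "c")))
  Xd <- cbind(Xd, dup = Xd[, "a"])
  yd <- 3 * Xd[, "a"] + rnorm(80, 0, 0.3)
  cod <- fit_linear_risk_score(Xd, yd, alpha = 1, seed = 2)
  expect_lte(sum(c("a", "dup") %in% names(cod)), 1L)

  expect_error(fit_linear_risk_score(X, rep(1, 30), seed = 1), "degeneracy")
})

test_that("SMOTE balances exactly and interpolates within the minority set", {
  set.seed(21)
  X <- matrix(rnorm(40 * 3), 40)
  y <- factor(c(rep("neg", 32), rep("pos", 8)))
  sb <- smote_balance(X, y)
  expect_equal(as.vector(table(sb$y)), c(32L, 32L))
  synth <- sb$X[-seq_len(40), , drop = FALSE]
  # every synthetic sample lies within the minority bounding box
  Xm <- X[y == "pos", ]
  for (j in 1:3) {
    expect_true(all(synth[, j] >= min(Xm[, j]) - 1e-9))
    expect_true(all(synth[, j] <= max(Xm[, j]) + 1e-9))
  }
  # already balanced input is returned unchanged
  yb <- factor(rep(c("a", "b"), 20))
  expect_identical(smote_balance(X, yb)$X, X)
})

test_that("classifier protocol is calibrated on null labels and sharp on separable ones", {
  # null behavior: single fixed datasets carry large dataset-level variance
  # (cross-validation on a finite null sample is pessimistically biased), so
  # the calibration check averages the protocol over permuted-label draws
  set.seed(31)
  n <- 60
  null_means <- vapply(1:12, function(r) {
    X0 <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
    y0 <- factor(sample(c(rep("sensitive", 46), rep("resistant", 14))),
                 levels = c("sensitive", "resistant"))
    train_platinum_classifier(X0, y0, repeats = 8, seed = r)$auroc
  }, numeric(1))
  expect_gte(mean(null_means), 0.4)
  expect_lte(mean(null_means), 0.6)

  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
  y_perm <- factor(c(rep("sensitive", 46), rep("resistant", 14)),
                   levels = c("sensitive", "resistant"))
  mu <- ifelse(y_perm == "resistant", 2, -2)  # margin >> noise SD
  Xs <- X + matrix(mu, n, 5)
  rep_sep <- train_platinum_classifier(Xs, y_perm, repeats = 40, seed = 31)
  expect_gte(rep_sep$auroc, 0.95)
  expect_true(all(rep_sep$auroc_ci >= 0 & rep_sep$auroc_ci <= 1))
  expect_lte(rep_sep$auroc_ci[1], rep_sep$auroc_ci[2])
  expect_equal(max(rep_sep$importance), 100)

  expect_error(train_platinum_classifier(X, factor(rep("a", n))), "protocol")
})

test_that("nested RFE variant runs and model comparison reports p-values", {
  set.seed(41)
  n <- 45
  X <- matrix(rnorm(n * 12), n, dimnames = list(NULL, paste0("f", 1:12)))
  y <- factor(ifelse(X[, 1] + X[, 2] + rnorm(n, 0, 0.8) > 0, "res", "sen"),
              levels = c("sen", "res"))
  rep_rfe <- train_platinum_classifier(X, y, repeats = 5,
                                       rfe_sizes = c(5, 10), seed = 41)
  expect_true(is.finite(rep_rfe$auroc))
  rep_plain <- train_platinum_classifier(X, y, repeats = 5, seed = 41)
  cmp <- compare_classifiers(rep_rfe, rep_plain)
  expect_true(is.finite(cmp$p_paired))
  expect_true(cmp$p_paired >= 0 && cmp$p_paired <= 1)
})

test_that("scanner robustness screen is calibrated and powered", {
  set.seed(51)
  scanner <- c(rep("GE", 40), rep("Siemens", 35))
  X <- matrix(rnorm(75 * 20), 75, dimnames = list(NULL, paste0("f", 1:20)))
  res <- scanner_robustness_screen(X, scanner)
  expect_gte(mean(res$robust), 0.9)

  # +3 SD shift in the non-GE group is flagged non-robust almost always
  rejected <- 0
  for (r in 1:50) {
    set.seed(600 + r)
    f <- rnorm(75)
    f[scanner != "GE"] <- f[scanner != "GE"] + 3
    rr <- scanner_robustness_screen(matrix(f, dimnames = list(NULL, "f")),
                                    scanner)
    if (!rr$robust) rejected <- rejected + 1
  }
  expect_gte(rejected / 50, 0.95)

  cst <- scanner_robustness_screen(matrix(1, 75, dimnames = list(NULL, "c")),
                                   scanner)
  expect_true(cst$constant)
  expect_equal(cst$p_value, 1)
  expect_error(scanner_robustness_screen(X, rep("GE", 75)), "non-empty")
})

test_that("Spearman correlation screen matches the tie-corrected rank formula", {
  x <- 1:10
  up <- data.frame(a = x)
  expect_equal(correlation_screen(up, data.frame(b = x^3))$rho, 1)
  expect_equal(correlation_screen(up, data.frame(b = -sqrt(x)))$rho, -1)

  # heavy ties: oracle is Pearson on mid-ranks
  xf <- c(1, 1, 2, 2, 2, 3, 4, 4, 5, 5)
  yf <- c(2, 2, 2, 1, 3, 3, 3, 4, 4, 4)
  got <- correlation_screen(data.frame(a = xf), data.frame(b = yf))
  expect_equal(got$rho, cor(rank(xf), rank(yf)), tolerance = 1e-12)

  few <- correlation_screen(data.frame(a = c(1, 2, 3, NA, NA, NA, NA, NA, NA, NA)),
                            data.frame(b = yf))
  expect_false(few$evaluable)
  expect_true(is.na(few$rho))
})

test_that("survival contracts delegate correctly and detect degeneracy", {
  # null score: Wald CI covers 1 in most replicates
  cover <- 0
  for (r in 1:25) {
    set.seed(700 + r)
    sc <- rnorm(200)
    tt <- rexp(200, 1 / 12)
    ev <- runif(200) < 0.7
    sa <- survival_association(sc, tt, ev)
    if (sa$hr_ci[1] <= 1 && sa$hr_ci[2] >= 1) cover <- cover + 1
  }
  expect_gte(cover / 25, 0.9)

  # parameter recovery: hazard exp(0.03 * score)
  set.seed(99)
  sc <- rnorm(500, 0, 10)
  tt <- rexp(500, rate = (1 / 15) * exp(0.03 * sc))
  sa <- survival_association(sc, tt, rep(TRUE, 500))
  expect_lt(abs(log(sa$hr) - 0.03) / 0.03, 0.3)

  expect_error(survival_association(rep(2, 50), rexp(50), rep(TRUE, 50)),
               "degeneracy")

  km <- kaplan_meier_by_group(rep(c("low", "high"), each = 100),
                              c(rexp(100, 1 / 24), rexp(100, 1 / 6)),
                              rep(TRUE, 200))
  expect_lt(km$logrank_p, 0.01)
})

test_that("PCA group contrast returns loadings and explained variance", {
  set.seed(61)
  enr <- as.data.frame(matrix(rnorm(40 * 6), 40,
                              dimnames = list(NULL, paste0("path", 1:6))))
  grp <- rep(c("low", "high"), each = 20)
  pc <- pca_group_contrast(enr, grp)
  expect_named(pc, c("high", "low"))
  expect_equal(ncol(pc$low$loadings), 2L)
  expect_true(all(pc$low$var_explained > 0))
})
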