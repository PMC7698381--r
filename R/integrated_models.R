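#' Built-in risk score coefficient presets
#'
#' Named coefficient maps for the three published linear risk scores of
#' progression-free survival. Variables enter in raw units (age in years,
#' CNB as a genome fraction, cluDiss as computed, resection ordinally
#' encoded complete = 0 / optimal = 1 / suboptimal = 2).
#'
#' * `iRCG_PFS`: 4.44 x cluDiss + 3.72 x age + 2.11 x CNB
#' * `CCG_PFS`: 2.86 x age + 1.85 x sites + 1.17 x CNB + 0.235 x resection
#' * `aRCG_PFS`: 2.08 x age + 1.30 x CNB + 1.22 x resection + 0.10 x SZN +
#'   1.26 x coarseness + 1.73 x Sobel mean + 0.30 x Gabor(45deg,2) kurtosis +
#'   1.41 x Gabor(90deg,2) mean + 0.30 x Gabor(90deg,2) skewness +
#'   1.91 x Gabor(135deg,2) mean (the last term carries no statistic suffix
#'   in the source and is taken as the mean).
#'
#' @param model one of `"iRCG_PFS"`, `"CCG_PFS"`, `"aRCG_PFS"`.
#' @return object of class `score_coefficients` (named numeric vector with
#'   a `model` attribute).
#' @export
score_preset <- function(model = c("iRCG_PFS", "CCG_PFS", "aRCG_PFS")) {
  model <- match.arg(model)
  co <- switch(model,
    iRCG_PFS = c(cluDiss = 4.44, age = 3.72, CNB = 2.11),
    CCG_PFS = c(age = 2.86, sites = 1.85, CNB = 1.17, resection = 0.235),
    aRCG_PFS = c(age = 2.08, CNB = 1.30, resection = 1.22,
                 GLSZM.SZN = 0.10, NGTDM.coarseness = 1.26,
                 Sobel.mean = 1.73, Gabor45.kurtosis = 0.30,
                 Gabor90.mean = 1.41, Gabor90.skewness = 0.30,
                 Gabor135.mean = 1.91))
  structure(co, model = model, class = "score_coefficients")
}

#' Evaluate a linear risk score
#'
#' score = sum over named coefficients of coefficient x variable, in raw
#' units. If a cutoff is supplied the patient is dichotomized with the
#' boundary in the high-risk group (high risk iff score >= cutoff).
#'
#' @param coeffs a `score_coefficients` (e.g. [score_preset()]) or named
#'   numeric vector.
#' @param variables named numeric list/vector resolving every coefficient
#'   name.
#' @param cutoff optional scalar cutoff.
#' @return list with `score`, `model`, `risk_group` (`"low"`/`"high"` or
#'   `NA` without a cutoff).
#' @export
evaluate_score <- function(coeffs, variables, cutoff = NULL) {
  vars <- unlist(variables)
  missing_v <- setdiff(names(coeffs), names(vars))
  if (length(missing_v))
    stop(sprintf("resolution error: variable(s) not supplied: %s",
                 paste(missing_v, collapse = ", ")), call. = FALSE)
  v <- vars[names(coeffs)]
  if (any(!is.finite(v)))
    stop("resolution error: non-finite variable value", call. = FALSE)
  s <- sum(as.numeric(coeffs) * v)
  list(score = s,
       model = attr(coeffs, "model") %||% "custom",
       risk_group = if (is.null(cutoff)) NA_character_
                    else if (s >= cutoff) "high" else "low")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default published cut-offs
#'
#' Dichotomization defaults determined on the original training cohort:
#' iRCG 642.00 and cluDiss 68.62 (one figure in the source prints 68.82 for
#' the cluDiss cut point; 68.62 is used here and the discrepancy is
#' documented). These defaults are tied to that cohort's GDM conventions
#' and are not expected to transfer numerically to recomputed scores;
#' refit with [find_cutpoint()] for new data.
#'
#' @return named numeric vector of default cutoffs.
#' @export
default_cutpoints <- function() c(iRCG_PFS = 642.00, cluDiss = 68.62)

#' Optimal ROC cut point (Youden index)
#'
#' Maximizes sensitivity + specificity - 1 over candidate cutoffs (the
#' midpoints between adjacent sorted unique scores, plus outer sentinels),
#' with the dichotomization rule positive iff score >= cutoff. Ties are
#' broken toward the lower cutoff.
#'
#' @param scores numeric vector.
#' @param outcome logical/0-1 vector (TRUE = positive class).
#' @return list with `cutoff`, `youden`, `sensitivity`, `specificity`,
#'   `direction` (`">="` or `"<"` for whichever orientation scored higher).
#' @export
find_cutpoint <- function(scores, outcome) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  su <- sort(unique(scores))
  cand <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)])
  best <- NULL
  for (dirflip in c(FALSE, TRUE)) {
    pos <- if (dirflip) !outcome else outcome
    for (ct in cand) {
      pred <- scores >= ct
      se <- mean(pred[pos]); sp <- mean(!pred[!pos])
      y <- se + sp - 1
      if (is.null(best) || y > best$youden + 1e-12)
        best <- list(cutoff = ct, youden = y, sensitivity = se,
                     specificity = sp,
                     direction = if (dirflip) "<" else ">=")
    }
  }
  best
}

#' Fit a sparse linear risk score by elastic net
#'
#' Elastic-net regression (glmnet) of an outcome on a feature table;
#' rows with missing values are excluded before fitting. With `alpha`
#' near 1 the selected coefficient set is sparse. `lambda = NULL` tunes the
#' penalty by cross-validation (`cv.glmnet`, lambda.min). Deterministic
#' given `seed`.
#'
#' @param features data frame / matrix of predictors (numeric).
#' @param outcome numeric response (e.g. PFS months) or binary.
#' @param alpha elastic-net mixing parameter in `[0, 1]` (1 = lasso).
#' @param lambda penalty; `NULL` to tune by CV.
#' @param family glmnet family (default `"gaussian"`).
#' @param nfolds CV folds for tuning.
#' @param rule CV tuning rule: `"1se"` (default; largest penalty within one
#'   standard error of the CV minimum, the conventional parsimonious
#'   choice) or `"min"`.
#' @param seed integer seed.
#' @return object of class `score_coefficients` holding the nonzero
#'   coefficients (intercept dropped), with attributes `lambda`, `alpha`.
#' @export
fit_linear_risk_score <- function(features, outcome, alpha = 1,
                                  lambda = NULL, family = "gaussian",
                                  nfolds = 5, rule = c("1se", "min"),
                                  seed = 1L) {
  rule <- match.arg(rule)
  X <- as.matrix(features)
  keep <- complete.cases(X) & is.finite(outcome)
  X <- X[keep, , drop = FALSE]
  y <- outcome[keep]
  if (nrow(X) < 10L)
    stop("need at least 10 complete patients to fit a risk score",
         call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degeneracy error: constant outcome", call. = FALSE)
  with_seed_local(seed, {
    if (is.null(lambda)) {
      cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, family = family,
                                 nfolds = nfolds)
      lambda <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
    }
    fit <- glmnet::glmnet(X, y, alpha = alpha, family = family,
                          lambda = lambda)
    co <- as.matrix(stats::coef(fit))[, 1]
  })
  co <- co[setdiff(names(co), "(Intercept)")]
  co <- co[co != 0]
  structure(co, model = "fitted", lambda = lambda, alpha = alpha,
            class = "score_coefficients")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a two-class data set by interpolating new minority samples
#' between each minority point and one of its `k` nearest minority
#' neighbors, until minority count equals majority count. Applied by the
#' classifier protocol to training folds only.
#'
#' @param X numeric matrix of predictors.
#' @param y two-class factor/vector.
#' @param k neighbors (default 5, capped at minority size - 1).
#' @return list with balanced `X` and `y`.
#' @export
smote_balance <- function(X, y, k = 5L) {
  y <- as.factor(y)
  tab <- table(y)
  if (length(tab) != 2L) stop("SMOTE needs exactly two classes", call. = FALSE)
  if (tab[1] == tab[2]) return(list(X = X, y = y))
  min_cl <- names(tab)[which.min(tab)]
  Xm <- X[y == min_cl, , drop = FALSE]
  need <- max(tab) - min(tab)
  nm <- nrow(Xm)
  if (nm == 1L) {
    # degenerate minority: replicate the single point
    synth <- Xm[rep(1L, need), , drop = FALSE]
  } else {
    kk <- min(k, nm - 1L)
    Dm <- as.matrix(dist(Xm))
    diag(Dm) <- Inf
    nn <- t(apply(Dm, 1, function(r) order(r)[seq_len(kk)]))
    base_idx <- sample.int(nm, need, replace = TRUE)
    synth <- t(vapply(base_idx, function(i) {
      j <- nn[i, sample.int(kk, 1)]
      g <- runif(1)
      Xm[i, ] + g * (Xm[j, ] - Xm[i, ])
    }, numeric(ncol(X))))
  }
  colnames(synth) <- colnames(X)
  list(X = rbind(X, synth),
       y = factor(c(as.character(y), rep(min_cl, need)), levels = levels(y)))
}

stratified_folds <- function(y, nfolds) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

auc_from_scores <- function(scores, labels) {
  # labels logical (TRUE = positive); Mann-Whitney AUC
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

svm_weights <- function(fit) {
  w <- t(fit$coefs) %*% fit$SV
  as.numeric(w)
}

fit_linear_svm <- function(X, y) {
  e1071::svm(x = X, y = y, kernel = "linear", scale = FALSE, cost = 1)
}

# decision values oriented so larger = more likely pos_level
decision_score <- function(fit, newdata, pos_level) {
  pr <- stats::predict(fit, newdata, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s <- as.numeric(dv)
  if (first != pos_level) s <- -s
  list(score = s, class = as.character(pr))
}

rfe_select <- function(X, y, sizes, inner_folds = 3L) {
  # rank features by |weight| of a linear SVM on the full training set,
  # evaluate each candidate size by inner stratified CV AUC
  sizes <- sizes[sizes <= ncol(X)]
  if (length(sizes) == 0L) sizes <- ncol(X)
  y <- as.factor(y)
  pos_level <- levels(y)[2]
  sb <- smote_balance(X, y)
  rank_w <- order(abs(svm_weights(fit_linear_svm(sb$X, sb$y))),
                  decreasing = TRUE)
  best <- NULL
  for (nsize in sizes) {
    keep <- rank_w[seq_len(nsize)]
    fold <- stratified_folds(y, inner_folds)
    sc <- rep(NA_real_, length(y))
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      sbf <- smote_balance(X[tr, keep, drop = FALSE], y[tr])
      fitf <- fit_linear_svm(sbf$X, sbf$y)
      sc[!tr] <- decision_score(fitf, X[!tr, keep, drop = FALSE],
                                pos_level)$score
    }
    ok <- !is.na(sc)
    a <- auc_from_scores(sc[ok], (y == pos_level)[ok])
    if (is.null(best) || (!is.na(a) && a > best$auc))
      best <- list(keep = keep, auc = if (is.na(a)) -Inf else a, n = nsize)
  }
  best$keep
}

#' Platinum resistance classifier protocol
#'
#' Linear-margin (SVM) classification with repeated stratified 3-fold
#' cross-validation: SMOTE balancing and feature standardization are fit on
#' each training fold only, out-of-fold decision values are aggregated per
#' repetition into AUROC / sensitivity / specificity, and percentile 95%
#' CIs are taken over the repetitions. The `rfe_sizes` argument switches on
#' recursive feature elimination with nested 3-fold inner CV selecting the
#' feature count (used by the average-radiomics variant).
#'
#' @param features numeric data frame/matrix of predictors.
#' @param labels two-class vector; the second factor level is the positive
#'   (minority/resistant) class by convention.
#' @param folds outer folds (default 3).
#' @param repeats CV repetitions (default 100).
#' @param rfe_sizes `NULL` (no RFE) or candidate feature counts, e.g.
#'   `c(5, 10, 15, 20, 25)`.
#' @param seed integer seed.
#' @return object of class `classifier_report`: list with `auroc`,
#'   `sensitivity`, `specificity` (each value + 95% CI), per-repetition
#'   vectors, pooled out-of-fold scores/labels, and `importance`
#'   (0-100 scale).
#' @export
train_platinum_classifier <- function(features, labels, folds = 3L,
                                      repeats = 100L, rfe_sizes = NULL,
                                      seed = 1L) {
  X <- as.matrix(features)
  y <- as.factor(labels)
  if (length(levels(y)) != 2L)
    stop("protocol error: labels must have exactly two classes", call. = FALSE)
  if (min(table(y)) < 2L)
    stop("protocol error: each class needs at least 2 members", call. = FALSE)
  pos_level <- levels(y)[2]
  rep_auc <- rep_se <- rep_sp <- numeric(repeats)
  pooled_scores <- pooled_labels <- NULL
  with_seed_local(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(y, folds)
      sc <- rep(NA_real_, length(y))
      pred <- rep(NA, length(y))
      for (f in seq_len(folds)) {
        tr <- fold != f
        Xtr <- X[tr, , drop = FALSE]
        mu <- colMeans(Xtr); sdev <- apply(Xtr, 2, sd)
        sdev[sdev < 1e-12] <- 1
        Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdev, "/")
        Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdev, "/")
        keep <- seq_len(ncol(X))
        if (!is.null(rfe_sizes))
          keep <- rfe_select(Ztr, y[tr], rfe_sizes)
        sb <- smote_balance(Ztr[, keep, drop = FALSE], y[tr])
        fitf <- fit_linear_svm(sb$X, sb$y)
        ds <- decision_score(fitf, Zte[, keep, drop = FALSE], pos_level)
        sc[!tr] <- ds$score
        pred[!tr] <- ds$class == pos_level
      }
      is_pos <- y == pos_level
      rep_auc[r] <- auc_from_scores(sc, is_pos)
      rep_se[r] <- mean(pred[is_pos])
      rep_sp[r] <- mean(!pred[!is_pos])
      pooled_scores <- cbind(pooled_scores, sc)
      pooled_labels <- is_pos
    }
  })
  ci <- function(v) quantile(v, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  # importance from a final standardized model on the full data
  with_seed_local(seed + 1L, {
    Z <- scale(X)
    Z[, attr(Z, "scaled:scale") < 1e-12] <- 0
    sb <- smote_balance(Z, y)
    w <- abs(svm_weights(fit_linear_svm(sb$X, sb$y)))
  })
  imp <- if (max(w) > 0) 100 * w / max(w) else w
  names(imp) <- colnames(X)
  structure(
    list(auroc = mean(rep_auc), auroc_ci = ci(rep_auc),
         sensitivity = mean(rep_se), sensitivity_ci = ci(rep_se),
         specificity = mean(rep_sp), specificity_ci = ci(rep_sp),
         rep_auroc = rep_auc, rep_sensitivity = rep_se,
         rep_specificity = rep_sp,
         oof_scores = rowMeans(pooled_scores, na.rm = TRUE),
         oof_labels = pooled_labels,
         importance = sort(imp, decreasing = TRUE),
         folds = folds, repeats = repeats),
    class = "classifier_report")
}

#' @exportS3Method base::print
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %dx%d-fold CV\n", x$repeats, x$folds))
  cat(sprintf("  AUROC %.3f [%.3f, %.3f]\n", x$auroc, x$auroc_ci[1],
              x$auroc_ci[2]))
  cat(sprintf("  sensitivity %.3f [%.3f, %.3f]  specificity %.3f [%.3f, %.3f]\n",
              x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
              x$specificity, x$specificity_ci[1], x$specificity_ci[2]))
  invisible(x)
}

#' Compare two classifier reports
#'
#' Paired two-sided Wilcoxon test on the per-repetition AUROCs (the two
#' protocols must have been run with the same repetition/fold structure)
#' plus a DeLong test on the pooled out-of-fold mean decision scores.
#'
#' @param a,b `classifier_report` objects on the same patients.
#' @return list with `delta_auroc`, `p_paired`, `p_delong`.
#' @export
compare_classifiers <- function(a, b) {
  stopifnot(length(a$rep_auroc) == length(b$rep_auroc))
  pw <- wilcox.test(a$rep_auroc, b$rep_auroc, paired = TRUE,
                    exact = FALSE)$p.value
  pd <- tryCatch({
    ra <- pROC::roc(a$oof_labels, a$oof_scores, quiet = TRUE,
                    direction = "<")
    rb <- pROC::roc(b$oof_labels, b$oof_scores, quiet = TRUE,
                    direction = "<")
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value
  }, error = function(e) NA_real_)
  list(delta_auroc = a$auroc - b$auroc, p_paired = pw, p_delong = pd)
}

#' Scanner robustness screen
#'
#' Two-sided Wilcoxon rank-sum test of every feature between scanner groups
#' (GE vs non-GE). A feature is robust iff p > 0.05 (no detectable scanner
#' shift); the robust set is the input for the average-radiomics
#' classifier. Constant features get p = 1 by convention and are flagged.
#'
#' @param features data frame/matrix (patients x features).
#' @param scanner character/factor; `"GE"` vs anything else.
#' @param alpha robustness threshold on the p-value (default 0.05).
#' @return data frame with `feature`, `p_value`, `robust`, `constant`.
#' @export
scanner_robustness_screen <- function(features, scanner, alpha = 0.05) {
  ge <- scanner == "GE"
  if (!any(ge) || !any(!ge))
    stop("both scanner groups (GE and non-GE) must be non-empty",
         call. = FALSE)
  X <- as.matrix(features)
  res <- lapply(colnames(X), function(nm) {
    v <- X[, nm]
    if (sd(v) < 1e-15)
      return(data.frame(feature = nm, p_value = 1, robust = TRUE,
                        constant = TRUE))
    p <- suppressWarnings(wilcox.test(v[ge], v[!ge], exact = FALSE)$p.value)
    data.frame(feature = nm, p_value = p, robust = p > alpha,
               constant = FALSE)
  })
  do.call(rbind, res)
}

#' Radiomic / gene-set correlation screen
#'
#' Spearman rank correlation (tie-corrected) between every radiomic column
#' and every enrichment-score column, with two-sided p-values, unadjusted
#' significance flags at p < 0.05 and BH-adjusted q-values. Cells with
#' fewer than `min_pairs` complete pairs are marked not evaluable.
#'
#' @param radiomics data frame (patients x radiomic features).
#' @param enrichment data frame (same patients x pathway scores).
#' @param min_pairs minimum complete pairs per cell (default 5).
#' @return long data frame: `feature`, `pathway`, `rho`, `p_value`,
#'   `significant`, `q_value`, `evaluable`.
#' @export
correlation_screen <- function(radiomics, enrichment, min_pairs = 5L) {
  stopifnot(nrow(radiomics) == nrow(enrichment))
  out <- list()
  for (f in colnames(radiomics)) for (g in colnames(enrichment)) {
    x <- radiomics[[f]]; y <- enrichment[[g]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_pairs) {
      out[[length(out) + 1L]] <- data.frame(
        feature = f, pathway = g, rho = NA_real_, p_value = NA_real_,
        significant = NA, evaluable = FALSE)
      next
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    out[[length(out) + 1L]] <- data.frame(
      feature = f, pathway = g, rho = unname(ct$estimate),
      p_value = ct$p.value, significant = ct$p.value < 0.05,
      evaluable = TRUE)
  }
  res <- do.call(rbind, out)
  res$q_value <- NA_real_
  ev <- res$evaluable
  res$q_value[ev] <- p.adjust(res$p_value[ev], method = "BH")
  res
}

#' Survival association of a score (thin Cox contract)
#'
#' Delegates to `survival::coxph`; reports the per-1-unit hazard ratio with
#' Wald 95% CI and the model concordance.
#'
#' @param scores numeric vector.
#' @param pfs_months follow-up times.
#' @param pfs_event event indicators (TRUE = progression/death).
#' @return list with `hr`, `hr_ci`, `p_value`, `concordance`, `fit`.
#' @export
survival_association <- function(scores, pfs_months, pfs_event) {
  if (sum(pfs_event) < 1L) stop("no events", call. = FALSE)
  if (sd(scores) < 1e-15)
    stop("degeneracy error: constant score", call. = FALSE)
  fit <- survival::coxph(survival::Surv(pfs_months, pfs_event) ~ scores)
  s <- summary(fit)
  list(hr = unname(s$coefficients[1, "exp(coef)"]),
       hr_ci = unname(s$conf.int[1, c("lower .95", "upper .95")]),
       p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
       concordance = unname(s$concordance["C"]),
       fit = fit)
}

#' Kaplan-Meier summary by risk group (thin contract)
#'
#' Stratified survival curves plus the log-rank p-value for dichotomized
#' scores, via `survival::survfit` / `survival::survdiff`.
#'
#' @param risk_group factor/character of group labels.
#' @param pfs_months follow-up times.
#' @param pfs_event event indicators.
#' @return list with `fit` (survfit), `logrank_p`, `median_by_group`.
#' @export
kaplan_meier_by_group <- function(risk_group, pfs_months, pfs_event) {
  g <- as.factor(risk_group)
  if (length(levels(g)) < 2L)
    stop("need at least two risk groups", call. = FALSE)
  fit <- survival::survfit(survival::Surv(pfs_months, pfs_event) ~ g)
  sd0 <- survival::survdiff(survival::Surv(pfs_months, pfs_event) ~ g)
  p <- stats::pchisq(sd0$chisq, df = length(levels(g)) - 1,
                     lower.tail = FALSE)
  med <- summary(fit)$table
  list(fit = fit, logrank_p = p, median_by_group = med)
}

#' PCA loadings for a group contrast
#'
#' Numeric PCA loading table (standard linear algebra via `prcomp`) of
#' scaled enrichment scores within each risk group, for contrasting which
#' pathways drive variability in the low- and high-risk strata.
#'
#' @param enrichment data frame (patients x pathways).
#' @param group two-level factor.
#' @param n_components components to keep (default 2).
#' @return list per group: `loadings` matrix and `var_explained`.
#' @export
pca_group_contrast <- function(enrichment, group, n_components = 2L) {
  g <- as.factor(group)
  out <- list()
  for (lv in levels(g)) {
    X <- as.matrix(enrichment[g == lv, , drop = FALSE])
    keep <- apply(X, 2, sd) > 1e-12
    pc <- stats::prcomp(X[, keep, drop = FALSE], scale. = TRUE)
    k <- min(n_components, ncol(pc$rotation))
    out[[lv]] <- list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                      var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
  }
  out
}
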