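#' Stratified train/test split
#'
#' The training set takes `floor(train_fraction * n)` samples within
#' each label stratum; the remainder form the test set. A 235-sample
#' cohort split 119/116 therefore yields 164 training and 71 testing
#' samples at the default 70%.
#'
#' @param sample_ids Character sample ids.
#' @param labels Binary labels per sample.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed for the within-stratum sampling.
#' @return List with `train` and `test` id vectors (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(sample_ids, labels, train_fraction = 0.7, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("labels must be binary")
  if (any(table(labels) < 2)) stop("every stratum needs >= 2 samples")
  set.seed(seed)
  train <- character(0)
  for (lv in levels(labels)) {
    ids <- sample_ids[labels == lv]
    n_tr <- floor(train_fraction * length(ids))
    train <- c(train, sample(ids, n_tr))
  }
  list(train = train, test = setdiff(sample_ids, train))
}

#' Fit a penalized logistic (elastic net) model
#'
#' Minimizes the logistic negative log-likelihood plus
#' `lambda * ((1 - alpha)/2 * sum(coef^2) + alpha * sum(|coef|))` with
#' features standardized internally; coefficients are reported on the
#' original scale. The optimizer is glmnet's cyclic coordinate descent.
#'
#' @param X Samples x features numeric matrix.
#' @param y Binary labels (factor or 0/1); the second level / 1 is the
#'   positive class.
#' @param alpha Mixing parameter in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param lambda Penalty strength (>= 0).
#' @return Object of class `elastic_net_model`: `alpha`, `lambda`,
#'   `intercept`, `coefficients` (named, original scale),
#'   `selected_features`, `feature_sd`, `importance` and the underlying
#'   `fit`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda) {
  X <- as.matrix(X)
  yf <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(yf) != 2) stop("y must be binary and non-constant")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  fit <- glmnet::glmnet(X, yf, family = "binomial", alpha = alpha,
                        standardize = TRUE, thresh = 1e-12)
  cf <- glmnet::coef.glmnet(fit, s = lambda, exact = TRUE, x = X, y = yf,
                            alpha = alpha, family = "binomial",
                            standardize = TRUE, thresh = 1e-12)
  coefs <- setNames(as.numeric(cf)[-1], rownames(cf)[-1])
  sds <- apply(X, 2, sd)
  model <- structure(list(
    alpha = alpha, lambda = lambda,
    intercept = as.numeric(cf)[1],
    coefficients = coefs,
    selected_features = names(coefs)[coefs != 0],
    feature_sd = sds,
    fit = fit,
    positive_class = levels(yf)[2]
  ), class = "elastic_net_model")
  model$importance <- variable_importance(model)
  model
}

#' Predicted probabilities from an elastic net model
#'
#' @param object An `elastic_net_model`.
#' @param newdata Samples x features matrix with the training columns.
#' @param ... Unused.
#' @return Probability of the positive class per sample.
#' @export
predict.elastic_net_model <- function(object, newdata, ...) {
  eta <- object$intercept +
    drop(as.matrix(newdata)[, names(object$coefficients), drop = FALSE] %*%
           object$coefficients)
  setNames(1 / (1 + exp(-eta)), rownames(newdata))
}

#' Cross-validated tuning of elastic net hyperparameters
#'
#' Grid search over `alpha_grid`; for each alpha a k-fold
#' cross-validated binomial deviance path over glmnet's lambda sequence
#' (folds stratified by class, fixed by `seed`). Returns the
#' (alpha, lambda) minimizing mean CV deviance; deviance ties go to the
#' larger lambda (sparser model).
#'
#' @param X Samples x features matrix.
#' @param y Binary labels.
#' @param alpha_grid Candidate alpha values (default 0.1 to 1 by 0.1).
#' @param k_folds Number of CV folds (default 10; must not exceed the
#'   smallest class size).
#' @param seed Integer seed for fold assignment.
#' @return List with `alpha`, `lambda`, and `cv_deviance` at the
#'   optimum.
#' @export
tune_elastic_net <- function(X, y, alpha_grid = seq(0.1, 1, by = 0.1),
                             k_folds = 10, seed = 1L) {
  X <- as.matrix(X)
  yf <- if (is.factor(y)) droplevels(y) else factor(y)
  if (k_folds > min(table(yf))) {
    stop("k_folds must not exceed the smallest class size")
  }
  set.seed(seed)
  foldid <- integer(length(yf))
  for (lv in levels(yf)) {
    idx <- which(yf == lv)
    foldid[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  best <- NULL
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(X, yf, family = "binomial", alpha = a,
                            foldid = foldid, type.measure = "deviance")
    # within this alpha: smallest deviance, ties to larger lambda
    ord <- order(cv$cvm, -cv$lambda)
    cand <- list(alpha = a, lambda = cv$lambda[ord[1]],
                 cv_deviance = cv$cvm[ord[1]])
    if (is.null(best) || cand$cv_deviance < best$cv_deviance ||
        (cand$cv_deviance == best$cv_deviance && cand$lambda > best$lambda)) {
      best <- cand
    }
  }
  best
}

#' Scaled variable importance of an elastic net model
#'
#' Importance is `100 * |standardized coefficient| / max`, where the
#' standardized coefficient is the original-scale coefficient times the
#' training-set feature SD; zero-coefficient features score 0 and the
#' top feature scores 100.
#'
#' @param model An `elastic_net_model`.
#' @return Named numeric vector in \[0, 100\].
#' @export
variable_importance <- function(model) {
  std <- abs(model$coefficients * model$feature_sd[names(model$coefficients)])
  if (all(std == 0)) return(setNames(rep(0, length(std)), names(std)))
  100 * std / max(std)
}

#' Standardization constants for the weighted methylation risk score
#'
#' @param beta_train Probes x training-samples beta matrix.
#' @param dmp_ids DMP probe ids entering the score.
#' @return List with named `mean` and `sd` vectors.
#' @export
train_wmrs_stats <- function(beta_train, dmp_ids) {
  b <- get_beta(beta_train)[dmp_ids, , drop = FALSE]
  list(mean = rowMeans(b), sd = apply(b, 1, sd))
}

#' Weighted methylation risk score
#'
#' For each sample, the sum over discovery DMPs of the standardized beta
#' value times the discovery effect size:
#' `wMRS = sum_i z_i(sample) * delta_i`, with z-scores computed from
#' training-set means and SDs only. DMPs with zero training SD are
#' dropped with a warning.
#'
#' @param beta Probes x samples beta matrix (the samples to score).
#' @param weights Named vector of discovery delta-beta weights per DMP.
#' @param train_stats Output of [train_wmrs_stats()].
#' @return Named numeric score per sample.
#' @export
compute_wmrs <- function(beta, weights, train_stats) {
  b <- get_beta(beta)
  ids <- names(weights)
  bad <- ids[train_stats$sd[ids] <= 0 | !is.finite(train_stats$sd[ids])]
  if (length(bad)) {
    warning("dropping ", length(bad), " DMPs with zero training SD")
    ids <- setdiff(ids, bad)
  }
  if (!all(ids %in% rownames(b))) stop("beta matrix missing score DMPs")
  z <- (b[ids, , drop = FALSE] - train_stats$mean[ids]) / train_stats$sd[ids]
  drop(weights[ids] %*% z)
}

#' Logistic model of severity on the wMRS
#'
#' Univariate logistic regression with severity as the outcome, plus a
#' normality-gated two-group comparison of the scores themselves.
#' Perfectly separated fits fall back to a ridge-penalized fit and are
#' flagged.
#'
#' @param scores wMRS per sample.
#' @param labels `mild`/`severe` per sample.
#' @return List with `coefficient`, `p_value`, `flag`, `group_test`.
#' @export
wmrs_model <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("mild", "severe"))
  if (var(scores) == 0) stop("degenerate (constant) scores")
  y <- as.integer(labels == "severe")
  r <- logistic_probe_test(scores, y)
  sep <- identical(r$flag, "separation_penalized")
  fit_coef <- if (sep) {
    ridge_logistic(cbind(score = scores), y)$coef[2]
  } else {
    glm(y ~ scores, family = binomial())$coefficients[2]
  }
  gt <- normality_gated_test(scores[labels == "severe"],
                             scores[labels == "mild"])
  list(coefficient = unname(fit_coef), p_value = r$p, flag = r$flag,
       group_test = gt)
}

#' ROC curve and AUC
#'
#' AUC equals the normalized Mann-Whitney statistic,
#' `(concordant pairs + 0.5 * ties) / (n_severe * n_mild)`, with higher
#' scores treated as evidence for the severe class; the curve is built
#' from the sorted unique score thresholds.
#'
#' @param scores Numeric classifier scores per sample.
#' @param labels `mild`/`severe` (or two-level factor; second level is
#'   positive) per sample.
#' @return List of class `roc_result`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(as.character(labels),
                   levels = if (all(labels %in% c("mild", "severe"))) {
                     c("mild", "severe")
                   } else {
                     levels(factor(labels))
                   })
  if (nlevels(droplevels(labels)) != 2) {
    stop("both classes must be present")
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = levels(labels), direction = "<", quiet = TRUE)
  structure(list(
    thresholds = r$thresholds,
    sensitivities = r$sensitivities,
    specificities = r$specificities,
    auc = as.numeric(r$auc)
  ), class = "roc_result")
}

#' Train and compare the three severity classification models
#'
#' Model 1 is an elastic net on clinical features, model 2 an elastic
#' net on genome-wide methylation (optionally including cell-proportion
#' columns), and model 3 a logistic model on the weighted methylation
#' risk score built from discovery DMP weights. All tuning, fitting and
#' wMRS standardization constants use training samples only; test AUC is
#' reported for each model. Any overlap between training statistics and
#' test ids raises a hard error.
#'
#' @param clinical_X Samples x clinical-features matrix (all samples).
#' @param methylation_X Samples x CpG-features matrix (all samples).
#' @param dmp_weights Named vector of discovery delta-beta weights.
#' @param labels `mild`/`severe` per sample (named by sample id).
#' @param split List with `train`/`test` ids from [split_cohort()].
#' @param alpha_grid,k_folds,seed Tuning controls (see
#'   [tune_elastic_net()]).
#' @return List with `auc` (named numeric: clinical, methylation, wmrs),
#'   per-model objects, `wmrs_fit`, and `overlap` (model-2 selected CpGs
#'   intersected with the discovery DMPs).
#' @export
compare_models <- function(clinical_X, methylation_X, dmp_weights, labels,
                           split, alpha_grid = c(0.1, 0.5, 1),
                           k_folds = 10, seed = 1L) {
  if (length(intersect(split$train, split$test))) {
    stop("leakage guard: train and test ids overlap")
  }
  tr <- split$train
  te <- split$test
  y_tr <- labels[tr]
  y_te <- labels[te]
  k <- min(k_folds, min(table(factor(y_tr))))

  run_enet <- function(X) {
    tune <- tune_elastic_net(X[tr, , drop = FALSE], y_tr,
                             alpha_grid = alpha_grid, k_folds = k,
                             seed = seed)
    model <- fit_elastic_net(X[tr, , drop = FALSE], y_tr,
                             alpha = tune$alpha, lambda = tune$lambda)
    pred <- predict(model, X[te, , drop = FALSE])
    list(model = model, tune = tune,
         auc = roc_auc(pred, y_te)$auc)
  }
  m1 <- run_enet(clinical_X)
  m2 <- run_enet(methylation_X)

  beta_t <- t(methylation_X)  # probes x samples view for the wMRS
  stats <- train_wmrs_stats(beta_t[, tr, drop = FALSE],
                            intersect(names(dmp_weights), rownames(beta_t)))
  w <- dmp_weights[intersect(names(dmp_weights), rownames(beta_t))]
  sc_tr <- compute_wmrs(beta_t[, tr, drop = FALSE], w, stats)
  sc_te <- compute_wmrs(beta_t[, te, drop = FALSE], w, stats)
  wfit <- wmrs_model(sc_tr, y_tr)
  m3_auc <- roc_auc(sc_te, y_te)$auc

  list(
    auc = c(clinical = m1$auc, methylation = m2$auc, wmrs = m3_auc),
    clinical = m1, methylation = m2,
    wmrs_fit = wfit, wmrs_scores = list(train = sc_tr, test = sc_te),
    overlap = intersect(m2$model$selected_features, names(dmp_weights))
  )
}
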