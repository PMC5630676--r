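# Cancer type/stage prediction from 5hmC feature matrices: per-fold feature
# selection under three comparison rules, EDDA Gaussian-mixture and
# random-forest classifiers, leave-one-out cross-validation, an LDA-based
# disease score, and Cohen's kappa for inter-classifier agreement.

#' Build the comparison list for feature selection
#'
#' Three rules generate two-group comparisons: (1) each cancer group vs the
#' healthy group, (2) each cancer group vs all other cancer samples pooled
#' (healthy excluded), (3) every unordered pair of distinct cancer groups.
#' Order is deterministic: cancers in `cancer_groups` order, rules in the
#' order above.
#'
#' @param labels Character vector of sample class labels.
#' @param cancer_groups Cancer classes, in canonical order.
#' @param healthy Label of the healthy group.
#' @return Data frame with `comparison`, `rule`, `group_a`, `group_b`
#'   (`group_b` is the healthy label, `"_other_cancers_"`, or a cancer).
#' @export
make_comparisons <- function(labels,
                             cancer_groups = c("HCC", "Pancreatic",
                                               "Lung_NM", "Lung_M"),
                             healthy = "Healthy") {
  present <- cancer_groups[cancer_groups %in% labels]
  if (!healthy %in% labels) stop("missing healthy group '", healthy, "'")
  if (length(present) == 0) stop("no cancer group present")
  rows <- list()
  for (g in present)
    rows[[length(rows) + 1]] <- data.frame(rule = "vs_healthy", group_a = g,
                                           group_b = healthy)
  for (g in present)
    rows[[length(rows) + 1]] <- data.frame(rule = "vs_other_cancers",
                                           group_a = g,
                                           group_b = "_other_cancers_")
  if (length(present) > 1) {
    pairs <- utils::combn(present, 2)
    for (j in seq_len(ncol(pairs)))
      rows[[length(rows) + 1]] <- data.frame(rule = "pairwise",
                                             group_a = pairs[1, j],
                                             group_b = pairs[2, j])
  }
  out <- do.call(rbind, rows)
  out$comparison <- paste(out$group_a,
                          ifelse(out$group_b == "_other_cancers_",
                                 "others", out$group_b), sep = "_vs_")
  out <- out[, c("comparison", "rule", "group_a", "group_b")]
  attr(out, "cancer_groups") <- present
  attr(out, "healthy") <- healthy
  out
}

.comparison_sides <- function(cmp_row, labels, cancer_groups, healthy) {
  a <- labels == cmp_row$group_a
  b <- if (cmp_row$group_b == "_other_cancers_")
    labels %in% setdiff(cancer_groups, cmp_row$group_a)
  else labels == cmp_row$group_b
  list(a = a, b = b)
}

#' Per-comparison top-k feature selection
#'
#' For each comparison, a per-feature two-group Student (pooled-variance)
#' t-test is computed on the training samples, p-values are BH-adjusted
#' within the comparison, features are ranked by (q, p, feature id) and the
#' top `k` taken; the selection is the deduplicated union over comparisons.
#'
#' @param mat Features x samples matrix (training samples only).
#' @param labels Class labels for the columns of `mat`.
#' @param comparisons From [make_comparisons()].
#' @param k Features per comparison (default 5).
#' @return A `feature_selection` list: `selected` (character vector, at most
#'   `k * nrow(comparisons)` ids) and `per_comparison` (ranked tables).
#' @export
select_features <- function(mat, labels, comparisons, k = 5) {
  cg <- attr(comparisons, "cancer_groups")
  healthy <- attr(comparisons, "healthy")
  per <- list(); selected <- character(0)
  ids <- rownames(mat)
  for (r in seq_len(nrow(comparisons))) {
    sides <- .comparison_sides(comparisons[r, ], labels, cg, healthy)
    if (sum(sides$a) < 2 || sum(sides$b) < 2)
      stop("comparison ", comparisons$comparison[r],
           " has fewer than 2 samples on one side")
    rt <- row_t(mat, sides$a, sides$b, kind = "student")
    q <- bh_adjust(rt$p)
    o <- order(q, rt$p, ids, method = "radix")
    top <- head(o, k)
    per[[comparisons$comparison[r]]] <-
      data.frame(feature = ids[top], t = rt$t[top], p = rt$p[top],
                 q = q[top], stringsAsFactors = FALSE)
    selected <- c(selected, ids[top])
  }
  structure(list(selected = unique(selected), per_comparison = per, k = k),
            class = "feature_selection")
}

# ---------------------------------------------------------------------------
# EDDA Gaussian mixture: one Gaussian component per class with a constrained
# covariance shared in structure across classes. EEI = shared diagonal
# (equal volume and shape); VII = per-class spherical (unequal volume).

#' Fit an EDDA Gaussian-mixture classifier
#'
#' Maximum-likelihood parameters given the class labels: class priors are
#' frequencies, class means are sample means. EEI uses a shared diagonal
#' covariance `diag(lambda_1..lambda_d)` with `lambda_j` the pooled
#' within-class variance of dimension j (MLE, divisor n); VII uses a
#' per-class spherical covariance `lambda_k I` with `lambda_k` the mean
#' within-class variance over dimensions. The reported log-likelihood is the
#' classification likelihood `sum_i log N(x_i; mu_{y_i}, Sigma_{y_i})` and
#' `BIC = 2 logL - m log n`. With `model = "auto"` both structures are fit
#' and the higher-BIC one kept.
#'
#' @param X Samples x features numeric matrix.
#' @param y Class labels (>= 2 samples per class).
#' @param model `"auto"`, `"EEI"` or `"VII"`.
#' @param var_floor Lower floor applied to every variance estimate.
#' @return A `gmm_edda` model object.
#' @export
fit_gmm_edda <- function(X, y, model = c("auto", "EEI", "VII"),
                         var_floor = 1e-6) {
  model <- match.arg(model)
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (any(table(y) < 2)) stop("need at least 2 samples per class")
  n <- nrow(X); d <- ncol(X); K <- length(classes)
  mu <- do.call(rbind, lapply(classes, function(k)
    colMeans(X[y == k, , drop = FALSE])))
  R <- X - mu[match(y, classes), , drop = FALSE]
  fit_one <- function(mdl) {
    if (mdl == "EEI") {
      lambda <- pmax(colSums(R^2) / n, var_floor)
      m <- (K - 1) + K * d + d
    } else {
      lambda <- pmax(vapply(classes, function(k)
        sum(R[y == k, , drop = FALSE]^2) / (sum(y == k) * d), 0), var_floor)
      m <- (K - 1) + K * d + K
    }
    obj <- structure(list(classes = classes,
                          prior = as.numeric(table(factor(y, classes)) / n),
                          mean = mu, model = mdl, lambda = lambda, d = d),
                     class = "gmm_edda")
    ll <- sum(.gmm_logdens(obj, X)[cbind(seq_len(n), match(y, classes))])
    obj$logLik <- ll
    obj$bic <- 2 * ll - m * log(n)
    obj
  }
  if (model != "auto") return(fit_one(model))
  fits <- list(EEI = fit_one("EEI"), VII = fit_one("VII"))
  fits[[which.max(vapply(fits, `[[`, 0, "bic"))]]
}

# n x K matrix of per-class log Gaussian densities
.gmm_logdens <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("dimension mismatch")
  K <- length(model$classes); d <- model$d
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    lam <- if (model$model == "EEI") model$lambda else
      rep(model$lambda[k], d)
    Z <- sweep(X, 2, model$mean[k, ], "-")
    out[, k] <- -0.5 * (d * log(2 * pi) + sum(log(lam)) +
                          rowSums(sweep(Z^2, 2, lam, "/")))
  }
  colnames(out) <- model$classes
  out
}

#' Predict class labels from an EDDA Gaussian mixture
#'
#' Labels are `argmax_k prior_k N(x; mu_k, Sigma_k)`; ties break in class
#' order. Posteriors are normalized with a log-sum-exp.
#'
#' @param model A [fit_gmm_edda()] object.
#' @param X Samples x features matrix (same dimensionality).
#' @return List with `labels` and `posterior` (samples x classes).
#' @export
predict_gmm <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  S <- .gmm_logdens(model, X) +
    matrix(log(model$prior), nrow(X), length(model$classes), byrow = TRUE)
  mx <- apply(S, 1, max)
  post <- exp(S - mx)
  post <- post / rowSums(post)
  labels <- model$classes[apply(S, 1, which.max)]
  list(labels = labels, posterior = post)
}

#' Random-forest classification with a fixed seed
#'
#' Thin deterministic wrapper over [randomForest::randomForest()]; the same
#' seed is set before every fit so repeated runs are identical.
#'
#' @param train_x,train_y Training samples x features and labels.
#' @param test_x Samples to predict.
#' @param seed RNG seed (default 5).
#' @param ntree Number of trees (default 500).
#' @return List with `labels` and `importance` (mean decrease in Gini).
#' @export
rf_predict <- function(train_x, train_y, test_x, seed = 5, ntree = 500) {
  train_y <- factor(train_y)
  if (nlevels(train_y) < 2) stop("degenerate single-class training set")
  fit <- with_seed(seed,
                   randomForest::randomForest(x = as.matrix(train_x),
                                              y = train_y, ntree = ntree))
  test_x <- as.matrix(test_x)
  if (ncol(test_x) != ncol(train_x)) test_x <- t(test_x)
  labels <- as.character(predict(fit, test_x))
  imp <- fit$importance[, "MeanDecreaseGini"]
  list(labels = labels, importance = sort(imp, decreasing = TRUE))
}

#' Leave-one-out cross-validation with per-fold feature selection
#'
#' For every sample: drop it, run [make_comparisons()] + [select_features()]
#' on the remaining samples only, fit the classifier on the selected
#' features, and predict the held-out sample. This per-fold selection is the
#' integrity contract -- selecting features on all samples first leaks the
#' test sample into training and inflates accuracy on null data (pass
#' `features` to demonstrate that, or to evaluate a fixed panel).
#'
#' @param mat Features x samples matrix.
#' @param labels Class labels per column.
#' @param classifier `"mclust"` (EDDA Gaussian mixture) or `"rf"`.
#' @param cancer_groups,healthy Passed to [make_comparisons()].
#' @param k_top Features per comparison (default 5).
#' @param covariance_model EDDA structure for `"mclust"` (default
#'   `"auto"` = BIC choice between EEI and VII).
#' @param rf_seed Seed for every random-forest fit (default 5).
#' @param features Optional fixed feature ids; skips per-fold selection
#'   (leakage diagnostic / fixed panel evaluation).
#' @param type_collapse Named vector mapping stage labels onto types for the
#'   type-only accuracy (default collapses lung stages).
#' @return A `prediction_report`: `predictions` data frame (sample_id, true,
#'   predicted), `accuracy`, `accuracy_type_only`, `per_class_accuracy`,
#'   `n_features` per fold.
#' @export
loo_cross_validate <- function(mat, labels,
                               classifier = c("mclust", "rf"),
                               cancer_groups = c("HCC", "Pancreatic",
                                                 "Lung_NM", "Lung_M"),
                               healthy = "Healthy", k_top = 5,
                               covariance_model = "auto", rf_seed = 5,
                               features = NULL,
                               type_collapse = c(Lung_NM = "Lung",
                                                 Lung_M = "Lung")) {
  classifier <- match.arg(classifier)
  labels <- as.character(labels)
  stopifnot(ncol(mat) == length(labels))
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("class with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (is.null(features) && any(sizes < 3))
    stop("per-fold feature selection needs >= 3 samples in every class ",
         "(a left-out fold would leave fewer than 2)")
  n <- ncol(mat)
  pred <- character(n); nfeat <- integer(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel <- if (is.null(features)) {
      cmp <- make_comparisons(labels[tr], cancer_groups, healthy)
      select_features(mat[, tr, drop = FALSE], labels[tr], cmp,
                      k = k_top)$selected
    } else features
    nfeat[i] <- length(sel)
    Xtr <- t(mat[sel, tr, drop = FALSE])
    Xte <- matrix(mat[sel, i], nrow = 1,
                  dimnames = list(NULL, sel))
    pred[i] <- if (classifier == "mclust") {
      fit <- fit_gmm_edda(Xtr, labels[tr], model = covariance_model)
      predict_gmm(fit, Xte)$labels
    } else {
      rf_predict(Xtr, labels[tr], Xte, seed = rf_seed)$labels
    }
  }
  collapse <- function(x) ifelse(x %in% names(type_collapse),
                                 type_collapse[x], x)
  per_class <- vapply(sort(unique(labels)),
                      function(k) mean(pred[labels == k] == k), 0)
  structure(list(predictions = data.frame(sample_id = colnames(mat) %||%
                                            seq_len(n),
                                          true = labels, predicted = pred,
                                          stringsAsFactors = FALSE),
                 accuracy = mean(pred == labels),
                 accuracy_type_only = mean(collapse(pred) == collapse(labels)),
                 per_class_accuracy = per_class,
                 n_features = nfeat, classifier = classifier),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %s: accuracy %.3f (type-only %.3f), n = %d\n",
              x$classifier, x$accuracy, x$accuracy_type_only,
              nrow(x$predictions)))
  invisible(x)
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement from marginal products, and the Fleiss-Cohen-Everitt
#' large-sample standard error for the confidence interval.
#'
#' @param a,b Equal-length label vectors over a shared label space.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `kappa`, `se`, `ci`, `p_observed`, `p_expected`.
#' @export
cohens_kappa <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == length(b))
  lev <- sort(unique(c(as.character(a), as.character(b))))
  n <- length(a)
  tab <- table(factor(a, lev), factor(b, lev)) / n
  po <- sum(diag(tab))
  pr <- rowSums(tab); pc <- colSums(tab)
  pe <- sum(pr * pc)
  if (pe >= 1 - 1e-12)
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA, NA),
                p_observed = po, p_expected = pe,
                note = "undefined: both raters use a single label"))
  kappa <- (po - pe) / (1 - pe)
  dg <- diag(tab)
  sum1 <- sum(dg * (1 - (pr + pc) * (1 - kappa))^2)
  # off-diagonal term: sum over i != j of p_ij (p_.i + p_j.)^2
  W <- outer(pc, pr, `+`)^2   # W[i, j] = (p_.i + p_j.)^2
  off <- tab * W
  diag(off) <- 0
  sum2 <- (1 - kappa)^2 * sum(off)
  sum3 <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(pmax(sum1 + sum2 - sum3, 0)) / ((1 - pe) * sqrt(n))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kappa, se = se, ci = c(kappa - z * se, kappa + z * se),
       p_observed = po, p_expected = pe)
}

#' Linear-discriminant disease score
#'
#' Fisher discriminant between a case and a control training group with a
#' ridge-regularized within-class scatter (`alpha = ridge * trace(S_w) / d`,
#' needed since the feature count typically exceeds the sample count). The
#' projection is affinely calibrated on the training data so the control
#' mean scores 0 and the case mean scores 1; held-out samples are scored
#' with the frozen direction and calibration.
#'
#' @param train_x Training samples x features matrix.
#' @param train_y Two-group labels for the training rows.
#' @param case Label of the group calibrated to score 1.
#' @param test_x Optional samples x features matrix to score.
#' @param ridge Ridge fraction (default 1e-3).
#' @return List with `w`, `train_scores`, `scores` (for `test_x`), and a
#'   `score` function for later samples.
#' @export
lda_score <- function(train_x, train_y, case, test_x = NULL, ridge = 1e-3) {
  train_x <- as.matrix(train_x)
  train_y <- as.character(train_y)
  stopifnot(case %in% train_y, length(unique(train_y)) == 2)
  other <- setdiff(unique(train_y), case)
  a <- train_x[train_y == case, , drop = FALSE]
  b <- train_x[train_y == other, , drop = FALSE]
  stopifnot(nrow(a) >= 2, nrow(b) >= 2)
  d <- ncol(train_x)
  Ra <- sweep(a, 2, colMeans(a)); Rb <- sweep(b, 2, colMeans(b))
  Sw <- (crossprod(Ra) + crossprod(Rb)) / (nrow(a) + nrow(b) - 2)
  alpha <- ridge * sum(diag(Sw)) / d
  if (alpha <= 0) alpha <- ridge
  w <- solve(Sw + diag(alpha, d), colMeans(a) - colMeans(b))
  raw <- function(X) as.numeric(as.matrix(X) %*% w)
  mu0 <- mean(raw(b)); mu1 <- mean(raw(a))
  score_fun <- function(X) (raw(X) - mu0) / (mu1 - mu0)
  list(w = w, train_scores = score_fun(train_x),
       scores = if (!is.null(test_x)) score_fun(test_x),
       score = score_fun)
}
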