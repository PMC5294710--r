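#' Assemble a labeled feature table
#'
#' @param sample_id character vector of sample identifiers.
#' @param tissue_label factor or character vector of tissue types (e.g.
#'   normal, benign, LGS, endometrioid, HGS).
#' @param features numeric data.frame or matrix of named metric columns
#'   (e.g. `fb_988`, `fb_slope`, `eff_988`, `eff_slope`,
#'   `mus_prime_390`..., `m_shape`).
#' @return A `feature_table` data.frame.
#' @export
feature_table <- function(sample_id, tissue_label, features) {
  features <- as.data.frame(features)
  stopifnot(length(sample_id) == nrow(features),
            length(tissue_label) == nrow(features))
  if (any(is.na(tissue_label))) stop("every row must be labeled", call. = FALSE)
  out <- cbind(data.frame(sample_id = as.character(sample_id),
                          tissue_label = as.character(tissue_label),
                          stringsAsFactors = FALSE), features)
  class(out) <- c("feature_table", class(out))
  out
}

feature_matrix <- function(features) {
  num <- vapply(features, is.numeric, logical(1))
  num[names(num) %in% c("sample_id", "tissue_label")] <- FALSE
  as.matrix(features[, num, drop = FALSE])
}

#' Fit a canonical linear discriminant
#'
#' Canonical discriminant analysis: features are standardized internally,
#' then the generalized eigenproblem on the between-class and pooled
#' within-class scatter matrices yields canonical axes maximizing the
#' between- to within-class variance ratio. At most `n_canonical` axes are
#' retained (never more than classes - 1). The within-class scatter is
#' shrunk toward its diagonal (`(1 - lambda) W + lambda diag(W)`) to stay
#' well-posed in the tiny-sample regime; when W is singular a warning
#' notes that the shrinkage carried the fit.
#'
#' @param features a [feature_table()] (or data.frame with `tissue_label`
#'   and numeric metric columns).
#' @param n_canonical maximum number of canonical variables (default 3).
#' @param shrinkage diagonal shrinkage weight lambda (default 1e-3).
#' @return A `discriminant_model`: canonical weights (features x
#'   variables, on the standardized scale), class centroids in canonical
#'   space, standardization constants, canonical correlations.
#' @export
fit_canonical_discriminant <- function(features, n_canonical = 3,
                                       shrinkage = 1e-3) {
  x <- feature_matrix(features)
  labels <- features$tissue_label
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs >= 2 samples", call. = FALSE)
  centers <- colMeans(x)
  scales <- apply(x, 2, sd)
  scales[scales == 0] <- 1
  xs <- scale(x, center = centers, scale = scales)
  p <- ncol(xs); n <- nrow(xs)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  grand <- colMeans(xs)
  for (cl in classes) {
    xi <- xs[labels == cl, , drop = FALSE]
    mu <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, mu))
    B <- B + nrow(xi) * tcrossprod(mu - grand)
  }
  W <- W / (n - length(classes))
  B <- B / (length(classes) - 1)
  if (rcond_sym(W) < 1e-10)
    warning("singular within-class scatter: diagonal shrinkage applied",
            call. = FALSE)
  Wr <- (1 - shrinkage) * W + shrinkage * diag(diag(W), p)
  # symmetric whitening: eigenvectors of W^-1/2 B W^-1/2
  ew <- eigen(Wr, symmetric = TRUE)
  vals <- pmax(ew$values, max(ew$values) * 1e-12)
  Wi2 <- ew$vectors %*% diag(1 / sqrt(vals), p) %*% t(ew$vectors)
  S <- Wi2 %*% B %*% Wi2
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  k <- min(n_canonical, length(classes) - 1, p)
  weights <- Wi2 %*% es$vectors[, seq_len(k), drop = FALSE]
  colnames(weights) <- paste0("can", seq_len(k))
  rownames(weights) <- colnames(x)
  scores <- xs %*% weights
  centroids <- do.call(rbind, lapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE])))
  rownames(centroids) <- classes
  ev <- pmax(es$values[seq_len(k)], 0)
  # back to raw-scatter eigenvalues for the canonical correlations
  ev_raw <- ev * (length(classes) - 1) / (n - length(classes))
  structure(list(weights = weights, centroids = centroids,
                 feature_names = colnames(x), centers = centers,
                 scales = scales, classes = classes,
                 eigenvalues = ev,
                 canonical_correlations = sqrt(ev_raw / (1 + ev_raw))),
            class = "discriminant_model")
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Project samples into canonical space
#'
#' @param model a [fit_canonical_discriminant()] result.
#' @param features feature table or matrix with the training features.
#' @return Matrix of canonical scores.
#' @export
canonical_scores <- function(model, features) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  x <- x[, model$feature_names, drop = FALSE]
  xs <- scale(x, center = model$centers, scale = model$scales)
  xs %*% model$weights
}

#' Classify by nearest class centroid in canonical space
#'
#' @param model a `discriminant_model`.
#' @param features feature table or matrix.
#' @return Character vector of predicted class labels (equal priors).
#' @export
predict_discriminant <- function(model, features) {
  sc <- canonical_scores(model, features)
  d2 <- vapply(seq_len(nrow(model$centroids)), function(i)
    rowSums(sweep(sc, 2, model$centroids[i, ])^2),
    numeric(nrow(sc)))
  d2 <- matrix(d2, nrow = nrow(sc))
  rownames(model$centroids)[apply(d2, 1, which.min)]
}

#' Pairwise tissue-classification accuracies
#'
#' For every unordered pair of tissue types, fits the canonical
#' discriminant on that pair alone and scores sample-level accuracy:
#' the fraction of held-out samples assigned to their true class by
#' nearest centroid in canonical space. Validation is leave-one-out by
#' default; resubstitution (fit and score on the same samples) is
#' available for comparison.
#'
#' @param features a [feature_table()].
#' @param method `"loo"` (leave-one-out, default) or `"resubstitution"`.
#' @param n_canonical,shrinkage passed to
#'   [fit_canonical_discriminant()].
#' @return A symmetric `pairwise_accuracy` matrix with `NA` diagonal.
#' @export
pairwise_classify <- function(features, method = c("loo", "resubstitution"),
                              n_canonical = 3, shrinkage = 1e-3) {
  method <- match.arg(method)
  classes <- unique(features$tissue_label)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  acc <- matrix(NA_real_, length(classes), length(classes),
                dimnames = list(classes, classes))
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (j <= i) next
    sub <- features[features$tissue_label %in% classes[c(i, j)], ,
                    drop = FALSE]
    if (min(table(sub$tissue_label)) < 2)
      stop("every class in a pair needs >= 2 samples", call. = FALSE)
    correct <- if (method == "resubstitution") {
      m <- fit_canonical_discriminant(sub, n_canonical, shrinkage)
      predict_discriminant(m, sub) == sub$tissue_label
    } else {
      vapply(seq_len(nrow(sub)), function(k) {
        train <- sub[-k, , drop = FALSE]
        if (min(table(train$tissue_label)) < 2) return(NA)
        m <- fit_canonical_discriminant(train, n_canonical, shrinkage)
        predict_discriminant(m, sub[k, , drop = FALSE]) ==
          sub$tissue_label[k]
      }, logical(1))
    }
    acc[i, j] <- acc[j, i] <- mean(correct, na.rm = TRUE)
  }
  structure(acc, class = c("pairwise_accuracy", class(acc)))
}

#' ROC curve via logistic regression
#'
#' Fits a logistic regression of the binary label on the supplied scores
#' (canonical scores or any feature subset), sweeps the predicted
#' probability over all thresholds, and integrates the ROC by the
#' trapezoid rule. Under perfect separation the (divergent) maximum
#' likelihood fit still orders the samples, so the ROC and AUC remain
#' defined; a warning notes the separation.
#'
#' @param scores numeric vector or matrix of predictors.
#' @param labels binary labels (logical, 0/1, or two-level factor); the
#'   second level / `TRUE` / `1` is the positive class.
#' @return A `roc_result`: data.frame of `threshold`, `tpr`, `fpr`
#'   (monotone along thresholds), with attribute `auc`.
#' @export
roc_from_logistic <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("both classes must be present",
                                   call. = FALSE)
  x <- as.matrix(scores)
  fit <- withCallingHandlers(
    glm.fit2(x, y),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        warning("perfect separation: ROC from the ordered fit", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  # one predictor: sweep the score itself (keeps the score's direction,
  # which a refitted slope would silently flip); otherwise sweep the
  # fitted probability of the logistic model
  p <- if (ncol(x) == 1) as.numeric(x[, 1]) else fit$fitted
  thr <- c(Inf, sort(unique(p), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(p[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(p[y == 0] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(data.frame(threshold = thr, tpr = tpr, fpr = fpr),
            auc = auc, class = c("roc_result", "data.frame"))
}

glm.fit2 <- function(x, y) {
  d <- data.frame(y = y, x)
  glm(y ~ ., data = d, family = binomial())
}

#' AUC of a ROC result
#'
#' @param roc a `roc_result`.
#' @return The trapezoid-rule area under the curve.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' One-way ANOVA with pairwise Fisher LSD comparisons
#'
#' One-way ANOVA F-test across tissue groups followed by Fisher's least
#' significant difference: pairwise t-tests using the pooled within-group
#' variance (ANOVA mean-square error) with N - k degrees of freedom.
#' Significance is flagged at p < 0.05.
#'
#' @param values numeric metric values.
#' @param groups group labels (one per value).
#' @return List with `anova_p`, `anova_F`, and `pairs` (data.frame of
#'   `group1`, `group2`, `difference`, `p_value`, `significant`).
#' @export
group_comparison <- function(values, groups) {
  groups <- as.character(groups)
  classes <- unique(groups)
  if (length(classes) < 2) stop("need at least 2 groups", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2)) stop("every group needs >= 2 values", call. = FALSE)
  n <- length(values); k <- length(classes)
  means <- tapply(values, groups, mean)
  sse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (sse <= 0)
    stop("degenerate variance: no within-group variability", call. = FALSE)
  mse <- sse / (n - k)
  ssb <- sum(tab[classes] * (means[classes] - mean(values))^2)
  f_stat <- (ssb / (k - 1)) / mse
  anova_p <- stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE)
  pairs <- do.call(rbind, lapply(seq_len(k - 1), function(i)
    do.call(rbind, lapply((i + 1):k, function(j) {
      g1 <- classes[i]; g2 <- classes[j]
      diff <- means[[g1]] - means[[g2]]
      se <- sqrt(mse * (1 / tab[[g1]] + 1 / tab[[g2]]))
      p <- 2 * pt(abs(diff) / se, df = n - k, lower.tail = FALSE)
      data.frame(group1 = g1, group2 = g2, difference = diff,
                 p_value = p, significant = p < 0.05)
    }))))
  rownames(pairs) <- NULL
  list(anova_F = f_stat, anova_p = anova_p, pairs = pairs)
}
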