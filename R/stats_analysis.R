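#' Pearson correlation with significance
#'
#' Product-moment correlation; the two-sided p-value comes from the
#' t-transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, both nonconstant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Simple least-squares regression
#'
#' Ordinary least squares of y on x with intercept; `r_squared` is
#' 1 - SSres/SStot and equals the squared Pearson coefficient. A constant
#' response is handled as the degenerate flat fit (slope 0, `r_squared`
#' defined as 0).
#'
#' @param x,y numeric vectors, n >= 3; x nonconstant.
#' @return A `regression_result`: list with `slope`, `intercept`, `r`,
#'   `r_squared`, `p_value`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0) stop("zero variance input")
  n <- length(x)
  if (sd(y) == 0) {
    return(structure(list(slope = 0, intercept = y[1], r = 0,
                          r_squared = 0, p_value = 1, n = n),
                     class = "regression_result"))
  }
  fit <- lm(y ~ x)
  co <- coef(fit)
  pr <- pearson(x, y)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r = pr$r, r_squared = pr$r^2, p_value = pr$p_value,
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression> y = %.4g + %.4g x, r = %.3f, r^2 = %.3f, p = %.3g (n = %d)\n",
    x$intercept, x$slope, x$r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

# ---- canonical discriminant analysis -------------------------------------

#' Fit a canonical discriminant model
#'
#' Canonical axes maximize between-group over pooled within-group scatter
#' (the generalized eigenproblem B a = lambda W a, solved through the
#' Cholesky factor of W). Observations are classified to the nearest group
#' centroid in canonical space; because axes are scaled to unit pooled
#' within-group variance, this is the Mahalanobis rule under the pooled
#' covariance with equal priors. A singular within-group scatter (e.g.
#' collinear height features from small field samples) is
#' ridge-regularized with 1e-8 times its trace.
#'
#' @param features numeric matrix (samples x features) or data.frame.
#' @param labels factor (or character) of group memberships; every group
#'   needs at least 2 samples.
#' @return A `cda_model`: group labels and centroids, canonical
#'   coefficients, pooled within-group covariance, and projected group
#'   means.
#' @export
cda_fit <- function(features, labels) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- droplevels(as.factor(labels))
  if (nrow(features) != length(labels))
    stop("features and labels must have matching length")
  counts <- table(labels)
  if (any(counts < 2))
    stop(sprintf("group '%s' has fewer than 2 samples",
                 names(counts)[counts < 2][1]))
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  fit <- cda_fit_unchecked(features, labels)
  fit
}

cda_fit_unchecked <- function(features, labels) {
  p <- ncol(features)
  g <- nlevels(labels)
  n <- nrow(features)
  means <- do.call(rbind, lapply(levels(labels), function(l)
    colMeans(features[labels == l, , drop = FALSE])))
  rownames(means) <- levels(labels)
  grand <- colMeans(features)
  W <- matrix(0, p, p)
  for (l in levels(labels)) {
    xc <- sweep(features[labels == l, , drop = FALSE], 2,
                means[l, ])
    W <- W + crossprod(xc)
  }
  W <- W / max(n - g, 1)
  counts <- as.numeric(table(labels))
  mc <- sweep(means, 2, grand)
  B <- crossprod(mc * sqrt(counts)) / max(g - 1, 1)
  ridge_used <- FALSE
  L <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(L) || rcond(W) < 1e-10) {
    W_r <- W + diag(1e-8 * sum(diag(W)) + 1e-30, p)
    L <- chol(W_r)
    ridge_used <- TRUE
  }
  Linv <- backsolve(L, diag(p))
  S <- t(Linv) %*% B %*% Linv
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  naxes <- min(g - 1, p)
  axes <- Linv %*% es$vectors[, seq_len(naxes), drop = FALSE]
  # unit pooled within-group variance along each axis
  wvar <- diag(t(axes) %*% W %*% axes)
  wvar[wvar < 1e-300] <- 1
  axes <- sweep(axes, 2, sqrt(wvar), "/")
  structure(list(group_labels = levels(labels),
                 group_means = means,
                 grand_mean = grand,
                 canonical_coefficients = axes,
                 eigenvalues = es$values[seq_len(naxes)],
                 pooled_within_scatter = W,
                 ridge_used = ridge_used,
                 group_scores = sweep(means, 2, grand) %*% axes),
            class = "cda_model")
}

#' @export
print.cda_model <- function(x, ...) {
  cat(sprintf("<cda_model> %d groups (%s), %d canonical axes%s\n",
              length(x$group_labels),
              paste(x$group_labels, collapse = ", "),
              ncol(x$canonical_coefficients),
              if (x$ridge_used) ", ridge-regularized" else ""))
  invisible(x)
}

#' Classify samples with a canonical discriminant model
#'
#' @param object a `cda_model`.
#' @param newdata numeric matrix or data.frame of features.
#' @param ... unused.
#' @return Factor of predicted group labels.
#' @export
predict.cda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sc <- sweep(newdata, 2, object$grand_mean) %*%
    object$canonical_coefficients
  gs <- object$group_scores
  d2 <- outer(rowSums(sc^2), rowSums(gs^2), "+") - 2 * sc %*% t(gs)
  factor(object$group_labels[max.col(-d2, ties.method = "first")],
         levels = object$group_labels)
}

#' Confusion matrix of canonical discriminant classification
#'
#' Rows are true groups, columns predicted groups, entries row-normalized
#' percentages (each row sums to 100). The default scheme is
#' leave-one-out — the model is refitted without each sample before
#' classifying it — which is the less optimistic choice;
#' `"resubstitution"` classifies the training samples directly.
#'
#' @param features numeric matrix or data.frame (samples x features).
#' @param labels factor of true groups; row/column order follows its level
#'   order.
#' @param scheme `"leave_one_out"` or `"resubstitution"`.
#' @param model optional pre-fitted `cda_model` (used for
#'   resubstitution; leave-one-out always refits).
#' @return Numeric matrix of percentages with class `confusion_matrix` and
#'   attribute `counts` (row sample sizes).
#' @export
cda_confusion <- function(features, labels,
                          scheme = c("leave_one_out", "resubstitution"),
                          model = NULL) {
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  lev <- levels(labels)
  pred <- if (scheme == "resubstitution") {
    if (is.null(model)) model <- cda_fit(features, labels)
    predict(model, features)
  } else {
    p <- factor(rep(lev[1], nrow(features)), levels = lev)
    for (i in seq_len(nrow(features))) {
      fit_i <- cda_fit_unchecked(features[-i, , drop = FALSE],
                                 droplevels(labels[-i]))
      p[i] <- as.character(predict(fit_i,
                                   features[i, , drop = FALSE]))
    }
    p
  }
  tab <- table(true = labels, predicted = factor(pred, levels = lev))
  counts <- rowSums(tab)
  pct <- sweep(100 * tab, 1, pmax(counts, 1), "/")
  out <- matrix(as.numeric(pct), nrow = length(lev),
                dimnames = list(true = lev, predicted = lev))
  structure(out, counts = counts, scheme = scheme,
            class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%s), row percentages:\n",
              attr(x, "scheme")))
  m <- round(unclass(x), 1)
  attr(m, "counts") <- attr(m, "scheme") <- NULL
  print(m)
  invisible(x)
}

# ---- dataset-level analysis ----------------------------------------------

#' Relate estimated volumes to ground-truth biomass and density
#'
#' Computes the study's six bivariate relationships — total volume vs
#' total biomass, maize volume vs maize biomass, weed volume vs weed
#' biomass, total and weed volume vs weed density, and maize count vs
#' maize volume (flagged degenerate when the count is constant across
#' samples, as in a uniformly planted crop) — plus the canonical
#' discriminant classification of weed class from weed height features
#' (max and 90th-percentile height), with leave-one-out and
#' resubstitution confusion matrices.
#'
#' @param volumes data.frame with columns `sample_id`, `maize_volume_m3`,
#'   `weed_volume_m3`, `total_volume_m3`, `weed_max_height_m`,
#'   `weed_p90_height_m`.
#' @param truth data.frame with columns `sample_id`, `maize_biomass_g`,
#'   `weed_biomass_g`, `weed_density`, `weed_class` (`monocots`, `dicots`,
#'   `mixture`, or `none`), `maize_count`.
#' @return List with `relationships` (data.frame), `confusion_loo`,
#'   `confusion_resub`, and `n_samples`.
#' @export
analyze_dataset <- function(volumes, truth) {
  d <- merge(volumes, truth, by = "sample_id")
  if (nrow(d) < nrow(volumes) || nrow(d) < nrow(truth))
    stop("sample ids of volumes and truth do not match")
  total_biomass <- d$maize_biomass_g + d$weed_biomass_g
  rel <- function(name, x, y) {
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
      return(data.frame(relationship = name, slope = NA_real_,
                        intercept = NA_real_, r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        n = length(x),
                        flag = "degenerate",
                        stringsAsFactors = FALSE))
    fit <- ols_fit(x, y)
    data.frame(relationship = name, slope = fit$slope,
               intercept = fit$intercept, r = fit$r,
               r_squared = fit$r_squared, p_value = fit$p_value,
               n = fit$n, flag = "", stringsAsFactors = FALSE)
  }
  relationships <- rbind(
    rel("total_volume~total_biomass", d$total_volume_m3, total_biomass),
    rel("maize_volume~maize_biomass", d$maize_volume_m3,
        d$maize_biomass_g),
    rel("weed_volume~weed_biomass", d$weed_volume_m3, d$weed_biomass_g),
    rel("total_volume~weed_density", d$total_volume_m3, d$weed_density),
    rel("weed_volume~weed_density", d$weed_volume_m3, d$weed_density),
    rel("maize_count~maize_volume", d$maize_count, d$maize_volume_m3))
  # a near-constant crop stand makes the count relationship uninformative
  if (!is.na(relationships$flag[6]) && relationships$flag[6] == "" &&
      length(unique(d$maize_count[d$maize_count > 0])) <= 1)
    relationships$flag[6] <- "degenerate"

  weedy <- d$weed_class %in% c("monocots", "dicots", "mixture") &
    is.finite(d$weed_max_height_m)
  confusion_loo <- confusion_resub <- NULL
  if (sum(weedy) >= 6) {
    labs <- factor(d$weed_class[weedy],
                   levels = c("monocots", "dicots", "mixture"))
    labs <- droplevels(labs)
    feats <- cbind(max = d$weed_max_height_m[weedy],
                   p90 = d$weed_p90_height_m[weedy])
    if (nlevels(labs) >= 2 && all(table(labs) >= 2)) {
      confusion_loo <- cda_confusion(feats, labs, "leave_one_out")
      confusion_resub <- cda_confusion(feats, labs, "resubstitution")
    }
  }
  list(relationships = relationships,
       confusion_loo = confusion_loo,
       confusion_resub = confusion_resub,
       n_samples = nrow(d))
}
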