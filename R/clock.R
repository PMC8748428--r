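# Elastic-net epigenetic clocks: fitting, prediction, and the
# cross-validation schemes used to report unbiased accuracy (LOO, seeded
# stratified 10-fold, and leave-one-species-out).

new_equiclock <- function(intercept, coefficients, alpha, lambda, transform,
                          cpg_means, n_train) {
  structure(list(
    intercept = intercept,
    coefficients = coefficients,
    alpha = alpha,
    lambda = lambda,
    transform = transform,
    cpg_means = cpg_means,
    n_train = n_train
  ), class = "equiclock")
}

#' Fit an elastic-net epigenetic clock
#'
#' Regresses transformed chronological age on CpG methylation fractions with
#' an elastic-net penalty at mixing parameter `alpha = 0.5` (midway between
#' ridge and lasso; fixed by convention, not optimized). The penalty
#' strength is chosen automatically by an internal seeded 10-fold
#' cross-validation minimizing mean squared error; among ties the smallest
#' lambda (densest model) is taken. Predictors are standardized internally
#' and coefficients are returned on the original beta scale.
#'
#' @param beta A [beta_matrix()] (samples x CpGs).
#' @param sheet A [sample_sheet()] aligned with `beta`.
#' @param transform An [age_transform()]; the dependent variable is the
#'   transformed age and predictions are inverted back to years.
#' @param alpha Elastic-net mixing parameter, default 0.5.
#' @param seed Integer seed for the internal fold assignment (required for
#'   reproducibility).
#' @param nfolds Internal cross-validation folds for the penalty search.
#' @param nlambda,lambda.min.ratio Penalty path resolution passed to
#'   `glmnet`; the default short path (30 points down to 1% of lambda-max)
#'   is adequate for the dense, strong aging signal this model targets.
#' @param na_action `"error"` (default) refuses missing betas; `"drop"`
#'   removes CpGs with any missing value before fitting.
#' @param ... Further arguments passed to `glmnet::cv.glmnet` (e.g.
#'   `thresh` for a tighter coordinate-descent tolerance).
#' @return An object of class `"equiclock"` with components `intercept`
#'   (transformed-age units), `coefficients` (named vector of nonzero CpG
#'   weights on the beta scale), `alpha`, `lambda`, `transform`, `cpg_means`
#'   (training means of the model CpGs, used by the optional imputation
#'   policy at prediction) and `n_train`.
#' @seealso [predict.equiclock()], [cross_validate()], [save_clock()]
#' @export
fit_clock <- function(beta, sheet, transform = age_transform("identity"),
                      alpha = 0.5, seed = 1, nfolds = 10, ...,
                      nlambda = 30, lambda.min.ratio = 0.01,
                      na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  sheet <- align_samples(beta, sheet)
  X <- unclass(beta)
  n <- nrow(X)
  if (n < 20) eq_stop("eq_fit_error", "need >= 20 training samples, got %d", n)
  if (n < nfolds) eq_stop("eq_fold_error", "n = %d < nfolds = %d", n, nfolds)
  if (anyNA(X)) {
    if (na_action == "error") {
      bad <- colnames(X)[colSums(is.na(X)) > 0]
      eq_stop("eq_missing_error",
              "%d CpG(s) carry missing betas (na_action = 'error'): %s%s",
              length(bad), paste(utils::head(bad, 5), collapse = ", "),
              if (length(bad) > 5) ", ..." else "")
    }
    X <- X[, colSums(is.na(X)) == 0, drop = FALSE]
  }
  y <- transform_age(transform, sheet$age, sheet$species)
  if (stats::sd(y) == 0) {
    eq_stop("eq_degenerate_error", "constant (transformed) age response")
  }
  cpg_means <- colMeans(X)
  keep <- matrixStats_colSds(X) > 0
  if (!any(keep)) {
    # No informative predictor at all: intercept-only clock.
    return(new_equiclock(mean(y), stats::setNames(numeric(0), character(0)),
                         alpha, NA_real_, transform,
                         stats::setNames(numeric(0), character(0)), n))
  }
  Xk <- X[, keep, drop = FALSE]
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  # Compute the whole requested lambda path (no early exit on small deviance
  # changes) so the selected penalty depends only on data, seed and path
  # settings — and so a noiseless signal can be fit essentially exactly.
  prev <- glmnet::glmnet.control()
  glmnet::glmnet.control(fdev = 0, devmax = 1)
  on.exit(glmnet::glmnet.control(fdev = prev$fdev, devmax = prev$devmax),
          add = TRUE)
  cv <- glmnet::cv.glmnet(Xk, y, alpha = alpha, foldid = foldid,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda.min.ratio,
                          standardize = TRUE, family = "gaussian", ...)
  # Smallest lambda among CV-MSE minimizers: deterministic, denser model.
  lam <- min(cv$lambda[cv$cvm <= min(cv$cvm) + 1e-12])
  cf <- stats::coef(cv, s = lam)
  w <- as.numeric(cf)[-1]
  names(w) <- rownames(cf)[-1]
  w <- w[w != 0]
  new_equiclock(as.numeric(cf)[1], w, alpha, lam, transform,
                cpg_means[names(w)], n)
}

# Column standard deviations without extra dependencies.
matrixStats_colSds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

#' Predict DNAm age from methylation
#'
#' Applies the linear predictor (intercept + sum of coefficient times beta)
#' and inverts the clock's age transform per sample species, returning DNAm
#' age in years.
#'
#' @param object An `"equiclock"` model.
#' @param beta A [beta_matrix()] containing at least the model's CpGs.
#' @param sheet A [sample_sheet()] aligned with `beta` (supplies species for
#'   the inverse transform; not needed for identity-transform clocks, pass
#'   `NULL`).
#' @param missing_cpgs `"error"` (default) refuses absent or missing model
#'   CpGs; `"impute_mean"` substitutes the training mean recorded in the
#'   model file.
#' @param ... Unused.
#' @return Named numeric vector of DNAm ages in years.
#' @export
predict.equiclock <- function(object, beta, sheet = NULL,
                              missing_cpgs = c("error", "impute_mean"), ...) {
  missing_cpgs <- match.arg(missing_cpgs)
  X <- unclass(beta)
  cpgs <- names(object$coefficients)
  absent <- setdiff(cpgs, colnames(X))
  if (length(absent) > 0 && missing_cpgs == "error") {
    eq_stop("eq_missing_error", "model CpG(s) absent from matrix: %s%s",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ..." else "")
  }
  lp <- rep(object$intercept, nrow(X))
  names(lp) <- rownames(X)
  if (length(cpgs) > 0) {
    present <- setdiff(cpgs, absent)
    V <- X[, present, drop = FALSE]
    if (anyNA(V)) {
      if (missing_cpgs == "error") {
        bad <- colnames(V)[colSums(is.na(V)) > 0]
        eq_stop("eq_missing_error",
                "missing beta values for model CpG(s): %s",
                paste(utils::head(bad, 5), collapse = ", "))
      }
      for (j in colnames(V)) {
        V[is.na(V[, j]), j] <- object$cpg_means[[j]]
      }
    }
    lp <- lp + as.numeric(V %*% object$coefficients[present])
    if (length(absent) > 0) {
      lp <- lp + sum(object$coefficients[absent] * object$cpg_means[absent])
    }
  }
  if (object$transform$kind == "identity") {
    return(lp)
  }
  if (is.null(sheet)) {
    eq_stop("eq_validation_error",
            "a sample sheet (species) is required to invert a '%s' clock",
            object$transform$kind)
  }
  sheet <- align_samples(beta, sheet)
  out <- inverse_transform_age(object$transform, lp, sheet$species)
  names(out) <- rownames(X)
  out
}

#' @exportS3Method base::print
print.equiclock <- function(x, ...) {
  cat(sprintf("equiclock: elastic-net clock (alpha = %g)\n", x$alpha))
  cat(sprintf("  %d CpGs, intercept %.4f (transformed-age units)\n",
              length(x$coefficients), x$intercept))
  cat(sprintf("  lambda = %s, trained on %d samples\n",
              if (is.na(x$lambda)) "NA (intercept-only)" else
                format(x$lambda, digits = 4), x$n_train))
  cat(sprintf("  age transform: %s\n", x$transform$kind))
  invisible(x)
}

#' @export
coef.equiclock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @exportS3Method base::summary
summary.equiclock <- function(object, ...) {
  w <- object$coefficients
  out <- list(
    n_cpgs = length(w),
    n_positive = sum(w > 0),
    n_negative = sum(w < 0),
    alpha = object$alpha,
    lambda = object$lambda,
    transform = object$transform$kind,
    n_train = object$n_train,
    top = utils::head(w[order(-abs(w))], 10)
  )
  class(out) <- "summary.equiclock"
  out
}

#' @exportS3Method base::print
print.summary.equiclock <- function(x, ...) {
  cat(sprintf("Elastic-net clock: %d CpGs (%d +, %d -), transform %s\n",
              x$n_cpgs, x$n_positive, x$n_negative, x$transform))
  cat(sprintf("alpha = %g, lambda = %s, n_train = %d\n", x$alpha,
              format(x$lambda, digits = 4), x$n_train))
  if (length(x$top) > 0) {
    cat("largest |coefficient|:\n")
    print(round(x$top, 5))
  }
  invisible(x)
}

#' Accuracy of age predictions
#'
#' The two accuracy metrics used throughout: the age correlation R (Pearson
#' correlation between chronological age and its DNAm estimate) and the
#' median absolute error in years.
#'
#' @param pred Predicted ages, years.
#' @param true Chronological ages, years.
#' @return List with `r` (Pearson correlation; `NA` with a warning when
#'   either vector is constant) and `mae` (median absolute error, years).
#' @export
evaluate_predictions <- function(pred, true) {
  if (length(pred) != length(true) || length(pred) < 3) {
    eq_stop("eq_validation_error", "need >= 3 aligned prediction pairs")
  }
  r <- if (stats::sd(pred) == 0 || stats::sd(true) == 0) {
    eq_warn("constant vector: correlation undefined")
    NA_real_
  } else {
    stats::cor(pred, true)
  }
  list(r = r, mae = stats::median(abs(pred - true)))
}

#' Cross-validate an epigenetic clock
#'
#' Estimates out-of-sample clock accuracy under one of three schemes:
#' `"LOO"` (leave one sample out), `"KFOLD10"` (ten folds, assignment
#' seeded and stratified by species), or `"LOSO"` (leave one species out —
#' the accuracy to expect in a species absent from training). Every fold
#' refits the clock from scratch on its training split, including the
#' internal penalty search, so no information leaks from held-out samples.
#'
#' @inheritParams fit_clock
#' @param scheme One of `"LOO"`, `"KFOLD10"`, `"LOSO"`.
#' @param seed Integer seed controlling fold assignment and the per-fold
#'   internal penalty search.
#' @param ... Further arguments passed to [fit_clock()].
#' @return An object of class `"equiclock_cv"`: `predictions` (data frame
#'   with sample_id, species, tissue, age, dnam_age, fold), `scheme`,
#'   `overall` (r and MAE in years) and `by_species` / `by_tissue` metric
#'   tables. Every sample is predicted exactly once.
#' @export
cross_validate <- function(beta, sheet, transform = age_transform("identity"),
                           scheme = c("LOO", "KFOLD10", "LOSO"), seed = 1,
                           ...) {
  scheme <- match.arg(scheme)
  sheet <- align_samples(beta, sheet)
  n <- nrow(beta)
  folds <- switch(scheme,
    LOO = as.list(seq_len(n)),
    KFOLD10 = {
      if (n < 10) eq_stop("eq_fold_error", "KFOLD10 needs >= 10 samples")
      assignment <- integer(n)
      with_seed(seed, {
        for (sp in unique(sheet$species)) {
          idx <- which(sheet$species == sp)
          assignment[idx] <- sample(rep_len(sample(10), length(idx)))
        }
      })
      split(seq_len(n), assignment)
    },
    LOSO = {
      if (length(unique(sheet$species)) < 2) {
        eq_stop("eq_fold_error", "LOSO requires >= 2 species")
      }
      split(seq_len(n), sheet$species)
    }
  )
  pred <- rep(NA_real_, n)
  fold_of <- integer(n)
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(train_idx) < 20) {
      eq_stop("eq_fold_error",
              "fold %d leaves only %d training samples (< 20)", f,
              length(train_idx))
    }
    model <- fit_clock(beta[train_idx, , drop = FALSE],
                       sheet[train_idx, , drop = FALSE],
                       transform = transform, seed = seed * 1000L + f, ...)
    pred[test_idx] <- predict(model, beta[test_idx, , drop = FALSE],
                              sheet[test_idx, , drop = FALSE])
    fold_of[test_idx] <- f
  }
  predictions <- data.frame(
    sample_id = sheet$sample_id, species = sheet$species,
    tissue = sheet$tissue, age = sheet$age, dnam_age = pred,
    fold = fold_of, stringsAsFactors = FALSE
  )
  group_metrics <- function(g) {
    do.call(rbind, lapply(split(predictions, predictions[[g]]), function(d) {
      m <- if (nrow(d) >= 3 && stats::sd(d$age) > 0 && stats::sd(d$dnam_age) > 0) {
        evaluate_predictions(d$dnam_age, d$age)
      } else {
        list(r = NA_real_, mae = stats::median(abs(d$dnam_age - d$age)))
      }
      data.frame(group = d[[g]][1], n = nrow(d), r = m$r, mae = m$mae,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    predictions = predictions,
    scheme = scheme,
    overall = evaluate_predictions(pred, sheet$age),
    by_species = group_metrics("species"),
    by_tissue = group_metrics("tissue")
  ), class = "equiclock_cv")
}

#' @exportS3Method base::print
print.equiclock_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation, %d samples\n", x$scheme,
              nrow(x$predictions)))
  cat(sprintf("  overall: r = %.3f, MAE = %.2f years\n", x$overall$r,
              x$overall$mae))
  if (nrow(x$by_species) > 1) {
    cat("  by species:\n")
    bs <- x$by_species
    for (i in seq_len(nrow(bs))) {
      cat(sprintf("    %-16s n = %3d  r = %s  MAE = %.2f\n", bs$group[i],
                  bs$n[i],
                  ifelse(is.na(bs$r[i]), "  NA", sprintf("%.3f", bs$r[i])),
                  bs$mae[i]))
    }
  }
  invisible(x)
}

#' @export
plot.equiclock_cv <- function(x, ...) {
  d <- x$predictions
  sp <- factor(d$species)
  graphics::plot(d$age, d$dnam_age, col = as.integer(sp), pch = 16,
                 xlab = "chronological age (years)",
                 ylab = "DNAm age (years)",
                 main = sprintf("%s CV: r = %.2f, MAE = %.2f y", x$scheme,
                                x$overall$r, x$overall$mae), ...)
  graphics::abline(0, 1, lty = 2)
  if (nlevels(sp) > 1) {
    graphics::legend("topleft", legend = levels(sp), col = seq_len(nlevels(sp)),
                     pch = 16, bty = "n", cex = 0.8)
  }
  invisible(x)
}
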