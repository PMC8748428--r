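# Castration EWAS: per-CpG regression of methylation on castration status
# with chronological age as covariate, and the sector classification of
# aging CpGs into shared versus group-specific patterns.

#' Per-CpG castration covariate screen
#'
#' For every CpG, an ordinary least-squares regression of methylation on a
#' castration indicator (1 = gelding, so a positive coefficient means
#' higher methylation in geldings) with chronological age in years as a
#' nuisance covariate. Reports the castration coefficient (beta-fraction
#' units), its t statistic, two-sided p-value and BH q-value; the age
#' coefficient is retained. Restricted to male samples: the sheet must
#' contain both castration states (`"yes"` and `"no"`).
#'
#' @param beta A [beta_matrix()].
#' @param sheet A [sample_sheet()]; only rows with `sex == "male"` and a
#'   declared castration state are used.
#' @param covariates Optional data frame of extra per-sample covariates
#'   (e.g. breed as a factor) to adjust for; rows aligned with `sheet`.
#' @return A data frame of class `"covariate_screen_table"`: `cpg_id`,
#'   `castration_coef`, `castration_t`, `castration_p`, `castration_q`,
#'   `age_coef`, `n`.
#' @export
covariate_screen <- function(beta, sheet, covariates = NULL) {
  sheet <- align_samples(beta, sheet)
  male <- sheet$sex == "male" & sheet$castrated %in% c("yes", "no")
  if (sum(male) < 10) {
    eq_stop("eq_design_error", "need >= 10 male samples, got %d", sum(male))
  }
  sub <- sheet[male, , drop = FALSE]
  states <- unique(sub$castrated)
  if (length(states) < 2) {
    eq_stop("eq_design_error",
            "both castration states required; found only '%s'", states)
  }
  Y <- unclass(beta)[male, , drop = FALSE]
  design <- data.frame(castrated = as.numeric(sub$castrated == "yes"),
                       age = sub$age)
  if (!is.null(covariates)) {
    design <- cbind(design, covariates[male, , drop = FALSE])
  }
  X <- stats::model.matrix(~ ., design)
  if (qr(X)$rank < ncol(X)) {
    eq_stop("eq_design_error", "design matrix is rank deficient")
  }
  n <- nrow(X)
  df_res <- n - ncol(X)
  fit <- stats::lm.fit(X, Y)
  coefs <- fit$coefficients
  rss <- colSums(fit$residuals^2)
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(chol(crossprod(X)))
  j <- which(colnames(X) == "castrated")
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tstat <- coefs[j, ] / se
  # Zero-variance CpGs have sigma2 = 0: coefficient 0/0, flagged missing.
  tstat[!is.finite(tstat)] <- NA_real_
  p <- 2 * stats::pt(-abs(tstat), df = df_res)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok])
  out <- data.frame(cpg_id = colnames(Y),
                    castration_coef = unname(coefs[j, ]),
                    castration_t = unname(tstat),
                    castration_p = unname(p),
                    castration_q = unname(q),
                    age_coef = unname(coefs[which(colnames(X) == "age"), ]),
                    n = n, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("covariate_screen_table", "data.frame")
  out
}

#' Sector classification of aging CpGs between two groups
#'
#' Classifies each CpG by comparing its age-correlation Fisher z statistic
#' in two groups (e.g. geldings = A, stallions = B): `"shared"` when the
#' association is strong (two-sided p < `p_strong`) with the same sign in
#' both groups; `"A_specific"` when strong in A while null in B (p >
#' `p_null`); symmetrically `"B_specific"`; `"neither"` otherwise. The
#' default thresholds are p < 1e-4 (strong) and p > 0.05 (null).
#'
#' @param zA,zB Named (by cpg_id) or aligned numeric vectors of Fisher z
#'   statistics for the two groups.
#' @param cpg_ids CpG identifiers when `zA`/`zB` are unnamed.
#' @param p_strong,p_null The two significance thresholds.
#' @return A data frame of class `"sector_table"`: `cpg_id`, `zA`, `zB`,
#'   `class`.
#' @export
sector_classify <- function(zA, zB, cpg_ids = NULL, p_strong = 1e-4,
                            p_null = 0.05) {
  if (is.null(cpg_ids)) {
    if (is.null(names(zA)) || is.null(names(zB))) {
      eq_stop("eq_alignment_error",
              "provide cpg_ids or named z vectors")
    }
    if (!setequal(names(zA), names(zB))) {
      eq_stop("eq_alignment_error", "zA and zB cover different CpGs")
    }
    cpg_ids <- names(zA)
    zB <- zB[cpg_ids]
  } else if (length(zA) != length(zB) || length(zA) != length(cpg_ids)) {
    eq_stop("eq_alignment_error", "zA, zB and cpg_ids must align")
  }
  pA <- 2 * stats::pnorm(-abs(zA))
  pB <- 2 * stats::pnorm(-abs(zB))
  strongA <- pA < p_strong
  strongB <- pB < p_strong
  nullA <- pA > p_null
  nullB <- pB > p_null
  cls <- rep("neither", length(zA))
  cls[strongA & strongB & sign(zA) == sign(zB)] <- "shared"
  cls[strongA & nullB] <- "A_specific"
  cls[strongB & nullA] <- "B_specific"
  out <- data.frame(cpg_id = cpg_ids, zA = unname(zA), zB = unname(zB),
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("sector_table", "data.frame")
  out
}
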