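# Epigenome-wide association screens of a numeric trait, cross-tissue
# Stouffer meta-analysis, FDR control, top-k selection, overlap tests and
# effect-size contrasts.

# Fisher z statistic for a Pearson correlation at pairwise-complete size n:
# sqrt(n - 3) * atanh(r), with r clamped just inside +/-1 so perfect
# correlations map to a large finite statistic. Undefined (NA) for n <= 3.
fisher_z <- function(r, n) {
  r <- pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15)
  z <- sqrt(pmax(n - 3, 0)) * atanh(r)
  z[n <= 3] <- NA_real_
  z
}

#' Per-CpG Pearson correlation screen against a numeric trait
#'
#' For every CpG, computes the Pearson correlation with the trait over
#' pairwise-complete samples, the Student t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` with its two-sided p-value on n - 2
#' degrees of freedom, the Fisher z statistic `sqrt(n - 3) * atanh(r)`, and
#' a Benjamini-Hochberg q-value computed over the testable CpGs. CpGs with
#' fewer than 4 pairwise-complete samples or zero variance are flagged
#' missing and excluded from the q computation, never dropped.
#'
#' @param beta A [beta_matrix()].
#' @param trait Numeric trait per sample (e.g. age in years), aligned with
#'   the rows of `beta`.
#' @return A data frame of class `"ewas_table"` with columns `cpg_id`, `n`,
#'   `r`, `t`, `p`, `z`, `q`.
#' @export
correlation_screen <- function(beta, trait) {
  X <- unclass(beta)
  if (length(trait) != nrow(X)) {
    eq_stop("eq_validation_error", "trait length != number of samples")
  }
  ok_trait <- is.finite(trait)
  n <- colSums(!is.na(X) & ok_trait)
  suppressWarnings(
    r <- as.numeric(stats::cor(X, trait, use = "pairwise.complete.obs"))
  )
  testable <- n >= 4 & !is.na(r)
  r[!testable] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- fisher_z(r, n)
  q <- rep(NA_real_, length(r))
  q[testable] <- bh_fdr(p[testable])
  out <- data.frame(cpg_id = colnames(X), n = as.integer(n), r = r,
                    t = tstat, p = p, z = z, q = q,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ewas_table", "data.frame")
  out
}

#' Unweighted Stouffer meta-analysis across tissues
#'
#' Combines per-tissue Fisher z statistics for each CpG as
#' `z_meta = sum(z_i) / sqrt(k)` over the k tissues contributing a finite z
#' (tissues weighted equally; `weights = "sqrt_n"` weights each tissue by
#' the square root of its per-CpG sample size instead). The meta p-value is
#' two-sided normal; a BH q-value is appended over the combinable CpGs.
#' CpGs contributing to fewer than two tissues are flagged missing.
#'
#' @param tables Named list (one element per tissue) of `"ewas_table"`
#'   results from [correlation_screen()]; at least two tissues.
#' @param weights `"equal"` (default) or `"sqrt_n"`.
#' @return A data frame of class `"meta_result"`: `cpg_id`, one `z_<tissue>`
#'   column per tissue, `k`, `meta_z`, `meta_p`, `meta_q`.
#' @export
stouffer_meta <- function(tables, weights = c("equal", "sqrt_n")) {
  weights <- match.arg(weights)
  if (!is.list(tables) || length(tables) < 2) {
    eq_stop("eq_validation_error",
            "stouffer_meta requires >= 2 per-tissue tables")
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("tissue", seq_along(tables))
  }
  universe <- sort(unique(unlist(lapply(tables, `[[`, "cpg_id"))))
  Z <- do.call(cbind, lapply(tables, function(tb) {
    tb$z[match(universe, tb$cpg_id)]
  }))
  N <- do.call(cbind, lapply(tables, function(tb) {
    tb$n[match(universe, tb$cpg_id)]
  }))
  colnames(Z) <- colnames(N) <- names(tables)
  fin <- is.finite(Z)
  k <- rowSums(fin)
  meta_z <- rep(NA_real_, length(universe))
  comb <- k >= 2
  if (weights == "equal") {
    meta_z[comb] <- rowSums(Z * fin, na.rm = TRUE)[comb] / sqrt(k[comb])
  } else {
    W <- sqrt(N) * fin
    meta_z[comb] <- (rowSums(Z * W, na.rm = TRUE) /
                       sqrt(rowSums(W^2, na.rm = TRUE)))[comb]
  }
  meta_p <- 2 * stats::pnorm(-abs(meta_z))
  meta_q <- rep(NA_real_, length(universe))
  meta_q[comb] <- bh_fdr(meta_p[comb])
  out <- data.frame(cpg_id = universe, stringsAsFactors = FALSE)
  for (t in names(tables)) out[[paste0("z_", t)]] <- Z[, t]
  out$k <- as.integer(k)
  out$meta_z <- meta_z
  out$meta_p <- meta_p
  out$meta_q <- meta_q
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment (via `stats::p.adjust`), with domain validation.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    eq_stop("eq_domain_error", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select the strongest positively and negatively associated CpGs
#'
#' Ranks CpGs by their (Fisher z) statistic and returns the top `k` in each
#' direction — the sample-size-free summary used to compare tissues with
#' very different power. Ties are broken by lexicographic `cpg_id`.
#'
#' @param table An `"ewas_table"` (or any data frame with `cpg_id` and the
#'   ranking column).
#' @param k Set size per direction (default 500); truncated with a warning
#'   when fewer CpGs are available.
#' @param stat Column used for ranking (default `"z"`).
#' @return List with character vectors `top_pos` and `top_neg`.
#' @export
select_top <- function(table, k = 500, stat = "z") {
  z <- table[[stat]]
  ids <- table$cpg_id
  usable <- is.finite(z)
  z <- z[usable]
  ids <- ids[usable]
  if (length(ids) < k) {
    eq_warn("only %d rankable CpGs; truncating top-%d selection",
            length(ids), k)
    k <- length(ids)
  }
  ord_pos <- order(-z, ids)
  ord_neg <- order(z, ids)
  list(top_pos = ids[ord_pos[seq_len(k)]],
       top_neg = ids[ord_neg[seq_len(k)]])
}

#' Hypergeometric overlap test between two CpG sets
#'
#' One-sided upper-tail hypergeometric p-value for observing at least the
#' shared count when drawing `|B|` elements from a universe containing
#' `|A|` marked elements, plus the odds ratio of the induced 2x2 table
#' (Haldane 0.5 correction when any cell is zero).
#'
#' @param setA,setB Character vectors (duplicates ignored).
#' @param universe_size Size of the common universe both sets came from.
#' @return List with `shared_count`, `odds_ratio`, `p`.
#' @export
overlap_test <- function(setA, setB, universe_size) {
  setA <- unique(setA)
  setB <- unique(setB)
  nA <- length(setA)
  nB <- length(setB)
  shared <- length(intersect(setA, setB))
  union_size <- nA + nB - shared
  if (universe_size < union_size) {
    eq_stop("eq_domain_error",
            "universe (%d) smaller than |A union B| (%d)", universe_size,
            union_size)
  }
  p <- stats::phyper(shared - 1, nA, universe_size - nA, nB,
                     lower.tail = FALSE)
  a <- shared
  b <- nA - shared
  c2 <- nB - shared
  d <- universe_size - nA - nB + shared
  if (min(a, b, c2, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c2 <- c2 + 0.5; d <- d + 0.5
  }
  list(shared_count = shared, odds_ratio = (a * d) / (b * c2), p = p)
}

#' Cohen's d effect-size screen between two age groups
#'
#' For every CpG, the standardized mean methylation difference between two
#' declared groups (e.g. newborns versus aged animals):
#' `d = (mean_old - mean_young) / pooled_sd` with the usual pooled standard
#' deviation. CpGs with zero pooled sd are flagged missing.
#'
#' @param beta A [beta_matrix()].
#' @param group Factor-like vector per sample with exactly two levels;
#'   samples with NA are ignored.
#' @param old_level The level treated as "old" (difference is old minus
#'   young); defaults to the second level.
#' @return Data frame `cpg_id`, `n_young`, `n_old`, `d`.
#' @export
cohens_d_screen <- function(beta, group, old_level = NULL) {
  X <- unclass(beta)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    eq_stop("eq_validation_error", "group must have exactly two levels")
  }
  group <- droplevels(group)
  old_level <- old_level %||% levels(group)[2]
  if (!old_level %in% levels(group)) {
    eq_stop("eq_validation_error", "old_level '%s' not a group level",
            old_level)
  }
  old <- !is.na(group) & group == old_level
  young <- !is.na(group) & group != old_level
  n1 <- sum(young)
  n2 <- sum(old)
  if (n1 < 2 || n2 < 2) {
    eq_stop("eq_validation_error", "both groups need >= 2 samples")
  }
  m_old <- colMeans(X[old, , drop = FALSE])
  m_young <- colMeans(X[young, , drop = FALSE])
  v_old <- matrixStats_colSds(X[old, , drop = FALSE])^2
  v_young <- matrixStats_colSds(X[young, , drop = FALSE])^2
  pooled <- sqrt(((n1 - 1) * v_young + (n2 - 1) * v_old) / (n1 + n2 - 2))
  d <- ifelse(pooled > 0, (m_old - m_young) / pooled, NA_real_)
  data.frame(cpg_id = colnames(X), n_young = n1, n_old = n2, d = d,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kruskal-Wallis association between a per-CpG statistic and categories
#'
#' Tests whether a per-CpG statistic (typically the Fisher z of the age
#' correlation) differs across CpG categories such as island status or
#' position class. Uses the tie-corrected Kruskal-Wallis H with a
#' chi-square p on (groups - 1) degrees of freedom; with all values tied,
#' H is 0 and p is 1.
#'
#' @param z Numeric per-CpG statistic.
#' @param categories Per-CpG category labels (>= 2 categories with >= 2
#'   members each).
#' @return List with `H`, `df`, `p`.
#' @export
category_association <- function(z, categories) {
  keep <- is.finite(z) & !is.na(categories)
  z <- z[keep]
  categories <- droplevels(as.factor(categories[keep]))
  if (nlevels(categories) < 2) {
    eq_stop("eq_domain_error", "need >= 2 categories")
  }
  if (any(table(categories) < 2)) {
    eq_stop("eq_domain_error", "every category needs >= 2 members")
  }
  if (length(unique(z)) == 1) {
    return(list(H = 0, df = nlevels(categories) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(z, categories)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
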