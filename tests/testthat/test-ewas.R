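# EWAS statistics against independent brute-force oracles and their
# closed-form anchor values.

test_that("correlation screen matches a per-CpG cor.test loop to 1e-12", {
  set.seed(61)
  n <- 50; p <- 200
  X <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%03d", 1:p)))
  X[sample(length(X), 100)] <- NA  # pairwise-complete handling
  trait <- runif(n, 0, 30)
  tab <- correlation_screen(beta_matrix(X), trait)
  for (j in seq_len(p)) {
    ok <- !is.na(X[, j])
    ct <- cor.test(X[ok, j], trait[ok])
    expect_equal(tab$r[j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(tab$t[j], unname(ct$statistic), tolerance = 1e-12)
    expect_equal(tab$p[j], ct$p.value, tolerance = 1e-12)
    expect_equal(tab$z[j], sqrt(sum(ok) - 3) * atanh(unname(ct$estimate)),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(tab$r) <= 1, na.rm = TRUE))
  expect_true(all(tab$q >= tab$p, na.rm = TRUE))
})

test_that("Fisher z hits its closed form and preserves sign and order", {
  expect_equal(equiclock:::fisher_z(0.5, 39), 6 * atanh(0.5))
  expect_equal(equiclock:::fisher_z(0, 100), 0)
  r <- seq(-0.95, 0.95, by = 0.05)
  z <- equiclock:::fisher_z(r, 30)
  expect_true(all(diff(z) > 0))
  expect_identical(sign(z), sign(r))
  expect_true(is.finite(equiclock:::fisher_z(1, 30)))  # clamped, not Inf
})

test_that("constant CpGs are flagged missing, not silently scored", {
  X <- cbind(cg_const = rep(0.5, 10), cg_var = seq(0.1, 0.9, length.out = 10))
  rownames(X) <- sprintf("s%02d", 1:10)
  tab <- correlation_screen(beta_matrix(X), 1:10)
  expect_true(is.na(tab$r[tab$cpg_id == "cg_const"]))
  expect_false(is.na(tab$q[tab$cpg_id == "cg_var"]))
})

test_that("Stouffer combination matches its closed forms", {
  mk <- function(z, n = 50) {
    data.frame(cpg_id = "cg1", n = n, r = NA, t = NA, p = NA, z = z, q = NA)
  }
  res <- stouffer_meta(list(blood = mk(2), liver = mk(2)))
  expect_equal(res$meta_z, 2 * sqrt(2))
  res <- stouffer_meta(list(a = mk(3), b = mk(-3)))
  expect_equal(res$meta_z, 0)
  expect_equal(res$meta_p, 1)
  expect_error(stouffer_meta(list(only = mk(1))),
               class = "eq_validation_error")
})

test_that("Stouffer meta matches a brute-force loop and is order-invariant", {
  set.seed(99)
  cpgs <- sprintf("cg%03d", 1:150)
  mk_table <- function(frac_present) {
    present <- sort(sample(cpgs, round(frac_present * length(cpgs))))
    data.frame(cpg_id = present, n = sample(30:60, length(present), TRUE),
               r = NA, t = NA, p = NA, z = rnorm(length(present)), q = NA,
               stringsAsFactors = FALSE)
  }
  tabs <- list(blood = mk_table(0.9), liver = mk_table(0.8),
               skin = mk_table(0.7))
  res <- stouffer_meta(tabs)
  for (cg in res$cpg_id) {
    zs <- vapply(tabs, function(tb) {
      z <- tb$z[tb$cpg_id == cg]
      if (length(z) == 0) NA_real_ else z
    }, 0)
    zs <- zs[is.finite(zs)]
    row <- res[res$cpg_id == cg, ]
    if (length(zs) >= 2) {
      expect_equal(row$meta_z, sum(zs) / sqrt(length(zs)), tolerance = 1e-12)
      expect_equal(row$meta_p, 2 * pnorm(-abs(row$meta_z)), tolerance = 1e-12)
    } else {
      expect_true(is.na(row$meta_z))
    }
  }
  # permuting tissue order changes nothing
  res2 <- stouffer_meta(tabs[c(3, 1, 2)])
  expect_equal(res2$meta_z, res$meta_z)
  # k identical tables scale as sqrt(k)
  same <- tabs$blood
  res3 <- stouffer_meta(list(a = same, b = same, c = same, d = same))
  expect_equal(res3$meta_z[match(same$cpg_id, res3$cpg_id)],
               same$z * sqrt(4), tolerance = 1e-12)
})

test_that("BH q-values match a hand-rolled step-up on random input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), class = "eq_domain_error")

  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    q_sorted <- p[o] * n / seq_len(n)
    # enforce step-up monotonicity from the largest p downwards
    for (i in (n - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
    q <- numeric(n)
    q[o] <- pmin(q_sorted, 1)
    q
  }
  set.seed(8)
  p <- runif(10000)
  expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-15)
  p_ties <- round(runif(500, 0, 1), 2)
  expect_equal(bh_fdr(p_ties), brute_bh(p_ties), tolerance = 1e-15)
})

test_that("top-k selection ranks by z with lexicographic tie-break", {
  tab <- data.frame(cpg_id = c("cgB", "cgA", "cgC"), z = c(2, -1, 5))
  sel <- select_top(tab, k = 1)
  expect_identical(sel$top_pos, "cgC")
  expect_identical(sel$top_neg, "cgA")

  tied <- data.frame(cpg_id = c("cgZ", "cgA", "cgM"), z = c(3, 3, 1))
  expect_identical(select_top(tied, k = 2)$top_pos, c("cgA", "cgZ"))
  expect_warning(sel <- select_top(tied, k = 10), "truncating")
  expect_length(sel$top_pos, 3)
})

test_that("top-k recovers the strongest planted CpGs", {
  ds <- simulate_methylation(sim_config(design = horse_blood_design(188),
                                        seed = 47))
  tab <- correlation_screen(ds$beta, ds$sheet$age)
  truth <- ds$truth[ds$truth$planted_b > 0, ]
  k <- nrow(truth)
  sel <- select_top(tab, k = k)
  expect_gte(length(intersect(sel$top_pos, truth$cpg_id)) / k, 0.9)
})

test_that("hypergeometric overlap matches exact enumeration", {
  res <- overlap_test(paste0("x", 1:5), c(paste0("x", 1:3), "y1"), 10)
  expect_equal(res$shared_count, 3)
  expect_equal(res$p, 55 / 210, tolerance = 1e-12)
  expect_equal(res$odds_ratio, 6)

  # brute-force tail from binomial coefficients
  brute_p <- function(N, nA, nB, shared) {
    sum(vapply(shared:min(nA, nB), function(j) {
      choose(nA, j) * choose(N - nA, nB - j) / choose(N, nB)
    }, 0))
  }
  set.seed(23)
  for (i in 1:20) {
    N <- sample(20:60, 1)
    nA <- sample(3:15, 1)
    nB <- sample(3:15, 1)
    A <- paste0("u", sample(N, nA))
    B <- paste0("u", sample(N, nB))
    res <- overlap_test(A, B, N)
    expect_equal(res$p, brute_p(N, nA, nB, res$shared_count),
                 tolerance = 1e-12)
  }

  # disjoint sets covering the universe: zero overlap, p = 1
  res <- overlap_test(paste0("a", 1:4), paste0("b", 1:6), 10)
  expect_equal(res$shared_count, 0)
  expect_equal(res$p, 1)
  # A = B achieves the minimal tail for its margins
  res <- overlap_test(paste0("a", 1:4), paste0("a", 1:4), 12)
  expect_equal(res$p, brute_p(12, 4, 4, 4), tolerance = 1e-12)
  expect_error(overlap_test(paste0("a", 1:4), paste0("b", 1:4), 6),
               class = "eq_domain_error")
})

test_that("Cohen's d matches its definition and a per-CpG loop", {
  X <- rbind(matrix(c(0.2, 0.3, 0.4), 3, 1),
             matrix(c(0.6, 0.7, 0.8), 3, 1))
  dimnames(X) <- list(sprintf("s%d", 1:6), "cg1")
  g <- rep(c("young", "old"), each = 3)
  res <- cohens_d_screen(beta_matrix(X), factor(g, c("young", "old")))
  expect_equal(res$d, 4)  # (0.7 - 0.3) / 0.1

  # identical groups: d = 0
  X2 <- rbind(X[1:3, , drop = FALSE], X[1:3, , drop = FALSE])
  rownames(X2) <- sprintf("s%d", 1:6)
  expect_equal(cohens_d_screen(beta_matrix(X2),
                               factor(g, c("young", "old")))$d, 0)

  set.seed(71)
  n <- 30; p <- 1000
  M <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%04d", 1:p)))
  grp <- factor(rep(c("young", "old"), length.out = n), c("young", "old"))
  res <- cohens_d_screen(beta_matrix(M), grp)
  for (j in sample(p, 50)) {
    x1 <- M[grp == "young", j]; x2 <- M[grp == "old", j]
    pooled <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
                     (length(x1) + length(x2) - 2))
    expect_equal(res$d[j], (mean(x2) - mean(x1)) / pooled, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis category association matches rank arithmetic", {
  res <- category_association(c(1, 2, 3, 4, 5, 6),
                              rep(c("a", "b"), each = 3))
  # ranks 1..6, group means 2 and 5: H = 12/(6*7) * 3*((2-3.5)^2+(5-3.5)^2)
  expect_equal(res$H, 12 / 42 * 3 * (1.5^2 + 1.5^2) , tolerance = 1e-12)
  expect_equal(res$H, 3.857142857, tolerance = 1e-9)

  # independent oracle with tie correction on a random instance
  set.seed(15)
  z <- round(rnorm(60), 1)  # rounding forces ties
  g <- sample(c("a", "b", "c"), 60, replace = TRUE)
  res <- category_association(z, g)
  rk <- rank(z)
  n <- length(z)
  H_raw <- 12 / (n * (n + 1)) *
    sum(tapply(rk, g, function(v) length(v) * (mean(v) - (n + 1) / 2)^2))
  ties <- table(z)
  H <- H_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(res$H, H, tolerance = 1e-12)
  expect_equal(res$p, pchisq(H, 2, lower.tail = FALSE), tolerance = 1e-12)

  expect_equal(category_association(rep(1, 10),
                                    rep(c("a", "b"), 5))$H, 0)
  expect_error(category_association(1:5, rep("a", 5)),
               class = "eq_domain_error")
})

test_that("null category labels give uniform Kruskal-Wallis p-values", {
  set.seed(19)
  z <- rnorm(200)
  p_vals <- vapply(1:200, function(i) {
    category_association(z, sample(rep(c("a", "b"), 100)))$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(p_vals, "punif"))$p.value, 0.01)
})

test_that("blood and liver z statistics agree on shared planted effects", {
  ds <- simulate_methylation(sim_config(design = blood_liver_design(),
                                        seed = 83))
  tabs <- lapply(split(seq_len(nrow(ds$sheet)), ds$sheet$tissue), function(i)
    correlation_screen(ds$beta[i, , drop = FALSE], ds$sheet$age[i]))
  shared <- with(ds$truth, intersect(cpg_id[tissue == "blood" & planted_b != 0],
                                     cpg_id[tissue == "liver" & planted_b != 0]))
  zb <- tabs$blood$z[match(shared, tabs$blood$cpg_id)]
  zl <- tabs$liver$z[match(shared, tabs$liver$cpg_id)]
  expect_gt(cor(zb, zl), 0.5)
})

test_that("island CpGs dominate the age-correlation magnitude among causal CpGs", {
  ds <- simulate_methylation(sim_config(design = horse_blood_design(188),
                                        seed = 37))
  tab <- correlation_screen(ds$beta, ds$sheet$age)
  causal <- unique(ds$truth$cpg_id[ds$truth$planted_b != 0])
  z <- abs(tab$z[match(causal, tab$cpg_id)])
  isl <- ds$annot$island[match(causal, ds$annot$cpg_id)]
  res <- category_association(z, isl)
  expect_lt(res$p, 1e-6)
  expect_gt(median(z[isl == "island"]), median(z[isl == "non-island"]))
})
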