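# Nearest-gene assignment, promoter-window coupling screen and
# chromatin-state summaries.

test_that("nearest-gene assignment signs distances by strand", {
  cpgs <- data.frame(cpg_id = "cg1", chrom = "chr1", pos = 500)
  tss <- data.frame(gene = "GENEA", chrom = "chr1", pos = 400, strand = "+")
  res <- assign_nearest_gene(cpgs, tss)
  expect_identical(res$gene, "GENEA")
  expect_identical(res$tss_distance, 100L)  # downstream of a + strand TSS

  tss$strand <- "-"
  res <- assign_nearest_gene(cpgs, tss)
  expect_identical(res$tss_distance, -100L)  # upstream relative to gene
})

test_that("equidistant ties resolve to the lexicographically first gene", {
  cpgs <- data.frame(cpg_id = "cg1", chrom = "chr1", pos = 500)
  tss <- data.frame(gene = c("ZED", "ALPHA"), chrom = "chr1",
                    pos = c(400, 600), strand = "+")
  res <- assign_nearest_gene(cpgs, tss)
  expect_identical(res$gene, "ALPHA")
})

test_that("CpGs on sequences without a TSS stay unassigned", {
  cpgs <- data.frame(cpg_id = c("cg1", "cg2"), chrom = c("chr1", "chrUn"),
                     pos = c(100, 100))
  tss <- data.frame(gene = "G", chrom = "chr1", pos = 50, strand = "+")
  res <- assign_nearest_gene(cpgs, tss)
  expect_true(res$assigned[1])
  expect_false(res$assigned[2])
  expect_true(is.na(res$gene[2]))
})

test_that("nearest-gene assignment matches an all-pairs brute force", {
  set.seed(27)
  cpgs <- data.frame(cpg_id = sprintf("cg%04d", 1:1000),
                     chrom = sample(c("chr1", "chr2", "chr3"), 1000, TRUE),
                     pos = sample.int(5e5, 1000))
  tss <- data.frame(gene = sprintf("G%03d", 1:50),
                    chrom = sample(c("chr1", "chr2", "chr3"), 50, TRUE),
                    pos = sample.int(5e5, 50),
                    strand = sample(c("+", "-"), 50, TRUE))
  res <- assign_nearest_gene(cpgs, tss)
  for (i in sample(1000, 200)) {
    tt <- tss[tss$chrom == cpgs$chrom[i], ]
    if (nrow(tt) == 0) {
      expect_false(res$assigned[i])
      next
    }
    dabs <- abs(cpgs$pos[i] - tt$pos)
    best <- tt[order(dabs, tt$gene), ][1, ]
    expect_identical(res$gene[i], best$gene)
    raw <- cpgs$pos[i] - best$pos
    expect_identical(res$tss_distance[i],
                     as.integer(if (best$strand == "+") raw else -raw))
  }
})

test_that("perfect negative coupling saturates the Fisher statistic", {
  # noiseless: expression exactly -1 * beta
  at <- simulate_atlas(atlas_sim_config(
    n_genes = 24, cpgs_per_gene = 1, distal_cpgs_per_gene = 0,
    state_coupling = c(EnhA = -1), cpg_noise_sd = 0, expr_noise_sd = 0,
    seed = 2))
  ct <- coupling_screen(at$beta, at$expression, at$annot)
  expect_true(all(ct$r < -0.999))
  expect_true(all(ct$significant))
})

test_that("coupling screen excludes CpGs outside the promoter window", {
  at <- simulate_atlas(atlas_sim_config(n_genes = 40, seed = 9))
  ct <- coupling_screen(at$beta, at$expression, at$annot)
  in_window <- at$truth$cpg_id[at$truth$in_window]
  expect_setequal(ct$cpg_id, in_window)
  # distal CpGs correlate with expression too, so exclusion is the window,
  # not a lack of signal
  expect_gt(length(setdiff(at$truth$cpg_id, in_window)), 0)
})

test_that("genes with constant expression flag their CpGs missing", {
  at <- simulate_atlas(atlas_sim_config(n_genes = 10, seed = 4))
  expr <- at$expression
  expr[1, ] <- 3.7
  ct <- coupling_screen(at$beta, expr, at$annot)
  g1 <- at$truth$gene[1]
  expect_true(all(is.na(ct$r[ct$gene == g1])))
})

test_that("state summary computes medians, notches and the reported flag", {
  tab <- data.frame(cpg_id = c("a", "b", "c"), gene = "G", n = 29,
                    r = -0.5, z = c(-3, -4, -5), p = 0.001,
                    significant = TRUE)
  ann <- cpg_annotation(data.frame(
    cpg_id = c("a", "b", "c"), gene = "G", tss_distance = 0L,
    island = "island", position_class = "promoter", chrom_state = "EnhA",
    stringsAsFactors = FALSE))
  res <- state_summary(tab, ann)
  expect_equal(res$median_z, -4)
  expect_equal(res$n, 3)
  expect_true(res$reported)
  expect_equal(res$notch_lo, -4 - 1.57 * IQR(c(-3, -4, -5)) / sqrt(3))

  empty <- state_summary(tab[0, ], ann)
  expect_equal(nrow(empty), 0)
})

test_that("state medians recover the planted coupling directions", {
  at <- simulate_atlas(atlas_sim_config(seed = 33))
  ct <- coupling_screen(at$beta, at$expression, at$annot)
  sig <- ct[!is.na(ct$p) & ct$p < 0.05, ]
  res <- state_summary(sig, at$annot)
  expect_equal(sum(res$n), nrow(sig))
  couplings <- default_state_coupling()
  for (st in c("EnhA", "EnhWk", "TxEnh", "BivProm", "TSS", "PromF")) {
    row <- res[res$chrom_state == st, ]
    if (nrow(row) == 1 && row$n >= 20) {
      expect_identical(sign(row$median_z), sign(couplings[[st]]))
    }
  }
})

test_that("distance-decaying couplings weaken with distance from the TSS", {
  at <- simulate_atlas(atlas_sim_config(
    n_genes = 360, distance_decay_bp = 2500, seed = 57))
  ct <- coupling_screen(at$beta, at$expression, at$annot)
  d <- abs(at$annot$tss_distance[match(ct$cpg_id, at$annot$cpg_id)])
  bins <- cut(d, c(-1, 2000, 5000, 11000))
  med <- tapply(abs(ct$z), bins, median, na.rm = TRUE)
  expect_true(all(diff(med) <= 0))
})

test_that("dropping the most extreme tissue rarely flips state medians", {
  flips <- vapply(1:5, function(seed) {
    at <- simulate_atlas(atlas_sim_config(seed = 400 + seed))
    ct <- coupling_screen(at$beta, at$expression, at$annot)
    full <- state_summary(ct, at$annot)
    # remove the tissue with the most extreme average expression
    E <- log2(at$expression + 1)
    tissue <- sub("_a[0-9]+$", "", colnames(E))
    dev <- tapply(rowMeans(scale(t(E))), tissue, mean)
    drop_t <- names(which.max(abs(dev)))
    keep <- !startsWith(rownames(at$beta), paste0(drop_t, "_"))
    ct2 <- coupling_screen(at$beta[keep, , drop = FALSE],
                           at$expression[, rownames(at$beta)[keep]],
                           at$annot)
    red <- state_summary(ct2, at$annot)
    m <- merge(full, red, by = "chrom_state")
    # only states with a planted coupling have a meaningful median sign
    m <- m[default_state_coupling()[m$chrom_state] != 0 & m$n.x >= 20, ]
    mean(sign(m$median_z.x) != sign(m$median_z.y))
  }, 0)
  expect_lt(mean(flips), 0.05)
})
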