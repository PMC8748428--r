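# Cross-tissue DNAm-mRNA coupling: nearest-gene assignment, per-CpG
# methylation/expression correlation across tissue samples, and
# chromatin-state stratification of the resulting Fisher z statistics.

#' Assign each CpG to the gene with the nearest TSS
#'
#' Minimizes the absolute genomic distance between the CpG and any
#' transcription start site on the same sequence. The reported distance is
#' signed relative to gene orientation: negative = upstream of the TSS,
#' 0 at the TSS. Ties (equal absolute distance) resolve to the
#' lexicographically smallest gene id. CpGs on sequences without any TSS
#' are returned unassigned (NA gene) and flagged.
#'
#' @param cpg_positions Data frame with `cpg_id`, `chrom`, `pos`.
#' @param tss_table Data frame with `gene`, `chrom`, `pos`, `strand`
#'   (`"+"`/`"-"`).
#' @return Data frame `cpg_id`, `gene`, `tss_distance`, `assigned`.
#' @export
assign_nearest_gene <- function(cpg_positions, tss_table) {
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(cpg_positions)),
            all(c("gene", "chrom", "pos", "strand") %in% names(tss_table)))
  if (!all(tss_table$strand %in% c("+", "-"))) {
    eq_stop("eq_validation_error", "strand must be '+' or '-'")
  }
  out <- data.frame(cpg_id = cpg_positions$cpg_id,
                    gene = NA_character_, tss_distance = NA_integer_,
                    assigned = FALSE, stringsAsFactors = FALSE)
  for (ch in unique(cpg_positions$chrom)) {
    qi <- which(cpg_positions$chrom == ch)
    tt <- tss_table[tss_table$chrom == ch, , drop = FALSE]
    if (nrow(tt) == 0) next
    # Order TSSs by position, breaking position ties by gene id so the
    # lexicographic tie rule falls out of the candidate scan below.
    tt <- tt[order(tt$pos, tt$gene), , drop = FALSE]
    idx <- findInterval(cpg_positions$pos[qi], tt$pos)
    for (k in seq_along(qi)) {
      i <- qi[k]
      # Candidates: flanking TSSs plus any sharing their positions.
      cand <- unique(pmin(pmax(c(idx[k], idx[k] + 1L,
                                 idx[k] - 1L, idx[k] + 2L), 1L), nrow(tt)))
      dabs <- abs(cpg_positions$pos[i] - tt$pos[cand])
      best <- cand[order(dabs, tt$gene[cand])][1]
      raw <- cpg_positions$pos[i] - tt$pos[best]
      out$gene[i] <- tt$gene[best]
      out$tss_distance[i] <- as.integer(
        if (tt$strand[best] == "+") raw else -raw)
      out$assigned[i] <- TRUE
    }
  }
  out
}

#' Per-CpG methylation-expression coupling across tissue samples
#'
#' For each CpG inside the promoter window of its assigned gene, the
#' Pearson correlation across shared samples between the CpG's methylation
#' and the adjacent gene's log2 expression, with the Fisher z statistic,
#' two-sided Student t p-value, and a significance flag at |z| > 2.8
#' (two-sided normal p < 0.005). CpGs outside the window are excluded;
#' genes with constant expression have their CpGs flagged missing.
#'
#' @param beta A [beta_matrix()] (tissue samples x CpGs).
#' @param expression Numeric matrix, genes x samples. Linear-scale values
#'   are transformed as `log2(x + 1)` when `log2_transform = TRUE` (the
#'   default); set to `FALSE` if the matrix is already on a log scale.
#' @param annot A [cpg_annotation()] supplying each CpG's gene and signed
#'   TSS distance.
#' @param promoter_window Length-2 signed window in bp (negative =
#'   upstream); default `c(-10000, 1000)`.
#' @param log2_transform Transform expression before correlating.
#' @param z_threshold Significance threshold on |z| (default 2.8).
#' @return A data frame of class `"coupling_table"`: `cpg_id`, `gene`, `n`,
#'   `r`, `z`, `p`, `significant`.
#' @export
coupling_screen <- function(beta, expression, annot,
                            promoter_window = c(-10000, 1000),
                            log2_transform = TRUE, z_threshold = 2.8) {
  samples <- intersect(rownames(beta), colnames(expression))
  if (length(samples) < 5) {
    eq_stop("eq_validation_error",
            "need >= 5 shared samples between beta and expression, got %d",
            length(samples))
  }
  X <- unclass(beta)[samples, , drop = FALSE]
  E <- expression[, samples, drop = FALSE]
  if (log2_transform) E <- log2(E + 1)
  ann <- annot[match(colnames(X), annot$cpg_id), , drop = FALSE]
  in_win <- !is.na(ann$tss_distance) &
    ann$tss_distance >= promoter_window[1] &
    ann$tss_distance <= promoter_window[2] &
    !is.na(ann$gene) & ann$gene %in% rownames(E)
  cpgs <- colnames(X)[in_win]
  genes <- ann$gene[in_win]
  n_used <- integer(length(cpgs))
  r <- numeric(length(cpgs))
  for (i in seq_along(cpgs)) {
    x <- X[, cpgs[i]]
    y <- E[genes[i], ]
    ok <- !is.na(x) & !is.na(y)
    n_used[i] <- sum(ok)
    r[i] <- if (n_used[i] >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      stats::cor(x[ok], y[ok])
    } else NA_real_
  }
  z <- fisher_z(r, n_used)
  rc <- pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15)
  tstat <- rc * sqrt((n_used - 2) / (1 - rc^2))
  p <- ifelse(is.na(r), NA_real_,
              2 * stats::pt(-abs(tstat), df = n_used - 2))
  out <- data.frame(cpg_id = cpgs, gene = genes, n = n_used, r = r, z = z,
                    p = p, significant = !is.na(z) & abs(z) > z_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("coupling_table", "data.frame")
  out
}

#' Chromatin-state summary of DNAm-mRNA coupling statistics
#'
#' Summarizes a (typically significance-restricted) coupling table per
#' chromatin state: member count, median Fisher z, the median's notch
#' interval `median +/- 1.57 * IQR / sqrt(n)`, and a reported flag for
#' states whose |median z| exceeds the threshold (default 2.8). States
#' without members are omitted; counts sum to the rows analysed.
#'
#' @param table A `"coupling_table"`, usually restricted to significant
#'   CpGs first (e.g. `table[table$p < 0.05, ]`).
#' @param annot A [cpg_annotation()] supplying `chrom_state` per CpG.
#' @param z_threshold Reporting threshold on |median z|.
#' @return Data frame `chrom_state`, `n`, `median_z`, `notch_lo`,
#'   `notch_hi`, `reported`, ordered by median z.
#' @export
state_summary <- function(table, annot, z_threshold = 2.8) {
  if (nrow(table) == 0) {
    return(data.frame(chrom_state = character(0), n = integer(0),
                      median_z = numeric(0), notch_lo = numeric(0),
                      notch_hi = numeric(0), reported = logical(0)))
  }
  st <- annot$chrom_state[match(table$cpg_id, annot$cpg_id)]
  keep <- !is.na(st) & is.finite(table$z)
  z <- table$z[keep]
  st <- st[keep]
  rows <- lapply(split(z, st), function(v) {
    med <- stats::median(v)
    notch <- 1.57 * stats::IQR(v) / sqrt(length(v))
    data.frame(n = length(v), median_z = med, notch_lo = med - notch,
               notch_hi = med + notch,
               reported = abs(med) > z_threshold)
  })
  out <- do.call(rbind, rows)
  out <- cbind(chrom_state = names(rows), out)
  rownames(out) <- NULL
  out[order(out$median_z), , drop = FALSE]
}
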