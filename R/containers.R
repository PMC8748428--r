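#' Construct and validate a beta-value matrix
#'
#' A beta matrix holds CpG methylation fractions for a set of samples:
#' rows are samples, columns are CpGs, entries lie in \[0, 1\] (missing
#' values are permitted and treated as missing downstream, never imputed
#' silently).
#'
#' @param values Numeric matrix of methylation fractions (samples x CpGs).
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `rownames(values)`.
#' @param cpg_ids Character vector of unique CpG identifiers; defaults to
#'   `colnames(values)`.
#' @return A numeric matrix of class `"beta_matrix"` with sample ids as row
#'   names and CpG ids as column names.
#' @examples
#' b <- beta_matrix(matrix(runif(12), 3, 4,
#'   dimnames = list(paste0("s", 1:3), paste0("cg", 1:4))))
#' dim(b)
#' @export
beta_matrix <- function(values, sample_ids = rownames(values),
                        cpg_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    eq_stop("eq_validation_error", "beta values must be a numeric matrix")
  }
  if (is.null(sample_ids) || is.null(cpg_ids)) {
    eq_stop("eq_validation_error",
            "beta matrix requires sample and CpG identifiers")
  }
  sample_ids <- as.character(sample_ids)
  cpg_ids <- as.character(cpg_ids)
  if (length(sample_ids) != nrow(values) || length(cpg_ids) != ncol(values)) {
    eq_stop("eq_validation_error",
            "identifier lengths (%d samples, %d CpGs) do not match matrix %d x %d",
            length(sample_ids), length(cpg_ids), nrow(values), ncol(values))
  }
  if (anyDuplicated(sample_ids)) {
    eq_stop("eq_validation_error", "duplicated sample ids: %s",
            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(cpg_ids)) {
    eq_stop("eq_validation_error", "duplicated CpG ids: %s",
            paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "))
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1 | !is.finite(values)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    k <- bad[1, , drop = TRUE]
    eq_stop("eq_validation_error",
            "%d beta value(s) outside [0,1]; first offender: sample '%s', CpG '%s' (value %g)",
            nrow(bad), sample_ids[k[1]], cpg_ids[k[2]], values[k[1], k[2]])
  }
  dimnames(values) <- list(sample_ids, cpg_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' @exportS3Method base::print
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d samples x %d CpGs\n", nrow(x), ncol(x)))
  n_na <- sum(is.na(x))
  if (n_na > 0) cat(sprintf("  missing entries: %d\n", n_na))
  rng <- range(x, na.rm = TRUE)
  cat(sprintf("  beta range: [%.3f, %.3f]\n", rng[1], rng[2]))
  invisible(x)
}

#' Construct and validate a sample sheet
#'
#' Per-sample covariates accompanying a beta matrix: chronological age in
#' years, species, tissue, sex and castration status. Castrated animals must
#' be male; females and animals of unknown status carry
#' `castrated = "not_applicable"`.
#'
#' @param df Data frame with columns `sample_id`, `age`, `species`, `tissue`,
#'   `sex` (`"female"`/`"male"`), `castrated` (`"yes"`/`"no"`/
#'   `"not_applicable"`), and optionally `breed`.
#' @return The validated data frame with class `"sample_sheet"`.
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "age", "species", "tissue", "sex", "castrated")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    eq_stop("eq_validation_error", "sample sheet lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    eq_stop("eq_validation_error", "duplicated sample ids in sheet")
  }
  if (any(!is.finite(df$age)) || any(df$age < 0)) {
    eq_stop("eq_validation_error", "ages must be finite and non-negative")
  }
  if (!all(df$sex %in% c("female", "male"))) {
    eq_stop("eq_validation_error", "sex must be 'female' or 'male'")
  }
  if (!all(df$castrated %in% c("yes", "no", "not_applicable"))) {
    eq_stop("eq_validation_error",
            "castrated must be 'yes', 'no' or 'not_applicable'")
  }
  offenders <- df$sample_id[df$castrated == "yes" & df$sex != "male"]
  if (length(offenders) > 0) {
    eq_stop("eq_validation_error",
            "castrated = 'yes' requires sex = 'male': %s",
            paste(offenders, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @exportS3Method base::print
print.sample_sheet <- function(x, ...) {
  cat(sprintf("sample_sheet: %d samples, %d species, %d tissue(s)\n",
              nrow(x), length(unique(x$species)), length(unique(x$tissue))))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Construct a species parameter table
#'
#' Holds the two species constants the age transformations need: the maximum
#' recorded lifespan (anchors relative age) and the average age at sexual
#' maturity (anchors the log-linear transform). Both are in years and
#' `0 < maturity_age < max_lifespan` is enforced.
#'
#' @param df Data frame with columns `species`, `max_lifespan`,
#'   `maturity_age`.
#' @return The validated table with class `"species_table"`.
#' @seealso [equid_species_table()] for the bundled defaults.
#' @export
species_table <- function(df) {
  req <- c("species", "max_lifespan", "maturity_age")
  if (!all(req %in% names(df))) {
    eq_stop("eq_validation_error", "species table needs columns: %s",
            paste(req, collapse = ", "))
  }
  df$species <- as.character(df$species)
  if (anyDuplicated(df$species)) {
    eq_stop("eq_validation_error", "duplicated species in species table")
  }
  bad <- !(df$maturity_age > 0 & df$maturity_age < df$max_lifespan)
  if (any(bad)) {
    eq_stop("eq_validation_error",
            "need 0 < maturity_age < max_lifespan; violated for: %s",
            paste(df$species[bad], collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("species_table", "data.frame")
  df
}

#' Default species constants for equids and human
#'
#' Maximum lifespan and age at sexual maturity (years) for the species used
#' throughout: horse (57 / 3), human (122.5 / 15), plains zebra (38 / 2.5),
#' Grevy's zebra (31 / 3) and Somali wild ass (40 / 2). The horse and human
#' lifespans are the anAge values used for relative age; the remaining
#' entries are typical literature values and are freely overridable.
#'
#' @return A [species_table()].
#' @export
equid_species_table <- function() {
  species_table(data.frame(
    species = c("horse", "human", "plains_zebra", "grevys_zebra",
                "somali_wild_ass"),
    max_lifespan = c(57, 122.5, 38, 31, 40),
    maturity_age = c(3, 15, 2.5, 3, 2),
    stringsAsFactors = FALSE
  ))
}

# Controlled vocabulary for consensus (stackHMM-style) chromatin states.
chrom_state_vocabulary <- function() {
  c("TSS", "PromF", "BivProm", "ReprPC", "EnhA", "EnhWk", "TxEnh",
    "Tx", "TxEx", "Acet", "Het", "Quies")
}

position_class_vocabulary <- function() {
  c("promoter", "5utr", "exon", "intron", "3utr", "intergenic")
}

#' Construct a CpG annotation table
#'
#' Genomic context for each CpG: nearest gene, signed distance to its
#' transcription start site (negative = upstream), CpG-island membership,
#' position class relative to the gene, and a consensus chromatin-state
#' label drawn from a fixed vocabulary.
#'
#' @param df Data frame with columns `cpg_id`, `gene`, `tss_distance`,
#'   `island` (`"island"`/`"non-island"`), `position_class`, `chrom_state`.
#' @return The validated table with class `"cpg_annotation"`.
#' @export
cpg_annotation <- function(df) {
  req <- c("cpg_id", "gene", "tss_distance", "island", "position_class",
           "chrom_state")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    eq_stop("eq_validation_error", "annotation lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  df$cpg_id <- as.character(df$cpg_id)
  if (anyDuplicated(df$cpg_id)) {
    eq_stop("eq_validation_error", "duplicated CpG ids in annotation")
  }
  if (!all(df$island %in% c("island", "non-island"))) {
    eq_stop("eq_validation_error", "island must be 'island' or 'non-island'")
  }
  ok_state <- df$chrom_state %in% chrom_state_vocabulary() | is.na(df$chrom_state)
  if (!all(ok_state)) {
    eq_stop("eq_validation_error", "unknown chromatin state(s): %s",
            paste(unique(df$chrom_state[!ok_state]), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("cpg_annotation", "data.frame")
  df
}

# Check that a beta matrix and a sample sheet describe the same samples, in
# the same order. Returns the sheet reordered to the matrix if needed.
align_samples <- function(beta, sheet) {
  only_sheet <- setdiff(sheet$sample_id, rownames(beta))
  only_beta <- setdiff(rownames(beta), sheet$sample_id)
  if (length(only_sheet) > 0 || length(only_beta) > 0) {
    eq_stop("eq_alignment_error",
            "sample mismatch between beta matrix and sheet%s%s",
            if (length(only_sheet)) paste0("; sheet-only: ",
                                           paste(only_sheet, collapse = ", ")) else "",
            if (length(only_beta)) paste0("; matrix-only: ",
                                          paste(only_beta, collapse = ", ")) else "")
  }
  sheet[match(rownames(beta), sheet$sample_id), , drop = FALSE]
}
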