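# Readers and writers for the plain-text formats the pipeline exchanges:
# CSV (RFC-4180, UTF-8) for beta matrices, sample sheets and clock
# coefficient files; TSV for CpG annotation. Numeric round trips are exact:
# values are written with 17 significant digits.

#' Write / read a beta matrix as CSV
#'
#' On disk the matrix is sample-major: one row per sample, first column
#' `sample_id`, remaining columns one per CpG. Missing betas are empty
#' cells. Values round-trip exactly.
#'
#' @param beta A [beta_matrix()].
#' @param path File path.
#' @return `write_beta_matrix()` returns `path` invisibly;
#'   `read_beta_matrix()` returns a [beta_matrix()].
#' @export
write_beta_matrix <- function(beta, path) {
  df <- as.data.frame(apply(unclass(beta), 2, format_full, simplify = FALSE),
                      optional = TRUE, check.names = FALSE)
  df[is.na(unclass(beta))] <- ""
  df <- cbind(sample_id = rownames(beta), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) eq_stop("eq_io_error", "no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  if (names(df)[1] != "sample_id") {
    eq_stop("eq_format_error",
            "beta CSV must have 'sample_id' as its first column")
  }
  ids <- df$sample_id
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == ""] <- NA_character_
  storage.mode(m) <- "double"
  beta_matrix(m, sample_ids = ids, cpg_ids = colnames(m))
}

#' Write / read a sample sheet as CSV
#'
#' @param sheet A [sample_sheet()].
#' @param path File path.
#' @return `read_sample_sheet()` returns a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  df <- as.data.frame(sheet)
  df$age <- format_full(df$age)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) eq_stop("eq_io_error", "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  sample_sheet(df)
}

#' Write / read a CpG annotation table as TSV
#'
#' @param annot A [cpg_annotation()].
#' @param path File path.
#' @return `read_cpg_annotation()` returns a [cpg_annotation()].
#' @export
write_cpg_annotation <- function(annot, path) {
  utils::write.table(as.data.frame(annot), path, sep = "\t",
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cpg_annotation
#' @export
read_cpg_annotation <- function(path) {
  if (!file.exists(path)) eq_stop("eq_io_error", "no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  cpg_annotation(df)
}

#' Load an aligned methylation dataset from disk
#'
#' Reads a beta matrix, its sample sheet and (optionally) a CpG annotation
#' table, validates every container and checks that samples align between
#' matrix and sheet. CpGs present in the matrix but missing from the
#' annotation are flagged with a warning, never dropped.
#'
#' @param beta_path CSV path of the beta matrix (samples x CpGs).
#' @param sheet_path CSV path of the sample sheet.
#' @param annot_path Optional TSV path of the CpG annotation.
#' @return A list with elements `beta`, `sheet` and (if requested) `annot`.
#' @export
load_dataset <- function(beta_path, sheet_path, annot_path = NULL) {
  beta <- read_beta_matrix(beta_path)
  sheet <- read_sample_sheet(sheet_path)
  sheet <- align_samples(beta, sheet)
  out <- list(beta = beta, sheet = sheet)
  if (!is.null(annot_path)) {
    annot <- read_cpg_annotation(annot_path)
    unannotated <- setdiff(colnames(beta), annot$cpg_id)
    if (length(unannotated) > 0) {
      eq_warn("%d CpG(s) lack annotation (kept, flagged): %s%s",
              length(unannotated),
              paste(utils::head(unannotated, 5), collapse = ", "),
              if (length(unannotated) > 5) ", ..." else "")
    }
    attr(annot, "unannotated_cpgs") <- unannotated
    out$annot <- annot
  }
  out
}

#' Serialize a fitted clock to a coefficient file
#'
#' The clock file is a CSV whose header block records the intercept,
#' elastic-net mixing parameter, selected penalty and the age-transform
#' parameters as commented `# key=value` lines, followed by one row per
#' nonzero coefficient (`cpg_id, coefficient, train_mean`). All numerics are
#' written at full precision, so `load_clock(save_clock(m))` reproduces the
#' model exactly.
#'
#' @param model An `"equiclock"` model from [fit_clock()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_clock <- function(model, path) {
  stopifnot(inherits(model, "equiclock"))
  hdr <- c(
    sprintf("# intercept=%s", format_full(model$intercept)),
    sprintf("# alpha=%s", format_full(model$alpha)),
    sprintf("# lambda=%s", format_full(model$lambda)),
    sprintf("# transform=%s", model$transform$kind),
    sprintf("# c_offset=%s", format_full(model$transform$c_offset)),
    sprintf("# n_train=%d", model$n_train)
  )
  st <- model$transform$species_table
  if (!is.null(st)) {
    hdr <- c(hdr, sprintf("# species=%s,%s,%s", st$species,
                          format_full(st$max_lifespan),
                          format_full(st$maturity_age)))
  }
  cpgs <- names(model$coefficients)
  body <- c("cpg_id,coefficient,train_mean",
            if (length(cpgs) > 0) {
              sprintf("%s,%s,%s", cpgs,
                      format_full(unname(model$coefficients)),
                      format_full(unname(model$cpg_means[cpgs])))
            })
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_clock
#' @export
load_clock <- function(path) {
  if (!file.exists(path)) eq_stop("eq_io_error", "no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- startsWith(lines, "# ")
  kv <- sub("^# ", "", lines[is_hdr])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  get1 <- function(key) {
    v <- vals[keys == key]
    if (length(v) != 1) eq_stop("eq_format_error",
                                "clock file lacks unique header key '%s'", key)
    v
  }
  kind <- get1("transform")
  if (!kind %in% c("identity", "relative_age", "loglinear")) {
    eq_stop("eq_format_error", "unknown transform label '%s'", kind)
  }
  st <- NULL
  if (any(keys == "species")) {
    parts <- strsplit(vals[keys == "species"], ",", fixed = TRUE)
    st <- species_table(data.frame(
      species = vapply(parts, `[`, "", 1),
      max_lifespan = as.numeric(vapply(parts, `[`, "", 2)),
      maturity_age = as.numeric(vapply(parts, `[`, "", 3)),
      stringsAsFactors = FALSE
    ))
  }
  spec <- age_transform(kind, species_table = st,
                        c_offset = as.numeric(get1("c_offset")))
  body <- lines[!is_hdr]
  if (length(body) < 1 || body[1] != "cpg_id,coefficient,train_mean") {
    eq_stop("eq_format_error", "clock file lacks coefficient header row")
  }
  coefs <- numeric(0)
  means <- numeric(0)
  if (length(body) > 1) {
    df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
    coefs <- stats::setNames(df$coefficient, df$cpg_id)
    means <- stats::setNames(df$train_mean, df$cpg_id)
  }
  new_equiclock(
    intercept = as.numeric(get1("intercept")),
    coefficients = coefs,
    alpha = as.numeric(get1("alpha")),
    lambda = as.numeric(get1("lambda")),
    transform = spec,
    cpg_means = means,
    n_train = as.integer(get1("n_train"))
  )
}
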