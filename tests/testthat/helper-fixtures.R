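# Small fixture builders shared across test files. Everything is generated
# in code under fixed seeds; nothing is read from disk.

tiny_beta <- function(n = 3, p = 4, seed = 42) {
  set.seed(seed)
  beta_matrix(matrix(runif(n * p), n, p,
                     dimnames = list(sprintf("s%02d", seq_len(n)),
                                     sprintf("cg%03d", seq_len(p)))))
}

tiny_sheet <- function(beta, ages = NULL, species = "horse",
                       tissue = "blood") {
  n <- nrow(beta)
  sample_sheet(data.frame(
    sample_id = rownames(beta),
    age = ages %||% seq(1, 20, length.out = n),
    species = species, tissue = tissue,
    sex = rep(c("female", "male"), length.out = n),
    castrated = "not_applicable",
    stringsAsFactors = FALSE
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noiseless single-CpG aging dataset: one informative CpG carries age
# exactly, the rest are constant-free random noise predictors.
single_cpg_dataset <- function(n = 24, p = 5, seed = 7) {
  set.seed(seed)
  age <- seq(0.5, 24, length.out = n)
  X <- matrix(runif(n * (p - 1), 0.3, 0.7), n, p - 1)
  X <- cbind(age / 40, X)  # beta of CpG 1 is age/40, so age = 40 * beta
  dimnames(X) <- list(sprintf("s%02d", seq_len(n)),
                      sprintf("cg%03d", seq_len(p)))
  list(beta = beta_matrix(X),
       sheet = tiny_sheet(beta_matrix(X), ages = age))
}

# Small male-only design for castration screens.
male_design <- function(n_gelding = 48, n_stallion = 10) {
  data.frame(tissue = "blood", species = "horse", n_female = 0,
             n_gelding = n_gelding, n_stallion = n_stallion,
             age_min = 0, age_max = 28, stringsAsFactors = FALSE)
}

horse_blood_design <- function(n = 188) {
  n_geld <- if (n >= 150) 49 else round(0.26 * n)
  n_stal <- if (n >= 150) 12 else max(1, round(0.06 * n))
  data.frame(tissue = "blood", species = "horse",
             n_female = n - n_geld - n_stal, n_gelding = n_geld,
             n_stallion = n_stal, age_min = 0, age_max = 28,
             stringsAsFactors = FALSE)
}

# The equid log-linear transform used by the multi-species clock tests.
equid_loglinear <- function() age_transform("loglinear", equid_species_table())
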