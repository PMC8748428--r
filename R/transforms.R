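#' Relative age: chronological age as a fraction of maximum lifespan
#'
#' Relative age is `age / max_lifespan`, a unitless ratio in roughly
#' \[0, 1\] that aligns species with very different lifespans (e.g. 57 years
#' for horses against 122.5 for humans) onto a common scale, so a single
#' penalized-regression formula can serve both species.
#'
#' @param age Chronological age(s) in years, non-negative.
#' @param max_lifespan Maximum recorded lifespan of the species, years.
#' @return `age / max_lifespan`.
#' @examples
#' relative_age(57, 57)     # 1: a horse at the species record age
#' relative_age(24.5, 122.5)
#' @export
relative_age <- function(age, max_lifespan) {
  if (any(max_lifespan <= 0)) {
    eq_stop("eq_domain_error", "max_lifespan must be positive")
  }
  if (any(age < 0)) eq_stop("eq_domain_error", "age must be non-negative")
  age / max_lifespan
}

#' @rdname relative_age
#' @param value Relative age value(s) to invert back to years.
#' @export
inverse_relative_age <- function(value, max_lifespan) {
  if (any(max_lifespan <= 0)) {
    eq_stop("eq_domain_error", "max_lifespan must be positive")
  }
  value * max_lifespan
}

#' Log-linear age transform anchored at sexual maturity
#'
#' The maturity-anchored transform used for multi-species clocks when
#' maximum lifespan is unreliable: logarithmic before sexual maturity
#' (where methylation change is fast) and linear after it, with value 0 and
#' matching first derivative at the junction `age = m`:
#' \deqn{f(a) = \log\frac{a + c}{m + c} \quad (a \le m), \qquad
#'       f(a) = \frac{a - m}{m + c} \quad (a > m)}
#' where `m` is the species' average age at sexual maturity and `c > 0` a
#' small offset (default 2 years) keeping the logarithm finite at birth.
#'
#' @param age Chronological age(s), years (>= 0 in normal use; any
#'   `age > -c` is mathematically valid).
#' @param m Age at sexual maturity, years (> 0).
#' @param c_offset Offset constant in years (> 0), default 2.
#' @return Transformed age, dimensionless.
#' @examples
#' loglinear_age(3, m = 3)        # 0 at the junction
#' loglinear_age(13, m = 3, c_offset = 2)  # (13-3)/(3+2) = 2
#' @export
loglinear_age <- function(age, m, c_offset = 2) {
  if (any(m <= 0) || any(c_offset <= 0)) {
    eq_stop("eq_domain_error", "need m > 0 and c_offset > 0")
  }
  if (any(age + c_offset <= 0)) {
    eq_stop("eq_domain_error", "age + c_offset must be positive")
  }
  ifelse(age <= m,
         log((age + c_offset) / (m + c_offset)),
         (age - m) / (m + c_offset))
}

#' @rdname loglinear_age
#' @param value Transformed value(s) to map back to years.
#' @export
inverse_loglinear_age <- function(value, m, c_offset = 2) {
  if (any(m <= 0) || any(c_offset <= 0)) {
    eq_stop("eq_domain_error", "need m > 0 and c_offset > 0")
  }
  ifelse(value <= 0,
         exp(value) * (m + c_offset) - c_offset,
         value * (m + c_offset) + m)
}

#' Species-aware age transform specification
#'
#' Bundles a transform kind with the per-species constants required to apply
#' and invert it, so a fitted clock can report DNAm age in years for any
#' species it was trained on.
#'
#' @param kind One of `"identity"`, `"relative_age"`, `"loglinear"`.
#' @param species_table A [species_table()]; required for the non-identity
#'   kinds.
#' @param c_offset Offset constant (years) for the log-linear transform.
#' @return An object of class `"age_transform"`.
#' @examples
#' tr <- age_transform("relative_age", equid_species_table())
#' transform_age(tr, 28.5, "horse")
#' @export
age_transform <- function(kind = c("identity", "relative_age", "loglinear"),
                          species_table = NULL, c_offset = 2) {
  kind <- match.arg(kind)
  if (kind != "identity" && is.null(species_table)) {
    eq_stop("eq_validation_error",
            "transform '%s' requires a species_table", kind)
  }
  if (c_offset <= 0) eq_stop("eq_domain_error", "c_offset must be > 0")
  structure(list(kind = kind, species_table = species_table,
                 c_offset = c_offset),
            class = "age_transform")
}

species_params <- function(spec, species) {
  st <- spec$species_table
  idx <- match(species, st$species)
  if (anyNA(idx)) {
    eq_stop("eq_lookup_error", "species not in species table: %s",
            paste(unique(species[is.na(idx)]), collapse = ", "))
  }
  st[idx, , drop = FALSE]
}

#' Apply or invert an age transform for given species
#'
#' @param spec An [age_transform()] object.
#' @param age,value Ages in years (forward) or transformed values (inverse).
#' @param species Character vector of species labels, recycled against
#'   `age`/`value`; ignored by the identity transform.
#' @return Transformed values (forward) or ages in years (inverse).
#' @export
transform_age <- function(spec, age, species = NULL) {
  switch(spec$kind,
    identity = age,
    relative_age = {
      p <- species_params(spec, species)
      relative_age(age, p$max_lifespan)
    },
    loglinear = {
      p <- species_params(spec, species)
      loglinear_age(age, p$maturity_age, spec$c_offset)
    }
  )
}

#' @rdname transform_age
#' @export
inverse_transform_age <- function(spec, value, species = NULL) {
  switch(spec$kind,
    identity = value,
    relative_age = {
      p <- species_params(spec, species)
      inverse_relative_age(value, p$max_lifespan)
    },
    loglinear = {
      p <- species_params(spec, species)
      inverse_loglinear_age(value, p$maturity_age, spec$c_offset)
    }
  )
}

#' @exportS3Method base::print
print.age_transform <- function(x, ...) {
  cat(sprintf("age_transform: %s", x$kind))
  if (x$kind == "loglinear") cat(sprintf(" (c = %g years)", x$c_offset))
  cat("\n")
  if (!is.null(x$species_table)) {
    print(as.data.frame(x$species_table))
  }
  invisible(x)
}
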