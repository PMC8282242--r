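# Invertible transformations of chronological age used as the dependent
# variable of the penalized regression.  Multi-species clocks regress on a
# log-linear transform (logarithmic before a species' adult age, linear with
# matched slope after, so juvenile errors are comparable across species) or
# on relative age (age divided by the species' maximum lifespan, in [0,1]).
# Pure single- or dual-species blood clocks use untransformed age.

#' Log-linear age transform
#'
#' \deqn{F(a) = \log\frac{a+1}{m+1} \quad (a \le m), \qquad
#'       F(a) = \frac{a-m}{m+1} \quad (a > m)}
#' where `m` is the species' adult age.  F is continuous, strictly
#' increasing, zero at `m`, and both branches have slope `1/(m+1)` at `m`.
#'
#' @param age chronological age in years (vectorized, non-negative).
#' @param adult_age species adult age in years (positive scalar).
#' @return transformed age (dimensionless).
#' @export
loglinear_age <- function(age, adult_age) {
  if (adult_age <= 0) stop("adult_age must be positive")
  if (any(age < 0, na.rm = TRUE)) stop("age must be non-negative")
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' Inverse of the log-linear age transform
#'
#' Exact inverse of [loglinear_age()]: `exp(y)*(m+1) - 1` for `y <= 0`,
#' `y*(m+1) + m` for `y > 0`.  Values that invert below zero (possible for
#' extreme negative predictions) are clamped to 0 with a warning.
#'
#' @param y transformed age.
#' @param adult_age species adult age in years (positive scalar).
#' @return age in years.
#' @export
loglinear_age_inverse <- function(y, adult_age) {
  if (adult_age <= 0) stop("adult_age must be positive")
  a <- ifelse(y <= 0, exp(y) * (adult_age + 1) - 1, y * (adult_age + 1) + adult_age)
  if (any(a < 0, na.rm = TRUE)) {
    warning("inverse transform produced negative ages; clamped to 0")
    a[a < 0] <- 0
  }
  a
}

#' Relative age
#'
#' `age / max_lifespan`, the dimensionless age used by the multi-species
#' relative-age clock.  Values above 1 (an animal older than the configured
#' maximum) are allowed but flagged with a warning.
#'
#' @param age chronological age in years (non-negative).
#' @param max_lifespan species maximum lifespan in years (positive scalar).
#' @return relative age, normally in \[0, 1\].
#' @export
relative_age <- function(age, max_lifespan) {
  if (max_lifespan <= 0) stop("max_lifespan must be positive")
  if (any(age < 0, na.rm = TRUE)) stop("age must be non-negative")
  out <- age / max_lifespan
  if (any(out > 1, na.rm = TRUE))
    warning("relative age above 1: animal older than the configured maximum lifespan")
  out
}

#' @rdname relative_age
#' @param y relative age to convert back to years; negative values are
#'   clamped to 0 with a warning.
#' @export
relative_age_inverse <- function(y, max_lifespan) {
  if (max_lifespan <= 0) stop("max_lifespan must be positive")
  a <- y * max_lifespan
  if (any(a < 0, na.rm = TRUE)) {
    warning("inverse transform produced negative ages; clamped to 0")
    a[a < 0] <- 0
  }
  a
}

#' Age-transform specification
#'
#' Bundles a transform kind with its per-species parameters so clocks can be
#' trained and applied across species with one formula.
#'
#' @param kind one of `"identity"`, `"loglinear"`, `"relative"`.
#' @param adult_age named numeric vector of adult ages (years) per species;
#'   required for `"loglinear"`.
#' @param max_lifespan named numeric vector of maximum lifespans (years) per
#'   species; required for `"relative"`.
#' @return an object of class `age_transform`.
#' @examples
#' tr <- age_transform("relative",
#'                     max_lifespan = c(asian_elephant = 85, human = 122))
#' transform_age(tr, 42.5, "asian_elephant")
#' @export
age_transform <- function(kind = c("identity", "loglinear", "relative"),
                          adult_age = NULL, max_lifespan = NULL) {
  kind <- match.arg(kind)
  if (kind == "loglinear") {
    if (is.null(adult_age) || is.null(names(adult_age)))
      stop("loglinear transform requires a named adult_age vector")
    if (any(adult_age <= 0)) stop("adult_age values must be positive")
  }
  if (kind == "relative") {
    if (is.null(max_lifespan) || is.null(names(max_lifespan)))
      stop("relative transform requires a named max_lifespan vector")
    if (any(max_lifespan <= 0)) stop("max_lifespan values must be positive")
  }
  structure(list(kind = kind, adult_age = adult_age,
                 max_lifespan = max_lifespan),
            class = "age_transform")
}

transform_param_ <- function(spec, field, species) {
  p <- spec[[field]][as.character(species)]
  if (anyNA(p)) {
    missing_sp <- unique(as.character(species)[is.na(p)])
    stop(sprintf("no %s configured for species: %s", field,
                 paste(missing_sp, collapse = ", ")))
  }
  unname(p)
}

#' Apply / invert an age transform
#'
#' @param spec an [age_transform()] object.
#' @param age age in years (`transform_age`) or transformed value
#'   (`inverse_transform_age`).
#' @param species character vector of species, recycled against `age`;
#'   ignored for the identity transform.
#' @return numeric vector on the transformed scale, or years.
#' @export
transform_age <- function(spec, age, species = NULL) {
  stopifnot(inherits(spec, "age_transform"))
  switch(spec$kind,
    identity = {
      if (any(age < 0, na.rm = TRUE)) stop("age must be non-negative")
      age
    },
    loglinear = {
      m <- transform_param_(spec, "adult_age", species)
      loglinear_vec_(age, m, inverse = FALSE)
    },
    relative = {
      L <- transform_param_(spec, "max_lifespan", species)
      if (any(age < 0, na.rm = TRUE)) stop("age must be non-negative")
      age / rep_len(L, length(age))
    })
}

#' @rdname transform_age
#' @export
inverse_transform_age <- function(spec, age, species = NULL) {
  stopifnot(inherits(spec, "age_transform"))
  switch(spec$kind,
    identity = pmax(age, 0),
    loglinear = {
      m <- transform_param_(spec, "adult_age", species)
      loglinear_vec_(age, m, inverse = TRUE)
    },
    relative = {
      L <- transform_param_(spec, "max_lifespan", species)
      pmax(age * L, 0)
    })
}

# Per-element loglinear with a (possibly vector) adult age.
loglinear_vec_ <- function(x, m, inverse) {
  m <- rep_len(m, length(x))
  if (!inverse) {
    if (any(x < 0, na.rm = TRUE)) stop("age must be non-negative")
    ifelse(x <= m, log((x + 1) / (m + 1)), (x - m) / (m + 1))
  } else {
    a <- ifelse(x <= 0, exp(x) * (m + 1) - 1, x * (m + 1) + m)
    pmax(a, 0)
  }
}
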