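# Tabular formats shared by every stage: beta-value matrices (TSV, probes in
# rows, samples in columns), sample sheets and probe-annotation manifests
# (CSV), and clock models (JSON).  Validation is strict: malformed input
# raises a typed condition rather than being silently coerced.

SPECIES_LEVELS <- c("asian_elephant", "african_elephant", "human")
REGION_LEVELS <- c("promoter", "exon", "intron", "upstream", "downstream",
                   "intergenic")

mc_error_ <- function(class, msg, ...) {
  stop(structure(class = c(class, "mammclock_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Read a methylation beta-value matrix
#'
#' Reads a TSV whose first column (`probe_id`) holds probe identifiers and
#' whose remaining columns are samples; every value must lie in \[0, 1\] or
#' equal the missing marker.  Matrices are stored probes x samples (the
#' array-manifest convention); set `transpose = TRUE` only if the file is
#' known to be samples x probes — orientation is never guessed.
#'
#' @param path file path to a TSV (tab-separated, UTF-8, header row).
#' @param missing_marker string treated as missing (default `"NA"`).
#' @param transpose transpose after reading (explicit flag, no
#'   auto-detection).
#' @return numeric matrix, probes in rows, samples in columns, with
#'   dimnames.
#' @export
read_beta_matrix <- function(path, missing_marker = "NA", transpose = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = missing_marker, colClasses = "character")
  if (ncol(dt) < 2L)
    mc_error_("mammclock_format_error", "beta matrix needs a probe_id column and at least one sample")
  probe_ids <- dt[[1L]]
  sample_ids <- colnames(dt)[-1L]
  if (anyDuplicated(probe_ids))
    mc_error_("mammclock_format_error", "duplicated probe id(s): %s",
              paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    mc_error_("mammclock_format_error", "duplicated sample id(s): %s",
              paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(dt[, -1L, with = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad_parse <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad_parse)) {
    mc_error_("mammclock_parse_error",
              "non-numeric value '%s' at probe %s, sample %s",
              vals[bad_parse[1L, , drop = FALSE]],
              probe_ids[bad_parse[1L, 1L]], sample_ids[bad_parse[1L, 2L]])
  }
  out_of_range <- which(!is.na(num) & (num < 0 | num > 1), arr.ind = TRUE)
  if (nrow(out_of_range)) {
    i <- out_of_range[1L, 1L]; j <- out_of_range[1L, 2L]
    mc_error_("mammclock_validation_error",
              "beta value %g outside [0,1] at probe %s, sample %s",
              num[i, j], probe_ids[i], sample_ids[j])
  }
  dimnames(num) <- list(probe_ids, sample_ids)
  if (transpose) num <- t(num)
  num
}

#' Write a beta matrix as TSV
#'
#' Inverse of [read_beta_matrix()]: first column `probe_id`, values with 10+
#' significant digits, missing written as `NA`.
#'
#' @param beta numeric matrix, probes x samples, with dimnames.
#' @param path output file path.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  dt <- data.table::data.table(probe_id = rownames(beta))
  for (j in colnames(beta)) dt[[j]] <- format(beta[, j], digits = 12, trim = TRUE)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with required columns `sample_id`, `species`, `sex`, `age_years`,
#' `age_confidence` (`tissue` optional).  Species strings are normalized
#' case-insensitively to `asian_elephant` / `african_elephant` / `human`;
#' anything else is kept verbatim ("other" species).  Sex is `F`, `M` or
#' `unknown`.
#'
#' @param path file path to the CSV.
#' @return data.frame of typed sample records, one row per animal.
#' @export
read_sample_sheet <- function(path) {
  df <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  req <- c("sample_id", "species", "sex", "age_years", "age_confidence")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    mc_error_("mammclock_format_error", "sample sheet missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    return(data.frame(sample_id = character(), species = character(),
                      sex = character(), age_years = numeric(),
                      tissue = character(), age_confidence = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(df$sample_id))
    mc_error_("mammclock_format_error", "duplicated sample id(s): %s",
              paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  species <- normalize_species_(df$species)
  sex <- toupper(trimws(df$sex))
  sex[!sex %in% c("F", "M")] <- "unknown"
  age <- suppressWarnings(as.numeric(df$age_years))
  if (anyNA(age))
    mc_error_("mammclock_parse_error", "non-numeric age_years for sample %s",
              df$sample_id[which(is.na(age))[1L]])
  if (any(age < 0))
    mc_error_("mammclock_validation_error", "negative age_years for sample %s",
              df$sample_id[which(age < 0)[1L]])
  conf <- suppressWarnings(as.numeric(df$age_confidence))
  if (anyNA(conf) || any(conf < 0 | conf > 100))
    mc_error_("mammclock_validation_error",
              "age_confidence must be numeric in [0,100]")
  data.frame(sample_id = df$sample_id, species = species, sex = sex,
             age_years = age,
             tissue = if ("tissue" %in% colnames(df)) df$tissue else "blood",
             age_confidence = conf, stringsAsFactors = FALSE)
}

normalize_species_ <- function(x) {
  key <- gsub("[ .-]+", "_", tolower(trimws(x)))
  map <- c(asian_elephant = "asian_elephant", asian = "asian_elephant",
           elephas_maximus = "asian_elephant",
           african_elephant = "african_elephant", african = "african_elephant",
           loxodonta_africana = "african_elephant",
           human = "human", homo_sapiens = "human")
  out <- unname(map[key])
  out[is.na(out)] <- key[is.na(out)]
  out
}

#' @rdname read_sample_sheet
#' @param samples data.frame of sample records.
#' @param path output CSV path.
#' @export
write_sample_sheet <- function(samples, path) {
  data.table::fwrite(samples, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Filter samples by confidence in the age estimate
#'
#' Retains records whose `age_confidence` (percent) is at or above the
#' threshold; order is preserved.  The default of 90 drops animals whose
#' studbook age is too uncertain for clock training.
#'
#' @param samples data.frame from [read_sample_sheet()].
#' @param min_confidence minimum confidence in percent (default 90).
#' @return the filtered data.frame.
#' @export
filter_by_age_confidence <- function(samples, min_confidence = 90) {
  samples[samples$age_confidence >= min_confidence, , drop = FALSE]
}

#' Read a probe-annotation manifest
#'
#' CSV with columns `probe_id`, `chrom`, `pos` (1-based), `nearest_gene`,
#' `tss_distance` (signed bp, negative = upstream of the TSS),
#' `region_class` (promoter/exon/intron/upstream/downstream/intergenic) and
#' `cgi` (logical: in a CpG island).
#'
#' @param path file path to the CSV.
#' @return data.frame of probe annotations.
#' @export
read_probe_annotation <- function(path) {
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  req <- c("probe_id", "chrom", "pos", "nearest_gene", "tss_distance",
           "region_class", "cgi")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    mc_error_("mammclock_format_error", "manifest missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (any(df$pos < 1))
    mc_error_("mammclock_validation_error", "positions must be 1-based (>= 1)")
  bad_region <- setdiff(unique(df$region_class), REGION_LEVELS)
  if (length(bad_region))
    mc_error_("mammclock_validation_error", "unknown region_class: %s",
              paste(bad_region, collapse = ", "))
  df$cgi <- as.logical(df$cgi)
  df
}

#' @rdname read_probe_annotation
#' @param annot data.frame of probe annotations.
#' @param path output CSV path.
#' @export
write_probe_annotation <- function(annot, path) {
  data.table::fwrite(annot, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Serialize / restore a clock model
#'
#' Clock models are stored as JSON with the intercept, elastic-net mixing
#' and selected penalty, the age transform with its per-species parameters,
#' and only the nonzero probe coefficients, at full double precision.
#'
#' @param model a `clock_model` object from [train_clock()].
#' @param path file path for the JSON.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  tr <- model$transform
  obj <- list(intercept = model$intercept, alpha = model$alpha,
              lambda = model$lambda,
              transform = list(kind = tr$kind,
                               adult_age = as.list(tr$adult_age),
                               max_lifespan = as.list(tr$max_lifespan)),
              coefficients = as.list(model$coefficients),
              training_species = model$training_species,
              n_train = model$n_train)
  # I(17) significant digits: doubles survive the round-trip bit-faithfully
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_clock_model
#' @return `read_clock_model` returns the restored `clock_model`.
#' @export
read_clock_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  kind <- obj$transform$kind
  if (is.null(kind) || !kind %in% c("identity", "loglinear", "relative"))
    mc_error_("mammclock_format_error", "unknown transform kind '%s'",
              if (is.null(kind)) "<missing>" else kind)
  coefs <- obj$coefficients
  cv <- vapply(coefs, function(x) {
    if (!is.numeric(x)) mc_error_("mammclock_parse_error",
                                  "non-numeric coefficient in clock model")
    as.numeric(x)
  }, numeric(1))
  if (length(cv) && (is.null(names(cv)) || any(!nzchar(names(cv)))))
    mc_error_("mammclock_parse_error", "malformed probe id in coefficient table")
  tr <- age_transform(kind,
                      adult_age = unlist_named_(obj$transform$adult_age),
                      max_lifespan = unlist_named_(obj$transform$max_lifespan))
  structure(list(intercept = as.numeric(obj$intercept),
                 coefficients = cv, alpha = as.numeric(obj$alpha),
                 lambda = as.numeric(obj$lambda), transform = tr,
                 training_species = unlist(obj$training_species),
                 n_train = as.integer(obj$n_train)),
            class = "clock_model")
}

unlist_named_ <- function(x) {
  if (is.null(x) || !length(x)) return(NULL)
  setNames(vapply(x, as.numeric, numeric(1)), names(x))
}
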