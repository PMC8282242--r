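# End-to-end orchestration: confidence filter -> integrity classifiers ->
# clock cross-validation -> clock training -> per-species age EWAS ->
# Stouffer meta-analysis -> top-CpG selection -> cross-species concordance
# -> genomic-context summary.  One root seed feeds named substreams so
# every numeric output is reproducible bit-for-bit from the config.

#' Pipeline run configuration
#'
#' Inputs may be given as file paths (read with the package readers) or as
#' in-memory objects; paths are validated at construction time.
#'
#' @param beta,samples,annotation in-memory inputs (a probes x samples
#'   matrix, a sample sheet data.frame, a manifest data.frame), or `NULL`
#'   when the corresponding path is given.
#' @param beta_path,sample_sheet_path,manifest_path file paths
#'   (`manifest_path` optional).
#' @param out_dir output directory (created if absent).
#' @param transform an [age_transform()] for the clock.
#' @param alpha elastic-net mixing (default 0.5).
#' @param cv_scheme `"loo"` or `"lofo10"`.
#' @param min_age_confidence confidence filter threshold in percent.
#' @param p_threshold,cap_per_direction EWAS selection rule.
#' @param stouffer_weights `"sqrt_n"` or `"equal"`.
#' @param run_classifiers run the random-forest species/sex integrity
#'   checks.
#' @param seed root seed; all stage seeds are derived from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(beta = NULL, samples = NULL, annotation = NULL,
                       beta_path = NULL, sample_sheet_path = NULL,
                       manifest_path = NULL, out_dir = tempfile("mammclock_"),
                       transform = age_transform("identity"), alpha = 0.5,
                       cv_scheme = c("loo", "lofo10"),
                       min_age_confidence = 90, p_threshold = 1e-5,
                       cap_per_direction = 500,
                       stouffer_weights = c("sqrt_n", "equal"),
                       run_classifiers = TRUE, seed = 1) {
  cv_scheme <- match.arg(cv_scheme)
  stouffer_weights <- match.arg(stouffer_weights)
  for (p in c(beta_path, sample_sheet_path, manifest_path))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  if (is.null(beta) && is.null(beta_path)) stop("no beta matrix provided")
  if (is.null(samples) && is.null(sample_sheet_path)) stop("no sample sheet provided")
  structure(list(beta = beta, samples = samples, annotation = annotation,
                 beta_path = beta_path, sample_sheet_path = sample_sheet_path,
                 manifest_path = manifest_path, out_dir = out_dir,
                 transform = transform, alpha = alpha, cv_scheme = cv_scheme,
                 min_age_confidence = min_age_confidence,
                 p_threshold = p_threshold,
                 cap_per_direction = cap_per_direction,
                 stouffer_weights = stouffer_weights,
                 run_classifiers = run_classifiers, seed = seed),
            class = "run_config")
}

# Polynomial rolling hash of a string; good enough to fingerprint a config.
config_hash_ <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full clock-and-EWAS workflow
#'
#' Executes every stage of the analysis on one dataset and writes its
#' outputs (clock model JSON, CV report CSV + metrics JSON, per-species
#' EWAS TSVs, meta-analysis, top selections, concordance, context summary)
#' under `config$out_dir`, together with a manifest listing every file and
#' the config fingerprint.  A failure in any stage aborts with the stage
#' name; outputs of completed stages are preserved.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list bundle with all stage results and the
#'   manifest.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }
  stage <- "load_inputs"
  bundle <- list()
  tryCatch({
    beta <- if (!is.null(config$beta)) config$beta else
      read_beta_matrix(config$beta_path)
    samples <- if (!is.null(config$samples)) config$samples else
      read_sample_sheet(config$sample_sheet_path)
    annotation <- if (!is.null(config$annotation)) config$annotation else
      if (!is.null(config$manifest_path)) read_probe_annotation(config$manifest_path)
      else NULL
    if (config$transform$kind == "relative") {
      missing_sp <- setdiff(unique(samples$species),
                            names(config$transform$max_lifespan))
      if (length(missing_sp))
        stop("no max_lifespan configured for species: ",
             paste(missing_sp, collapse = ", "))
    }
    if (config$transform$kind == "loglinear") {
      missing_sp <- setdiff(unique(samples$species),
                            names(config$transform$adult_age))
      if (length(missing_sp))
        stop("no adult_age configured for species: ",
             paste(missing_sp, collapse = ", "))
    }

    stage <- "confidence_filter"
    samples <- filter_by_age_confidence(samples, config$min_age_confidence)
    beta <- beta[, samples$sample_id, drop = FALSE]

    stage <- "integrity_classifiers"
    if (config$run_classifiers) {
      if (length(unique(samples$species)) >= 2L) {
        rep_sp <- fit_rf_classifier(beta, samples$species, target = "species",
                                    seed = derive_seed_(config$seed, "rf_species"))
        bundle$species_check <- rep_sp
        jsonlite::write_json(list(target = "species", oob_error = rep_sp$oob_error,
                                  n_trees = rep_sp$n_trees),
                             emit(file.path(config$out_dir, "check_species.json")),
                             auto_unbox = TRUE, digits = NA)
      }
      if (all(c("F", "M") %in% samples$sex)) {
        rep_sx <- fit_rf_classifier(beta, samples$sex, target = "sex",
                                    seed = derive_seed_(config$seed, "rf_sex"))
        bundle$sex_check <- rep_sx
        jsonlite::write_json(list(target = "sex", oob_error = rep_sx$oob_error,
                                  n_trees = rep_sx$n_trees),
                             emit(file.path(config$out_dir, "check_sex.json")),
                             auto_unbox = TRUE, digits = NA)
      }
    }

    stage <- "clock_cross_validation"
    cv <- if (config$cv_scheme == "loo")
      loocv(beta, samples, config$transform, alpha = config$alpha,
            seed = derive_seed_(config$seed, "cv"))
    else lofo10(beta, samples, config$transform, alpha = config$alpha,
                seed = derive_seed_(config$seed, "cv"))
    bundle$cv_report <- cv
    data.table::fwrite(cv$per_sample,
                       emit(file.path(config$out_dir, "cv_per_sample.csv")))
    jsonlite::write_json(list(pearson_r = cv$pearson_r,
                              mae_years = cv$mae_years, n = cv$n,
                              scheme = config$cv_scheme),
                         emit(file.path(config$out_dir, "cv_metrics.json")),
                         auto_unbox = TRUE, digits = NA)

    stage <- "clock_training"
    clock <- train_clock(beta, samples, config$transform,
                         alpha = config$alpha,
                         seed = derive_seed_(config$seed, "train"))
    bundle$clock <- clock
    write_clock_model(clock, emit(file.path(config$out_dir, "clock_model.json")))

    stage <- "age_ewas"
    species_list <- unique(samples$species)
    screens <- lapply(species_list, function(sp) {
      ss <- samples[samples$species == sp, , drop = FALSE]
      correlation_screen(beta[, ss$sample_id, drop = FALSE], ss$age_years)
    })
    names(screens) <- species_list
    bundle$ewas <- screens
    for (sp in species_list)
      write_ewas(screens[[sp]],
                 emit(file.path(config$out_dir, paste0("ewas_age_", sp, ".tsv"))))

    stage <- "meta_analysis"
    if (length(screens) >= 2L) {
      meta <- ewas_meta(screens, weights = config$stouffer_weights)
      bundle$meta <- meta
      write_ewas(meta, emit(file.path(config$out_dir, "ewas_age_meta.tsv")))
    }

    stage <- "top_selection"
    bundle$top <- lapply(screens, select_top,
                         p_threshold = config$p_threshold,
                         cap_per_direction = config$cap_per_direction)

    stage <- "concordance"
    if (length(screens) == 2L) {
      conc <- concordance(screens[[1L]], screens[[2L]],
                          p_threshold = config$p_threshold)
      bundle$concordance <- conc
      data.table::fwrite(conc, emit(file.path(config$out_dir, "concordance.tsv")),
                         sep = "\t")
    }

    stage <- "context_summary"
    if (!is.null(annotation)) {
      sel <- do.call(rbind, unlist(lapply(bundle$top, unname), recursive = FALSE))
      if (!is.null(sel) && nrow(sel)) {
        ctx <- context_summary(sel, annotation)
        bundle$context <- ctx
        data.table::fwrite(ctx, emit(file.path(config$out_dir, "context_summary.tsv")),
                           sep = "\t")
      }
    }

    stage <- "manifest"
    cfg_json <- jsonlite::toJSON(list(alpha = config$alpha,
                                      cv_scheme = config$cv_scheme,
                                      transform = config$transform$kind,
                                      min_age_confidence = config$min_age_confidence,
                                      p_threshold = config$p_threshold,
                                      cap_per_direction = config$cap_per_direction,
                                      stouffer_weights = config$stouffer_weights,
                                      seed = config$seed),
                                 auto_unbox = TRUE, digits = NA)
    manifest <- list(config = jsonlite::fromJSON(cfg_json),
                     config_hash = config_hash_(as.character(cfg_json)),
                     outputs = basename(outputs))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    bundle$manifest <- manifest
    invisible(bundle)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
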