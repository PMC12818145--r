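#' Read an indicator table from CSV
#'
#' Expects a header row of indicator names and one row per observational
#' unit, numeric throughout, decimal point only (locale-independent). When a
#' model is supplied the columns are matched to its indicators by exact
#' (case-sensitive) name and reordered to model order; extra columns are
#' dropped with a warning and missing columns are a schema error listing all
#' missing names.
#'
#' @param path CSV file path.
#' @param spec optional `pls_model` to match columns against.
#' @param id_column optional name of a non-numeric identifier column; it is
#'   moved to row names.
#' @return Numeric matrix (observations x indicators).
#' @export
read_indicator_csv <- function(path, spec = NULL, id_column = NULL) {
  if (!file.exists(path)) stop_spec("data file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(id_column)) {
    if (!id_column %in% names(df))
      stop_spec("id column '%s' not present", id_column)
    rn <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
    rownames(df) <- rn
  }
  for (j in names(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop_spec("non-numeric value in column '%s', row %d", j,
                if (is.na(bad)) 1L else bad)
    }
    if (anyNA(df[[j]]))
      stop_spec("missing value in column '%s', row %d", j,
                which(is.na(df[[j]]))[1])
  }
  if (!is.null(spec)) {
    ind <- indicator_names(spec)
    miss <- setdiff(ind, names(df))
    if (length(miss))
      stop_spec("data is missing indicator column(s): %s",
                paste(miss, collapse = ", "))
    extra <- setdiff(names(df), ind)
    if (length(extra))
      warning("ignoring column(s) not in the model: ",
              paste(extra, collapse = ", "), call. = FALSE)
    df <- df[, ind, drop = FALSE]
  }
  as.matrix(df)
}

#' Write an indicator table to CSV at full precision
#'
#' Serializes with 17 significant digits so that a write/read round trip
#' preserves the values exactly.
#'
#' @param data numeric matrix or data frame.
#' @param path output path.
#' @export
write_indicator_csv <- function(data, path) {
  x <- as_data_matrix(data)
  df <- as.data.frame(lapply(as.data.frame(x),
                             function(v) sprintf("%.17g", v)),
                      check.names = FALSE)
  names(df) <- colnames(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes fit, evaluation and bootstrap inference; optionally prunes weak
#' indicators (those whose loading does not exceed the validity threshold
#' *and* whose bootstrap test is not significant) and refits on the pruned
#' measurement model; then runs the importance-performance analysis. The
#' report bundle — evaluation, bootstrap table, IPMA points and a run
#' manifest that fully determines a re-run — is written to `out_dir`. Any
#' stage error aborts the run with a stage-tagged message and removes
#' partial outputs.
#'
#' @param data indicator table: a CSV path, matrix or data frame.
#' @param spec model: a JSON path or a `pls_model`.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param B bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param alpha significance level.
#' @param prune prune invalid-and-insignificant indicators before IPMA
#'   (default `TRUE`).
#' @param loading_threshold validity cut-off for loadings.
#' @param bounds optional theoretical rescaling bounds.
#' @param target IPMA target (default: the spec's `ipma_target`; IPMA is
#'   skipped with a message when neither is set).
#' @return Invisibly, a list with `fit`, `evaluation`, `bootstrap`,
#'   `pruned_indicators`, `refit` (when pruning removed anything),
#'   `ipma`, `manifest` and `files`.
#' @export
run_pls_pipeline <- function(data, spec, out_dir = NULL, B = 2000, seed = 1L,
                             alpha = 0.05, prune = TRUE,
                             loading_threshold = 0.5, bounds = NULL,
                             target = NULL) {
  data_path <- if (is.character(data)) data else NA_character_
  model_path <- if (is.character(spec)) spec else NA_character_
  if (is.character(spec)) spec <- read_model_spec(spec)
  if (is.character(data)) data <- read_indicator_csv(data, spec = spec)

  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(errorCondition(
        sprintf("stage '%s': %s", name, conditionMessage(e)),
        class = class(e)[class(e) != "simpleError"]))
    })
  }

  fit <- stage("fit", pls_fit(data, spec, bounds = bounds))
  evaluation <- stage("evaluate", pls_evaluate(fit, loading_threshold))
  boot <- stage("bootstrap",
                pls_bootstrap(data, spec, B = B, seed = seed, alpha = alpha))

  pruned <- character(0)
  refit <- NULL
  if (prune) {
    res <- boot$results[boot$results$type == "loading", ]
    weak <- res$parameter[res$estimate <= loading_threshold &
                            res$testable & !res$significant]
    if (length(weak)) {
      pruned <- weak
      spec2 <- stage("prune", prune_spec(spec, weak))
      refit <- stage("refit", pls_fit(data[, indicator_names(spec2),
                                           drop = FALSE],
                                      spec2, bounds = bounds))
    }
  }

  ipma_fit <- refit %||% fit
  target <- target %||% spec$ipma_target
  ipma <- NULL
  if (is.null(target)) {
    message("no IPMA target set; skipping the importance-performance stage")
  } else {
    ipma <- stage("ipma", pls_ipma(ipma_fit, target = target))
  }

  manifest <- list(
    data = data_path, model = model_path,
    model_hash = model_hash(spec),
    n_obs = fit$n_obs, B = B, seed = seed, alpha = alpha,
    loading_threshold = loading_threshold,
    pruned_indicators = as.list(pruned),
    pruning_rule = "loading <= threshold AND bootstrap not significant",
    bootstrap_failed_resamples = boot$n_failed,
    ipma_target = target,
    package_version = as.character(utils::packageVersion("plsipa")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- stage("write", {
      f <- file.path(out_dir, c("evaluation.json", "bootstrap.csv",
                                "ipma.csv", "manifest.json"))
      jsonlite::write_json(evaluation_export(evaluation), f[1],
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      utils::write.csv(boot$results, f[2], row.names = FALSE)
      if (!is.null(ipma)) {
        pts <- rbind(
          data.frame(item = ipma$latent_points$latent, level = "latent",
                     importance = ipma$latent_points$importance,
                     performance = ipma$latent_points$performance,
                     quadrant = ipma$latent_points$quadrant),
          data.frame(item = ipma$indicator_points$indicator,
                     level = "indicator",
                     importance = ipma$indicator_points$importance,
                     performance = ipma$indicator_points$performance,
                     quadrant = ipma$indicator_points$quadrant))
        utils::write.csv(pts, f[3], row.names = FALSE)
      } else f <- f[-3]
      jsonlite::write_json(manifest, f[length(f)], auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      f
    })
  }

  invisible(list(fit = fit, evaluation = evaluation, bootstrap = boot,
                 pruned_indicators = pruned, refit = refit, ipma = ipma,
                 manifest = manifest, files = written))
}

# drop indicators from a model; a block that would become empty is an error
prune_spec <- function(spec, drop) {
  latents <- lapply(spec$latents, function(l) {
    keep <- setdiff(l$indicators, drop)
    if (!length(keep))
      stop_spec("pruning would empty block '%s'; relax the rule or keep at least one indicator",
                l$name)
    list(name = l$name, mode = l$mode, indicators = keep)
  })
  bounds <- spec$scale_bounds
  if (!is.null(bounds)) bounds <- bounds[setdiff(names(bounds), drop)]
  if (!is.null(bounds) && !length(bounds)) bounds <- NULL
  model_spec(latents = latents,
             paths = spec$paths,
             ipma_target = spec$ipma_target,
             scale_bounds = bounds)
}

# canonical hash of the model document (md5 of its JSON serialization)
model_hash <- function(spec) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_model_spec(spec, tmp)
  unname(tools::md5sum(tmp))
}

# machine-readable export of an evaluation report
evaluation_export <- function(ev) {
  list(loadings = ev$loadings,
       ave = ev$ave,
       composite_reliability = ev$composite_reliability,
       cross_loadings = as.data.frame(ev$cross_loadings),
       discriminant = as.list(ev$discriminant),
       fornell_larcker = if (!is.null(ev$fornell_larcker))
         as.data.frame(ev$fornell_larcker$matrix) else NULL,
       fornell_larcker_pass = if (!is.null(ev$fornell_larcker))
         as.list(ev$fornell_larcker$pass) else NULL,
       r_squared = ev$r_squared,
       gof = ev$gof,
       q_squared = ev$q_squared,
       mean_ave = ev$mean_ave,
       mean_r_squared = ev$mean_r2)
}
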