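# Interchange formats: per-cell tables, tag libraries and pairwise
# matrices travel as headered CSV; fitted models and search results as
# JSON; pipeline configuration as YAML.

#' Read a per-cell intensity table
#'
#' Reads the standard cell-table CSV (columns `cell_id`, optional
#' `population`, optional `x_um`/`y_um`, `ch_C`, `ch_G`, `ch_R`,
#' optional `ch_ref`). Arbitrary headers are supported through
#' `channel_map`, which renames source columns onto the standard
#' schema. Rows with non-numeric or non-finite intensities are rejected
#' with their line numbers.
#'
#' @param path CSV file path.
#' @param channel_map optional named character vector mapping standard
#'   names to source column names, e.g. `c(ch_C = "CFP2_mean")`.
#' @return A validated data.frame.
#' @export
read_cell_table <- function(path, channel_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty cell table: ", path)
  if (!is.null(channel_map))
    for (std in names(channel_map)) {
      src <- channel_map[[std]]
      if (!src %in% names(tab))
        stop("mapped column missing from ", path, ": ", src)
      names(tab)[names(tab) == src] <- std
    }
  required <- c("cell_id", CHANNELS)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("required column(s) missing: ", paste(missing, collapse = ", "))
  num_cols <- intersect(c(CHANNELS, "ch_ref", "x_um", "y_um"), names(tab))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric/non-finite %s at data row(s) %s", col,
                   paste(head(bad, 5L), collapse = ", ")))
    tab[[col]] <- v
  }
  tab
}

#' Write a per-cell intensity table
#'
#' @param table data.frame to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Tag library CSV export / import
#'
#' @param library a [tag_library()].
#' @param path CSV path with columns `tag_id`, `c_C`, `c_G`, `c_R`.
#' @return `write_tag_library` returns `path` invisibly;
#'   `read_tag_library` returns a data.frame of tags (ids re-validated
#'   against the copy numbers).
#' @export
write_tag_library <- function(library, path) {
  write.csv(as.data.frame(library)[, c("tag_id", "c_C", "c_G", "c_R")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_library
#' @export
read_tag_library <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tag_id", "c_C", "c_G", "c_R") %in% names(tab)))
  expect_id <- tag_id(tab$c_C, tab$c_G, tab$c_R)
  if (!all(tab$tag_id == expect_id))
    stop("tag_id column inconsistent with copy numbers")
  if (anyDuplicated(tab$tag_id)) stop("duplicate tag ids")
  tab
}

#' Serialize a fitted classifier to JSON
#'
#' Writes the complete model state (labels, means, covariances in
#' row-major order, weights, feature names, regularization) so a fit
#' can be archived alongside its predictions and reloaded elsewhere.
#'
#' @param model a fitted [fpmix()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fpmix <- function(model, path) {
  stopifnot(inherits(model, "fpmix"))
  obj <- list(
    format = "fpmix-1",
    labels = model$labels,
    feature_names = model$feature_names,
    means = unname(split(model$means, row(model$means))),
    covariances = lapply(model$covariances,
                         function(S) as.numeric(t(S))),  # row-major
    weights = as.numeric(model$weights),
    n_per_class = as.integer(model$n_per_class),
    regularization = model$regularization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fpmix
#' @export
read_fpmix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fpmix-1")) stop("unrecognized model file")
  d <- length(obj$feature_names)
  K <- length(obj$labels)
  means <- if (is.matrix(obj$means)) obj$means
           else do.call(rbind, as.list(obj$means))
  dimnames(means) <- list(obj$labels, obj$feature_names)
  covs <- lapply(seq_len(K), function(k)
    matrix(as.numeric(obj$covariances[[k]]), d, d, byrow = TRUE,
           dimnames = list(obj$feature_names, obj$feature_names)))
  names(covs) <- obj$labels
  structure(list(labels = obj$labels, means = means, covariances = covs,
                 weights = setNames(as.numeric(obj$weights), obj$labels),
                 feature_names = obj$feature_names,
                 n_per_class = setNames(as.integer(obj$n_per_class),
                                        obj$labels),
                 regularization = obj$regularization,
                 formula = NULL, call = NULL),
            class = "fpmix")
}

#' Pairwise matrix CSV export / import
#'
#' @param matrix a [pairwise_matrix()].
#' @param path square headered CSV path (first column = population id).
#' @return `write_pairwise_matrix` returns `path` invisibly;
#'   `read_pairwise_matrix` returns the matrix.
#' @export
write_pairwise_matrix <- function(matrix, path) {
  df <- data.frame(population = rownames(matrix), as.data.frame(matrix),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairwise_matrix
#' @export
read_pairwise_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df[[1L]]
  if (!identical(rownames(M), colnames(M))) stop("matrix is not square")
  structure(M, class = c("pairwise_matrix", "matrix"))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the identification pipeline into one
#' serializable object; [write_pipeline_config()] /
#' [read_pipeline_config()] round-trip it through YAML exactly.
#'
#' @param channel_map named character vector renaming source columns to
#'   the standard schema (identity by default).
#' @param background_medians optional named numeric vector for
#'   [subtract_background()]; `NULL` skips the correction.
#' @param normalize apply [normalize_global_median()]?
#' @param train_fraction,split_seed stratified split parameters.
#' @param regularization covariance ridge for [fpmix()].
#' @param reliability_threshold posterior cutoff defining
#'   high-confidence calls.
#' @param n_draws,k,search_seed max–min search parameters.
#' @param n_shuffles,area_mode spatial-statistics parameters.
#' @param output_dir where pipeline runs write their reports.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(channel_map = NULL, background_medians = NULL,
                            normalize = TRUE, train_fraction = 0.8,
                            split_seed = 1L, regularization = 1e-6,
                            reliability_threshold = 0.95,
                            n_draws = 1e7, k = 20L, search_seed = 1L,
                            n_shuffles = 100L, area_mode = "given",
                            output_dir = ".") {
  structure(list(channel_map = channel_map,
                 background_medians = background_medians,
                 normalize = normalize, train_fraction = train_fraction,
                 split_seed = as.integer(split_seed),
                 regularization = regularization,
                 reliability_threshold = reliability_threshold,
                 n_draws = n_draws, k = as.integer(k),
                 search_seed = as.integer(search_seed),
                 n_shuffles = as.integer(n_shuffles),
                 area_mode = area_mode, output_dir = output_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  for (nm in c("channel_map", "background_medians"))  # keep names in YAML
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.list(obj[[nm]])
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  for (nm in c("channel_map", "background_medians"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- unlist(obj[[nm]])
  do.call(pipeline_config, obj[!vapply(obj, is.null, logical(1))])
}

#' Run the end-to-end identification workflow
#'
#' Executes the full per-cell pipeline: optional background
#' subtraction, global-median normalization, spherical-angle
#' featurization, classifier fitting on the labeled training table, and
#' posterior membership on the target table. Reports per-cell
#' predictions with membership probabilities, the confusion matrix and
#' accuracies when the target carries true labels, and the fraction of
#' cells called above the reliability threshold.
#'
#' @param train labeled cell table (column `population`).
#' @param target cell table to classify (labels optional).
#' @param config a [pipeline_config()].
#' @return A list: `model` (the [fpmix()] fit), `predictions`
#'   (data.frame with `cell_id`, `predicted`, `max_posterior`),
#'   `high_reliability_fraction`, and — when the target is labeled —
#'   `accuracy`, `macro_accuracy`, `confusion`.
#' @export
run_identification <- function(train, target, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"),
            "population" %in% names(train))
  prep <- function(tab) {
    if (!is.null(config$background_medians))
      tab <- subtract_background(tab, config$background_medians)
    if (isTRUE(config$normalize)) tab <- normalize_global_median(tab)
    tab <- spherical_features(tab)
    tab[tab$valid, , drop = FALSE]
  }
  train_f <- prep(train)
  target_f <- prep(target)
  model <- fpmix(population ~ angle_cvsg_deg + angle_rvscg_deg, train_f,
                 regularization = config$regularization)
  pred <- predict(model, target_f)
  out <- list(
    model = model,
    predictions = data.frame(cell_id = target_f$cell_id,
                             predicted = as.character(pred$class),
                             max_posterior = pred$max_posterior,
                             stringsAsFactors = FALSE),
    high_reliability_fraction =
      mean(pred$max_posterior >= config$reliability_threshold, na.rm = TRUE))
  if ("population" %in% names(target_f)) {
    ca <- confusion_accuracy(target_f$population, pred$class,
                             labels = model$labels)
    out$accuracy <- ca$accuracy
    out$macro_accuracy <- ca$macro_accuracy
    out$confusion <- ca$confusion
  }
  out
}
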