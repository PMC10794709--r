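#' Read and write pipeline artifacts
#'
#' All artifacts serialize to standard formats: event and behavioral tables
#' to tab-separated files, predictor sets to tab-separated matrices with a
#' JSON sidecar, BOLD runs to 4-D NIfTI with a JSON sidecar (TR, grid,
#' seed, events path), configurations to JSON. Write-then-read returns an
#' equal object.
#'
#' @param events event table (see [simulate_bold_run()]).
#' @param path file path.
#' @name calcrsa-io
NULL

#' @rdname calcrsa-io
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname calcrsa-io
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "condition", "is_catch", "probe_onset", "probe_ratio",
            "correct_side")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols)) {
    stop("malformed event table ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.unsorted(ev$onset, strictly = TRUE)) {
    stop("malformed event table ", path, ": onsets not strictly increasing")
  }
  ev$is_catch <- as.logical(ev$is_catch)
  ev
}

#' @rdname calcrsa-io
#' @param behavior a `behavioral_data` frame (see [simulate_observer()]).
#' @export
write_behavior_tsv <- function(behavior, path) {
  utils::write.table(behavior, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname calcrsa-io
#' @export
read_behavior_tsv <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("operation", "operand", "ratio", "response", "correct")
  if (length(setdiff(need, names(b)))) {
    stop("malformed behavioral table ", path, ": missing column(s) ",
         paste(setdiff(need, names(b)), collapse = ", "))
  }
  b$correct <- as.logical(b$correct)
  class(b) <- c("behavioral_data", "data.frame")
  b
}

#' @rdname calcrsa-io
#' @param predictors a [build_predictor_rdms()] result.
#' @param dir directory to hold one TSV per matrix plus a JSON sidecar.
#' @export
write_predictor_set <- function(predictors, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(predictors$matrices)) {
    utils::write.table(predictors$matrices[[nm]],
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_events_tsv(predictors$conditions, file.path(dir, "conditions.tsv"))
  jsonlite::write_json(list(labels = names(predictors$matrices),
                            log_base = predictors$log_base),
                       file.path(dir, "predictor_set.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname calcrsa-io
#' @export
read_predictor_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "predictor_set.json"),
                              simplifyVector = TRUE)
  mats <- lapply(meta$labels, function(nm)
    as.matrix(utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
                                header = FALSE)))
  names(mats) <- meta$labels
  conditions <- utils::read.delim(file.path(dir, "conditions.tsv"),
                                  stringsAsFactors = FALSE)
  mats <- lapply(mats, function(m) {
    dimnames(m) <- list(conditions$condition, conditions$condition)
    m
  })
  structure(list(matrices = mats, log_base = meta$log_base,
                 conditions = conditions),
            class = "predictor_set")
}

#' @rdname calcrsa-io
#' @param run a `bold_run` (see [simulate_bold_run()]).
#' @param prefix path prefix; writes `<prefix>.nii`, `<prefix>.json` and
#'   `<prefix>_events.tsv`.
#' @export
write_bold_run <- function(run, prefix) {
  arr <- array(t(run$data), c(run$grid_shape, nrow(run$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr)
  RNifti::writeNifti(img, paste0(prefix, ".nii"))
  jsonlite::write_json(list(tr = run$tr, grid_shape = run$grid_shape,
                            seed = run$seed),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_events_tsv(run$events, paste0(prefix, "_events.tsv"))
  invisible(prefix)
}

#' @rdname calcrsa-io
#' @export
read_bold_run <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  arr <- as.array(img)
  nvol <- dim(arr)[4]
  data <- t(matrix(arr, ncol = nvol))
  structure(list(data = data, tr = meta$tr,
                 grid_shape = as.integer(meta$grid_shape),
                 events = read_events_tsv(paste0(prefix, "_events.tsv")),
                 seed = meta$seed),
            class = "bold_run")
}

#' @rdname calcrsa-io
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  raw$amplitudes <- as.list(raw$amplitudes) # keep names in JSON
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calcrsa-io
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}
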