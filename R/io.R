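#' Read and write configurations
#'
#' Configurations round-trip through YAML or JSON files whose keys match
#' the [pgg_config()] field names exactly (format chosen by extension;
#' `.yml`/`.yaml` or `.json`).
#'
#' @param path file path.
#' @return `read_config()` returns a validated `pgg_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- switch(tolower(tools::file_ext(path)),
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", path))
  build_config(as.list(raw))
}

#' @rdname read_config
#' @param config a `pgg_config` to serialize.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pgg_config"))
  x <- unclass(config)
  switch(tolower(tools::file_ext(path)),
    yml = , yaml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config format: ", path))
  invisible(path)
}

#' Trajectory CSV round-trip
#'
#' `write_trajectories()` serializes every realization of an ensemble to a
#' single CSV, one row per generation per realization, with floats at full
#' precision (17 significant digits) so a re-read reproduces the in-run
#' numbers bit for bit.  `read_trajectories()` rebuilds a `pgg_ensemble`
#' from such a file (realizations are recognised by the `realization`
#' column; a realization is extinct when its last recorded `N` is 0), so
#' stored runs can be re-summarized with [equilibrium_summary()].
#'
#' @param ensemble a [run_ensemble()] result.
#' @param path CSV file path.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` a `pgg_ensemble`.
#' @export
write_trajectories <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pgg_ensemble"))
  pieces <- lapply(seq_along(ensemble$trajectories), function(i) {
    tr <- ensemble$trajectories[[i]]
    cbind(realization = i, seed = attr(tr, "seed"), as.data.frame(tr))
  })
  df <- do.call(rbind, pieces)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.17g", v)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param config the `pgg_config` the run used (stored alongside, e.g. via
#'   [write_config()] or a manifest).
#' @export
read_trajectories <- function(path, config) {
  stopifnot(inherits(config, "pgg_config"))
  df <- utils::read.csv(path)
  ids <- sort(unique(df$realization))
  trajectories <- lapply(ids, function(i) {
    tr <- df[df$realization == i, REC_FIELDS]
    tr[] <- lapply(tr, as.numeric)   # whole-valued columns parse as integer
    rownames(tr) <- NULL
    last <- tr[nrow(tr), ]
    attr(tr, "seed") <- as.integer(df$seed[df$realization == i][1L])
    attr(tr, "config") <- config
    attr(tr, "extinction_generation") <-
      if (last$N == 0) as.integer(last$t) else NA_integer_
    class(tr) <- c("pgg_trajectory", "data.frame")
    tr
  })
  ext <- vapply(trajectories, function(tr)
    as.integer(attr(tr, "extinction_generation")), integer(1))
  structure(
    list(trajectories = trajectories,
         mean = ensemble_mean(trajectories, config$T),
         extinction_generation = ext,
         survived = is.na(ext),
         config = config,
         n_realizations = length(trajectories),
         master_seed = NA_integer_),
    class = "pgg_ensemble")
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte for byte: the fully
#' resolved configuration, the master seed, the package version, a
#' timestamp and the output paths.
#'
#' @param config a `pgg_config`.
#' @param master_seed integer master seed of the run.
#' @param outputs named character vector/list of output paths.
#' @param path manifest destination (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, master_seed, outputs, path) {
  stopifnot(inherits(config, "pgg_config"))
  manifest <- list(
    package = "pggevol",
    version = as.character(utils::packageVersion("pggevol")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = as.integer(master_seed),
    config = unclass(config),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write sweep results as tidy CSV and JSON
#'
#' One CSV row per grid cell with the equilibrium statistics, plus a JSON
#' copy carrying the axes and run metadata.
#'
#' @param sweep a [pgg_sweep()] result.
#' @param csv_path,json_path destinations (either may be `NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_sweep <- function(sweep, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(sweep, "pgg_sweep"))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(sweep), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(axes = attr(sweep, "axes"),
           n_realizations = attr(sweep, "n_realizations"),
           master_seed = attr(sweep, "master_seed"),
           window_fraction = attr(sweep, "window_fraction"),
           cells = as.data.frame(sweep)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(csv = csv_path, json = json_path))
}
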