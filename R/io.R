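#' Read and write kinetic curves as CSV
#'
#' Curves travel as two-column RFC-4180 CSV files with a header row
#' \code{t,signal}; a dataset is a directory of such files plus a
#' \code{manifest.yaml} mapping each file to its initial precursor
#' concentration \code{w0} (the format the fitting protocol reads).
#'
#' @param path CSV file path.
#' @param ts a \code{\link{time_series}} or
#'   \code{\link{experimental_curve}}.
#' @return \code{read_curve_csv}: a data frame \code{(t, signal)}.
#' @export
write_curve_csv <- function(ts, path) {
  utils::write.csv(data.frame(t = ts$times, signal = ts$values), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t", "signal") %in% names(df)))
    stop("curve CSV must have columns t, signal")
  df
}

#' @rdname write_curve_csv
#' @param ds a \code{"tht_dataset"} (or a plain list of
#'   \code{experimental_curve}).
#' @param dir dataset directory.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  curves <- if (inherits(ds, "tht_dataset")) ds$curves else ds
  entries <- lapply(seq_along(curves), function(k) {
    f <- sprintf("curve_%02d.csv", k)
    write_curve_csv(curves[[k]], file.path(dir, f))
    list(file = f, w0 = curves[[k]]$w0)
  })
  meta <- list(curves = entries)
  if (inherits(ds, "tht_dataset")) {
    meta$noise_sd <- ds$noise_sd
    meta$seed <- ds$seed
  }
  yaml::write_yaml(meta, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_curve_csv
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml in ", dir)
  meta <- yaml::read_yaml(mf)
  lapply(meta$curves, function(e) {
    df <- read_curve_csv(file.path(dir, e$file))
    experimental_curve(df$t, df$signal, e$w0)
  })
}

#' Read a model configuration file
#'
#' YAML configuration for the shipped model families. The top-level
#' \code{model} field selects the family (\code{polyq},
#' \code{knowles} or \code{xue}); the remaining fields are the
#' corresponding parameter-constructor arguments. Presets are shipped
#' under \code{system.file("extdata", ..., package = "amykin")}.
#'
#' @param path YAML file path.
#' @return A \code{polyq_params}, \code{knowles_params} or
#'   \code{xue_params} object (with any extra fields attached as
#'   attribute \code{"extra"}).
#' @examples
#' p <- read_model_config(system.file("extdata", "polyq.yaml",
#'                                    package = "amykin"))
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cf <- yaml::read_yaml(path)
  if (is.null(cf$model)) stop("config must have a 'model' field")
  ctor <- switch(cf$model,
                 polyq = polyq_params, knowles = knowles_params,
                 xue = xue_params,
                 stop("unknown model family: ", cf$model))
  args <- cf[setdiff(names(cf), c("model", "extra"))]
  known <- intersect(names(args), names(formals(ctor)))
  obj <- do.call(ctor, args[known])
  extra <- args[setdiff(names(args), known)]
  if (length(extra)) attr(obj, "extra") <- extra
  obj
}
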