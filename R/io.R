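#' Read a survival table from delimited text
#'
#' Reads a comma-separated file with a header; columns `time` (days) and
#' `event` (0/1) are mandatory, every other column is treated as a numeric
#' covariate. Missing covariate cells are imputed by the column median, with
#' a message reporting the count per column.
#'
#' @param path Path to a CSV file.
#' @return Data frame with `time`, `event` and covariate columns.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  for (col in c("time", "event")) {
    if (!col %in% names(d))
      stop("input file ", path, " lacks mandatory column '", col, "'")
  }
  if (anyNA(d$time) || anyNA(d$event))
    stop("'time'/'event' columns must not contain missing values")
  if (!all(d$event %in% c(0, 1)))
    stop("'event' column must be binary 0/1; found value(s): ",
         paste(utils::head(setdiff(unique(d$event), c(0, 1))), collapse = ", "))
  cov_cols <- setdiff(names(d), c("time", "event"))
  for (col in cov_cols) {
    if (!is.numeric(d[[col]]))
      stop("covariate column '", col, "' is not numeric")
    n_miss <- sum(is.na(d[[col]]))
    if (n_miss > 0) {
      d[[col]][is.na(d[[col]])] <- stats::median(d[[col]], na.rm = TRUE)
      message("imputed ", n_miss, " missing value(s) in column '", col,
              "' by the column median")
    }
  }
  d
}

#' Write a survival table as delimited text
#'
#' @param data Data frame with `time`, `event` and covariate columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-individual survival curves
#'
#' One row per individual, one column per interval end; the header carries
#' the boundary times in days.
#'
#' @param curves A [survival_curve()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_curves <- function(curves, path) {
  stopifnot(inherits(curves, "surv_curve"))
  S <- as.data.frame(curves$S)
  names(S) <- as.character(curves$grid$boundaries)
  utils::write.csv(S, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-individual survival curves
#'
#' Inverse of [write_survival_curves()].
#'
#' @param path CSV path written by [write_survival_curves()].
#' @return A `surv_curve` object.
#' @export
read_survival_curves <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  grid <- time_grid(as.numeric(names(d)))
  structure(list(grid = grid, S = as.matrix(d)), class = "surv_curve")
}

#' Save a fitted model as a portable text checkpoint
#'
#' Serialises the parameters, grid boundaries, architecture and training
#' configuration of a `dtsurv` fit to a single JSON file, at full numeric
#' precision, so that predictions are exactly reproducible elsewhere.
#'
#' @param model A `dtsurv` fit.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dtsurv"))
  pack <- function(p) list(dim = dim(p) %||% length(p), data = as.vector(p))
  obj <- list(format = "dtsurv-checkpoint-1",
              head = model$head,
              hidden = as.integer(model$hidden),
              grid = model$grid$boundaries,
              features = model$features %||% character(0),
              config = model$config,
              final_loss = model$final_loss,
              params = lapply(model$params, pack))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [write_checkpoint()].
#' @return A `dtsurv` fit usable with [predict.dtsurv()].
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dtsurv-checkpoint-1"))
    stop("not a dtsurv checkpoint: ", path)
  unpack <- function(p) {
    v <- as.numeric(unlist(p$data))
    if (length(p$dim) == 2L) matrix(v, p$dim[1], p$dim[2]) else v
  }
  structure(list(params = lapply(obj$params, unpack),
                 head = obj$head,
                 hidden = as.integer(obj$hidden),
                 grid = time_grid(obj$grid),
                 features = as.character(obj$features),
                 config = obj$config,
                 loss_history = NULL,
                 final_loss = obj$final_loss),
            class = "dtsurv")
}
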