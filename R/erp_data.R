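#' Two-condition evoked-response dataset for one subject
#'
#' Source-by-time evoked responses for the `novel` and `repeated` conditions
#' on a common peristimulus sampling grid.
#'
#' @param novel,repeated matrices `[n_sources x n_times]` with source
#'   rownames.
#' @param times output sampling times (ms peristimulus).
#' @param subject optional subject identifier.
#' @param sampling_rate_hz sampling rate of `times` (informational).
#' @return object of class `erp_dataset`.
#' @export
erp_dataset <- function(novel, repeated, times, subject = NA_character_,
                        sampling_rate_hz = NA_real_) {
  stopifnot(is.matrix(novel), is.matrix(repeated),
            identical(dim(novel), dim(repeated)),
            ncol(novel) == length(times))
  if (is.null(rownames(novel))) stop("novel needs source rownames")
  structure(list(novel = novel, repeated = repeated, times = times,
                 subject = subject, sampling_rate_hz = sampling_rate_hz),
            class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  cat(sprintf("erp_dataset: %d sources x %d samples (%.0f-%.0f ms), subject %s\n",
              nrow(x$novel), length(x$times), min(x$times), max(x$times),
              x$subject))
  invisible(x)
}

#' Write an ERP matrix as tab-delimited text
#'
#' First column is time (ms), one column per source, header row of source
#' names; a JSON sidecar (`<path>.json`) records the grid metadata.
#'
#' @param erp matrix `[n_sources x n_times]` with source rownames.
#' @param times sampling times (ms).
#' @param path output TSV path.
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_erp_matrix <- function(erp, times, path, meta = list()) {
  df <- data.frame(time_ms = times, t(erp), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(list(sources = rownames(erp), n_times = length(times),
                 t_start = min(times), t_end = max(times),
                 sampling_rate_hz = if (length(times) > 1)
                   1000 / diff(times[1:2]) else NA_real_),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ERP matrix written by [write_erp_matrix()]
#' @param path TSV path.
#' @return list with `erp` (matrix `[n_sources x n_times]`), `times`, `meta`.
#' @export
read_erp_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  times <- df[[1]]
  erp <- t(as.matrix(df[, -1, drop = FALSE]))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::fromJSON(side) else NULL
  list(erp = erp, times = times, meta = meta)
}

#' Write a two-condition dataset to a subject directory
#' @param data an [erp_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_erp_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in c("novel", "repeated"))
    write_erp_matrix(data[[cond]], data$times,
                     file.path(dir, paste0(cond, ".tsv")),
                     meta = list(condition = cond, subject = data$subject))
  invisible(dir)
}

#' Read a two-condition dataset from a subject directory
#' @param dir directory holding `novel.tsv` and `repeated.tsv`.
#' @param subject optional subject id (defaults to the directory name).
#' @return an [erp_dataset()].
#' @export
read_erp_dataset <- function(dir, subject = basename(dir)) {
  nv <- read_erp_matrix(file.path(dir, "novel.tsv"))
  rp <- read_erp_matrix(file.path(dir, "repeated.tsv"))
  sr <- if (!is.null(nv$meta)) nv$meta$sampling_rate_hz else NA_real_
  erp_dataset(nv$erp, rp$erp, nv$times, subject = subject,
              sampling_rate_hz = sr)
}
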