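#' Read and write the pipeline's plain-text tables
#'
#' Pedigrees, traces and switch calls travel as TSV; flow plates as CSV.
#' Traces are stored long (one row per cell and frame) and re-nested on
#' read.
#'
#' @param x Table to write.
#' @param path File path.
#' @name switchscope_io
NULL

#' @rdname switchscope_io
#' @export
write_pedigree_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname switchscope_io
#' @export
read_pedigree_tsv <- function(path) {
  as_tibble(utils::read.delim(path, colClasses = c(cell_id = "character")))
}

#' @rdname switchscope_io
#' @export
write_traces_tsv <- function(x, path) {
  long <- tidyr::unnest(x[, c("trap_id", "cell_id", "frames", "values")],
                        cols = c("frames", "values"))
  names(long)[names(long) == "frames"] <- "frame"
  names(long)[names(long) == "values"] <- "value"
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname switchscope_io
#' @export
read_traces_tsv <- function(path) {
  long <- as_tibble(utils::read.delim(path, colClasses = c(cell_id = "character")))
  out <- long |>
    dplyr::summarise(birth_frame = min(.data$frame),
                     end_frame = max(.data$frame),
                     frames = list(.data$frame), values = list(.data$value),
                     .by = c("trap_id", "cell_id"))
  out
}

#' @rdname switchscope_io
#' @export
write_calls_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname switchscope_io
#' @export
write_flow_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname switchscope_io
#' @export
read_flow_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  need <- c("fsc", "ssc", "gfp", "mcherry", "v670")
  missing <- setdiff(need, names(out))
  if (length(missing))
    abort(paste0("flow CSV lacks channel column(s): ",
                 paste(missing, collapse = ", ")),
          class = "switchscope_data_error")
  class(out) <- c("flow_plate", class(out))
  out
}
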