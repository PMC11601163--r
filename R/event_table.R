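#' Single-cell event table
#'
#' The universal carrier through the pipeline: a cells x channels matrix of
#' marker intensities plus a per-cell sample label and a transform-state flag.
#' Raw ion counts are non-negative; asinh-transformed (and corrected) values
#' may be any real number.
#'
#' @param values numeric matrix, cells in rows, channels in columns.
#' @param channel_names character vector of unique channel names; defaults to
#'   the column names of `values`.
#' @param sample_labels per-cell sample label (cell line, condition, batch);
#'   recycled if length 1.
#' @param transform_state one of `"raw"`, `"asinh"`, `"asinh_zscored"`.
#' @return An object of class `event_table`: a list with elements `values`,
#'   `channel_names`, `sample_labels`, `transform_state`.
#' @examples
#' m <- matrix(rpois(20, 50), 5, 4,
#'             dimnames = list(NULL, c("Ir191", "Ir193", "panAkt", "cCasp3")))
#' tab <- event_table(m, sample_labels = "Cal33")
#' dim(tab)
#' @export
event_table <- function(values, channel_names = colnames(values),
                        sample_labels, transform_state = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channel_names))
    stop("channel names are required (set colnames or pass channel_names)")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(values))
    stop("length(channel_names) != number of channel columns")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (length(sample_labels) == 1L)
    sample_labels <- rep(sample_labels, nrow(values))
  if (length(sample_labels) != nrow(values))
    stop("one sample label per cell is required")
  transform_state <- match.arg(transform_state,
                               c("raw", "asinh", "asinh_zscored"))
  if (transform_state == "raw" && any(values < 0))
    stop("raw intensities must be non-negative")
  colnames(values) <- channel_names
  structure(list(values = values,
                 channel_names = channel_names,
                 sample_labels = as.character(sample_labels),
                 transform_state = transform_state),
            class = "event_table")
}

#' @export
dim.event_table <- function(x) dim(x$values)

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d cells x %d channels [%s]\n",
              nrow(x$values), ncol(x$values), x$transform_state))
  cat("channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "...\n" else "\n")
  cat("samples: ", paste(utils::head(unique(x$sample_labels), 8),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Subset an event table by cells
#'
#' @param table an [event_table].
#' @param mask logical or integer index over cells (rows).
#' @return An `event_table` restricted to the selected cells.
#' @export
subset_cells <- function(table, mask) {
  stopifnot(inherits(table, "event_table"))
  event_table(table$values[mask, , drop = FALSE],
              channel_names = table$channel_names,
              sample_labels = table$sample_labels[mask],
              transform_state = table$transform_state)
}

stop_config <- function(...) {
  stop(structure(class = c("cycovar_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("cycovar_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("cycovar_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
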