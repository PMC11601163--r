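# Minimal FCS 3.1 list-mode reader/writer.
#
# Scope: the primary TEXT + DATA segments only; $DATATYPE F (float32) and
# D (float64); little- or big-endian on read, always D little-endian on
# write. No analysis segment, no supplemental text, no multi-dataset files.
# Corrected (residual) values may be negative, so data are written as
# floating point without clipping.

FCS_DELIM <- "/"

fcs_keyword_text <- function(kw) {
  # delimiter-separated key/value stream, leading and trailing delimiter
  paste0(FCS_DELIM,
         paste(rbind(names(kw), unlist(kw)), collapse = FCS_DELIM),
         FCS_DELIM)
}

#' Write a matrix as a minimal FCS 3.1 file
#'
#' @param values numeric matrix (events x parameters) with column names.
#' @param path output path.
#' @param extra_keywords named character vector of additional TEXT keywords.
#' @return Invisibly, the path.
#' @keywords internal
write_fcs <- function(values, path, extra_keywords = character()) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop_data("FCS write requires column names")
  n_par <- ncol(values)
  n_tot <- nrow(values)

  kw <- c(list("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
               "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
               # fixed-width placeholders so the TEXT length is stable
               "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
               "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "D", "$MODE" = "L",
               "$NEXTDATA" = "0",
               "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)))
  for (p in seq_len(n_par)) {
    rng <- max(values[, p], 1)
    kw[[sprintf("$P%dN", p)]] <- colnames(values)[p]
    kw[[sprintf("$P%dS", p)]] <- colnames(values)[p]
    kw[[sprintf("$P%dB", p)]] <- "64"
    kw[[sprintf("$P%dE", p)]] <- "0,0"
    kw[[sprintf("$P%dR", p)]] <- format(ceiling(rng), scientific = FALSE)
  }
  for (k in names(extra_keywords)) kw[[k]] <- extra_keywords[[k]]

  text_start <- 58L
  # two passes: placeholder widths (8 digits) fix the TEXT length
  probe <- fcs_keyword_text(kw)
  text_len <- nchar(probe, type = "bytes") + 2L * (8L - 4L)  # %BD% -> 8 digits
  data_start <- text_start + text_len
  data_len <- 8L * n_par * n_tot
  data_end <- data_start + data_len - 1L
  kw[["$BEGINDATA"]] <- formatC(data_start, width = 8, flag = "0")
  kw[["$ENDDATA"]] <- formatC(data_end, width = 8, flag = "0")
  text <- fcs_keyword_text(kw)
  stopifnot(nchar(text, type = "bytes") == text_len)
  text_end <- text_start + text_len - 1L

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end,
                    if (data_end <= 99999999) data_start else 0L,
                    if (data_end <= 99999999) data_end else 0L,
                    0L, 0L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.double(t(values)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a minimal FCS 3.0/3.1 file
#'
#' @param path input path.
#' @return A list with `values` (events x parameters matrix; columns named
#'   from $PnS when present, else $PnN) and `keywords` (named list).
#' @keywords internal
read_fcs <- function(path) {
  if (!file.exists(path)) stop_data("FCS file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_data("unsupported FCS version: ", version)
  off <- suppressWarnings(as.integer(substring(header,
    c(11, 19, 27, 35), c(18, 26, 34, 42))))
  if (anyNA(off[1:2])) stop_data("malformed FCS header offsets")
  text_start <- off[1]; text_end <- off[2]

  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(as.list(vals), toupper(trimws(keys)))

  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  if (!dtype %in% c("F", "D"))
    stop_data("unsupported $DATATYPE '", dtype, "' (only F and D)")
  if (toupper(kw[["$MODE"]]) != "L") stop_data("only list-mode FCS supported")
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  size <- if (dtype == "D") 8L else 4L

  data_start <- off[3]
  if (is.na(data_start) || data_start == 0L)
    data_start <- as.integer(kw[["$BEGINDATA"]])
  seek(con, data_start)
  raw_vals <- readBin(con, "double", n = n_par * n_tot, size = size,
                      endian = endian)
  if (length(raw_vals) < n_par * n_tot)
    stop_data("truncated FCS data segment")
  values <- matrix(raw_vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  nm <- vapply(seq_len(n_par), function(p) {
    s <- kw[[sprintf("$P%dS", p)]]
    if (!is.null(s) && nzchar(s)) s else kw[[sprintf("$P%dN", p)]]
  }, character(1))
  colnames(values) <- nm
  list(values = values, keywords = kw)
}
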