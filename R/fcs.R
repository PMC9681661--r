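# Minimal FCS 3.1 I/O: list-mode float32 data, one data segment, no analysis
# segment. Sufficient for round-tripping the synthetic studies; $PnS is
# honored (preferred over $PnN) on read.

FCS_DELIM <- "/"

fcs_pad <- function(n) formatC(n, width = 8, flag = " ")

#' Write events to an FCS 3.1 file
#'
#' Marker intensities are stored as little-endian float32 list-mode data
#' ($DATATYPE F, $MODE L). Only the intensity channels are written;
#' provenance stays in the sample metadata table.
#'
#' @param events an event table or a numeric matrix (events x channels).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  mat <- if (is.matrix(events)) events else marker_matrix(events)
  stopifnot(is.numeric(mat), ncol(mat) >= 1)
  p <- ncol(mat); n <- nrow(mat)
  rng <- ceiling(max(mat, 1))
  kw <- c("$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
  for (j in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", j), colnames(mat)[j],
            sprintf("$P%dS", j), colnames(mat)[j],
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), as.character(rng))
  }
  # $BEGINDATA/$ENDDATA use fixed-width fields so the TEXT length is stable
  # while the offsets are being computed
  kw <- c(kw, "$BEGINDATA", fcs_pad(0), "$ENDDATA", fcs_pad(0))
  build_text <- function(kw) paste0(FCS_DELIM, paste(kw, collapse = FCS_DELIM), FCS_DELIM)
  txt <- build_text(kw)
  text_start <- 58L
  text_end <- text_start + nchar(txt, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  kw[which(kw == "$BEGINDATA") + 1L] <- fcs_pad(data_start)
  kw[which(kw == "$ENDDATA") + 1L] <- fcs_pad(data_end)
  txt <- build_text(kw)
  header <- paste0("FCS3.1    ",
                   fcs_pad(text_start), fcs_pad(text_end),
                   if (data_end <= 99999999) paste0(fcs_pad(data_start), fcs_pad(data_end))
                   else paste0(fcs_pad(0), fcs_pad(0)),
                   fcs_pad(0), fcs_pad(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a minimal FCS 3.x file
#'
#' Parses the HEADER offsets and TEXT keywords and returns the float/int
#' data as an events x channels matrix. Channel names use $PnS when present,
#' falling back to $PnN.
#'
#' @param path FCS file path.
#' @return numeric matrix with channel column names.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  hdr <- rawToChar(raw[1:58])
  if (!startsWith(hdr, "FCS3"))
    stop("not an FCS 3.x file: ", path)
  off <- function(i) as.integer(trimws(substr(hdr, 11 + 8 * (i - 1), 10 + 8 * i)))
  text_start <- off(1); text_end <- off(2)
  txt <- rawToChar(raw[(text_start + 1):(text_end + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substr(txt, 2, nchar(txt)), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, toupper(keys))
  data_start <- off(3); data_end <- off(4)
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  if (toupper(kw[["$DATATYPE"]]) != "F")
    stop("only $DATATYPE F is supported")
  con <- rawConnection(raw[(data_start + 1):(data_end + 1)])
  on.exit(close(con))
  little <- startsWith(kw[["$BYTEORD"]], "1")
  vals <- readBin(con, "numeric", n = n * p, size = 4,
                  endian = if (little) "little" else "big")
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  nm <- vapply(seq_len(p), function(j) {
    s <- kw[[sprintf("$P%dS", j)]]
    if (!is.null(s) && nzchar(trimws(s))) s else kw[[sprintf("$P%dN", j)]]
  }, character(1))
  colnames(mat) <- nm
  mat
}
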