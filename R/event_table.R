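#' Construct an event table
#'
#' An event table is a plain data.frame holding one row per measured cell
#' (event): the marker intensity columns plus per-event provenance
#' (sample id, mouse, embryonic day, organ, batch, treatment). The set of
#' marker columns and the transform state (raw counts vs. arcsinh) are
#' carried as attributes so that downstream stages can refuse, e.g., a
#' double transform.
#'
#' @param df data.frame with provenance and marker columns.
#' @param markers character vector naming the marker (channel) columns.
#' @param transformed logical; `TRUE` once intensities are on the arcsinh
#'   scale.
#' @param cofactor arcsinh cofactor associated with the transform state.
#' @return `df` with class `event_table` and the state attributes set.
#' @export
event_table <- function(df, markers, transformed = FALSE, cofactor = 5) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(markers, names(df))
  if (length(missing) > 0)
    stop("marker columns absent from data: ", paste(missing, collapse = ", "))
  structure(df,
            class = unique(c("event_table", class(df))),
            markers = markers,
            transformed = isTRUE(transformed),
            cofactor = cofactor)
}

#' @rdname event_table
#' @param x an event table.
#' @export
marker_names <- function(x) attr(x, "markers", exact = TRUE)

#' @rdname event_table
#' @export
is_transformed <- function(x) isTRUE(attr(x, "transformed", exact = TRUE))

#' @rdname event_table
#' @export
marker_matrix <- function(x) as.matrix(as.data.frame(x)[, marker_names(x), drop = FALSE])

# rebuild attrs after a base-R manipulation that may have dropped them
restore_event_table <- function(df, template, markers = marker_names(template)) {
  event_table(df, markers,
              transformed = is_transformed(template),
              cofactor = attr(template, "cofactor", exact = TRUE))
}

provenance_names <- function(x) setdiff(names(x), marker_names(x))

#' Write / read the delimited event dialect
#'
#' Events are stored as gzip-compressed tab-separated text, one row per
#' event, header = provenance plus channel names. Ground-truth labels, when
#' present, go to a sidecar table keyed by row order.
#'
#' @param events an event table.
#' @param path output path (".tsv.gz" recommended).
#' @param labels optional per-event label data.frame written to
#'   `paste0(path, ".labels")`.
#' @return `path`, invisibly.
#' @export
write_events_delim <- function(events, path, labels = NULL) {
  df <- as.data.frame(events)
  data.table::fwrite(df, path, sep = "\t", compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  if (!is.null(labels))
    data.table::fwrite(as.data.frame(labels), paste0(path, ".labels"), sep = "\t")
  invisible(path)
}

#' @rdname write_events_delim
#' @export
read_events_delim <- function(path) {
  if (grepl("\\.gz$", path)) {
    # base connections decompress transparently
    utils::read.delim(path, check.names = FALSE)
  } else {
    as.data.frame(data.table::fread(path, sep = "\t"))
  }
}
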