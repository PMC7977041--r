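#' Read a fossil occurrence table
#'
#' Reads a delimited file with columns `collection_id`, `genus`, `paleolat`,
#' `paleolon`, `stage` (the minimal 5-column format; database exports are
#' converted by selecting/renaming those columns). Every stage name must
#' resolve against the timescale; duplicated (collection_id, genus) rows are
#' collapsed to one record and the row counts before/after deduplication are
#' reported via `message()`.
#'
#' @param path delimited text file (comma or tab, auto-detected).
#' @param ts a [read_timescale()] table used to resolve stage names.
#' @return `data.table` of class `occurrences` with columns `collection_id`,
#'   `genus`, `paleolat`, `paleolon`, `stage`, `stage_index`.
#' @export
read_occurrences <- function(path, ts) {
  sep <- detect_sep(path)
  dt <- data.table::fread(path, sep = sep, showProgress = FALSE)
  for (col in intersect(c("collection_id", "genus", "stage"), names(dt)))
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  as_occurrences(dt, ts)
}

#' Validate an in-memory occurrence table
#' @param dt data.frame with columns `collection_id`, `genus`, `paleolat`,
#'   `paleolon`, `stage`.
#' @param ts timescale for stage resolution.
#' @return validated `occurrences` table (deduplicated, with `stage_index`).
#' @export
as_occurrences <- function(dt, ts) {
  stopifnot(inherits(ts, "timescale"))
  dt <- data.table::as.data.table(dt)
  require_columns(dt, c("collection_id", "genus", "paleolat", "paleolon", "stage"),
                  "occurrence table")
  if (nrow(dt) > 0L) {
    bad_lat <- which(!is.finite(dt$paleolat) | dt$paleolat < -90 | dt$paleolat > 90)
    if (length(bad_lat) > 0L)
      stop(sprintf("occurrence table: paleolat out of [-90, 90] at row(s) %s",
                   paste(head(bad_lat, 5L), collapse = ", ")))
    bad_lon <- which(!is.finite(dt$paleolon) | dt$paleolon < -180 | dt$paleolon >= 180)
    if (length(bad_lon) > 0L)
      stop(sprintf("occurrence table: paleolon out of [-180, 180) at row(s) %s",
                   paste(head(bad_lon, 5L), collapse = ", ")))
    unknown <- setdiff(unique(dt$stage), ts$stage)
    if (length(unknown) > 0L)
      stop("occurrence table: unresolvable stage name(s): ",
           paste(unknown, collapse = ", "))
  }
  n_before <- nrow(dt)
  dt <- unique(dt, by = c("collection_id", "genus"))
  if (nrow(dt) < n_before)
    message(sprintf("read_occurrences: %d rows, %d after (collection_id, genus) deduplication",
                    n_before, nrow(dt)))
  dt[, stage_index := ts$stage_index[match(stage, ts$stage)]]
  data.table::setattr(dt, "class", c("occurrences", class(data.table::data.table())))
  dt[]
}
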