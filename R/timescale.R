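#' Read a geological timescale table
#'
#' Reads a delimited text file with columns `stage`, `period`, `era`,
#' `age_base` and `age_top` (ages in Ma, base older than top) and returns a
#' validated timescale ordered from oldest to youngest. Stages are assigned a
#' 0-based `stage_index` (oldest = 0), which is the layer index used
#' throughout the multilayer network. Consecutive stages must abut: the top
#' age of one stage equals the base age of the next within 1e-6 Ma.
#'
#' @param path path to a comma- or tab-delimited file (auto-detected).
#' @return a `data.table` of class `timescale` with columns `stage`,
#'   `period`, `era`, `age_base`, `age_top`, `stage_index`.
#' @export
read_timescale <- function(path) {
  sep <- detect_sep(path)
  dt <- data.table::fread(path, sep = sep, showProgress = FALSE)
  for (col in intersect(c("stage", "period", "era"), names(dt)))
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  as_timescale(dt)
}

#' Validate an in-memory timescale table
#'
#' @param dt data.frame with columns `stage`, `period`, `era`, `age_base`,
#'   `age_top`.
#' @return validated `timescale` ordered oldest-first with `stage_index`.
#' @export
as_timescale <- function(dt) {
  dt <- data.table::as.data.table(dt)
  require_columns(dt, c("stage", "period", "era", "age_base", "age_top"),
                  "timescale table")
  if (!is.numeric(dt$age_base) || !is.numeric(dt$age_top))
    stop("timescale table: age_base and age_top must be numeric")
  if (anyDuplicated(dt$stage))
    stop("timescale table: duplicated stage name(s): ",
         paste(unique(dt$stage[duplicated(dt$stage)]), collapse = ", "))
  if (any(!nzchar(dt$period)) || any(!nzchar(dt$era)))
    stop("timescale table: every stage needs non-empty period and era labels")
  bad <- dt$age_top >= dt$age_base
  if (any(bad))
    stop("timescale table: age_top must be younger (smaller) than age_base for stage(s): ",
         paste(dt$stage[bad], collapse = ", "))
  data.table::setorder(dt, -age_base)
  if (nrow(dt) > 1L) {
    gap <- abs(dt$age_top[-nrow(dt)] - dt$age_base[-1L])
    if (any(gap > 1e-6)) {
      i <- which(gap > 1e-6)[1L]
      stop(sprintf("timescale table: stages '%s' and '%s' do not abut (%.6g vs %.6g Ma)",
                   dt$stage[i], dt$stage[i + 1L], dt$age_top[i], dt$age_base[i + 1L]))
    }
  }
  dt[, stage_index := 0:(.N - 1L)]
  data.table::setcolorder(dt, c("stage", "period", "era", "age_base",
                                "age_top", "stage_index"))
  data.table::setattr(dt, "class", c("timescale", class(data.table::data.table())))
  dt[]
}

#' Build a layer merge map from a timescale
#'
#' Produces the stage_index -> layer_id mapping that pools the named stages
#' into the layer of the oldest of them (for example, combining the two
#' terminal Cambrian stages into a single layer, as done for the Phanerozoic
#' benthic record to bridge the sparsely sampled uppermost Cambrian).
#'
#' @param ts timescale.
#' @param merge_stages character vector of stage names to pool; must be
#'   consecutive in the timescale.
#' @return integer vector: `layer_id` for each `stage_index` (0-based, named
#'   by stage).
#' @export
merge_map_for_stages <- function(ts, merge_stages) {
  stopifnot(inherits(ts, "timescale"))
  idx <- ts$stage_index[match(merge_stages, ts$stage)]
  if (anyNA(idx))
    stop("unknown stage name(s): ",
         paste(merge_stages[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  if (length(idx) > 1L && any(diff(idx) != 1L))
    stop("merged stages must be consecutive in the timescale")
  map <- ts$stage_index
  map[map %in% idx] <- idx[1L]
  # re-compact to 0..t-1
  map <- match(map, sort(unique(map))) - 1L
  stats::setNames(as.integer(map), ts$stage)
}
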