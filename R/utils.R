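#' @useDynLib fossilflows, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats dpois median rbinom rpois runif setNames
#' @importFrom utils head
NULL

# evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# detect comma vs tab delimiter from the header line of a text table
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("file is empty: ", path)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

require_columns <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing) > 0L)
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
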