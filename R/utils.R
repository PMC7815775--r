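#' @keywords internal
"_PACKAGE"

## Internal argument checkers shared across modules.

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  stop_if(length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) ||
            x < min, "'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_proportion <- function(x, name) {
  stop_if(length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1,
          "'%s' must be a single value in [0, 1]", name)
  as.numeric(x)
}

check_positive <- function(x, name) {
  stop_if(any(!is.finite(x)) || any(x <= 0), "'%s' must be positive", name)
  as.numeric(x)
}

check_seed <- function(seed) {
  stop_if(length(seed) != 1L || !is.numeric(seed) || is.na(seed) ||
            seed != floor(seed), "'seed' must be a single integer")
  as.integer(seed)
}

## Seed the RNG locally so a generator never disturbs the caller's RNG state.
with_seed <- function(seed, expr) {
  seed <- check_seed(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Write a data frame as tab-separated values
#'
#' All pipeline tables are exchanged as UTF-8 TSV with a header row and '.'
#' as the decimal mark.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8",
                    comment.char = "")
}
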