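# Internal helpers shared across modules.

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All seeded operations in the package route through this so that a call is
#' deterministic given its `seed` argument without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a child seed from a master seed and a stage offset, kept < 2^31
#' @noRd
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000 + offset) %% .Machine$integer.max)
}

# Minimal leveled logger writing to stderr (and optionally a file connection).
.log_env <- new.env(parent = emptyenv())
.log_env$level <- "info"
.log_env$file <- NULL
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set logging verbosity
#'
#' @param level One of "debug", "info", "warn", "error".
#' @param file Optional path of a log file to append to (NULL disables).
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error"), file = NULL) {
  level <- match.arg(level)
  prev <- .log_env$level
  .log_env$level <- level
  .log_env$file <- file
  invisible(prev)
}

#' @noRd
log_msg <- function(level, ...) {
  if (.log_levels[[level]] < .log_levels[[.log_env$level]]) return(invisible(NULL))
  line <- sprintf("[%s] %s", toupper(level), paste0(..., collapse = ""))
  message(line)
  if (!is.null(.log_env$file)) {
    cat(line, "\n", file = .log_env$file, append = TRUE, sep = "")
  }
  invisible(NULL)
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Rank-normalize a numeric vector to [0, 1]
#'
#' Average ranks mapped affinely so the smallest value is 0 and the largest 1;
#' a length-1 (or constant) vector maps to 1. Invariant under strictly
#' monotone transforms of the input.
#' @noRd
rank_normalize <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  r <- rank(x, ties.method = "average")
  if (n == 1L || max(r) == min(r)) return(rep(1, n))
  (r - 1) / (n - 1)
}
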