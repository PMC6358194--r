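# Internal helpers shared across modules.

# Two-sided 95% Wald critical value used throughout (matches standard
# statistics-package output).
Z95 <- 1.959964

#' Derive named independent sub-seeds from a master seed
#'
#' One master seed spawns a named set of sub-seeds so that adding a pipeline
#' stage never perturbs the random draws of earlier stages.  Sub-seeds are
#' drawn uniformly below 2^31 - 1 from a generator seeded with the master
#' seed, so the mapping master -> sub-seeds is deterministic.
#'
#' @param master integer master seed.
#' @param names character vector of stream names.
#' @return named integer vector of sub-seeds.
#' @keywords internal
derive_seeds <- function(master, names) {
  stopifnot(length(master) == 1L, is.finite(master))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  names(s) <- names
  s
}

# Run an expression under a given seed without disturbing the caller's RNG
# state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a classed condition so callers (and the CLI) can map error
# kinds to exit codes.
wgrs_error <- function(msg, class) {
  stop(structure(class = c(class, "wgrs_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

format_error <- function(msg) wgrs_error(msg, "wgrs_format_error")
numeric_error <- function(msg) wgrs_error(msg, "wgrs_numeric_error")
config_error <- function(msg) wgrs_error(msg, "wgrs_config_error")

# Check a vector is binary 0/1/NA.
is_binary01 <- function(x) all(x %in% c(0, 1) | is.na(x))
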