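# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb the
#' caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive reproducible sub-seeds from one master seed
#'
#' A single pipeline seed is expanded into independent per-stage seeds by a
#' fixed derivation (draws from the master-seeded stream), so stages can be
#' rerun in isolation with the seeds recorded in a manifest.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seeds(42, 3)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(n), n >= 1)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, as.integer(n)))
}

# consistent stop()s with a class so tests can assert on error types
sgs_stop <- function(msg, class) {
  stop(structure(class = c(class, "sparsegs_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# zero-padded ids: id_label("L", 3, 120) -> "L003"
id_label <- function(prefix, i, n) {
  sprintf("%s%0*d", prefix, max(2L, nchar(as.character(n))), i)
}

check_symmetric <- function(M, tol = 1e-8, name = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    sgs_stop(sprintf("%s must be a square matrix", name), "sgs_input_error")
  asym <- max(abs(M - t(M)))
  if (asym > tol)
    sgs_stop(sprintf("%s is not symmetric (max asymmetry %.3g)", name, asym),
             "sgs_input_error")
  invisible(TRUE)
}
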