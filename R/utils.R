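# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's random number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child-seed derivation so that sub-generators (counts,
# cytokines, strains, ...) can be re-run independently from one master seed.
# Keeps results below 2^31 - 1 so they remain valid R integers.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  streams <- c(
    cohort = 101L, categories = 211L, counts = 307L, depth = 401L,
    cytokines = 503L, strains = 601L, covariates = 701L, missing = 809L,
    receptivity = 907L
  )
  if (is.character(stream)) {
    if (!stream %in% names(streams)) stop("unknown stream: ", stream)
    stream <- streams[[stream]]
  }
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483629) + 1L
}

# Round-half-even percentage formatting (matches printed integer rates).
round_percent <- function(x, digits = 0L) round(100 * x, digits)

# Column-wise standardization returning the centers/scales used.
standardize_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0 | !is.finite(sdv))) {
    stop("constant column(s): ", paste(colnames(x)[sdv == 0 | !is.finite(sdv)], collapse = ", "))
  }
  list(x = sweep(sweep(x, 2, mu, "-"), 2, sdv, "/"), center = mu, scale = sdv)
}

# %||% : default for NULL
`%||%` <- function(a, b) if (is.null(a)) b else a
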