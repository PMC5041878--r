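#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package internals never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stop with a message assembled via sprintf.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# A binary 3D array coerced to logical, with shape validation.
as_mask <- function(x, name = "mask") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stopf("%s must be a 3-D array", name)
  }
  if (is.logical(x)) x else array(x > 0, dim = dim(x))
}

#' Shift a 3-D logical array by one voxel along an axis
#'
#' Vacated positions are filled with `FALSE`. Used by the morphology
#' routines (hole filling, frontier propagation).
#'
#' @keywords internal
shift_mask <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- lapply(d, seq_len)
  dst <- lapply(d, seq_len)
  if (by > 0) {
    dst[[axis]] <- (by + 1L):n
    src[[axis]] <- 1L:(n - by)
  } else {
    dst[[axis]] <- 1L:(n + by)
    src[[axis]] <- (1L - by):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}
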