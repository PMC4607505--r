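# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a reproducible child seed from a root seed and a counter
#'
#' Affine hash onto 32-bit integer range. Used to give every repeat of an
#' ensemble (and every ensemble of a sweep) its own RNG substream so results
#' do not depend on execution order.
#'
#' @param seed root integer seed
#' @param i nonnegative counter
#' @return an integer seed suitable for [set.seed()]
#' @export
derive_seed <- function(seed, i) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 69069 + as.double(i) * 104729 + 1) %% 2147483629)
}

# run expr under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stopf("a point must have 3 coordinates")
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stopf("points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  points
}
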