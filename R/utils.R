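# internal helpers shared across modules

# stop with a field-naming message if a scalar constraint is violated
.check_positive <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop(sprintf("'%s' must be a single positive finite number (got %s)",
                 name, paste(format(value), collapse = ", ")), call. = FALSE)
  invisible(value)
}

.check_nonnegative <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0)
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  invisible(value)
}

.check_count <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < 1 || value != round(value))
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  invisible(as.integer(value))
}

# coerce a point argument to an n x 3 numeric matrix
.as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L)
      stop("a point must have 3 coordinates (x, y, z)", call. = FALSE)
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("'points' must be an n x 3 matrix of (x, y, z) coordinates",
         call. = FALSE)
  storage.mode(points) <- "double"
  points
}

# short deterministic hash of an R object (used to stamp outputs)
.config_hash <- function(x) substr(rlang::hash(x), 1L, 12L)

# run an expression with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
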