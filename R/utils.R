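# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions stay deterministic without clobbering the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Column-wise Khatri-Rao product: column r is kronecker(A[, r], B[, r]).
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- kronecker(A[, r], B[, r])
  out
}

# Mode-n unfolding of a 3-way array; columns ordered with the earlier of the
# remaining modes varying fastest (matches the Khatri-Rao ordering above).
unfold3 <- function(x, mode) {
  d <- dim(x)
  stopifnot(length(d) == 3L, mode %in% 1:3)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  y <- aperm(x, perm)
  dim(y) <- c(d[mode], prod(d[-mode]))
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
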