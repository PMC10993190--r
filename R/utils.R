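# Shared small helpers.

#' Unitary centered n-dimensional FFT
#'
#' Forward transform with DC at the array centre (index \code{n %/% 2},
#' 0-based) and unitary normalization, so that \code{ufft_adj} (equal to the
#' inverse) is also the adjoint: \code{||ufft(x)|| == ||x||}.
#'
#' @param x complex array
#' @return complex array of the same shape
#' @export
ufft <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  x <- ifftshift(x)
  y <- stats::fft(x)
  fftshift(y) / sqrt(prod(d))
}

#' @rdname ufft
#' @export
ufft_adj <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  x <- ifftshift(x)
  y <- stats::fft(x, inverse = TRUE)
  fftshift(y) / sqrt(prod(d))
}

# Circular shifts that move the DC bin (0-based index n %/% 2) to/from the
# first array position, per dimension. The combined linear-index
# permutation is cached per array shape.
.shift_cache <- new.env(parent = emptyenv())

shift_perm <- function(d, inverse) {
  key <- paste(c(if (inverse) "i" else "f", d), collapse = "x")
  p <- .shift_cache[[key]]
  if (!is.null(p)) return(p)
  axis_idx <- lapply(d, function(n) {
    if (inverse) c(seq_len(n %/% 2) + (n - n %/% 2), seq_len(n - n %/% 2))
    else c(seq_len(n - n %/% 2) + n %/% 2, seq_len(n %/% 2))
  })
  grid <- do.call(expand.grid, axis_idx)
  mult <- cumprod(c(1, d[-length(d)]))
  p <- as.vector(1 + as.matrix(grid - 1) %*% mult)
  .shift_cache[[key]] <- p
  p
}

fftshift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  array(x[shift_perm(d, FALSE)], dim = d)
}

ifftshift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  array(x[shift_perm(d, TRUE)], dim = d)
}

# Index one axis of an array keeping the others intact.
slice_index <- function(x, axis, idx) {
  d <- dim(x)
  if (is.null(d)) return(x[idx])
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

# Complex array <-> stacked real representation [dims..., 2].
c2r <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  array(c(Re(x), Im(x)), dim = c(d, 2))
}

r2c <- function(x) {
  d <- dim(x)
  nd <- length(d)
  stopifnot(d[nd] == 2)
  re <- slice_index(x, nd, 1L)
  im <- slice_index(x, nd, 2L)
  out <- complex(real = as.vector(re), imaginary = as.vector(im))
  array(out, dim = d[-nd])
}

# Real inner product Re<x, y> for complex arrays.
re_inner <- function(x, y) sum(Re(Conj(x) * y))

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
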