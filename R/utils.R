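#' @useDynLib petrad, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom quantile sd median var pt qlogis plogis
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed if given, restoring the caller's RNG state afterwards so
#' that seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed or `NULL` (use the current stream).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one parent seed, kept < 2^31.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

stopifnot_binary <- function(y) {
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  invisible(as.integer(y))
}

# Separable convolution of a 3D array with a 1D kernel along each axis,
# replicate-padded at the borders (rows of the band matrix renormalized).
convolve_axes <- function(vol, kernel) {
  d <- dim(vol)
  half <- (length(kernel) - 1L) / 2L
  band <- function(n) {
    K <- matrix(0, n, n)
    for (r in seq_len(n)) {
      idx <- r + seq(-half, half)
      w <- kernel
      keep <- idx >= 1L & idx <= n
      K[r, idx[keep]] <- w[keep] / sum(w[keep])
    }
    K
  }
  # axis 1
  vol <- array(band(d[1]) %*% matrix(vol, d[1]), d)
  # axis 2: permute so the target axis is first
  vol <- aperm(vol, c(2, 1, 3))
  vol <- array(band(d[2]) %*% matrix(vol, d[2]), d[c(2, 1, 3)])
  vol <- aperm(vol, c(2, 1, 3))
  # axis 3
  vol <- aperm(vol, c(3, 1, 2))
  vol <- array(band(d[3]) %*% matrix(vol, d[3]), d[c(3, 1, 2)])
  aperm(vol, c(2, 3, 1))
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filter with replicate edge handling; used for the
#' phantom texture fields and as the pre-meshing anti-aliasing filter.
#'
#' @param vol 3D numeric array.
#' @param sigma kernel standard deviation in voxels.
#' @return smoothed array of the same dimensions.
#' @export
smooth3d <- function(vol, sigma) {
  stopifnot(length(dim(vol)) == 3L, sigma > 0)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * (seq(-half, half) / sigma)^2)
  convolve_axes(vol, k / sum(k))
}

mean_filter3d <- function(vol, width = 3L) {
  convolve_axes(vol, rep(1 / width, width))
}

iso_log <- function(fmt, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", sprintf(fmt, ...))
}
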