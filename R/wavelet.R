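#' Orthonormal Haar analysis filter pair
#'
#' Returns the two-tap Haar scaling (low-pass) and wavelet (high-pass)
#' filters in the orthonormal convention: every tap has magnitude
#' \eqn{1/\sqrt{2}}, so each filter has unit energy and the pair is
#' orthogonal.  Under this convention the 2-D transform conserves energy
#' (Parseval) and its inverse is the transpose, which is what makes the
#' round-trip and energy tests in this package exact to floating-point
#' precision.
#'
#' @return An object of class `filter_pair`: a list with components `kl`
#'   (low-pass taps) and `kh` (high-pass taps), each a numeric vector of
#'   length 2.
#' @examples
#' fp <- haar_filter_pair()
#' sum(fp$kl^2)          # 1
#' sum(fp$kl * fp$kh)    # 0
#' @export
haar_filter_pair <- function() {
  s <- 1 / sqrt(2)
  structure(list(kl = c(s, s), kh = c(s, -s)), class = "filter_pair")
}

validate_filter_pair <- function(filters) {
  if (!is.list(filters) || is.null(filters$kl) || is.null(filters$kh))
    stop("`filters` must be a filter_pair with components `kl` and `kh`", call. = FALSE)
  if (length(filters$kl) != length(filters$kh))
    stop("low-pass and high-pass filters must have equal length", call. = FALSE)
  if (length(filters$kl) != 2L)
    stop("only two-tap filter pairs are supported (Haar family)", call. = FALSE)
  if (abs(sum(filters$kl^2) - 1) > 1e-12 || abs(sum(filters$kh^2) - 1) > 1e-12)
    stop("filters must be orthonormal: each tap vector needs unit energy", call. = FALSE)
  if (abs(sum(filters$kl * filters$kh)) > 1e-12)
    stop("filters must be mutually orthogonal", call. = FALSE)
  invisible(filters)
}

#' Single-level 2-D discrete wavelet transform
#'
#' Applies one level of the separable 2-D DWT to a plane (or to each
#' channel of an `H x W x C` array): the analysis filters are applied along
#' both axes in every low/high combination, each followed by dyadic
#' downsampling that keeps even positions (0-based, i.e. positions
#' 1, 3, 5, ... in R's 1-based indexing).  For the two-tap Haar pair this
#' tiles the plane into non-overlapping 2x2 blocks, so no boundary
#' extension is ever needed; both dimensions must therefore be even.
#'
#' Sub-band naming follows the (vertical, horizontal) order: the first
#' letter is the filter applied along rows of pixels (axis 1), the second
#' the filter along columns (axis 2).  So `lh` is low-pass vertically and
#' high-pass horizontally (horizontal detail), `hl` the converse, `hh` the
#' diagonal detail.
#'
#' @param plane Numeric matrix with even dimensions, or an `H x W x C`
#'   array (each channel transformed independently).
#' @param filters A `filter_pair`, by default [haar_filter_pair()].
#' @return An object of class `subband_set`: a list with `level` (always
#'   `1L` here), and the four half-sized planes `ll`, `lh`, `hl`, `hh`.
#' @examples
#' s <- dwt_level(matrix(1, 2, 2))
#' s$ll   # 2: the DC gain of the orthonormal low-pass is sqrt(2) per axis
#' @export
dwt_level <- function(plane, filters = haar_filter_pair()) {
  validate_filter_pair(filters)
  if (is.matrix(plane)) {
    s <- dwt_level_plane(plane, filters)
  } else if (is.array(plane) && length(dim(plane)) == 3L) {
    per <- lapply(seq_len(dim(plane)[3]), function(c3)
      dwt_level_plane(plane[, , c3], filters))
    s <- list(
      ll = stack_planes(lapply(per, `[[`, "ll")),
      lh = stack_planes(lapply(per, `[[`, "lh")),
      hl = stack_planes(lapply(per, `[[`, "hl")),
      hh = stack_planes(lapply(per, `[[`, "hh")))
  } else {
    stop("`plane` must be a numeric matrix or an H x W x C array", call. = FALSE)
  }
  structure(c(list(level = 1L), s), class = "subband_set")
}

stack_planes <- function(planes) {
  array(unlist(planes, use.names = FALSE),
        dim = c(dim(planes[[1]]), length(planes)))
}

dwt_level_plane <- function(x, filters) {
  h <- nrow(x); w <- ncol(x)
  if (h %% 2L != 0L)
    stop(sprintf("plane height (%d, axis 1) must be even for a dyadic transform", h), call. = FALSE)
  if (w %% 2L != 0L)
    stop(sprintf("plane width (%d, axis 2) must be even for a dyadic transform", w), call. = FALSE)
  kl <- filters$kl; kh <- filters$kh
  oi <- seq.int(1L, h, 2L); ei <- oi + 1L   # vertical pair members
  a <- x[oi, , drop = FALSE]; b <- x[ei, , drop = FALSE]
  vl <- kl[1L] * a + kl[2L] * b
  vh <- kh[1L] * a + kh[2L] * b
  oj <- seq.int(1L, w, 2L); ej <- oj + 1L   # horizontal pair members
  list(
    ll = kl[1L] * vl[, oj, drop = FALSE] + kl[2L] * vl[, ej, drop = FALSE],
    lh = kh[1L] * vl[, oj, drop = FALSE] + kh[2L] * vl[, ej, drop = FALSE],
    hl = kl[1L] * vh[, oj, drop = FALSE] + kl[2L] * vh[, ej, drop = FALSE],
    hh = kh[1L] * vh[, oj, drop = FALSE] + kh[2L] * vh[, ej, drop = FALSE])
}

idwt_level_plane <- function(ll, lh, hl, hh, filters) {
  kl <- filters$kl; kh <- filters$kh
  h2 <- nrow(ll); w2 <- ncol(ll)
  # invert horizontal stage (orthonormal 2x2 synthesis = analysis transpose)
  vl <- matrix(0, h2, 2L * w2); vh <- vl
  oj <- seq.int(1L, 2L * w2, 2L); ej <- oj + 1L
  vl[, oj] <- kl[1L] * ll + kh[1L] * lh
  vl[, ej] <- kl[2L] * ll + kh[2L] * lh
  vh[, oj] <- kl[1L] * hl + kh[1L] * hh
  vh[, ej] <- kl[2L] * hl + kh[2L] * hh
  # invert vertical stage
  x <- matrix(0, 2L * h2, 2L * w2)
  oi <- seq.int(1L, 2L * h2, 2L); ei <- oi + 1L
  x[oi, ] <- kl[1L] * vl + kh[1L] * vh
  x[ei, ] <- kl[2L] * vl + kh[2L] * vh
  x
}

#' Iterated multiresolution decomposition
#'
#' Applies [dwt_level()] `T` times, always recursing on the low-pass (`ll`)
#' approximation, yielding the hierarchy of sub-band planes at dyadic
#' scales.  Both input dimensions must be divisible by `2^T`.
#'
#' @param plane Numeric matrix or `H x W x C` array.
#' @param T Non-negative integer decomposition depth.  `T = 0` returns a
#'   stack holding only the original plane.
#' @param filters A `filter_pair`.
#' @return An object of class `mra_stack`: a list with `original` (the
#'   level-0 plane) and `levels`, an ordered list of `subband_set`s for
#'   levels `1..T`.
#' @seealso [wavelet_reconstruct()] for the exact inverse.
#' @export
wavelet_decompose <- function(plane, T, filters = haar_filter_pair()) {
  stopifnot(length(T) == 1L, T >= 0, T == round(T))
  d <- if (is.matrix(plane)) dim(plane) else dim(plane)[1:2]
  max_T <- min(max_dyadic_depth(d[1]), max_dyadic_depth(d[2]))
  if (T > max_T)
    stop(sprintf(
      "dimensions %d x %d are not divisible by 2^%d; maximum feasible depth is T = %d",
      d[1], d[2], T, max_T), call. = FALSE)
  levels <- vector("list", T)
  cur <- plane
  for (t in seq_len(T)) {
    s <- dwt_level(cur, filters)
    s$level <- t
    levels[[t]] <- s
    cur <- s$ll
  }
  structure(list(original = plane, levels = levels, filters = filters),
            class = "mra_stack")
}

max_dyadic_depth <- function(n) {
  t <- 0L
  while (n %% 2L == 0L && n > 0L) { n <- n %/% 2L; t <- t + 1L }
  t
}

#' Invert a multiresolution decomposition
#'
#' Reconstructs the original plane from an `mra_stack` by inverting every
#' level from the deepest up.  With the orthonormal Haar pair the
#' round-trip `wavelet_reconstruct(wavelet_decompose(x, T))` is exact to
#' floating-point precision.
#'
#' @param stack An `mra_stack` produced by [wavelet_decompose()].
#' @return A numeric matrix (or array) with the shape of `stack$original`.
#' @export
wavelet_reconstruct <- function(stack) {
  if (!inherits(stack, "mra_stack"))
    stop("`stack` must be an mra_stack from wavelet_decompose()", call. = FALSE)
  filters <- stack$filters %||% haar_filter_pair()
  T <- length(stack$levels)
  if (T == 0L) return(stack$original)
  for (t in seq_len(T)) {
    s <- stack$levels[[t]]
    for (p in c("lh", "hl", "hh")) {
      if (!identical(dim2(s[[p]]), dim2(s$ll)))
        stop(sprintf("level %d: sub-band `%s` shape disagrees with `ll`", t, p), call. = FALSE)
    }
    if (t < T && !identical(dim2(stack$levels[[t + 1L]]$ll) * 2L, dim2(s$ll)))
      stop(sprintf("level %d planes are not half the size of level %d", t + 1L, t), call. = FALSE)
  }
  recon_set <- function(s, ll) {
    if (is.matrix(ll)) {
      idwt_level_plane(ll, s$lh, s$hl, s$hh, filters)
    } else {
      per <- lapply(seq_len(dim(ll)[3]), function(c3)
        idwt_level_plane(ll[, , c3], s$lh[, , c3], s$hl[, , c3], s$hh[, , c3], filters))
      stack_planes(per)
    }
  }
  cur <- stack$levels[[T]]$ll
  for (t in rev(seq_len(T))) cur <- recon_set(stack$levels[[t]], cur)
  cur
}

dim2 <- function(x) if (is.matrix(x)) dim(x) else dim(x)[1:2]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mra_stack <- function(x, ...) {
  d <- dim2(x$original)
  cat(sprintf("Haar multiresolution stack: %d x %d original, %d level(s)\n",
              d[1], d[2], length(x$levels)))
  for (s in x$levels) {
    ds <- dim2(s$ll)
    cat(sprintf("  level %d: four %d x %d sub-bands (ll, lh, hl, hh)\n",
                s$level, ds[1], ds[2]))
  }
  invisible(x)
}

#' Dump a multiresolution stack to PNG planes (debug aid)
#'
#' Writes each sub-band plane, linearly rescaled to `[0, 1]`, to
#' `<dir>/level<t>_<band>.png` for visual inspection.
#'
#' @param stack An `mra_stack`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
dump_stack_png <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (s in stack$levels) {
    for (band in c("ll", "lh", "hl", "hh")) {
      p <- s[[band]]
      if (!is.matrix(p)) p <- p[, , 1]
      rng <- range(p)
      p <- if (diff(rng) > 0) (p - rng[1]) / diff(rng) else p * 0
      f <- file.path(dir, sprintf("level%d_%s.png", s$level, band))
      png::writePNG(p, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
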