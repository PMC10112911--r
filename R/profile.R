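#' Sample an intensity profile along a transect line
#'
#' Bilinear interpolation of a 2-D intensity grid at `n_samples` evenly
#' spaced points from `p0` to `p1` (grid coordinates: x = column, y = row,
#' both 1-based).
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param p0,p1 numeric `(x, y)` endpoints, inside the grid.
#' @param n_samples number of sample points along the line.
#' @return list of class `profile`: `positions` (distance along the line,
#'   pixels) and `intensities`.
#' @export
extract_profile <- function(image, p0, p1, n_samples = 100L) {
  stopifnot(is.matrix(image), n_samples >= 2L)
  nx <- ncol(image); ny <- nrow(image)
  for (p in list(p0, p1)) {
    if (p[1L] < 1 || p[1L] > nx || p[2L] < 1 || p[2L] > ny)
      stop("line endpoint (", p[1L], ", ", p[2L], ") outside the ",
           nx, " x ", ny, " grid")
  }
  t <- seq(0, 1, length.out = n_samples)
  xs <- p0[1L] + t * (p1[1L] - p0[1L])
  ys <- p0[2L] + t * (p1[2L] - p0[2L])
  x0 <- pmin(floor(xs), nx - 1L); y0 <- pmin(floor(ys), ny - 1L)
  dx <- xs - x0; dy <- ys - y0
  v <- image[cbind(y0, x0)] * (1 - dx) * (1 - dy) +
    image[cbind(y0, x0 + 1L)] * dx * (1 - dy) +
    image[cbind(y0 + 1L, x0)] * (1 - dx) * dy +
    image[cbind(y0 + 1L, x0 + 1L)] * dx * dy
  structure(list(positions = t * sqrt(sum((p1 - p0)^2)), intensities = v),
            class = "profile")
}

# Topographic prominence of local maximum `i`: height above the higher of
# the lowest points separating it from higher ground on each side (profile
# end counts as a separating valley).
peak_prominence <- function(y, i) {
  left_min <- y[i]
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (y[j] > y[i]) break
    left_min <- min(left_min, y[j])
  }
  if (j == 1L && y[j] <= y[i]) left_min <- min(left_min, y[j])
  right_min <- y[i]
  j <- i
  n <- length(y)
  while (j < n) {
    j <- j + 1L
    if (y[j] > y[i]) break
    right_min <- min(right_min, y[j])
  }
  if (j == n && y[j] <= y[i]) right_min <- min(right_min, y[j])
  y[i] - max(left_min, right_min)
}

#' Count peaks in an intensity profile
#'
#' Local maxima whose topographic prominence reaches `min_prominence` times
#' the profile's dynamic range (max - min) and which are at least
#' `min_separation` positions apart; of two closer peaks the higher is kept.
#' Prominence is relative, so counting is invariant to affine intensity
#' rescaling.  Plateau maxima count once (at the plateau centre).
#'
#' @param profile a `profile` (or list with `intensities`, and optionally
#'   `positions`) or a bare numeric vector.
#' @param min_prominence fraction of the dynamic range, default 0.1.
#' @param min_separation minimum peak distance in position units, default 3.
#' @return integer peak count.
#' @export
count_peaks <- function(profile, min_prominence = 0.1, min_separation = 3) {
  y <- if (is.numeric(profile)) profile
    else profile$intensities %||% profile$intensity
  pos <- if (is.numeric(profile)) seq_along(y)
    else profile$positions %||% seq_along(y)
  stopifnot(length(y) >= 1L, all(is.finite(y)))
  rng <- max(y) - min(y)
  if (rng == 0) return(0L)
  # candidate maxima with plateau handling
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cand <- integer(0)
  for (j in seq_len(k)) {
    # interior runs strictly above both neighbours; endpoints never peak
    if (j > 1L && j < k &&
        r$values[j - 1L] < r$values[j] && r$values[j + 1L] < r$values[j])
      cand <- c(cand, (starts[j] + ends[j]) %/% 2L)
  }
  if (length(cand) == 0L) return(0L)
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence * rng
  cand <- cand[keep]
  if (length(cand) <= 1L) return(length(cand))
  # greedy suppression: highest first, drop peaks within min_separation
  ord <- cand[order(y[cand], decreasing = TRUE)]
  accepted <- numeric(0)
  for (i in ord) {
    if (all(abs(pos[i] - accepted) >= min_separation))
      accepted <- c(accepted, pos[i])
  }
  length(accepted)
}

#' Read an intensity grid from a plain-text matrix or TIFF
#'
#' Plain-text grids are whitespace-separated numeric matrices, one image row
#' per line.  Files ending in `.tif`/`.tiff` are read with the tiff package
#' (first channel of the first frame) when it is installed.
#'
#' @param path text or TIFF file.
#' @return numeric matrix.
#' @export
read_intensity_grid <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img)
  }
  as.matrix(read.table(path, header = FALSE))
}
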