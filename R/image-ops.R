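# Raster primitives for the eye-segmentation procedure.
#
# Images are 8-bit grayscale matrices: rows are image rows (y, top first),
# columns are x. Public pixel coordinates are 0-based with x rightward and
# y downward, so pixel (x, y) lives at m[y + 1, x + 1]. No installed R
# package provides these operations, so they are implemented here.

#' Create a blank grayscale image
#'
#' @param width,height Image dimensions in pixels.
#' @param fill Intensity in 0..255 used for every pixel.
#' @return An integer matrix with `height` rows and `width` columns.
#' @export
new_image <- function(width, height, fill = 0L) {
  if (width < 1 || height < 1) abort_input("image dimensions must be positive")
  matrix(as.integer(fill), nrow = height, ncol = width)
}

image_width <- function(img) ncol(img)
image_height <- function(img) nrow(img)

#' Fill a polygon on a pixel grid
#'
#' Even-odd scanline fill. Vertices are 0-based pixel coordinates; a pixel is
#' inside when its integer coordinate falls between a crossing pair on its row.
#'
#' @param width,height Grid dimensions.
#' @param xs,ys Numeric vectors of polygon vertex coordinates (same length).
#' @return A logical matrix, `TRUE` inside the polygon.
#' @export
polygon_mask <- function(width, height, xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  m <- matrix(FALSE, nrow = height, ncol = width)
  y_lo <- max(0L, as.integer(floor(min(ys))))
  y_hi <- min(height - 1L, as.integer(ceiling(max(ys))))
  if (y_hi < y_lo) return(m)
  n <- length(xs)
  jn <- c(seq_len(n)[-1], 1L)
  for (y in y_lo:y_hi) {
    cross <- numeric(0)
    for (i in seq_len(n)) {
      j <- jn[i]
      yi <- ys[i]; yj <- ys[j]
      if ((yi <= y && yj > y) || (yj <= y && yi > y)) {
        t <- (y - yi) / (yj - yi)
        cross <- c(cross, xs[i] + t * (xs[j] - xs[i]))
      }
    }
    if (length(cross) < 2) next
    cross <- sort(cross)
    k <- 1L
    while (k + 1L <= length(cross)) {
      xa <- max(0L, as.integer(ceiling(cross[k])))
      xb <- min(width - 1L, as.integer(floor(cross[k + 1L])))
      if (xb >= xa) m[y + 1L, (xa:xb) + 1L] <- TRUE
      k <- k + 2L
    }
  }
  m
}

#' Shoelace area of a polygon
#' @param xs,ys Vertex coordinates.
#' @return Signed area (positive counter-clockwise in image coordinates).
#' @export
polygon_area <- function(xs, ys) {
  n <- length(xs)
  j <- c(seq_len(n)[-1], 1L)
  sum(xs * ys[j] - xs[j] * ys) / 2
}

#' Binary dilation with a square structuring element
#'
#' @param m Logical matrix.
#' @param k Odd kernel side length in pixels; `k = 1` is the identity.
#' @return Dilated logical matrix of the same dimensions.
#' @export
dilate_mask <- function(m, k = 5L) {
  k <- as.integer(k)
  if (k < 1 || k %% 2L == 0L) abort_param("dilation kernel size must be a positive odd integer")
  if (k == 1L) return(m)
  r <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy == 0L && dx == 0L) next
      sr <- max(1L, 1L - dy):min(nr, nr - dy)
      sc <- max(1L, 1L - dx):min(nc, nc - dx)
      out[sr + dy, sc + dx] <- out[sr + dy, sc + dx] | m[sr, sc]
    }
  }
  out
}

# 8-connected components of a logical matrix; returns a list of integer
# cell-index vectors, largest first. Flood fill with a vectorised frontier:
# blobs here are pupil-sized (tens of pixels), so this is cheap.
label_components <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  todo <- which(m)
  if (length(todo) == 0) return(list())
  visited <- rep(FALSE, nr * nc)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  comps <- list()
  for (s in todo) {
    if (visited[s]) next
    visited[s] <- TRUE
    frontier <- s
    cells <- integer(0)
    while (length(frontier)) {
      cells <- c(cells, frontier)
      cand <- rep(frontier, each = length(off)) + rep(off, times = length(frontier))
      src_r <- rep((frontier - 1L) %% nr, each = length(off))
      ok <- cand >= 1L & cand <= nr * nc
      cand <- cand[ok]
      src_r <- src_r[ok]
      # column wrap-around guard: an 8-neighbour stays within +/-1 row index
      cand <- cand[abs(((cand - 1L) %% nr) - src_r) <= 1L]
      cand <- unique(cand)
      cand <- cand[m[cand] & !visited[cand]]
      visited[cand] <- TRUE
      frontier <- cand
    }
    comps[[length(comps) + 1L]] <- cells
  }
  comps[order(-vapply(comps, length, integer(1)))]
}

# centroid of a set of cell indices, in 0-based pixel coordinates
component_centroid <- function(cells, nr) {
  ys <- (cells - 1L) %% nr
  xs <- (cells - 1L) %/% nr
  c(x = mean(xs), y = mean(ys))
}

# filled disc as a logical matrix over the full grid (vectorised)
disc_mask <- function(width, height, cx, cy, r) {
  xs <- matrix(rep(0:(width - 1L), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1L), times = width), nrow = height)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Write a grayscale image as plain (ASCII) PGM
#'
#' Plain `P2` PGM keeps fixtures text-only while remaining a standard format
#' any image viewer opens.
#'
#' @param img Integer matrix with values in 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  rows <- apply(img, 1L, paste, collapse = " ")
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255", rows), path)
  invisible(path)
}

#' Read a plain (ASCII) PGM image
#' @param path File path of a `P2` PGM image.
#' @return An integer matrix.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) abort_io(paste0("no such image file: ", path))
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(tok) < 4 || tok[1] != "P2") abort_io(paste0("not a plain PGM (P2) file: ", path))
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  px <- as.integer(tok[-(1:4)])
  if (length(px) != w * h) abort_io(paste0("truncated PGM file: ", path))
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
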