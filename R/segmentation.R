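#' Rasterize a polygon to a binary slice mask
#'
#' A pixel belongs to the mask iff its center satisfies the even-odd
#' (crossing-number) rule for the polygon, with pixel centers at integer
#' 0-based `(row, col)` coordinates. Points lying exactly on a polygon edge
#' count as inside, so an axis-aligned rectangle with corners `(10,10)` and
#' `(19,19)` covers exactly 10 x 10 pixels. Self-intersecting polygons are
#' accepted and filled under the even-odd rule; a degenerate zero-area
#' polygon yields an empty mask with a warning.
#'
#' @param vertices An n x 2 matrix of `(row, col)` vertex coordinates,
#'   n >= 3, in order (the polygon is closed implicitly).
#' @param image_dims Integer length-2, `(n_rows, n_cols)`.
#' @return A binary matrix of the requested dimensions.
#' @examples
#' m <- rasterize_polygon(rbind(c(10, 10), c(10, 19), c(19, 19), c(19, 10)),
#'                        c(64, 64))
#' sum(m)  # 100
#' @export
rasterize_polygon <- function(vertices, image_dims) {
  if (!is.matrix(vertices)) vertices <- do.call(rbind, vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    abort("a polygon needs >= 3 (row, col) vertices")
  nr <- as.integer(image_dims[1]); nc <- as.integer(image_dims[2])
  mask <- matrix(0L, nr, nc)
  # shoelace area; zero-area polygons rasterize to nothing
  r <- vertices[, 1]; c <- vertices[, 2]
  r2 <- c(r[-1], r[1]); c2 <- c(c[-1], c[1])
  area2 <- sum(c * r2 - c2 * r)
  if (abs(area2) < .Machine$double.eps * max(1, sum(abs(vertices)))) {
    warn("zero-area polygon; returning an empty mask")
    return(mask)
  }
  # restrict to the polygon's bounding box
  rows <- max(0L, floor(min(r))):min(nr - 1L, ceiling(max(r)))
  cols <- max(0L, floor(min(c))):min(nc - 1L, ceiling(max(c)))
  if (length(rows) == 0L || length(cols) == 0L) return(mask)
  py <- rep(rows, times = length(cols))   # pixel-center row coords
  px <- rep(cols, each = length(rows))    # pixel-center col coords
  crossings <- integer(length(py))
  on_edge <- logical(length(py))
  eps <- 1e-9
  for (k in seq_len(nrow(vertices))) {
    r1 <- r[k]; c1 <- c[k]; rr2 <- r2[k]; cc2 <- c2[k]
    # crossing-number test: horizontal ray toward +col
    straddle <- (r1 > py) != (rr2 > py)
    if (any(straddle)) {
      xint <- (cc2 - c1) * (py - r1) / (rr2 - r1) + c1
      crossings <- crossings + as.integer(straddle & px < xint)
    }
    # boundary-inclusive: pixel center on the closed segment
    seg_len2 <- (rr2 - r1)^2 + (cc2 - c1)^2
    if (seg_len2 > 0) {
      tpar <- ((py - r1) * (rr2 - r1) + (px - c1) * (cc2 - c1)) / seg_len2
      cross <- (py - r1) * (cc2 - c1) - (px - c1) * (rr2 - r1)
      on_edge <- on_edge |
        (abs(cross) <= eps * sqrt(seg_len2) & tpar >= -eps & tpar <= 1 + eps)
    } else {
      on_edge <- on_edge | (abs(py - r1) <= eps & abs(px - c1) <= eps)
    }
  }
  inside <- (crossings %% 2L == 1L) | on_edge
  mask[cbind(py[inside] + 1L, px[inside] + 1L)] <- 1L
  mask
}

#' Threshold rule for intensity-based fat marking within an ROI
#'
#' @param mode `"absolute"` (cutoff is an intensity) or
#'   `"percentile-within-roi"` (cutoff is the nearest-rank percentile of the
#'   intensities inside the ROI).
#' @param value The intensity cutoff, or a percentile in `[0, 100]`.
#' @return A `pat_threshold_rule`.
#' @export
threshold_rule <- function(mode = c("absolute", "percentile-within-roi"),
                           value) {
  mode <- match.arg(mode)
  if (mode == "percentile-within-roi" && (value < 0 || value > 100))
    abort("percentile must lie in [0, 100]")
  structure(list(mode = mode, value = as.numeric(value)),
            class = "pat_threshold_rule")
}

# nearest-rank percentile: smallest value with at least ceil(p/100 * n)
# observations <= it
nearest_rank <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  x[max(1L, ceiling(p / 100 * n))]
}

#' Select fat pixels inside an ROI by intensity threshold
#'
#' Pixels of `image` inside `roi_mask` with intensity greater than or equal
#' to the cutoff are selected (ties included). In percentile mode the cutoff
#' is the nearest-rank percentile of the intensities inside the ROI only, so
#' a constant image is selected entirely at any percentile.
#'
#' @param image Numeric matrix.
#' @param roi_mask Binary matrix of the same dimensions, non-empty.
#' @param rule A [threshold_rule()].
#' @return A binary matrix, always a subset of `roi_mask`.
#' @export
threshold_within_roi <- function(image, roi_mask, rule) {
  stopifnot(inherits(rule, "pat_threshold_rule"))
  if (!all(dim(image) == dim(roi_mask)))
    abort("image and ROI mask dimensions differ")
  if (sum(roi_mask) == 0) abort("ROI mask is empty")
  cutoff <- if (rule$mode == "absolute") rule$value
            else nearest_rank(image[roi_mask == 1], rule$value)
  out <- (roi_mask == 1) & (image >= cutoff)
  matrix(as.integer(out), nrow(image), ncol(image))
}

#' Seeded region growing (4-connected)
#'
#' Returns the 4-connected component, containing the seed, of pixels whose
#' intensity differs from the seed pixel's intensity by at most `tolerance`.
#'
#' @param image Numeric matrix.
#' @param seed Length-2 `(row, col)`, 0-based integer pixel coordinates.
#' @param tolerance Non-negative intensity tolerance.
#' @return A binary matrix.
#' @export
region_grow <- function(image, seed, tolerance) {
  if (length(seed) != 2L) abort("`seed` must be (row, col)")
  if (!is.finite(tolerance) || tolerance < 0)
    abort("`tolerance` must be >= 0")
  nr <- nrow(image); nc <- ncol(image)
  sr <- as.integer(seed[1]) + 1L; sc <- as.integer(seed[2]) + 1L
  if (sr < 1L || sr > nr || sc < 1L || sc > nc)
    abort(sprintf("seed (%d, %d) outside the %d x %d image",
                  seed[1], seed[2], nr, nc))
  eligible <- abs(image - image[sr, sc]) <= tolerance
  grown <- matrix(FALSE, nr, nc)
  grown[sr, sc] <- TRUE
  # vectorized flood fill: dilate by the 4-neighbourhood until fixpoint
  repeat {
    nb <- matrix(FALSE, nr, nc)
    nb[-1, ] <- nb[-1, ] | grown[-nr, ]
    nb[-nr, ] <- nb[-nr, ] | grown[-1, ]
    nb[, -1] <- nb[, -1] | grown[, -nc]
    nb[, -nc] <- nb[, -nc] | grown[, -1]
    nxt <- grown | (nb & eligible)
    if (identical(nxt, grown)) break
    grown <- nxt
  }
  matrix(as.integer(grown), nr, nc)
}

#' Apply an ROI annotation set to a stack
#'
#' Builds the per-slice binary fat masks: annotations are applied in order,
#' `polygon` and `seed` annotations adding pixels (set union) and
#' `erase_polygon` removing them. The result is invariant to reordering of
#' the additive annotations between erasures.
#'
#' @param stack A `pat_image_stack` (intensities are used by seed
#'   annotations).
#' @param roi A `pat_roi_set`; it must bind to the stack (see
#'   [validate_roi_binding()]).
#' @return A binary `pat_image_stack` (mask stack) with the same geometry.
#' @export
apply_roi_set <- function(stack, roi) {
  validate_roi_binding(roi, stack)
  d <- dim(stack$data)
  masks <- array(0L, d)
  for (a in roi$annotations) {
    si <- a$slice + 1L
    add <- switch(a$type,
      polygon = rasterize_polygon(a$vertices, d[1:2]),
      erase_polygon = rasterize_polygon(a$vertices, d[1:2]),
      seed = region_grow(stack$data[, , si], a$seed, a$tolerance))
    if (a$type == "erase_polygon") {
      masks[, , si] <- masks[, , si] * (1L - add)
    } else {
      masks[, , si] <- pmax(masks[, , si], add)
    }
  }
  out <- image_stack(masks, stack$pixel_spacing, stack$slice_thickness,
                     stack$slice_gap, stack$subject_id)
  out
}
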