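# Independent oracles and fixture builders, deliberately written with
# different algorithms from the implementation under test.

# scalar even-odd point-in-polygon with boundary-inclusive rule
oracle_point_in_polygon <- function(py, px, vertices) {
  n <- nrow(vertices)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    ri <- vertices[i, 1]; ci <- vertices[i, 2]
    rj <- vertices[j, 1]; cj <- vertices[j, 2]
    # on-segment check
    d2 <- (rj - ri)^2 + (cj - ci)^2
    if (d2 == 0) {
      if (py == ri && px == ci) return(TRUE)
    } else {
      tpar <- ((py - ri) * (rj - ri) + (px - ci) * (cj - ci)) / d2
      cr <- (py - ri) * (cj - ci) - (px - ci) * (rj - ri)
      if (abs(cr) <= 1e-9 * sqrt(d2) && tpar >= -1e-9 && tpar <= 1 + 1e-9)
        return(TRUE)
    }
    if ((ri > py) != (rj > py)) {
      xint <- (cj - ci) * (py - ri) / (rj - ri) + ci
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(vertices, dims) {
  m <- matrix(0L, dims[1], dims[2])
  for (r in 0:(dims[1] - 1))
    for (c in 0:(dims[2] - 1))
      if (oracle_point_in_polygon(r, c, vertices)) m[r + 1, c + 1] <- 1L
  m
}

# queue-based BFS flood fill, 4-connected
oracle_flood_fill <- function(image, seed, tolerance) {
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0L, nr, nc)
  s <- c(seed[1] + 1L, seed[2] + 1L)
  ref <- image[s[1], s[2]]
  queue <- list(s)
  out[s[1], s[2]] <- 1L
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
          out[q[1], q[2]] == 0L && abs(image[q[1], q[2]] - ref) <= tolerance) {
        out[q[1], q[2]] <- 1L
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  out
}

# per-column linear interpolation via stats::approx
oracle_interpolate <- function(arr, zr) {
  d <- dim(arr)
  np <- (d[3] - 1) * zr + 1
  zout <- seq(0, d[3] - 1, length.out = np)
  out <- array(NA_real_, c(d[1], d[2], np))
  for (r in seq_len(d[1]))
    for (c in seq_len(d[2]))
      out[r, c, ] <- stats::approx(0:(d[3] - 1), arr[r, c, ], xout = zout)$y
  out
}

# two-way ANOVA ICC from raw sums of squares
oracle_icc <- function(m, form) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (form == "consistency") (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

oracle_bland_altman <- function(a, b, k = 2) {
  d <- b - a
  n <- length(d)
  bias <- sum(d) / n
  sdd <- sqrt(sum((d - bias)^2) / (n - 1))
  list(bias = bias, sd_diff = sdd,
       loa_lower = bias - k * sdd, loa_upper = bias + k * sdd)
}

random_stack <- function(dims = c(5, 6, 4), seed = NULL, binary = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  vals <- if (binary) sample(0:1, prod(dims), replace = TRUE)
          else runif(prod(dims), 0, 100)
  image_stack(array(vals, dims), pixel_spacing = runif(2, 0.5, 3),
              slice_thickness = runif(1, 2, 8), slice_gap = runif(1, 0, 2),
              subject_id = "random")
}

# random simple (star-shaped) polygon around a center
random_simple_polygon <- function(dims, n_vertices = sample(3:8, 1)) {
  ctr <- c(runif(1, 5, dims[1] - 6), runif(1, 5, dims[2] - 6))
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 2, 6)
  cbind(pmin(pmax(ctr[1] + rad * sin(ang), 0), dims[1] - 1),
        pmin(pmax(ctr[2] + rad * cos(ang), 0), dims[2] - 1))
}

table1_path <- function() pat_example("sheep_pat_autopsy_cmr.csv")
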