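# Internal rendering primitives for the synthetic-microscopy generators.
#
# Spots are rendered as pixel-integrated 2-D Gaussians (a separable product of
# pnorm differences) with FWHM equal to the particle diameter, truncated at a
# compact footprint of 3 sigma and renormalized so that the rendered kernel
# sums exactly to the requested integrated intensity. The exact-sum property
# is what makes zero-noise recovery of integrated intensities (and therefore
# uptake counts and drop fractions) exact rather than approximate.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

spot_sigma_px <- function(diameter_um, pixel_size_um) {
  fwhm_to_sigma(diameter_um) / pixel_size_um
}

spot_footprint_radius_px <- function(diameter_um, pixel_size_um) {
  max(1L, as.integer(ceiling(3 * spot_sigma_px(diameter_um, pixel_size_um))))
}

# Kernel centred on a pixel; sums exactly to `intensity`.
spot_kernel <- function(diameter_um, pixel_size_um, intensity = 1) {
  s <- spot_sigma_px(diameter_um, pixel_size_um)
  r <- spot_footprint_radius_px(diameter_um, pixel_size_um)
  edges <- seq(-r - 0.5, r + 0.5, by = 1)
  p <- diff(stats::pnorm(edges, sd = s))
  k <- outer(p, p)
  k * (intensity / sum(k))
}

# Add a kernel to `img` centred at 0-based pixel (x = col0, y = row0).
# The footprint must lie fully inside the image.
add_kernel <- function(img, x0, y0, k) {
  r <- (nrow(k) - 1L) %/% 2L
  rows <- (y0 + 1L - r):(y0 + 1L + r)
  cols <- (x0 + 1L - r):(x0 + 1L + r)
  if (rows[1] < 1L || cols[1] < 1L || rows[length(rows)] > nrow(img) ||
      cols[length(cols)] > ncol(img)) {
    stop("spot footprint extends outside the field")
  }
  img[rows, cols] <- img[rows, cols] + k
  img
}

# Linear (1-based) indices of pixels whose centres lie within `radius_px`
# of the 0-based centre (x0, y0).
disc_indices <- function(x0, y0, radius_px, dim) {
  r <- ceiling(radius_px)
  rows <- max(1L, y0 + 1L - r):min(dim[1], y0 + 1L + r)
  cols <- max(1L, x0 + 1L - r):min(dim[2], x0 + 1L + r)
  g <- expand.grid(row = rows, col = cols)
  keep <- ((g$row - 1 - y0)^2 + (g$col - 1 - x0)^2) <= radius_px^2
  as.integer(g$row[keep] + (g$col[keep] - 1L) * dim[1])
}

# Sample `n` 0-based integer centres with pairwise separation >= min_sep_px
# and margin >= margin_px from every edge. Errors if the field cannot hold
# the requested objects without overlap.
place_centers <- function(n, dim, min_sep_px, margin_px) {
  if (n == 0L) return(data.frame(x = integer(), y = integer()))
  lo_x <- margin_px; hi_x <- dim[2] - 1L - margin_px
  lo_y <- margin_px; hi_y <- dim[1] - 1L - margin_px
  if (hi_x < lo_x || hi_y < lo_y) stop("field too small to place objects without overlap")
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  max_tries <- 2000L * n
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("field too small to place objects without overlap")
    x <- sample.int(hi_x - lo_x + 1L, 1L) - 1L + lo_x
    y <- sample.int(hi_y - lo_y + 1L, 1L) - 1L + lo_y
    if (length(xs) == 0L ||
        all((xs - x)^2 + (ys - y)^2 >= min_sep_px^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x = as.integer(xs), y = as.integer(ys))
}

add_noise <- function(img, sd) {
  if (sd <= 0) return(img)
  img + matrix(stats::rnorm(length(img), sd = sd), nrow = nrow(img))
}

# Fill a convex polygon given 0-based vertex coordinates; returns a logical
# mask. Scanline fill over pixel centres.
fill_convex_polygon <- function(vx, vy, dim) {
  mask <- matrix(FALSE, dim[1], dim[2])
  n <- length(vx)
  rows <- max(1L, floor(min(vy)) + 1L):min(dim[1], ceiling(max(vy)) + 1L)
  for (row in rows) {
    y <- row - 1
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- vy[i]; y2 <- vy[j]
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        t <- (y - y1) / (y2 - y1)
        xs <- c(xs, vx[i] + t * (vx[j] - vx[i]))
      }
    }
    if (length(xs) >= 2) {
      xs <- range(xs)
      c1 <- max(1L, ceiling(xs[1]) + 1L)
      c2 <- min(dim[2], floor(xs[2]) + 1L)
      if (c2 >= c1) mask[row, c1:c2] <- TRUE
    }
  }
  mask
}

# Random convex-ish cell polygon around a 0-based centre.
random_cell_polygon <- function(x0, y0, radius_px, n_vertices = 10L) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- radius_px * stats::runif(n_vertices, 0.85, 1)
  list(x = x0 + rad * cos(ang), y = y0 + rad * sin(ang))
}
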