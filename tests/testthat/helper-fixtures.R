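# shared fixtures built in code

# histogram tibble of a Gaussian density sampled at uniform bin centers
gaussian_histogram <- function(mu, sigma, bin_width = 0.25,
                               lo = mu - 5 * sigma, hi = mu + 5 * sigma) {
  z <- seq(lo + bin_width / 2, hi, by = bin_width)
  p <- stats::dnorm(z, mu, sigma)
  p <- p / (sum(p) * bin_width)
  tibble::tibble(z_nm = z, density = p)
}

# uniform density on [0, L]
flat_histogram <- function(L = 10, bin_width = 0.25) {
  z <- seq(bin_width / 2, L, by = bin_width)
  tibble::tibble(z_nm = z, density = rep(1 / (length(z) * bin_width),
                                         length(z)))
}

# two-sample Kolmogorov-Smirnov distance without the test machinery
ks_distance <- function(a, b) {
  ecdf_a <- stats::ecdf(a)
  ecdf_b <- stats::ecdf(b)
  x <- sort(c(a, b))
  max(abs(ecdf_a(x) - ecdf_b(x)))
}

# KS distance between samples and a histogram-defined density
ks_distance_hist <- function(samples, hist) {
  dz <- diff(hist$z_nm)[1]
  edges <- c(hist$z_nm - dz / 2, max(hist$z_nm) + dz / 2)
  cdf <- c(0, cumsum(hist$density * dz))
  cdf <- cdf / max(cdf)
  emp <- stats::ecdf(samples)
  max(abs(emp(edges) - cdf))
}

# render an RGB frame with spots at given 0-based pixel coords
render_spot_image <- function(x_px, y_px, rg, npx = 128, peak_green = 0.5,
                              psf_sigma = 1.2, blue_fraction = 0.1,
                              offset = 0) {
  img <- array(offset, dim = c(npx, npx, 3))
  r_win <- ceiling(5 * psf_sigma)
  for (i in seq_along(x_px)) {
    rows <- max(1, floor(y_px[i]) - r_win):min(npx, ceiling(y_px[i]) + r_win + 1)
    cols <- max(1, floor(x_px[i]) - r_win):min(npx, ceiling(x_px[i]) + r_win + 1)
    psf <- exp(-outer(((rows - 1) - y_px[i])^2, ((cols - 1) - x_px[i])^2, `+`) /
                 (2 * psf_sigma^2))
    img[rows, cols, 1] <- img[rows, cols, 1] + peak_green * rg[i] * psf
    img[rows, cols, 2] <- img[rows, cols, 2] + peak_green * psf
    img[rows, cols, 3] <- img[rows, cols, 3] + peak_green * blue_fraction * psf
  }
  img
}
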