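#' Dark-field RGB image container
#'
#' @param pixels Numeric H x W x 3 array (channels R, G, B), non-negative.
#' @param pixel_size Physical pixel size in um/pixel (> 0).
#' @param bit_depth Camera bit depth (informational).
#' @param saturation_level Pixel value regarded as saturated (default the
#'   maximum representable value: 1 for normalised images).
#' @return An object of class `darkfield_image`.
#' @export
darkfield_image <- function(pixels, pixel_size, bit_depth = NA_integer_,
                            saturation_level = 1) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (any(pixels < 0)) stop("pixel intensities must be non-negative", call. = FALSE)
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  structure(
    list(pixels = pixels, pixel_size = pixel_size, bit_depth = bit_depth,
         saturation_level = saturation_level),
    class = "darkfield_image"
  )
}

#' Read a TIFF or PNG dark-field frame
#'
#' 8/16-bit 3-channel images are read and normalised to \[0, 1\].
#'
#' @param path File path (`.tif`, `.tiff`, or `.png`).
#' @param pixel_size Physical pixel size in um/pixel.
#' @return A [darkfield_image()].
#' @export
read_darkfield_image <- function(path, pixel_size) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3] # drop alpha
  darkfield_image(px, pixel_size = pixel_size)
}

#' @export
print.darkfield_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<darkfield_image: %d x %d px, %.3g um/px>\n",
              d[1], d[2], x$pixel_size))
  invisible(x)
}

.gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

.disk_offsets <- function(radius) {
  d <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  d[d$dy^2 + d$dx^2 <= radius^2, ]
}

.annulus_offsets <- function(radius, width) {
  outer_r <- radius + width
  d <- expand.grid(dy = -outer_r:outer_r, dx = -outer_r:outer_r)
  rr <- d$dy^2 + d$dx^2
  d[rr > radius^2 & rr <= outer_r^2, ]
}

# per-channel aperture photometry at integer pixel (row, col), 1-based
.measure_spot <- function(pixels, row, col, disk, annulus) {
  vals <- function(off, ch) {
    pixels[cbind(row + off$dy, col + off$dx, ch)]
  }
  bg_r <- stats::median(vals(annulus, 1))
  bg_g <- stats::median(vals(annulus, 2))
  c(mean_red = mean(vals(disk, 1)) - bg_r,
    mean_green = mean(vals(disk, 2)) - bg_g)
}

#' Detect isolated particles in a dark-field frame
#'
#' The channel-summed image is Gaussian-smoothed (`smooth_sigma`); local
#' maxima of the smoothed image above
#' `median + threshold_sigmas * sigma_bg` are collected, where `sigma_bg`
#' is a robust (upper-quantile) estimate of the raw per-pixel background
#' noise, so the smoothing gain acts as a false-positive safety margin.
#' Non-maximum suppression enforces `min_separation`, and
#' each surviving spot is measured with a disk aperture of
#' `aperture_radius` pixels against the median of a surrounding annulus
#' (`annulus_width` pixels). Detections whose aperture or annulus leaves
#' the frame are dropped. Centroids are intensity-weighted within the
#' aperture and reported in 0-based pixel coordinates (pixel centers at
#' integers).
#'
#' @param image A [darkfield_image()] (or H x W x 3 array).
#' @param min_separation Minimum center-to-center distance, pixels.
#' @param threshold_sigmas Detection threshold in robust raw-noise sigmas
#'   above the background median.
#' @param aperture_radius Photometry disk radius, pixels.
#' @param annulus_width Background annulus width, pixels.
#' @param smooth_sigma Detection smoothing sigma, pixels.
#' @return Tibble with columns `x_px`, `y_px` (0-based), `radius_px`,
#'   `mean_red`, `mean_green`, `rg`; zero rows when nothing is found.
#' @export
detect_particles <- function(image, min_separation = 5, threshold_sigmas = 3,
                             aperture_radius = 3, annulus_width = 2,
                             smooth_sigma = 1) {
  if (is.array(image)) image <- darkfield_image(image, pixel_size = 1)
  stopifnot(inherits(image, "darkfield_image"))
  px <- image$pixels
  sat <- mean(px >= image$saturation_level)
  if (sat > 0.01) {
    warning(sprintf("%.1f%% of pixels are saturated; intensities and RG ratios are unreliable",
                    100 * sat), call. = FALSE)
  }
  total <- px[, , 1] + px[, , 2] + px[, , 3]
  sm <- .gauss_smooth(total, smooth_sigma)
  med <- stats::median(sm)
  # robust upper-tail scale of the RAW summed image (quantile-based, so
  # it survives zero-clipped noise skew and a sparse bright-spot
  # fraction); thresholding the smoothed image against raw-noise sigmas
  # gives the smoothing gain as a false-positive safety margin
  sigma_bg <- (stats::quantile(total, 0.90, names = FALSE) -
                 stats::median(total)) / stats::qnorm(0.90)
  thresh <- med + threshold_sigmas * max(sigma_bg, .Machine$double.eps)

  h <- nrow(sm); w <- ncol(sm)
  # 8-neighbour local maxima (strict against raster-order ties)
  shift <- function(m, dy, dx) {
    out <- matrix(-Inf, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
    out
  }
  is_max <- sm > thresh
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- shift(sm, dy, dx)
    is_max <- is_max & (sm > nb | (sm == nb & (dy > 0 | (dy == 0 & dx > 0))))
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0) return(.empty_detections())
  ord <- order(sm[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]

  # greedy non-maximum suppression
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) == 0) { keep <- i; next }
    dd <- sqrt((cand[keep, 1] - cand[i, 1])^2 + (cand[keep, 2] - cand[i, 2])^2)
    if (all(dd >= min_separation)) keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]

  disk <- .disk_offsets(aperture_radius)
  annulus <- .annulus_offsets(aperture_radius, annulus_width)
  margin <- aperture_radius + annulus_width
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    if (r0 <= margin || r0 > h - margin || c0 <= margin || c0 > w - margin) next
    # intensity-weighted sub-pixel centroid within the aperture
    wts <- sm[cbind(r0 + disk$dy, c0 + disk$dx)]
    wts <- pmax(wts - med, 0)
    if (sum(wts) > 0) {
      cy <- r0 + sum(disk$dy * wts) / sum(wts)
      cx <- c0 + sum(disk$dx * wts) / sum(wts)
    } else {
      cy <- r0; cx <- c0
    }
    m <- .measure_spot(px, r0, c0, disk, annulus)
    if (!is.finite(m["mean_green"]) || m["mean_green"] <= 0) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      x_px = cx - 1, y_px = cy - 1, radius_px = aperture_radius,
      mean_red = unname(m["mean_red"]), mean_green = unname(m["mean_green"]),
      rg = unname(m["mean_red"] / m["mean_green"])
    )
  }
  if (length(rows) == 0) return(.empty_detections())
  dplyr::bind_rows(rows)
}

.empty_detections <- function() {
  tibble::tibble(x_px = numeric(), y_px = numeric(), radius_px = numeric(),
                 mean_red = numeric(), mean_green = numeric(), rg = numeric())
}

#' RG ratio of a single particle
#'
#' Background-subtracted mean red over mean green within a disk aperture
#' centered on the given 0-based pixel coordinates; the background per
#' channel is the median of a surrounding annulus.
#'
#' @param image A [darkfield_image()] (or H x W x 3 array).
#' @param x_px,y_px 0-based particle center (pixel centers at integers).
#' @param aperture_radius,annulus_width Photometry geometry, pixels.
#' @return A single dimensionless RG value.
#' @export
particle_rg <- function(image, x_px, y_px, aperture_radius = 3,
                        annulus_width = 2) {
  if (is.array(image)) image <- darkfield_image(image, pixel_size = 1)
  px <- image$pixels
  r0 <- round(y_px) + 1L
  c0 <- round(x_px) + 1L
  margin <- aperture_radius + annulus_width
  if (r0 <= margin || r0 > nrow(px[, , 1]) - margin ||
      c0 <= margin || c0 > ncol(px[, , 1]) - margin) {
    stop("aperture (incl. annulus) is not fully inside the image", call. = FALSE)
  }
  m <- .measure_spot(px, r0, c0,
                     .disk_offsets(aperture_radius),
                     .annulus_offsets(aperture_radius, annulus_width))
  if (!is.finite(m["mean_green"]) || m["mean_green"] <= 0) {
    stop("non-positive background-subtracted green mean; RG undefined",
         call. = FALSE)
  }
  unname(m["mean_red"] / m["mean_green"])
}

#' Population shift between two single-particle RG sets
#'
#' Frames before and after incubation contain independent particle sets;
#' the shift is assessed with a two-sided Student's t test (via
#' [compare_groups()]).
#'
#' @param before,after Numeric vectors of per-particle RG values (n >= 2
#'   each), or data frames with an `rg` column.
#' @param ... Passed to [compare_groups()].
#' @return A list with `summary` (per-group tibble: n, mean, sd),
#'   `shift` (mean(after) - mean(before)) and `comparison`
#'   (`group_comparison`).
#' @export
population_shift <- function(before, after, ...) {
  if (is.data.frame(before)) before <- before$rg
  if (is.data.frame(after)) after <- after$rg
  cmp <- compare_groups(list(before = before, after = after), ...)
  list(
    summary = tibble::tibble(
      group = c("before", "after"),
      n = c(length(before), length(after)),
      mean = c(mean(before), mean(after)),
      sd = c(stats::sd(before), stats::sd(after))
    ),
    shift = mean(after) - mean(before),
    comparison = cmp
  )
}

#' Nearest-neighbour spacing of a particle field
#'
#' Euclidean nearest-neighbour distance for every point; mean and SD in
#' um.
#'
#' @param coords Data frame (or detections tibble) with coordinate
#'   columns `x_px`/`y_px` or `x`/`y`, or a 2-column matrix.
#' @param pixel_size um per coordinate unit (1 if coordinates are already
#'   in um).
#' @return Tibble with `mean_um`, `sd_um`, `n`.
#' @export
nn_spacing <- function(coords, pixel_size = 1) {
  if (is.data.frame(coords)) {
    if (all(c("x_px", "y_px") %in% names(coords))) {
      coords <- cbind(coords$x_px, coords$y_px)
    } else if (all(c("x", "y") %in% names(coords))) {
      coords <- cbind(coords$x, coords$y)
    } else {
      stop("no coordinate columns (x_px/y_px or x/y) found", call. = FALSE)
    }
  }
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 points", call. = FALSE)
  dm <- as.matrix(stats::dist(coords)) * pixel_size
  diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  if (any(nn == 0)) {
    warning("duplicate coordinates: zero nearest-neighbour distances included",
            call. = FALSE)
  }
  tibble::tibble(mean_um = mean(nn), sd_um = stats::sd(nn), n = nrow(coords))
}
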