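#' Raster grid specification
#'
#' Defines the pixel grid onto which plot estimates are aggregated: pixel
#' size, grid origin, and projection label. The default is a 1-km grid in
#' World Mercator (EPSG:3395) with origin at (0, 0).
#'
#' @param pixel_size pixel edge length, m.
#' @param origin grid origin `c(x, y)`, projected meters.
#' @param crs projection identifier.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(pixel_size = 1000, origin = c(0, 0), crs = "EPSG:3395") {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(pixel_size = pixel_size, origin = origin, crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid: %g m pixels, origin (%g, %g), %s\n",
              x$pixel_size, x$origin[1], x$origin[2], x$crs))
  invisible(x)
}

#' Assign plots to grid pixels
#'
#' Computes per-axis pixel indices `floor((coord - origin) / pixel_size)`
#' (half-open pixel extents: a plot exactly on a pixel's lower-left corner
#' belongs to that pixel). Plots with non-finite coordinates are dropped with
#' a warning.
#'
#' @param estimates data frame of plot estimates with columns `x`, `y`
#'   (e.g. from [batch_estimate()]).
#' @param grid a [grid_spec()].
#' @return the input data frame with integer columns `ix`, `iy` added and
#'   non-finite-coordinate rows removed.
#' @export
assign_to_pixels <- function(estimates, grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"))
  ok <- is.finite(estimates$x) & is.finite(estimates$y)
  if (!all(ok))
    warning(sum(!ok), " plot(s) with non-finite coordinates skipped")
  estimates <- estimates[ok, , drop = FALSE]
  estimates$ix <- as.integer(floor((estimates$x - grid$origin[1]) / grid$pixel_size))
  estimates$iy <- as.integer(floor((estimates$y - grid$origin[2]) / grid$pixel_size))
  estimates
}

# area-weighted variance of plot means; unbiased reliability-weight form
.weighted_inter_var <- function(m, w, unbiased = TRUE) {
  if (length(m) < 2) return(0)
  mbar <- sum(w * m) / sum(w)
  ss <- sum(w * (m - mbar)^2)
  if (unbiased) {
    denom <- sum(w)^2 - sum(w^2)
    if (denom <= 0) return(0)
    ss * sum(w) / denom
  } else ss / sum(w)
}

#' Aggregate plot estimates within one pixel
#'
#' Combines the plots falling in a pixel into the pixel record: area-weighted
#' mean AGB; intra-plot variance (the area-weighted mean of the plots' Monte
#' Carlo variances: estimation uncertainty); inter-plot variance (the
#' area-weighted variance of the plots' mean AGB about the pixel mean, in its
#' unbiased reliability-weighted form: sampling uncertainty); the area
#' weighted mean inventory date; and the total CV,
#' `100 sqrt(inter + intra) / mean`.
#'
#' @param mean_agb,variance,area,date vectors over the plots of one pixel.
#' @param unbiased use the unbiased reliability-weighted variance (default);
#'   `FALSE` gives the population form.
#' @return one-row data frame with `mean_agb`, `n_plots`, `mean_date`,
#'   `inter_var`, `intra_var`, `total_cv_pct`.
#' @export
aggregate_pixel <- function(mean_agb, variance, area, date, unbiased = TRUE) {
  n <- length(mean_agb)
  if (n < 1) stop("a pixel must contain at least one plot")
  w <- area
  m <- sum(w * mean_agb) / sum(w)
  intra <- sum(w * variance) / sum(w)
  inter <- .weighted_inter_var(mean_agb, w, unbiased = unbiased)
  data.frame(mean_agb = m, n_plots = n,
             mean_date = sum(w * date) / sum(w),
             inter_var = inter, intra_var = intra,
             total_cv_pct = if (m > 0) 100 * sqrt(inter + intra) / m else NA_real_)
}

#' Aggregate a batch of plot estimates to pixels
#'
#' Assigns plots to pixels and aggregates each occupied pixel with
#' [aggregate_pixel()].
#'
#' @param estimates data frame from [batch_estimate()] (columns `mean_agb`,
#'   `variance`, `area`, `date`, `x`, `y`).
#' @param grid a [grid_spec()].
#' @param unbiased see [aggregate_pixel()].
#' @return data frame with one row per occupied pixel: `ix`, `iy` and the
#'   [aggregate_pixel()] fields.
#' @export
aggregate_pixels <- function(estimates, grid = grid_spec(), unbiased = TRUE) {
  est <- assign_to_pixels(estimates, grid)
  if (nrow(est) == 0)
    return(data.frame(ix = integer(0), iy = integer(0), mean_agb = numeric(0),
                      n_plots = integer(0), mean_date = numeric(0),
                      inter_var = numeric(0), intra_var = numeric(0),
                      total_cv_pct = numeric(0)))
  key <- paste(est$ix, est$iy, sep = ",")
  out <- do.call(rbind, lapply(split(seq_len(nrow(est)), key), function(i) {
    cbind(data.frame(ix = est$ix[i[1]], iy = est$iy[i[1]]),
          aggregate_pixel(est$mean_agb[i], est$variance[i], est$area[i],
                          est$date[i], unbiased = unbiased))
  }))
  rownames(out) <- NULL
  out[order(out$iy, out$ix), , drop = FALSE]
}

# ---- five-layer GeoTIFF -----------------------------------------------------
# Minimal single-strip-per-band float64 GeoTIFF writer/reader (little-endian,
# classic TIFF, PlanarConfiguration = 2). Georeferencing is carried by the
# ModelPixelScale / ModelTiepoint tags and a GeoKey directory holding the
# projected CRS EPSG code; the nodata value is stored in the GDAL_NODATA tag.

.RASTER_BANDS <- c("mean_agb", "n_plots", "mean_date", "inter_var", "intra_var")

#' Write pixel records as a five-layer GeoTIFF
#'
#' Writes the aggregated pixel table to a five-band float64 GeoTIFF with the
#' band order: (1) mean pixel AGB, Mg/ha; (2) number of plots in the pixel;
#' (3) mean inventory date, fractional year; (4) inter-plot variance,
#' Mg^2/ha^2; (5) intra-plot variance, Mg^2/ha^2. The raster extent is the
#' bounding box of occupied pixels; unoccupied pixels hold the nodata value
#' in all five bands. The CRS EPSG code of the grid is stored in the GeoTIFF
#' GeoKey directory.
#'
#' @param pixels data frame from [aggregate_pixels()].
#' @param grid the [grid_spec()] the pixels were computed on.
#' @param path output file path.
#' @param nodata value stored in empty pixels.
#' @return `path`, invisibly.
#' @seealso [read_agb_raster()]
#' @export
write_agb_raster <- function(pixels, grid = grid_spec(), path,
                             nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(pixels) == 0) stop("no pixels to write")
  ix0 <- min(pixels$ix); iy0 <- min(pixels$iy)
  w <- max(pixels$ix) - ix0 + 1L; h <- max(pixels$iy) - iy0 + 1L
  bands <- lapply(.RASTER_BANDS, function(nm) {
    m <- matrix(nodata, nrow = h, ncol = w)
    # raster row 1 = northernmost row (iy = iy0 + h - 1)
    r <- (iy0 + h - 1L) - pixels$iy + 1L
    c_ <- pixels$ix - ix0 + 1L
    m[cbind(r, c_)] <- pixels[[nm]]
    m
  })
  origin_x <- grid$origin[1] + ix0 * grid$pixel_size
  top_y <- grid$origin[2] + (iy0 + h) * grid$pixel_size
  epsg <- if (grepl("^EPSG:", grid$crs)) as.integer(sub("^EPSG:", "", grid$crs))
          else 0L
  .write_geotiff(path, bands, width = w, height = h,
                 pixel_size = grid$pixel_size, origin_x = origin_x,
                 top_y = top_y, epsg = epsg, nodata = nodata)
  invisible(path)
}

.write_geotiff <- function(path, bands, width, height, pixel_size,
                           origin_x, top_y, epsg, nodata) {
  nb <- length(bands)
  strip_bytes <- width * height * 8
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 1,    # model type: projected
                          1025, 0, 1, 1,    # raster type: pixel is area
                          3072, 0, 1, epsg))
  nodata_str <- c(charToRaw(format(nodata, scientific = FALSE)), as.raw(0))
  n_entries <- 15L
  ifd_offset <- 8L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  # out-of-line value block layout, after the IFD
  off <- ifd_offset + ifd_bytes
  off_bits <- off;                 off <- off + 2L * nb
  off_strips <- off;               off <- off + 4L * nb
  off_counts <- off;               off <- off + 4L * nb
  off_sfmt <- off;                 off <- off + 2L * nb
  off_scale <- off;                off <- off + 8L * 3L
  off_tie <- off;                  off <- off + 8L * 6L
  off_geo <- off;                  off <- off + 2L * length(geokeys)
  off_nodata <- off;               off <- off + length(nodata_str)
  if (off %% 2L) off <- off + 1L   # word-align image data
  data_start <- off
  strip_offsets <- data_start + (seq_len(nb) - 1L) * strip_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) {
    x <- if (size == 8) as.numeric(x) else if (is.raw(x)) x else
      as.integer(round(x))
    writeBin(x, con, size = size, endian = "little")
  }
  wb(charToRaw("II"), 1); wb(42L, 2); wb(ifd_offset, 4)
  wb(n_entries, 2)
  entry <- function(tag, type, count, value, inline = TRUE) {
    wb(as.integer(tag), 2); wb(as.integer(type), 2); wb(as.integer(count), 4)
    if (inline) {  # value fits in 4 bytes, left-justified
      if (type == 3) { wb(as.integer(value), 2); wb(0L, 2) }
      else wb(as.integer(value), 4)
    } else wb(as.integer(value), 4)  # offset
  }
  entry(256, 4, 1, width)
  entry(257, 4, 1, height)
  entry(258, 3, nb, off_bits, inline = FALSE)
  entry(259, 3, 1, 1)
  entry(262, 3, 1, 1)
  entry(273, 4, nb, off_strips, inline = FALSE)
  entry(277, 3, 1, nb)
  entry(278, 4, 1, height)
  entry(279, 4, nb, off_counts, inline = FALSE)
  entry(284, 3, 1, 2)
  entry(339, 3, nb, off_sfmt, inline = FALSE)
  entry(33550, 12, 3, off_scale, inline = FALSE)
  entry(33922, 12, 6, off_tie, inline = FALSE)
  entry(34735, 3, length(geokeys), off_geo, inline = FALSE)
  entry(42113, 2, length(nodata_str), off_nodata, inline = FALSE)
  wb(0L, 4)  # no next IFD
  wb(rep(64L, nb), 2)
  wb(strip_offsets, 4)
  wb(rep(strip_bytes, nb), 4)
  wb(rep(3L, nb), 2)
  wb(c(pixel_size, pixel_size, 0), 8)
  wb(c(0, 0, 0, origin_x, top_y, 0), 8)
  wb(geokeys, 2)
  writeBin(nodata_str, con)
  pad <- data_start - off_nodata - length(nodata_str)
  if (pad > 0) writeBin(as.raw(rep(0, pad)), con)
  for (b in bands) wb(as.numeric(t(b)), 8)  # row-major
  invisible(path)
}

#' Read a five-layer AGB GeoTIFF
#'
#' Reads rasters written by [write_agb_raster()] (classic little-endian TIFF,
#' float64 samples, one strip per band) and returns the five bands with the
#' georeferencing recovered from the ModelPixelScale/ModelTiepoint tags and
#' the GeoKey directory.
#'
#' @param path file path.
#' @return list with `bands` (named list of `height x width` matrices, row 1
#'   = northernmost row), `width`, `height`, `pixel_size`, `origin_x`,
#'   `top_y`, `epsg`.
#' @export
read_agb_raster <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rb <- function(n, size, what = "integer")
    readBin(con, what, n = n, size = size, endian = "little",
            signed = !(size == 2 && what == "integer"))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "II")) stop("not a little-endian TIFF")
  if (rb(1, 2) != 42L) stop("not a TIFF file")
  ifd <- rb(1, 4)
  seek(con, ifd)
  n_entries <- rb(1, 2)
  tags <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    tag <- rb(1, 2); type <- rb(1, 2); count <- rb(1, 4)
    raw4 <- readBin(con, "raw", 4)
    tags[[i]] <- list(tag = tag, type = type, count = count, raw = raw4)
  }
  le_uint <- function(r) sum(as.double(as.integer(r)) * 256^(seq_along(r) - 1))
  val <- function(tg) {
    e <- Filter(function(t) t$tag == tg, tags)
    if (length(e) == 0) return(NULL)
    e <- e[[1]]
    size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `12` = 8)[[as.character(e$type)]]
    if (size * e$count <= 4) {
      return(vapply(seq_len(e$count), function(k)
        le_uint(e$raw[((k - 1) * size + 1):(k * size)]), numeric(1)))
    }
    seek(con, le_uint(e$raw))
    if (e$type == 2) {
      ch <- readBin(con, "raw", e$count)
      rawToChar(ch[ch != as.raw(0)])
    } else rb(e$count, size, if (e$type == 12) "double" else "integer")
  }
  width <- val(256); height <- val(257); spp <- val(277)
  offsets <- val(273); fmt <- val(339); bits <- val(258)
  if (any(bits != 64) || any(fmt != 3))
    stop("expected float64 samples")
  scale <- val(33550); tie <- val(33922); geo <- val(34735)
  epsg <- NA_integer_
  if (!is.null(geo)) {
    keys <- matrix(geo[-(1:4)], ncol = 4, byrow = TRUE)
    hit <- which(keys[, 1] == 3072)
    if (length(hit)) epsg <- keys[hit[1], 4]
  }
  nodata <- val(42113)
  bands <- lapply(seq_len(spp), function(b) {
    seek(con, offsets[b])
    matrix(rb(width * height, 8, "double"), nrow = height, ncol = width,
           byrow = TRUE)
  })
  names(bands) <- .RASTER_BANDS[seq_len(spp)]
  list(bands = bands, width = width, height = height,
       pixel_size = scale[1], origin_x = tie[4], top_y = tie[5], epsg = epsg,
       nodata = if (is.null(nodata)) NA_real_ else as.numeric(nodata))
}
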