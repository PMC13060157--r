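#' Image simulator configuration
#'
#' Describes a synthetic smFISH field: a DAPI plane with disc-shaped nuclei
#' (optionally with bright chromocenters), and two spot channels with
#' Gaussian puncta over Gaussian background noise. Defaults give a
#' high-SNR field: spot amplitude 50x the background SD, matching the
#' regime in which the planted-truth recovery properties are stated.
#'
#' @param height,width image size in px.
#' @param nucleus_geometry data.frame of discs (`row`, `col`, `radius`);
#'   `NULL` places 3 radius-36 nuclei deterministically from the seed.
#' @param n_spots_per_channel named vector, spots for `red` and `green`.
#' @param nuclear_spot_fraction per-channel fraction of spots planted inside
#'   nuclei (recycled).
#' @param spot_sigma Gaussian punctum sigma in px.
#' @param spot_amplitude peak intensity added by a punctum.
#' @param background_mean,background_sd Gaussian background of the spot
#'   channels.
#' @param min_separation_px minimum centre-to-centre distance between
#'   planted spots of one channel (keeps planted truth unambiguous).
#' @param chromocenters_per_nucleus bright DAPI puncta per nucleus (0 to
#'   disable).
#' @param seed integer seed; fixed seed gives identical images.
#' @return object of class `image_sim_config`.
#' @export
image_sim_config <- function(height = 256L, width = 256L,
                             nucleus_geometry = NULL,
                             n_spots_per_channel = c(red = 100L, green = 100L),
                             nuclear_spot_fraction = 0.5,
                             spot_sigma = 0.8, spot_amplitude = 500,
                             background_mean = 100, background_sd = 10,
                             min_separation_px = 4,
                             chromocenters_per_nucleus = 0L,
                             seed = NULL) {
  stopifnot(height >= 32, width >= 32, all(n_spots_per_channel >= 0),
            all(nuclear_spot_fraction >= 0 & nuclear_spot_fraction <= 1),
            spot_sigma > 0, spot_amplitude > 0, background_sd >= 0,
            min_separation_px >= 0)
  if (is.null(nucleus_geometry)) {
    nucleus_geometry <- data.frame(
      row = c(0.28, 0.72, 0.55) * height,
      col = c(0.30, 0.35, 0.75) * width,
      radius = 36)
  }
  if (any(nucleus_geometry$row - nucleus_geometry$radius < 1) ||
      any(nucleus_geometry$row + nucleus_geometry$radius > height) ||
      any(nucleus_geometry$col - nucleus_geometry$radius < 1) ||
      any(nucleus_geometry$col + nucleus_geometry$radius > width)) {
    stop("nucleus geometry extends beyond the image", call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 nucleus_geometry = nucleus_geometry,
                 n_spots_per_channel = n_spots_per_channel,
                 nuclear_spot_fraction = rep_len(nuclear_spot_fraction,
                                                 length(n_spots_per_channel)),
                 spot_sigma = spot_sigma, spot_amplitude = spot_amplitude,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 min_separation_px = min_separation_px,
                 chromocenters_per_nucleus = as.integer(chromocenters_per_nucleus),
                 seed = seed),
            class = "image_sim_config")
}

# Distance of every pixel-or-point to the nearest nucleus boundary:
# positive inside, negative outside.
nucleus_depth <- function(row, col, geom) {
  d <- rep(-Inf, length(row))
  for (g in seq_len(nrow(geom))) {
    d <- pmax(d, geom$radius[g] -
                sqrt((row - geom$row[g])^2 + (col - geom$col[g])^2))
  }
  d
}

place_spots <- function(n, nuclear, geom, height, width, min_sep, margin = 6,
                        max_tries = 20000L) {
  rows <- numeric(0); cols <- numeric(0)
  tries <- 0L
  while (length(rows) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("spot placement retries exhausted; relax geometry or separation",
           call. = FALSE)
    }
    r <- runif(1, margin, height - margin)
    c <- runif(1, margin, width - margin)
    depth <- nucleus_depth(r, c, geom)
    want_nuclear <- nuclear[length(rows) + 1L]
    # keep 2.5 px clear of the compartment boundary so rounded centroids
    # cannot cross it
    if (want_nuclear && depth < 2.5) next
    if (!want_nuclear && depth > -2.5) next
    if (length(rows) > 0 &&
        min(sqrt((rows - r)^2 + (cols - c)^2)) < min_sep) next
    rows <- c(rows, r); cols <- c(cols, c)
  }
  data.frame(row = rows, col = cols, nuclear = nuclear)
}

add_gaussians <- function(plane, rows, cols, amplitude, sigma) {
  r4 <- ceiling(4 * sigma)
  nr <- nrow(plane); nc <- ncol(plane)
  for (i in seq_along(rows)) {
    ri <- max(1L, floor(rows[i] - r4)):min(nr, ceiling(rows[i] + r4))
    ci <- max(1L, floor(cols[i] - r4)):min(nc, ceiling(cols[i] + r4))
    g <- amplitude * exp(-(outer((ri - rows[i])^2, (ci - cols[i])^2, "+")) /
                           (2 * sigma^2))
    plane[ri, ci] <- plane[ri, ci] + g
  }
  plane
}

#' Simulate an smFISH field
#'
#' Produces a DAPI plane (bright discs for nuclei, dim background, optional
#' chromocenters), two spot channels with planted Gaussian puncta plus
#' Gaussian background noise, the truth spot table and the truth nuclear
#' mask. Channel planes are rounded to integers; DAPI is clamped to
#' `[0, 255]` (8-bit-equivalent scale used by the mask threshold), spot
#' channels to `[0, 65535]`.
#'
#' @param cfg an [image_sim_config()].
#' @return list with `dapi`, `red`, `green` (matrices), `truth_spots`
#'   (data.frame `channel`, `row`, `col`, `nuclear`) and `truth_mask`
#'   (logical matrix).
#' @export
simulate_image <- function(cfg) {
  stopifnot(inherits(cfg, "image_sim_config"))
  with_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width
    geom <- cfg$nucleus_geometry
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    depth <- matrix(nucleus_depth(as.vector(rr), as.vector(cc), geom), h, w)
    truth_mask <- depth > 0
    dapi <- matrix(8 + rnorm(h * w, sd = 2), h, w)
    dapi[truth_mask] <- 180 + rnorm(sum(truth_mask), sd = 2)
    if (cfg$chromocenters_per_nucleus > 0) {
      for (g in seq_len(nrow(geom))) {
        ang <- runif(cfg$chromocenters_per_nucleus, 0, 2 * pi)
        rad <- runif(cfg$chromocenters_per_nucleus, 0, 0.5 * geom$radius[g])
        dapi <- add_gaussians(dapi, geom$row[g] + rad * sin(ang),
                              geom$col[g] + rad * cos(ang),
                              amplitude = 70, sigma = 2)
      }
    }
    dapi <- pmin(pmax(round(dapi), 0), 255)

    channels <- names(cfg$n_spots_per_channel)
    planes <- list()
    truth <- list()
    for (k in seq_along(channels)) {
      n <- cfg$n_spots_per_channel[[k]]
      n_nuc <- round(cfg$nuclear_spot_fraction[k] * n)
      nuclear <- rep(c(TRUE, FALSE), c(n_nuc, n - n_nuc))
      spots <- if (n > 0) {
        place_spots(n, nuclear, geom, h, w, cfg$min_separation_px)
      } else data.frame(row = numeric(0), col = numeric(0), nuclear = logical(0))
      plane <- matrix(cfg$background_mean + rnorm(h * w, sd = cfg$background_sd),
                      h, w)
      plane <- add_gaussians(plane, spots$row, spots$col, cfg$spot_amplitude,
                             cfg$spot_sigma)
      planes[[channels[k]]] <- pmin(pmax(round(plane), 0), 65535)
      if (n > 0) spots$channel <- channels[k]
      truth[[k]] <- spots
    }
    truth_spots <- do.call(rbind, truth)
    list(dapi = dapi, red = planes[["red"]], green = planes[["green"]],
         truth_spots = truth_spots, truth_mask = truth_mask)
  })
}

#' Plain-text image round trip
#'
#' Writes/reads a numeric matrix as a TSV of pixel values (row-major), the
#' text stand-in for single-channel TIFF exchange.
#'
#' @param mat numeric matrix.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_image_tsv <- function(mat, path) {
  write.table(mat, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  as.matrix(read.delim(path, header = FALSE))
}
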