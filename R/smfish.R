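#' Spot-detection parameters
#'
#' Defaults map one-to-one to the cited detection settings: threshold at 20
#' robust SDs above background, minimum component size 3 px, pairing radius
#' 2 px. `smoothing_sigma` is the light Gaussian pre-smoothing applied
#' before background estimation and thresholding.
#'
#' @param min_intensity_sd threshold multiplier (default 20).
#' @param min_size_px minimum component area in px (default 3).
#' @param max_pair_dist_px colocalization pairing radius in px (default 2).
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px (default 0.4).
#' @return object of class `spot_params`.
#' @export
spot_params <- function(min_intensity_sd = 20, min_size_px = 3L,
                        max_pair_dist_px = 2, smoothing_sigma = 0.4) {
  for (v in c(min_intensity_sd, min_size_px, max_pair_dist_px, smoothing_sigma)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop("all spot parameters must be strictly positive scalars", call. = FALSE)
    }
  }
  structure(list(min_intensity_sd = min_intensity_sd,
                 min_size_px = as.integer(min_size_px),
                 max_pair_dist_px = max_pair_dist_px,
                 smoothing_sigma = smoothing_sigma),
            class = "spot_params")
}

#' Separable Gaussian blur with renormalized edges
#'
#' @param mat numeric matrix.
#' @param sigma Gaussian sigma in px; `0` returns the input unchanged.
#' @return smoothed matrix of the same dimensions.
#' @export
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  band <- function(n) {
    b <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      b[cbind(i[ok], j[ok])] <- k[d + r + 1]
    }
    b / rowSums(b) # renormalize truncated edge kernels
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}

#' Detect fluorescence puncta
#'
#' Pipeline: Gaussian pre-smoothing, robust background statistics (median
#' and 1.4826*MAD, falling back to the plain SD when the MAD is zero),
#' threshold at `mu + min_intensity_sd * sigma`, 8-connected component
#' labelling, area filter, and intensity-weighted sub-pixel centroids
#' (weights are the background-subtracted smoothed intensities). Spots are
#' ordered by (row, col).
#'
#' @param plane numeric matrix (single-channel image).
#' @param params a [spot_params()].
#' @return data.frame with `row`, `col` (sub-pixel centroid, 1-based),
#'   `area` (px) and `peak` (maximum smoothed intensity in the component).
#' @export
detect_spots <- function(plane, params = spot_params()) {
  stopifnot(is.matrix(plane), all(is.finite(plane)))
  sm <- gauss_blur(plane, params$smoothing_sigma)
  mu <- median(sm)
  sig <- mad(sm)
  if (sig == 0) sig <- sd(sm)
  empty <- data.frame(row = numeric(0), col = numeric(0), area = integer(0),
                      peak = numeric(0))
  if (is.na(sig) || sig <= 1e-9 * max(abs(mu), 1)) {
    warning("constant image: no spots detectable")
    return(empty)
  }
  thr <- mu + params$min_intensity_sd * sig
  mask <- sm >= thr
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  wts <- pmax(sm - mu, 0)
  idx <- which(lab > 0)
  labs <- lab[idx]
  areas <- tabulate(labs)
  keep <- which(areas >= params$min_size_px)
  if (length(keep) == 0) return(empty)
  ri <- (idx - 1L) %% nrow(plane) + 1L
  ci <- (idx - 1L) %/% nrow(plane) + 1L
  w <- wts[idx]
  rows <- vapply(keep, function(l) {
    s <- labs == l
    sum(ri[s] * w[s]) / sum(w[s])
  }, numeric(1))
  cols <- vapply(keep, function(l) {
    s <- labs == l
    sum(ci[s] * w[s]) / sum(w[s])
  }, numeric(1))
  peaks <- vapply(keep, function(l) max(sm[idx[labs == l]]), numeric(1))
  out <- data.frame(row = rows, col = cols, area = areas[keep], peak = peaks)
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nuclear mask from a DAPI plane
#'
#' Inclusive band threshold (`low <= pixel <= high`), no morphology by
#' default; `fill_holes` flood-fills background regions not connected to
#' the image border (closing holes left by e.g. bright chromocenters being
#' clipped).
#'
#' @param dapi numeric matrix.
#' @param low,high inclusive threshold bounds (defaults 35 and 255).
#' @param fill_holes logical.
#' @return logical matrix of the same dimensions.
#' @export
nucleus_mask <- function(dapi, low = 35, high = 255, fill_holes = FALSE) {
  stopifnot(is.matrix(dapi), low <= high)
  mask <- dapi >= low & dapi <= high
  if (fill_holes) {
    bg <- !mask
    lab <- label_components(bg)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0]
    hole <- bg & !(lab %in% border)
    mask <- mask | matrix(hole, nrow(mask))
  }
  mask
}

#' Classify spots as nuclear or cytoplasmic
#'
#' A spot is nuclear iff the mask is `TRUE` at its centroid pixel, with
#' half-up rounding of the sub-pixel centroid.
#'
#' @param spots data.frame with `row`, `col` (from [detect_spots()] or a
#'   truth table).
#' @param mask logical matrix (see [nucleus_mask()]).
#' @return list with `labels` (character `"nuclear"`/`"cytoplasmic"` per
#'   spot), `n_nuclear`, `n_cytoplasmic`, `fraction_nuclear`.
#' @export
classify_localization <- function(spots, mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  r <- floor(spots$row + 0.5)
  c <- floor(spots$col + 0.5)
  if (nrow(spots) > 0 &&
      (any(r < 1 | r > nrow(mask)) || any(c < 1 | c > ncol(mask)))) {
    stop("spot centroid outside image bounds", call. = FALSE)
  }
  nuclear <- if (nrow(spots) > 0) mask[cbind(r, c)] else logical(0)
  list(labels = ifelse(nuclear, "nuclear", "cytoplasmic"),
       n_nuclear = sum(nuclear), n_cytoplasmic = sum(!nuclear),
       fraction_nuclear = if (nrow(spots) > 0) mean(nuclear) else NA_real_)
}

#' Greedy mutual-nearest colocalization of two spot lists
#'
#' Repeatedly pairs the globally closest unmatched (x, y) spots with
#' Euclidean centroid distance <= `max_dist`; each spot matches at most
#' once. Per compartment of the x-spot (from `mask`), the matched fraction
#' is reported.
#'
#' @param spots_x,spots_y data.frames with `row`, `col`.
#' @param max_dist pairing radius in px (default 2).
#' @param mask optional logical nuclear mask for per-compartment fractions.
#' @return list with `pairs` (data.frame `ix`, `iy`, `dist`), `n_matched`,
#'   and, when `mask` is given, `by_compartment` (data.frame per
#'   compartment: `n_x`, `n_matched`, `fraction_matched`).
#' @export
colocalize <- function(spots_x, spots_y, max_dist = 2, mask = NULL) {
  nx <- nrow(spots_x); ny <- nrow(spots_y)
  pairs <- data.frame(ix = integer(0), iy = integer(0), dist = numeric(0))
  if (nx > 0 && ny > 0) {
    d <- sqrt(outer(spots_x$row, spots_y$row, "-")^2 +
              outer(spots_x$col, spots_y$col, "-")^2)
    d[d > max_dist] <- Inf
    repeat {
      m <- which.min(d)
      if (length(m) == 0 || !is.finite(d[m])) break
      ix <- (m - 1L) %% nx + 1L
      iy <- (m - 1L) %/% nx + 1L
      pairs <- rbind(pairs, data.frame(ix = ix, iy = iy, dist = d[m]))
      d[ix, ] <- Inf
      d[, iy] <- Inf
    }
  }
  out <- list(pairs = pairs, n_matched = nrow(pairs))
  if (!is.null(mask)) {
    comp <- classify_localization(spots_x, mask)$labels
    matched <- seq_len(nx) %in% pairs$ix
    by <- lapply(c("nuclear", "cytoplasmic"), function(cc) {
      s <- comp == cc
      data.frame(compartment = cc, n_x = sum(s), n_matched = sum(matched[s]),
                 fraction_matched = if (sum(s)) mean(matched[s]) else NA_real_)
    })
    out$by_compartment <- do.call(rbind, by)
  }
  out
}
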