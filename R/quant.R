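#' Per-fraction relative RNA abundance from qPCR cycle thresholds
#'
#' Anchored delta-CT quantification of polysome gradient fractions. For each
#' (amplicon, replicate), with `m` the maximum CT across its fractions, the
#' relative abundance of fraction `f` is `2^(m - ct_f)`, so the least
#' abundant fraction is anchored at `2^0 = 1` and every other fraction is a
#' multiple of it. Percent-of-total is `100 * abundance / sum(abundance)`
#' per replicate; the per-amplicon summary is the mean and SD of those
#' percents across replicates. No-template-control rows are excluded, and
#' missing fractions stay missing (absence of amplification at 40 cycles is
#' not zero abundance).
#'
#' @param ct data.frame with `amplicon`, `fraction`, `replicate`, `ct`, and
#'   optionally `is_ntc` (as from [simulate_ct()] or [read_ct_csv()]).
#' @param fraction_levels optional character vector fixing the gradient
#'   order of fractions; defaults to order of first appearance.
#' @return object of class `fraction_profile`: list with `per_replicate`
#'   (data.frame `amplicon`, `replicate`, `fraction`, `ct`, `rel_abundance`,
#'   `percent`) and `summary` (data.frame `amplicon`, `fraction`,
#'   `mean_percent`, `sd_percent`, `n`).
#' @export
fraction_abundance <- function(ct, fraction_levels = NULL) {
  stopifnot(is.data.frame(ct),
            all(c("amplicon", "fraction", "replicate", "ct") %in% names(ct)))
  if (!"is_ntc" %in% names(ct)) ct$is_ntc <- FALSE
  ct <- ct[!ct$is_ntc & !is.na(ct$ct), , drop = FALSE]
  if (nrow(ct) == 0) stop("no usable CT entries", call. = FALSE)
  if (any(ct$ct <= 0 | ct$ct > 40)) {
    stop("CT values must lie in (0, 40]", call. = FALSE)
  }
  if (is.null(fraction_levels)) fraction_levels <- unique(ct$fraction)
  key <- paste(ct$amplicon, ct$replicate, sep = "\r")
  per <- lapply(split(seq_len(nrow(ct)), key), function(i) {
    sub <- ct[i, , drop = FALSE]
    if (nrow(sub) < 2) {
      stop("each (amplicon, replicate) needs at least 2 fractions", call. = FALSE)
    }
    m <- max(sub$ct)
    rel <- 2^(m - sub$ct)
    data.frame(amplicon = sub$amplicon, replicate = sub$replicate,
               fraction = sub$fraction, ct = sub$ct, rel_abundance = rel,
               percent = 100 * rel / sum(rel), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  per$fraction <- factor(per$fraction, levels = fraction_levels)
  agg_mean <- aggregate(percent ~ amplicon + fraction, per, mean)
  agg_sd <- aggregate(percent ~ amplicon + fraction, per,
                      function(x) if (length(x) > 1) sd(x) else NA_real_)
  agg_n <- aggregate(percent ~ amplicon + fraction, per, length)
  summary <- data.frame(amplicon = agg_mean$amplicon,
                        fraction = agg_mean$fraction,
                        mean_percent = agg_mean$percent,
                        sd_percent = agg_sd$percent, n = agg_n$percent)
  summary <- summary[order(summary$amplicon, summary$fraction), ]
  rownames(summary) <- NULL
  structure(list(per_replicate = per, summary = summary),
            class = "fraction_profile")
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat("<fraction_profile>\n")
  print(x$summary)
  invisible(x)
}

#' Background-subtracted dual-luciferase reporter ratios
#'
#' Subtracts the mean luminescence of untransfected background wells from
#' each channel, then computes per-replicate N-luc / F-luc ratios; replicates
#' whose background-subtracted F-luc is <= 0 are flagged excluded. The
#' per-condition summary is the mean and SD over included replicates.
#'
#' @param plate data.frame with `condition`, `replicate`, `nluc`, `fluc`,
#'   `is_background` (logical).
#' @return list with `per_replicate` (data.frame adds `ratio`, `excluded`)
#'   and `summary` (data.frame `condition`, `mean_ratio`, `sd_ratio`, `n`).
#' @export
reporter_ratios <- function(plate) {
  stopifnot(is.data.frame(plate),
            all(c("condition", "replicate", "nluc", "fluc", "is_background")
                %in% names(plate)))
  if (any(plate$nluc < 0 | plate$fluc < 0)) {
    stop("luminescence must be non-negative", call. = FALSE)
  }
  bg <- plate[plate$is_background, , drop = FALSE]
  if (nrow(bg) == 0) stop("no background wells present", call. = FALSE)
  bg_n <- mean(bg$nluc)
  bg_f <- mean(bg$fluc)
  wells <- plate[!plate$is_background, , drop = FALSE]
  fl <- wells$fluc - bg_f
  wells$ratio <- ifelse(fl > 0, (wells$nluc - bg_n) / fl, NA_real_)
  wells$excluded <- fl <= 0
  inc <- wells[!wells$excluded, , drop = FALSE]
  if (nrow(inc) == 0) stop("all replicates excluded", call. = FALSE)
  agg_mean <- aggregate(ratio ~ condition, inc, mean)
  agg_sd <- aggregate(ratio ~ condition, inc,
                      function(x) if (length(x) > 1) sd(x) else NA_real_)
  agg_n <- aggregate(ratio ~ condition, inc, length)
  summary <- data.frame(condition = agg_mean$condition,
                        mean_ratio = agg_mean$ratio, sd_ratio = agg_sd$ratio,
                        n = agg_n$ratio)
  list(per_replicate = wells, summary = summary)
}

#' Read / write the CSV exchange formats of the quant module
#'
#' CT tables: columns `amplicon`, `fraction`, `replicate`, `ct`, `is_ntc`.
#' Plates: columns `condition`, `replicate`, `nluc`, `fluc`, `is_background`.
#'
#' @param path CSV file path.
#' @param x data.frame to write.
#' @return data.frame (readers) or `path` invisibly (writer).
#' @export
read_ct_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"is_ntc" %in% names(df)) df$is_ntc <- FALSE
  df$is_ntc <- as.logical(df$is_ntc)
  df
}

#' @rdname read_ct_csv
#' @export
read_plate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$is_background <- as.logical(df$is_background)
  df
}

#' @rdname read_ct_csv
#' @export
write_quant_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
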