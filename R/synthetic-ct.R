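#' qPCR cycle-threshold simulator configuration
#'
#' CT values are log2-linked to known RNA abundances:
#' `CT = ct_at_unit_abundance - log2(abundance) + noise`.
#'
#' @param true_abundances named positive vector, one entry per gradient
#'   fraction (names are fraction labels in gradient order, e.g. `top`,
#'   `40S`, `60-80S`, `light`, `medium`, `heavy`).
#' @param ct_at_unit_abundance CT of an abundance-1 fraction (cycles).
#' @param replicate_noise_sd per-replicate Gaussian noise SD (cycles).
#' @param n_replicates technical replicates.
#' @param amplicon amplicon label.
#' @param seed integer seed.
#' @return object of class `ct_sim_config`.
#' @export
ct_sim_config <- function(true_abundances, ct_at_unit_abundance = 30,
                          replicate_noise_sd = 0, n_replicates = 1L,
                          amplicon = "amp1", seed = NULL) {
  stopifnot(length(true_abundances) > 0, all(true_abundances > 0),
            replicate_noise_sd >= 0, n_replicates >= 1)
  if (is.null(names(true_abundances))) {
    names(true_abundances) <- sprintf("fraction%02d", seq_along(true_abundances))
  }
  structure(list(true_abundances = true_abundances,
                 ct_at_unit_abundance = ct_at_unit_abundance,
                 replicate_noise_sd = replicate_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 amplicon = amplicon, seed = seed),
            class = "ct_sim_config")
}

#' Simulate a qPCR cycle-threshold table
#'
#' @param cfg a [ct_sim_config()].
#' @return data.frame (`amplicon`, `fraction`, `replicate`, `ct`, `is_ntc`)
#'   with fractions in the configured gradient order. Errors if any
#'   simulated CT falls outside `(0, 40]` (unrealistic configuration).
#' @export
simulate_ct <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  with_seed(cfg$seed, {
    fr <- names(cfg$true_abundances)
    grid <- expand.grid(fraction = fr, replicate = seq_len(cfg$n_replicates),
                        stringsAsFactors = FALSE)
    ct <- cfg$ct_at_unit_abundance -
      log2(cfg$true_abundances[grid$fraction]) +
      rnorm(nrow(grid), sd = cfg$replicate_noise_sd)
    if (any(ct <= 0 | ct > 40)) {
      stop("simulated CT outside (0, 40]: unrealistic configuration",
           call. = FALSE)
    }
    data.frame(amplicon = cfg$amplicon, fraction = grid$fraction,
               replicate = grid$replicate, ct = unname(ct), is_ntc = FALSE,
               stringsAsFactors = FALSE)
  })
}
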