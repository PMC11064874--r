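#' Define an experiment matrix
#'
#' Describes a grid of denoising runs: synthetic fixtures (or input files)
#' crossed with noise kinds, input SNR levels, replicate seeds and methods.
#'
#' @param signals List of [ecg_spec]s (or a single one).
#' @param noise_kinds Character subset of the five noise kinds.
#' @param snr_levels_db Input SNR levels in dB (default `c(0, 5, 10)`).
#' @param n_seeds Number of replicate noise realisations per cell
#'   (default 10).
#' @param base_seed First replicate seed; replicate `i` uses
#'   `base_seed + i - 1` (default 1).
#' @param methods Subset of `c("proposed", "wt", "nlm1d")`.
#' @param config Optional [pipeline_config] for the proposed method.
#' @return An `experiment_matrix` list.
#' @export
experiment_matrix <- function(signals = list(ecg_spec()),
                              noise_kinds = c("pli", "gaussian",
                                              "baseline_wander",
                                              "muscle_artifact",
                                              "electrode_motion"),
                              snr_levels_db = c(0, 5, 10),
                              n_seeds = 10L, base_seed = 1L,
                              methods = c("proposed", "wt", "nlm1d"),
                              config = pipeline_config()) {
  if (inherits(signals, "ecg_spec")) signals <- list(signals)
  if (!length(signals) || !all(vapply(signals, inherits, TRUE, "ecg_spec")))
    stop_invalid_param("`signals` must be a non-empty list of ecg_spec")
  kinds_ok <- c("pli", "gaussian", "baseline_wander", "muscle_artifact",
                "electrode_motion")
  if (!length(noise_kinds) || !all(noise_kinds %in% kinds_ok))
    stop_invalid_param("`noise_kinds` must be a non-empty subset of the five kinds")
  if (!length(snr_levels_db) || !all(is.finite(snr_levels_db)))
    stop_invalid_param("`snr_levels_db` must be finite dB values")
  if (!is_scalar_num(n_seeds) || n_seeds < 1)
    stop_invalid_param("`n_seeds` must be >= 1")
  methods_ok <- c("proposed", "wt", "nlm1d")
  if (!length(methods) || !all(methods %in% methods_ok))
    stop_invalid_param("`methods` must be a non-empty subset of proposed/wt/nlm1d")
  structure(list(signals = signals, noise_kinds = unique(noise_kinds),
                 snr_levels_db = snr_levels_db,
                 n_seeds = as.integer(n_seeds),
                 base_seed = as.integer(base_seed),
                 methods = unique(methods), config = config),
            class = "experiment_matrix")
}

#' Run an experiment matrix
#'
#' For every (signal, noise kind, SNR level, seed, method) cell:
#' generate the clean fixture and the seeded noise realisation, mix at the
#' exact input SNR, denoise, and score against the clean reference.  Cell
#' failures are recorded and skipped.  Deterministic given the seed list.
#'
#' @param matrix An [experiment_matrix].
#' @param verbose Print one line per cell (default `FALSE`).
#' @return List with `cells` (one row per cell: identifiers + metrics),
#'   `summary` (mean and sd over seeds per signal x kind x level x method),
#'   and `failures` (data frame of failed cells, possibly empty).
#' @export
run_experiment <- function(matrix, verbose = FALSE) {
  stopifnot(inherits(matrix, "experiment_matrix"))
  cells <- list(); failures <- list()
  for (si in seq_along(matrix$signals)) {
    espec <- matrix$signals[[si]]
    for (kind in matrix$noise_kinds) {
      for (level in matrix$snr_levels_db) {
        for (rep_i in seq_len(matrix$n_seeds)) {
          seed <- matrix$base_seed + rep_i - 1L
          espec_i <- espec
          espec_i$seed <- seed
          clean <- gen_ecg(espec_i)
          nspec <- noise_spec(kind, target_snr_db = level,
                              seed = seed + 10000L)
          nz <- gen_noise(nspec, length(clean$samples), clean$fs)
          noisy <- add_noise_at_snr(clean, nz, level)$noisy
          for (method in matrix$methods) {
            if (verbose)
              message(sprintf("signal %d | %s | %g dB | seed %d | %s",
                              si, kind, level, seed, method))
            est <- tryCatch(
              switch(method,
                     proposed = st_denoise(noisy, matrix$config)$signal,
                     wt = wt_denoise(noisy),
                     nlm1d = nlm1d_denoise(noisy)),
              error = function(e) e)
            if (inherits(est, "error")) {
              failures[[length(failures) + 1L]] <-
                data.frame(signal = si, noise = kind, snr_in_db = level,
                           seed = seed, method = method,
                           message = conditionMessage(est))
              next
            }
            cells[[length(cells) + 1L]] <- cbind(
              data.frame(signal = si, noise = kind, snr_in_db = level,
                         seed = seed, method = method),
              metrics_report(clean, est))
          }
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(signal = integer(0), noise = character(0),
               snr_in_db = numeric(0), seed = integer(0),
               method = character(0), message = character(0))
  summary <- aggregate_cells(cells)
  list(cells = cells, summary = summary, failures = failures)
}

aggregate_cells <- function(cells) {
  if (is.null(cells) || !nrow(cells)) return(NULL)
  keys <- c("signal", "noise", "snr_in_db", "method")
  metrics <- c("snr_db", "rmse", "prd", "ssim")
  agg_mean <- stats::aggregate(cells[metrics], cells[keys], mean)
  agg_sd <- stats::aggregate(cells[metrics], cells[keys], sd)
  names(agg_mean)[match(metrics, names(agg_mean))] <-
    paste0(metrics, "_mean")
  names(agg_sd)[match(metrics, names(agg_sd))] <- paste0(metrics, "_sd")
  out <- merge(agg_mean, agg_sd, by = keys, sort = TRUE)
  out[order(out$signal, out$noise, out$snr_in_db, out$method), ]
}
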