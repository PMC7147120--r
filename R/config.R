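#' Frequency band specification
#'
#' Defines a band-pass filter band by its corner frequencies and its
#' transition bandwidths below and above the passband. The canonical bands
#' of slow cortical activity are available through [canonical_bands()]:
#' delta 1-4 Hz (transitions 1 Hz low / 2 Hz high), theta 4-8 Hz
#' (2 Hz / 2 Hz) and wideband 1-20 Hz (1 Hz / 5 Hz).
#'
#' @param name band name, one of `"delta"`, `"theta"`, `"wide"`.
#' @param f_lo,f_hi lower and upper corner frequencies in Hz.
#' @param tbw_lo,tbw_hi transition bandwidths in Hz below `f_lo` and above
#'   `f_hi`.
#'
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, f_lo, f_hi, tbw_lo, tbw_hi) {
  if (!(is.numeric(f_lo) && is.numeric(f_hi) && f_lo > 0 && f_lo < f_hi))
    stop("validation error: need 0 < f_lo < f_hi")
  if (tbw_lo <= 0 || tbw_hi <= 0)
    stop("validation error: transition bandwidths must be positive")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi,
                 tbw_lo = tbw_lo, tbw_hi = tbw_hi),
            class = "band_spec")
}

#' Canonical analysis bands
#'
#' @param which optional subset of band names.
#' @return A named list of [band_spec()] objects (delta, theta, wide).
#' @export
canonical_bands <- function(which = c("delta", "theta", "wide")) {
  all <- list(
    delta = band_spec("delta", 1, 4, 1, 2),
    theta = band_spec("theta", 4, 8, 2, 2),
    wide  = band_spec("wide", 1, 20, 1, 5))
  all[match.arg(which, several.ok = TRUE)]
}

#' Analysis configuration
#'
#' Bundles every tunable of the decoding pipeline with the canonical
#' defaults: decoder lags from -100 ms to +400 ms, processing rate 64 Hz,
#' five-fold cross-validation on 10-s scoring segments, and a sweep of 50
#' log-spaced ridge parameters from 1e-15 to 1e15.
#'
#' @param bands list of [band_spec()] objects.
#' @param lag_window numeric length-2, decoder lag window in seconds
#'   (EEG delay relative to the stimulus).
#' @param target_fs processing sampling rate in Hz after downsampling.
#' @param n_folds number of cross-validation folds.
#' @param segment_length scoring-segment length in seconds.
#' @param lambda_grid strictly increasing positive ridge parameters.
#' @param alpha significance level for response detection.
#' @param seed integer seed for any stochastic step.
#' @param scalp_only if `TRUE` (default) only the scalp channels enter the
#'   decoder and mastoid channels (labels `M1`/`M2`) are dropped after
#'   average referencing.
#' @param valid_rows_only if `TRUE`, restrict ridge training to rows whose
#'   full lag span lies inside the recording (default keeps all rows with
#'   zero-filled out-of-range lags).
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(bands = canonical_bands(),
                            lag_window = c(-0.100, 0.400),
                            target_fs = 64,
                            n_folds = 5L,
                            segment_length = 10,
                            lambda_grid = 10^seq(-15, 15, length.out = 50),
                            alpha = 0.05,
                            seed = 1L,
                            scalp_only = TRUE,
                            valid_rows_only = FALSE) {
  if (inherits(bands, "band_spec")) bands <- list(bands)
  stopifnot(lag_window[1L] < lag_window[2L], segment_length > 0,
            n_folds >= 2L, target_fs > 0)
  if (any(lambda_grid <= 0) || is.unsorted(lambda_grid, strictly = TRUE))
    stop("validation error: lambda_grid must be strictly increasing and positive")
  structure(list(bands = bands, lag_window = as.numeric(lag_window),
                 target_fs = target_fs, n_folds = as.integer(n_folds),
                 segment_length = segment_length, lambda_grid = lambda_grid,
                 alpha = alpha, seed = as.integer(seed),
                 scalp_only = isTRUE(scalp_only),
                 valid_rows_only = isTRUE(valid_rows_only)),
            class = "analysis_config")
}

#' Read / write an analysis configuration file
#'
#' Configurations are stored as YAML with nested sections mirroring the
#' fields of [analysis_config()]; bands are stored as a named section of
#' `(f_lo, f_hi, tbw_lo, tbw_hi)` records.
#'
#' @param cfg an `analysis_config`.
#' @param path file path.
#' @return `read_config` returns an `analysis_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  lst <- unclass(cfg)
  lst$bands <- lapply(cfg$bands, function(b) unclass(b)[-1L])
  names(lst$bands) <- vapply(cfg$bands, `[[`, "", "name")
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  bands <- lapply(names(lst$bands), function(nm) {
    b <- lst$bands[[nm]]
    band_spec(nm, b$f_lo, b$f_hi, b$tbw_lo, b$tbw_hi)
  })
  names(bands) <- names(lst$bands)
  analysis_config(bands = bands,
                  lag_window = unlist(lst$lag_window),
                  target_fs = lst$target_fs, n_folds = lst$n_folds,
                  segment_length = lst$segment_length,
                  lambda_grid = unlist(lst$lambda_grid), alpha = lst$alpha,
                  seed = lst$seed, scalp_only = lst$scalp_only,
                  valid_rows_only = lst$valid_rows_only)
}
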