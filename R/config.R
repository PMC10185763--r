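# Pipeline configuration: defaults, JSON round trip, validation.

#' Default pipeline configuration
#'
#' Nested list of all tunable parameters with their documented defaults:
#'
#' * `bands`: `include_gamma` (add canonical gamma to the phase bands,
#'   default `FALSE`), `include_low` (add each rhythm's own low-frequency
#'   signal to its mixed filter-bank output, default `FALSE`).
#' * `filter`: `order` — Butterworth order, applied forward-backward.
#' * `erpac`: amplitude scan grid (`grid_lo`/`grid_hi` range in Hz,
#'   `grid_step` center spacing, `grid_halfwidth` half bandwidth of each
#'   bin) and `time_step_s`, the decimation step of the coupling time axis.
#' * `selection`: `bw` half width in Hz of each selected interval
#'   (`[p - bw, p + bw]`), `n_peaks` intervals kept per rhythm,
#'   `compression` (`"max"` or `"mean"` over the time axis),
#'   Savitzky-Golay smoothing `sg_window` (odd bin count) and
#'   `sg_polyorder`, and `merge_overlaps`.
#' * `decoder`: split-branch convolutional classifier hyperparameters
#'   (see [build_pacnet()]).
#' * `cv`: `k` folds and `repeats`.
#' * `seed`: base random seed.
#'
#' @return An object of class `pipeline_config`.
#' @export
default_config <- function() {
  cfg <- list(
    bands = list(include_gamma = FALSE, include_low = FALSE),
    filter = list(order = 4L, pad = "lp"),
    erpac = list(grid_lo = 70, grid_hi = 200, grid_step = 2,
                 grid_halfwidth = 10, time_step_s = 0.010),
    selection = list(bw = 10, n_peaks = 2L, compression = "max",
                     sg_window = 11L, sg_polyorder = 3L,
                     merge_overlaps = FALSE),
    decoder = list(n_branches = 4L, f1 = 8L, depth_mult = 2L, f2 = 16L, kernel = NULL,
                   kernel_len2 = 16L, pool1 = 4L, pool2 = 8L,
                   dropout = 0.5, n_classes = 2L, lr = 1e-3,
                   batch = 16L, epochs = 300L, patience = 30L,
                   val_fraction = 0.2),
    cv = list(k = 10L, repeats = 5L),
    seed = 1L
  )
  class(cfg) <- "pipeline_config"
  cfg
}

.config_check <- function(cond, msg) if (!cond) stop("invalid config: ", msg)

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and out-of-range values.
#'
#' @param cfg A configuration list.
#' @return `cfg`, invisibly, with class `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  ref <- unclass(default_config())
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra)) stop("unknown configuration key: ", extra[1])
  for (sec in setdiff(names(ref), "seed")) {
    bad <- setdiff(names(cfg[[sec]]), names(ref[[sec]]))
    if (length(bad))
      stop("unknown configuration key: ", sec, ".", bad[1])
  }
  b <- cfg$bands; fl <- cfg$filter; e <- cfg$erpac; s <- cfg$selection
  d <- cfg$decoder; cv <- cfg$cv
  .config_check(is.logical(b$include_gamma) && is.logical(b$include_low),
                "bands flags must be logical")
  .config_check(fl$order >= 1 && fl$order == round(fl$order),
                "filter.order must be a positive integer")
  .config_check(fl$pad %in% c("lp", "reflect"),
                "filter.pad must be 'lp' or 'reflect'")
  .config_check(e$grid_lo > 0 && e$grid_hi > e$grid_lo,
                "erpac grid range must satisfy 0 < grid_lo < grid_hi")
  .config_check(e$grid_step > 0 && e$grid_halfwidth > 0,
                "erpac.grid_step and grid_halfwidth must be > 0")
  .config_check(e$time_step_s > 0, "erpac.time_step_s must be > 0")
  .config_check(s$bw > 0, "selection.bw must be > 0")
  .config_check(s$n_peaks >= 1, "selection.n_peaks must be >= 1")
  .config_check(s$compression %in% c("max", "mean"),
                "selection.compression must be 'max' or 'mean'")
  .config_check(s$sg_window %% 2 == 1 && s$sg_window > s$sg_polyorder,
                "selection.sg_window must be odd and exceed sg_polyorder")
  .config_check(d$n_branches >= 1, "decoder.n_branches must be >= 1")
  .config_check(d$f1 >= 1 && d$depth_mult >= 1 && d$f2 >= 1,
                "decoder filter counts must be >= 1")
  .config_check(d$dropout >= 0 && d$dropout < 1,
                "decoder.dropout must be in [0, 1)")
  .config_check(d$n_classes >= 2, "decoder.n_classes must be >= 2")
  .config_check(d$lr > 0 && d$epochs >= 1 && d$batch >= 1 && d$patience >= 1,
                "decoder optimiser settings out of range")
  .config_check(d$pool1 >= 1 && d$pool2 >= 1, "decoder pooling must be >= 1")
  .config_check(is.null(d$kernel) || (is.numeric(d$kernel) && d$kernel >= 4),
                "decoder.kernel must be NULL or >= 4 samples")
  .config_check(d$kernel_len2 >= 2, "decoder.kernel_len2 must be >= 2")
  .config_check(d$val_fraction > 0 && d$val_fraction < 1,
                "decoder.val_fraction must be in (0, 1)")
  .config_check(cv$k >= 2 && cv$repeats >= 1, "cv.k >= 2 and cv.repeats >= 1")
  .config_check(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
                "seed must be a single number")
  class(cfg) <- "pipeline_config"
  invisible(cfg)
}

.merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop("configuration section ", full, " must be an object")
      base[[key]] <- .merge_config(base[[key]], override[[key]], full)
    } else {
      val <- override[[key]]
      if (is.list(val)) val <- unlist(val)
      if (is.null(val)) base[key] <- list(NULL) else base[[key]] <- val
    }
  }
  base
}

#' Load a pipeline configuration from JSON
#'
#' Unspecified fields take their documented defaults; unknown keys are
#' rejected rather than silently ignored; the full effective configuration
#' is echoed via `message()`. Loading is idempotent:
#' `load(save(load(x))) == load(x)`.
#'
#' @param path Path to a JSON document (`{}` yields all defaults).
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- .merge_config(unclass(default_config()), as.list(user))
  cfg <- validate_config(cfg)
  message("effective config: ",
          jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"))
  cfg
}

#' Save a pipeline configuration to JSON
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE,
                       null = "null"), "\n")
  invisible(x)
}

# Short stable fingerprint of a configuration, recorded in results for
# provenance.
.config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null",
                          digits = NA)
  sum(utf8ToInt(as.character(txt)) * seq_len(nchar(txt))) %% 2147483647L
}
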