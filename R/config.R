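CONFIG_DEFAULTS <- list(
  rate_hz = 50,
  window_s = 1.0,
  overlap = 0.5,
  gravity_cutoff_hz = 0.3,
  butter_order = 3L,
  kmeans_max_iter = 100L,
  llof_k = 20L,
  llof_eps1 = 1.5,
  eps2_percentile = 1,
  eps3_deg = 60,
  split_frac = 0.8,
  seed = 1L
)

#' Pipeline configuration
#'
#' All tunables of the pipeline in one validated object. Defaults are the
#' supported protocol: 50 Hz sampling, 1-s windows with 50% overlap,
#' 0.3-Hz 3rd-order gravity filter, up to 100 K-Means iterations, LLOF
#' with 20 neighbors and threshold 1.5, the 1st-percentile vigorous
#' density for `eps2`, a 60-degree tilt threshold, and the 4:1 (0.8)
#' train/test split. Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults listed above.
#' @return object of class `har_config` (a named list).
#' @export
har_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(!nzchar(names(overrides)))))
    stop("all config overrides must be named")
  unknown <- setdiff(names(overrides), names(CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, overrides)
  validate_config(cfg)
  structure(cfg, class = "har_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(cfg$rate_hz > 0, "rate_hz must be > 0")
  chk(cfg$window_s > 0, "window_s must be > 0")
  chk(cfg$overlap >= 0 && cfg$overlap < 1,
      "overlap must be in [0, 1) (overlap 1 gives a zero hop)")
  chk(round(cfg$window_s * cfg$rate_hz * (1 - cfg$overlap)) >= 1,
      "window hop rounds to zero; decrease overlap")
  chk(cfg$gravity_cutoff_hz > 0 && cfg$gravity_cutoff_hz < cfg$rate_hz / 2,
      "gravity_cutoff_hz must lie in (0, rate_hz/2)")
  chk(cfg$butter_order >= 1, "butter_order must be >= 1")
  chk(cfg$kmeans_max_iter >= 1, "kmeans_max_iter must be >= 1")
  chk(cfg$llof_k >= 1, "llof_k must be >= 1")
  chk(cfg$llof_eps1 > 0, "llof_eps1 must be > 0")
  chk(cfg$eps2_percentile >= 0 && cfg$eps2_percentile <= 100,
      "eps2_percentile must be in [0, 100]")
  chk(cfg$eps3_deg > 0, "eps3_deg must be > 0")
  chk(cfg$split_frac > 0 && cfg$split_frac < 1,
      "split_frac must be in (0, 1)")
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML key/value file and merges it over the defaults; unknown
#' keys or invalid values abort with the offending keys named. With
#' `path = NULL` the defaults are returned unchanged.
#'
#' @param path path to a YAML file, or `NULL` for defaults.
#' @return a [har_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(har_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(har_config, vals)
}

#' Hash of the effective configuration
#'
#' 32-bit FNV-1a over the canonical `key=value` rendering, reported as
#' 8 hex digits. Every artifact the pipeline writes embeds this hash so
#' that later stages can refuse to mix artifacts produced under
#' different settings.
#'
#' @param config a [har_config()].
#' @return an 8-character hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "har_config"))
  keys <- sort(names(CONFIG_DEFAULTS))
  canon <- paste(keys, vapply(config[keys], function(v)
    sprintf("%.10g", as.numeric(v)), character(1L)),
    sep = "=", collapse = ";")
  bytes <- utf8ToInt(canon)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte (b < 256), arithmetic elsewhere: keeps h a
    # double so the 32-bit modular multiply below stays exact
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}
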