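#' Load the application configuration
#'
#' The YAML configuration bundles every component's settings: phantom
#' geometry, scan parameters, fiducial boards (needle marker and phantom
#' reference), camera intrinsics, needle geometry, hit tolerance, seed and
#' log level. Keys omitted from the file keep their defaults; unknown keys
#' are rejected.
#'
#' @param path YAML file path, or `NULL` for the built-in defaults.
#' @return An object of class `app_config`: list with elements `seed`,
#'   `log_level`, `hit_tolerance_mm`, `phantom` ([phantom_config()]),
#'   `scan` ([scan_params()]), `needle_board` and `reference_board`
#'   ([board_model()]), `camera` ([camera_model()]), `needle`
#'   ([needle_model()]).
#' @export
load_app_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_ct("config_error", "config file '%s' does not exist", path)
    }
    raw <- tryCatch(yaml::read_yaml(path),
                    error = function(e) abort_ct(
                      "config_error", "failed to parse YAML '%s': %s",
                      path, conditionMessage(e)))
    if (is.null(raw)) raw <- list()
    if (!is.list(raw)) {
      abort_ct("config_error", "config '%s' must be a YAML mapping", path)
    }
  }
  known <- c("seed", "log_level", "hit_tolerance_mm", "phantom", "scan",
             "needle_board", "reference_board", "camera", "needle")
  reject_unknown(raw, known, "top level")

  seed <- raw$seed %||% 1L
  log_level <- raw$log_level %||% "info"
  if (!log_level %in% c("debug", "info", "warn", "error")) {
    abort_ct("config_error", "log_level must be debug/info/warn/error")
  }
  hit_tol <- raw$hit_tolerance_mm %||% 0
  if (hit_tol < 0) abort_ct("config_error", "hit_tolerance_mm must be >= 0")

  cfg_err <- function(e) abort_ct("config_error", conditionMessage(e))
  structure(list(
    seed = as.integer(seed),
    log_level = log_level,
    hit_tolerance_mm = hit_tol,
    phantom = tryCatch(phantom_from_yaml(raw$phantom, seed),
                       ctbiopsim_error = cfg_err),
    scan = tryCatch(call_with(scan_params, raw$scan, "scan"),
                    ctbiopsim_error = cfg_err),
    needle_board = tryCatch(
      call_with(board_model, raw$needle_board, "needle_board"),
      ctbiopsim_error = cfg_err),
    reference_board = tryCatch(
      call_with(board_model,
                raw$reference_board %||%
                  list(squares_x = 8, squares_y = 10, square_size = 15),
                "reference_board"),
      ctbiopsim_error = cfg_err),
    camera = tryCatch(call_with(camera_model, raw$camera, "camera"),
                      ctbiopsim_error = cfg_err),
    needle = tryCatch(call_with(needle_model, raw$needle, "needle"),
                      ctbiopsim_error = cfg_err)
  ), class = "app_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reject_unknown <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) {
    abort_ct("config_error", "unknown config key(s) at %s: %s",
             where, paste(extra, collapse = ", "))
  }
}

call_with <- function(fn, args, where) {
  args <- args %||% list()
  reject_unknown(args, names(formals(fn)), where)
  do.call(fn, args)
}

phantom_from_yaml <- function(ph, seed) {
  ph <- ph %||% list()
  reject_unknown(ph, names(formals(phantom_config)), "phantom")
  if (!is.null(ph$lesions)) {
    ph$lesions <- lapply(ph$lesions, function(l) {
      l$centroid <- as.numeric(unlist(l$centroid))
      if (is.null(l$hu)) l$hu <- 60
      l
    })
  }
  if (is.null(ph$seed)) ph$seed <- as.integer(seed)
  do.call(phantom_config, ph)
}
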