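#' Default configuration
#'
#' Reads the package's default YAML configuration: acquisition constants
#' (TR 2000 ms, TE 30 ms, 1024 points, 1200 Hz, 128 averages), voxel
#' geometries, phantom concentration (20 mM), relaxation times and
#' temperatures, simulator peak model, fitting defaults, calibration and
#' cohort cell parameters, and the runner-panel sigmoid truth.
#'
#' @return a nested named list.
#' @examples
#' cfg <- defaultConfig()
#' cfg$acquisition$repetition_time_ms
#' @export
defaultConfig <- function() {
  path <- system.file("extdata", "default_config.yaml", package = "carnotype",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it (recursively) over the package
#' defaults, so a user file only needs to state what differs.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return a nested named list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  .mergeConfig(cfg, yaml::read_yaml(path))
}

.mergeConfig <- function(base, override) {
  if (!is.list(override)) return(override)
  if (!is.list(base) || is.null(names(override))) return(override)
  for (k in names(override)) {
    base[[k]] <- if (k %in% names(base))
      .mergeConfig(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

# Acquisition block -> plain list used by simulateFID()
.acqFromConfig <- function(config) {
  a <- config$acquisition
  need <- c("repetition_time_ms", "echo_time_ms", "n_points", "bandwidth_hz",
            "n_averages", "transmitter_frequency_mhz", "reference_ppm")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop("acquisition config is missing: ", paste(miss, collapse = ", "))
  a
}

.voxelFromConfig <- function(dims) {
  if (length(dims) != 3L) stop("voxel dimensions must have 3 elements (mm)")
  VoxelGeometry(dims[[1]], dims[[2]], dims[[3]])
}

# Evaluate a function with a locally seeded RNG, restoring the caller's
# RNG state afterwards. seed = NULL leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
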