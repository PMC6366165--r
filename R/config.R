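#' Load and save run configurations
#'
#' A run configuration is a flat declarative key-value (YAML) file holding
#' the model constants and landscape controls with the study defaults:
#' 250-step stopping point, cohorts of 2500, 90-degree maximum turn,
#' 180-degree perceptual arc, foraging speed 0.1 and gain 1, top-15\%
#' forage percentile, 100 x 100 grid.  Unknown keys are rejected; an empty
#' file yields the full defaults.
#'
#' @param path File path.
#' @return `load_config()` returns a `run_config` list with `landscape`
#'   ([landscape_params()]), `sim` ([sim_config()]), `traits`
#'   ([trait_set()]) and `seed`.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path, call. = FALSE)
  if (is.null(raw)) raw <- list()
  known <- c(names(formals(landscape_params)),
             names(formals(sim_config)),
             setdiff(names(formals(trait_set)), "validate"), "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pick <- function(fn) {
    keys <- intersect(names(raw), setdiff(names(formals(fn)), "validate"))
    do.call(fn, raw[keys])
  }
  structure(list(landscape = pick(landscape_params),
                 sim = pick(sim_config),
                 traits = pick(trait_set),
                 seed = if (!is.null(raw$seed)) as.integer(raw$seed) else 1L),
            class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config` object.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- c(unclass(config$landscape), unclass(config$sim),
            unclass(config$traits), list(seed = config$seed))
  yaml::write_yaml(flat, path)
  invisible(path)
}
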