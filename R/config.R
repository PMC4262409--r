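# Structured run configuration: YAML schema with defaults, strict validation
# (unknown keys rejected with their paths), and round-trip serialisation.

.config_defaults <- function() {
  list(
    grid = list(dim = 1L, cells = c(120L), delta = 0.01, courant = 0.5),
    scheme = "sfdtd",
    stages = "yoshida",
    boundary = "pec",
    n_steps = 100L,
    phantom = NULL,
    frequency = NULL,
    sources = list(),
    observers = list(),
    output_dir = "sfdtd-out"
  )
}

.check_unknown <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(paste(path, extra, sep = "/"), collapse = ", ")))
  }
}

# Resolve stage coefficients from a preset name or explicit lists.
resolve_stages <- function(stages) {
  if (is.character(stages)) {
    switch(stages,
           yoshida = yoshida_coefficients(),
           leapfrog = leapfrog_coefficients(),
           stop(sprintf("unknown stage preset '%s'", stages)))
  } else if (is.list(stages)) {
    .check_unknown(stages, c("c", "d", "p"), "stages")
    load_stage_coefficients(stages$c, stages$d, stages$p %||% 4L)
  } else {
    stop("`stages` must be a preset name or a list with c, d, p")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys (reporting their paths),
#' fills documented defaults, validates stage-coefficient identities and the
#' CFL condition, and returns the parsed configuration. All physical
#' quantities are SI: metres, seconds, Hz, V/m.
#'
#' @param path Path to a YAML file.
#' @return Object of class `run_config` with the normalized raw list
#'   (`$raw`), and parsed `grid` ([grid_spec()]), `coeffs`, `phantom`,
#'   `sources`, `scheme`, `boundary`, `n_steps`, `frequency`, `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  parse_config(raw)
}

#' @rdname load_config
#' @param raw A configuration list (as parsed from YAML).
#' @export
parse_config <- function(raw) {
  defaults <- .config_defaults()
  .check_unknown(raw, names(defaults), "")
  # top-level keys replace their defaults wholesale (modifyList would drop
  # unnamed list entries such as the sources array)
  cfg <- defaults
  for (nm in names(raw)) cfg[nm] <- list(raw[[nm]]) # keeps NULL-valued keys

  .check_unknown(cfg$grid, c("dim", "cells", "delta", "courant"), "grid")
  g <- utils::modifyList(defaults$grid, cfg$grid)
  if (!cfg$scheme %in% c("sfdtd", "fdtd22")) {
    stop("scheme: must be 'sfdtd' or 'fdtd22'")
  }
  coeffs <- if (cfg$scheme == "fdtd22") leapfrog_coefficients() else resolve_stages(cfg$stages)
  st <- if (cfg$scheme == "sfdtd") stencil_coefficients() else list(a1 = 1, a2 = 0)
  grid <- grid_spec(g$dim, unlist(g$cells), g$delta, g$courant, coeffs, st$a1, st$a2)

  if (!cfg$boundary %in% c("pec", "mur")) stop("boundary: must be 'pec' or 'mur'")
  if (cfg$n_steps < 1) stop("n_steps: must be >= 1")

  phantom <- NULL
  if (!is.null(cfg$phantom)) {
    allowed <- c("nx", "ny", "delta", "center", "r_uterus", "r_placenta",
                 "r_fetus", "layer_inner_radius", "layer_thickness",
                 "layer_angle", "layer_facing", "plasma_fp", "plasma_nu")
    .check_unknown(cfg$phantom, allowed, "phantom")
    phantom <- do.call(phantom_spec, cfg$phantom)
  }

  sources <- lapply(seq_along(cfg$sources), function(k) {
    s <- cfg$sources[[k]]
    kind <- s$kind %||% stop(sprintf("sources[%d]: missing 'kind'", k))
    s$kind <- NULL
    switch(kind,
           gaussian_hard = {
             .check_unknown(s, c("amplitude", "t0", "tau", "cell",
                                 "active_factor"), sprintf("sources[%d]", k))
             do.call(gaussian_source_spec, s)
           },
           sine_soft = {
             .check_unknown(s, c("amplitude", "frequency", "cell",
                                 "ramp_periods"), sprintf("sources[%d]", k))
             do.call(sine_soft_source_spec, s)
           },
           plane_wave = {
             .check_unknown(s, c("amplitude", "frequency", "ramp_periods"),
                            sprintf("sources[%d]", k))
             do.call(plane_wave_spec, s)
           },
           stop(sprintf("sources[%d]: unknown kind '%s'", k, kind)))
  })

  # normalized raw copy (defaults resolved) for provenance echo / round-trip
  norm <- cfg
  norm$grid <- g
  structure(
    list(raw = norm, grid = grid, coeffs = coeffs, scheme = cfg$scheme,
         boundary = cfg$boundary, n_steps = as.integer(cfg$n_steps),
         phantom = phantom, frequency = cfg$frequency, sources = sources,
         observers = cfg$observers, output_dir = cfg$output_dir),
    class = "run_config"
  )
}

#' Save a normalized configuration
#'
#' Writes the defaults-resolved configuration back to YAML; `load_config()`
#' of the written file parses to an identical configuration (round-trip
#' contract).
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> scheme %s, %d-D grid %s, %d steps, boundary %s\n",
              x$scheme, x$grid$dim, paste(x$grid$n, collapse = " x "),
              x$n_steps, x$boundary))
  invisible(x)
}
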