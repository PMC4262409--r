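# Concentric mother/fetus phantom: tissue dielectric database, parametric
# geometry, and material-map construction on the structured grid.

.tissues <- data.frame(
  name = c("uterus", "placenta", "fetus"),
  rho = c(1052, 1058, 987),
  eps_64 = c(92.19, 86.50, 42.68),
  sigma_64 = c(0.91, 0.95, 0.39),
  eps_128 = c(75.47, 73.19, 37.60),
  sigma_128 = c(0.961, 1.00, 0.412),
  stringsAsFactors = FALSE
)

#' Tissue dielectric properties at the MRI operating frequencies
#'
#' Built-in database of mass density, relative permittivity and conductivity
#' for the three phantom tissues (uterus, placenta, fetus) at 64 MHz (1.5 T)
#' and 128 MHz (3 T).
#'
#' @param frequency Operating frequency, Hz: one of `64e6` or `128e6`.
#' @return Named list, one entry per tissue, each a list with `eps_r`
#'   (relative permittivity, dimensionless), `sigma` (conductivity, S/m) and
#'   `rho` (mass density, kg/m^3).
#' @export
#' @examples
#' tissue_table(64e6)$fetus
tissue_table <- function(frequency) {
  if (!isTRUE(frequency %in% c(64e6, 128e6))) {
    stop("unsupported frequency: tissue properties are tabulated at 64e6 and 128e6 Hz")
  }
  suffix <- if (frequency == 64e6) "64" else "128"
  out <- lapply(seq_len(nrow(.tissues)), function(i) {
    list(
      eps_r = .tissues[[paste0("eps_", suffix)]][i],
      sigma = .tissues[[paste0("sigma_", suffix)]][i],
      rho = .tissues$rho[i]
    )
  })
  names(out) <- .tissues$name
  out
}

#' Parametric phantom geometry
#'
#' Concentric discs (fetus inside placenta inside uterus) centred on the grid,
#' plus an annular Drude-plasma protective arc facing the incident wave.
#' Defaults model a month-9 pregnancy on the full-resolution grid:
#' uterus/placenta/fetus radii 180/150/100 mm, 2 mm cells on a 450 x 450
#' domain, and a 2 cm plasma layer starting at 190 mm radius.
#'
#' @param nx,ny Grid size in cells.
#' @param delta Cell edge length, m.
#' @param center Phantom centre in metres, default the domain centre.
#' @param r_uterus,r_placenta,r_fetus Tissue radii, m (strictly decreasing).
#' @param layer_inner_radius Inner radius of the plasma annulus, m.
#' @param layer_thickness Radial thickness of the plasma layer, m.
#' @param layer_angle Angular extent of the plasma arc, degrees in \[0, 360);
#'   0 means no layer.
#' @param layer_facing Direction (degrees, anticlockwise from +x) of the arc
#'   centre; 180 faces an incident wave travelling towards +x.
#' @param plasma_fp,plasma_nu Plasma and collision frequencies, Hz.
#' @return Object of class `phantom_spec`.
#' @export
#' @examples
#' phantom_spec(nx = 225, ny = 225, delta = 4e-3)
phantom_spec <- function(nx = 450L, ny = 450L, delta = 2e-3,
                         center = NULL,
                         r_uterus = 0.180, r_placenta = 0.150, r_fetus = 0.100,
                         layer_inner_radius = 0.190, layer_thickness = 0.020,
                         layer_angle = 0, layer_facing = 180,
                         plasma_fp = 3e9, plasma_nu = 10e9) {
  if (!(r_fetus < r_placenta && r_placenta < r_uterus)) {
    stop("radii must be strictly nested: r_fetus < r_placenta < r_uterus")
  }
  if (layer_inner_radius < r_uterus) {
    stop("plasma layer must not overlap the uterus disc")
  }
  if (layer_angle < 0 || layer_angle >= 360) {
    stop("`layer_angle` must lie in [0, 360)")
  }
  if (is.null(center)) {
    center_units <- c(nx, ny) / 2
    center <- center_units * delta
  } else {
    center_units <- center / delta
  }
  r_outer <- layer_inner_radius + layer_thickness
  if (r_outer > min(center[1], center[2],
                    nx * delta - center[1], ny * delta - center[2])) {
    stop("geometry exceeds the grid: enlarge the domain or shrink the layer")
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), delta = delta,
         center = center, center_units = center_units,
         r_uterus = r_uterus, r_placenta = r_placenta, r_fetus = r_fetus,
         layer_inner_radius = layer_inner_radius,
         layer_thickness = layer_thickness,
         layer_angle = layer_angle, layer_facing = layer_facing,
         plasma_fp = plasma_fp, plasma_nu = plasma_nu),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d cells, delta = %g mm\n",
              x$nx, x$ny, 1e3 * x$delta))
  cat(sprintf("  radii (mm): uterus %g, placenta %g, fetus %g\n",
              1e3 * x$r_uterus, 1e3 * x$r_placenta, 1e3 * x$r_fetus))
  cat(sprintf("  plasma arc: %g deg facing %g deg, r in [%g, %g] mm, fp = %g GHz, nu = %g GHz\n",
              x$layer_angle, x$layer_facing,
              1e3 * x$layer_inner_radius,
              1e3 * (x$layer_inner_radius + x$layer_thickness),
              x$plasma_fp / 1e9, x$plasma_nu / 1e9))
  invisible(x)
}

# Classify points given in grid units (cell lengths) against the phantom.
# Working in units keeps the offsets from the centre exact (half-integers),
# so mirror-symmetric points classify identically even when they fall
# exactly on a tissue-boundary circle. Returns integer codes:
# 0 vacuum, 1 uterus, 2 placenta, 3 fetus, 4 plasma.
classify_units <- function(spec, xu, yu) {
  dx <- xu - spec$center_units[1]
  dy <- yu - spec$center_units[2]
  r <- sqrt(dx^2 + dy^2)
  ru <- spec$r_uterus / spec$delta
  rp <- spec$r_placenta / spec$delta
  rf <- spec$r_fetus / spec$delta
  kind <- integer(length(r))
  kind[r <= ru] <- 1L
  kind[r <= rp] <- 2L
  kind[r <= rf] <- 3L
  if (spec$layer_angle > 0) {
    # arc membership via the projection onto the facing direction:
    # |angle - facing| <= half  <=>  cos(angle - facing) >= cos(half).
    # cospi/sinpi keep axis-aligned facings exact, so ties at the arc edges
    # break identically for mirror-symmetric points.
    cphi <- cospi(spec$layer_facing / 180)
    sphi <- sinpi(spec$layer_facing / 180)
    proj <- dx * cphi + dy * sphi
    in_arc <- r >= spec$layer_inner_radius / spec$delta &
      r <= (spec$layer_inner_radius + spec$layer_thickness) / spec$delta &
      proj >= r * cospi(spec$layer_angle / 360)
    kind[in_arc] <- 4L
  }
  kind
}

# Classify arbitrary points (metres); thin wrapper over the unit-space
# classifier.
classify_points <- function(spec, x, y) {
  classify_units(spec, x / spec$delta, y / spec$delta)
}

.kind_levels <- c("vacuum", "uterus", "placenta", "fetus", "plasma")

# Material samples (eps_r, sigma, rho, kind code) for points classified
# against the phantom, at the given frequency. Coordinates in grid units.
material_at_units <- function(spec, frequency, xu, yu) {
  kind <- classify_units(spec, xu, yu)
  tt <- tissue_table(frequency)
  eps <- rep(1, length(kind))
  sig <- rep(0, length(kind))
  rho <- rep(0, length(kind))
  for (code in 1:3) {
    pr <- tt[[.kind_levels[code + 1L]]]
    sel <- kind == code
    eps[sel] <- pr$eps_r
    sig[sel] <- pr$sigma
    rho[sel] <- pr$rho
  }
  # plasma cells: instantaneous vacuum response, dispersion via the J current
  eps[kind == 4L] <- 1
  list(eps_r = eps, sigma = sig, rho = rho, kind = kind)
}

#' Build the per-cell material map for a phantom
#'
#' Classifies every cell centre by Euclidean distance from the phantom centre
#' (stair-cased, no partial-volume averaging) and fills per-cell relative
#' permittivity, conductivity, and mass density from the tissue table at the
#' requested frequency. Plasma cells are marked by kind; their dispersive
#' response is carried by the plasma current, not by `eps_r`.
#'
#' @param spec A [phantom_spec()].
#' @param frequency Operating frequency, Hz (64e6 or 128e6).
#' @return Object of class `material_map`: matrices `eps_r`, `sigma`, `rho`
#'   (`nx` x `ny`, cell centres), character-coded `kind` matrix, plasma
#'   parameters, and grid metadata.
#' @export
#' @examples
#' mm <- build_phantom(phantom_spec(nx = 101, ny = 101, delta = 8e-3,
#'                                  layer_angle = 60), 64e6)
#' table(mm$kind)
build_phantom <- function(spec, frequency) {
  stopifnot(inherits(spec, "phantom_spec"))
  xc <- seq_len(spec$nx) - 0.5
  yc <- seq_len(spec$ny) - 0.5
  pts <- expand.grid(x = xc, y = yc, KEEP.OUT.ATTRS = FALSE)
  mat <- material_at_units(spec, frequency, pts$x, pts$y)
  structure(
    list(
      eps_r = matrix(mat$eps_r, spec$nx, spec$ny),
      sigma = matrix(mat$sigma, spec$nx, spec$ny),
      rho = matrix(mat$rho, spec$nx, spec$ny),
      kind = matrix(.kind_levels[mat$kind + 1L], spec$nx, spec$ny),
      plasma_fp = spec$plasma_fp, plasma_nu = spec$plasma_nu,
      delta = spec$delta, nx = spec$nx, ny = spec$ny,
      frequency = frequency, spec = spec
    ),
    class = "material_map"
  )
}

#' @export
print.material_map <- function(x, ...) {
  cat(sprintf("<material_map> %d x %d cells at %g mm, frequency %g MHz\n",
              x$nx, x$ny, 1e3 * x$delta, x$frequency / 1e6))
  print(table(x$kind))
  invisible(x)
}
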