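#' Global vascular properties
#'
#' Blood and vessel-wall constants shared by every segment: blood viscosity
#' `nu` (J s m^-3), blood density `rho` (J s^2 m^-5), Young's modulus `E`
#' (J m^-3) and the wall-thickness fit coefficients `a`, `c` (dimensionless)
#' and `b`, `d` (m^-1) of the law `h = r (a e^{b r} + c e^{d r})`. The
#' defaults are the standard values used for the human arterial network.
#'
#' @param nu,rho,E,a,b,c,d Property values; see description for units.
#' @return A named list of class `bg_props`.
#' @export
#' @examples
#' vessel_properties()
vessel_properties <- function(nu = 0.004, rho = 1050, E = 0.4e6,
                              a = 0.2802, b = -505.3, c = 0.1324, d = -11.14) {
  stopifnot(nu > 0, rho > 0, E > 0)
  structure(list(nu = nu, rho = rho, E = E, a = a, b = b, c = c, d = d),
            class = "bg_props")
}

#' Arterial wall thickness from lumen radius
#'
#' Evaluates the empirical logarithmic-fit law
#' `h = r (a e^{b r} + c e^{d r})` relating wall thickness to radius.
#'
#' @param r Lumen radius in metres (vectorised, each `>= 0`).
#' @param props A [vessel_properties()] object.
#' @return Wall thickness in metres.
#' @export
#' @examples
#' wall_thickness(0.01)  # ~1.2 mm for a 1 cm vessel
wall_thickness <- function(r, props = vessel_properties()) {
  if (any(r < 0)) stop_bondnet("negative radius", "bondnet_domain")
  r * (props$a * exp(props$b * r) + props$c * exp(props$d * r))
}

#' Lumped segment parameters from vessel geometry
#'
#' Computes the three lumped mechanical parameters of a vessel segment from
#' its length `l` and radius `r` under Poiseuille flow and a thin elastic
#' wall:
#' \deqn{R = 8 \nu l / (\pi r^4), \quad I = \rho l / (\pi r^2), \quad
#'       C = 2 \pi r^3 l / (E h)}
#' with wall thickness `h` from [wall_thickness()]. All three scale linearly
#' in `l`; `R` falls as `r^-4`, `I` as `r^-2`, while `C` grows with `r`.
#'
#' @param geom A data frame (or list) with numeric columns `l` (length, m)
#'   and `r` (radius, m); rows are segments.
#' @param props A [vessel_properties()] object.
#' @return A tibble with one row per segment and columns `R` (J s m^-6),
#'   `I` (J s^2 m^-6), `C` (m^6 J^-1) and `h` (m).
#' @export
#' @examples
#' segment_params(data.frame(l = 0.1, r = 0.01))
segment_params <- function(geom, props = vessel_properties()) {
  l <- geom$l; r <- geom$r
  if (any(!is.finite(l)) || any(!is.finite(r)) || any(l <= 0) || any(r <= 0)) {
    stop_bondnet("nonpositive segment length or radius", "bondnet_domain")
  }
  h <- wall_thickness(r, props)
  tibble::tibble(
    R = 8 * props$nu * l / (pi * r^4),
    I = props$rho * l / (pi * r^2),
    C = 2 * pi * r^3 * l / (props$E * h),
    h = h
  )
}

#' Read a vessel geometry table
#'
#' Reads a delimited text file with columns `segment_id`, `kind`
#' (`initial`/`intermediate`/`terminal`), `length_m`, `radius_m` and
#' `parent_id` (empty or `NA` for the root).
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @return A tibble with the columns above.
#' @export
read_geometry <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("segment_id", "kind", "length_m", "radius_m", "parent_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_bondnet(paste0("geometry table missing column(s): ",
                        paste(missing, collapse = ", ")), "bondnet_io")
  }
  tibble::as_tibble(df[need])
}

#' Write a vessel geometry table
#'
#' @param geometry Tibble as returned by [read_geometry()].
#' @param path Output path (`.csv` comma, otherwise tab separated).
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(geometry, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read global vessel properties from JSON
#'
#' @param path JSON file with any of the keys `nu`, `rho`, `E`, `a`, `b`,
#'   `c`, `d`; absent keys take the [vessel_properties()] defaults.
#' @return A `bg_props` object.
#' @export
read_properties <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(vessel_properties, vals[intersect(names(vals),
                                            names(vessel_properties()))])
}
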