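#' The three vessel segment template kinds
#'
#' Every vessel in an open (acyclic) arterial tree can be built from three
#' reusable templates, according to its position: `initial` (adjacent to the
#' inflow source), `intermediate` (mid-network, branching or not) and
#' `terminal` (drains into a fixed venous pressure).
#'
#' @return Character vector of the template kinds.
#' @export
template_kinds <- function() c("initial", "intermediate", "terminal")

#' Instantiate a vessel segment template
#'
#' Builds a validated bond-graph module for one vessel segment. All three
#' templates share the core wiring: a one-junction carrying the viscous
#' resistance `R` and inertance `I` in series, feeding a zero-junction from
#' which a wall branch (a one-junction carrying the compliance `C` and an
#' optional series viscoelastic resistance) hangs.
#'
#' \describe{
#'   \item{initial}{a flow source `Sf` (the cardiac output, by default the
#'     external time function named by `inflow`) feeds the core through a
#'     leading zero-junction; the outlet zero-junction exposes
#'     `n_branch_ports` auxiliary flow ports `vx1..vxn` (unbound, value 0).}
#'   \item{intermediate}{the inlet one-junction exposes one auxiliary
#'     potential port `u_x`; the outlet zero-junction exposes
#'     `n_branch_ports` flow ports. The fixed port count is the a-priori
#'     maximum number of branches any segment may have (default 4).}
#'   \item{terminal}{inlet one-junction with `u_x`, then the zero-junction
#'     with the wall branch, then a one-junction carrying the terminal bed
#'     resistance and a potential source `Se` at the venous pressure. No flow
#'     ports.}
#' }
#'
#' When every port is left unbound the segment is a runnable model on its
#' own; binding ports at merge time couples it into a network without
#' touching its definition.
#'
#' @param kind One of [template_kinds()].
#' @param name Module name (namespace prefix once composed).
#' @param geom One-row data frame or list with `l` (m) and `r` (m).
#' @param props A [vessel_properties()] object.
#' @param n_branch_ports Number of auxiliary flow ports on the outlet
#'   zero-junction of non-terminal kinds (default 4, must be >= 1).
#' @param terminal_resistance Terminal-bed resistance (J s m^-6), terminal
#'   kind only. Default `3e8`, sized so that a few beds in parallel reproduce a systemic vascular resistance around 1.3e8 J s m-6 and physiological arterial pressures.
#' @param venous_pressure `Se` value (J m^-3), terminal kind only; default 0.
#' @param r_visc Length-2 numeric, viscoelastic wall resistances
#'   `c(R_A, R_B)` (J s m^-6); 0 disables the series resistor (default).
#' @param compliance_mode `"single"` (default: the full `C` in one wall
#'   branch) or `"split"` (two parallel half-compliance branches `C/2 + R_A`
#'   and `C/2 + R_B`; on initial segments branch A sits on the leading
#'   source junction and branch B on the outlet).
#' @param inflow Name of the external inflow time function bound to the
#'   `Sf` source of initial segments.
#' @return A `bg_module`.
#' @export
#' @examples
#' seg <- make_segment("intermediate", "aorta1", list(l = 0.1, r = 0.01))
#' sum(seg$ports$kind == "flow")  # 4 branch ports
make_segment <- function(kind, name, geom, props = vessel_properties(),
                         n_branch_ports = 4,
                         terminal_resistance = 3e8, venous_pressure = 0,
                         r_visc = c(0, 0),
                         compliance_mode = c("single", "split"),
                         inflow = "cardiac_inflow") {
  if (!kind %in% template_kinds()) {
    stop_bondnet(paste0("unknown template kind '", kind, "'"), "bondnet_template")
  }
  compliance_mode <- match.arg(compliance_mode)
  if (length(r_visc) == 1) r_visc <- c(r_visc, r_visc)
  par <- segment_params(tibble::tibble(l = geom$l, r = geom$r), props)
  if (kind != "terminal" && n_branch_ports < 1) {
    stop_bondnet("n_branch_ports must be >= 1 for non-terminal segments",
                 "bondnet_template")
  }

  comps <- dplyr::bind_rows(
    bg_component("R", "R", par$R, units = "J.s.m-6"),
    bg_component("I", "I", par$I, units = "J.s2.m-6")
  )
  juncs <- dplyr::bind_rows(
    bg_junction("j_in", "one"),
    bg_junction("j_out", "zero")
  )
  bonds <- dplyr::bind_rows(
    bg_bond("b_r", "j_in", "R"),
    bg_bond("b_i", "j_in", "I"),
    bg_bond("b_io", "j_in", "j_out")
  )
  ports <- NULL

  # wall branch factory: one-junction + compliance (+ optional series R)
  wall_branch <- function(tag, at, C_val, R_val) {
    jw <- paste0("j_wall", tag)
    out <- list(
      junctions = bg_junction(jw, "one"),
      components = bg_component(paste0("C", tag), "C", C_val, units = "m6.J-1"),
      bonds = dplyr::bind_rows(
        bg_bond(paste0("b_w", tag), at, jw),
        bg_bond(paste0("b_c", tag), jw, paste0("C", tag))
      )
    )
    if (R_val > 0) {
      out$components <- dplyr::bind_rows(
        out$components,
        bg_component(paste0("Rw", tag), "R", R_val, units = "J.s.m-6")
      )
      out$bonds <- dplyr::bind_rows(
        out$bonds, bg_bond(paste0("b_rw", tag), jw, paste0("Rw", tag))
      )
    }
    out
  }

  wall_at_default <- if (kind == "terminal") "j_mid" else "j_out"
  if (kind == "terminal") {
    juncs <- dplyr::bind_rows(juncs[juncs$id != "j_out", ],
                              bg_junction("j_mid", "zero"),
                              bg_junction("j_term", "one"))
    bonds <- dplyr::bind_rows(
      bg_bond("b_r", "j_in", "R"),
      bg_bond("b_i", "j_in", "I"),
      bg_bond("b_im", "j_in", "j_mid"),
      bg_bond("b_mt", "j_mid", "j_term"),
      bg_bond("b_rt", "j_term", "R_term"),
      bg_bond("b_se", "j_term", "Se")
    )
    comps <- dplyr::bind_rows(
      comps,
      bg_component("R_term", "R", terminal_resistance, units = "J.s.m-6"),
      bg_component("Se", "Se", venous_pressure, units = "J.m-3")
    )
  }

  # The initial segment always splits its compliance: half on the leading
  # source junction, half on the outlet. An ideal flow source in series with
  # an inertance through a storage-free junction is an index-2 constraint
  # (the source would pin the inertance state), so the inlet node of the
  # tree must be compliant; halving rather than duplicating keeps the
  # segment's total compliance at C.
  branches <- if (kind == "initial") {
    list(wall_branch("_a", "j_src", par$C / 2, r_visc[1]),
         wall_branch("_b", "j_out", par$C / 2, r_visc[2]))
  } else if (compliance_mode == "single") {
    list(wall_branch("", wall_at_default, par$C, r_visc[1]))
  } else {
    list(wall_branch("_a", wall_at_default, par$C / 2, r_visc[1]),
         wall_branch("_b", wall_at_default, par$C / 2, r_visc[2]))
  }
  for (br in branches) {
    juncs <- dplyr::bind_rows(juncs, br$junctions)
    comps <- dplyr::bind_rows(comps, br$components)
    bonds <- dplyr::bind_rows(bonds, br$bonds)
  }

  if (kind == "initial") {
    juncs <- dplyr::bind_rows(bg_junction("j_src", "zero"), juncs)
    comps <- dplyr::bind_rows(
      bg_component("Sf", "Sf", param_ref = inflow, units = "m3.s-1"),
      comps
    )
    bonds <- dplyr::bind_rows(
      bg_bond("b_sf", "Sf", "j_src"),
      bg_bond("b_si", "j_src", "j_in"),
      bonds
    )
  }

  if (kind %in% c("initial", "intermediate")) {
    ports <- purrr::map_dfr(seq_len(n_branch_ports), function(k) {
      bg_port(paste0("vx", k), "j_out", "flow")
    })
  }
  if (kind %in% c("intermediate", "terminal")) {
    ports <- dplyr::bind_rows(bg_port("u_x", "j_in", "potential"), ports)
  }

  m <- bg_module(name, comps, juncs, bonds, ports)
  m$meta$template <- kind
  m$meta$geometry <- list(l = geom$l, r = geom$r)
  m
}
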