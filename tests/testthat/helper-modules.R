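# Small hand-wired networks and matching utilities shared across the suite.

# Classic two-element windkessel: flow source into a compliant node that
# drains through a resistance to a fixed venous pressure. Closed form:
# q(t) = C R v0 (1 - exp(-t / (R C))), u_node = q / C -> R v0.
rc_module <- function(v0 = 1e-5, R = 1e5, C = 1e-9, Se = 0, with_I = NULL) {
  comps <- dplyr::bind_rows(
    bg_component("Sf", "Sf", v0, units = "m3.s-1"),
    bg_component("C", "C", C, units = "m6.J-1"),
    bg_component("R", "R", R, units = "J.s.m-6"),
    bg_component("Se", "Se", Se, units = "J.m-3")
  )
  bonds <- dplyr::bind_rows(
    bg_bond("b_sf", "Sf", "j0"),
    bg_bond("b_c", "j0", "C"),
    bg_bond("b_01", "j0", "j1"),
    bg_bond("b_r", "j1", "R"),
    bg_bond("b_se", "j1", "Se")
  )
  if (!is.null(with_I)) {
    comps <- dplyr::bind_rows(comps, bg_component("I", "I", with_I,
                                                  units = "J.s2.m-6"))
    bonds <- dplyr::bind_rows(bonds, bg_bond("b_i", "j1", "I"))
  }
  bg_module("wk", comps,
            dplyr::bind_rows(bg_junction("j0", "zero"), bg_junction("j1", "one")),
            bonds)
}

# Pure integrator: constant inflow into a single compliance.
single_c_module <- function(v0 = 1e-5, C = 1e-9) {
  bg_module("intgr",
    components = dplyr::bind_rows(
      bg_component("Sf", "Sf", v0, units = "m3.s-1"),
      bg_component("C", "C", C, units = "m6.J-1")
    ),
    junctions = bg_junction("j0", "zero"),
    bonds = dplyr::bind_rows(bg_bond("b1", "Sf", "j0"), bg_bond("b2", "j0", "C"))
  )
}

# Map reference (monolithic) ids onto composed ids: composition namespacing
# only prepends prefixes, so each monolithic id is a unique suffix.
match_by_suffix <- function(ids, refs) {
  vapply(refs, function(r) {
    hit <- ids[endsWith(ids, paste0(".", r)) | ids == r]
    if (length(hit) != 1) {
      stop("no unique suffix match for '", r, "'")
    }
    hit
  }, character(1))
}

# Max relative difference between composed and monolithic RHS over random
# state points (states matched by suffix).
rhs_max_rel_diff <- function(sys_comp, sys_mono, n_points = 100, seed = 1,
                             inflow = 3e-4, state_scale = 1e-5) {
  mids <- sys_mono$states$id
  cids <- match_by_suffix(sys_comp$states$id, mids)
  worst <- 0
  withr::with_seed(seed, {
    for (k in seq_len(n_points)) {
      s <- setNames(rnorm(length(mids), sd = state_scale), mids)
      fm <- evaluate_rhs(sys_mono, s, list(cardiac_inflow = inflow))
      sc <- setNames(as.numeric(s), cids)
      fc <- evaluate_rhs(sys_comp, sc[sys_comp$states$id],
                         list(cardiac_inflow = inflow))
      fmap <- setNames(as.numeric(fc[cids]), mids)
      d <- abs(fm[mids] - fmap) / pmax(1, abs(fm[mids]))
      worst <- max(worst, d)
    }
  })
  worst
}

# A three-segment chain (initial -> intermediate -> terminal), composed.
small_limb <- function(prefix = "") {
  geom <- tibble::tibble(
    segment_id = paste0(prefix, c("a", "b", "c")),
    kind = c("initial", "intermediate", "terminal"),
    length_m = c(0.1, 0.08, 0.05),
    radius_m = c(0.01, 0.007, 0.005),
    parent_id = c(NA, paste0(prefix, c("a", "b")))
  )
  sm <- segment_modules(geom)
  lump(sm$plan, sm$modules)
}
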