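#' Segment modules and a composition plan from a geometry table
#'
#' Instantiates one template module per geometry row and annotates the
#' coupling points: each parent-child edge gets a unique entity term
#' (`inlet_<child>`) carried by the parent's next free flow port and the
#' child's inlet junction flow, which is exactly what [suggest_mappings()]
#' needs to propose the coupling and [lump()] to execute it. A flat
#' left-to-right plan over the segments (parents before children) is
#' returned alongside.
#'
#' @param geometry Tibble with columns `segment_id`, `kind`, `length_m`,
#'   `radius_m`, `parent_id` (`NA` for the root).
#' @param props A [vessel_properties()] object.
#' @param ... Further options passed to [make_segment()].
#' @return A list with `modules` (named list of `bg_module`), `plan` (plan
#'   list) and `geometry`.
#' @export
segment_modules <- function(geometry, props = vessel_properties(), ...) {
  geometry <- tibble::as_tibble(geometry)
  mods <- list()
  port_used <- setNames(integer(nrow(geometry)), geometry$segment_id)
  for (i in seq_len(nrow(geometry))) {
    g <- geometry[i, ]
    m <- make_segment(g$kind, g$segment_id,
                      list(l = g$length_m, r = g$radius_m), props, ...)
    m <- annotate(m, "t", "time", "t")
    if (g$kind != "initial") {
      m <- annotate(m, "j_in.v", "flow", paste0("inlet_", g$segment_id))
    }
    mods[[g$segment_id]] <- m
  }
  for (i in seq_len(nrow(geometry))) {
    g <- geometry[i, ]
    if (is.na(g$parent_id)) next
    k <- port_used[[g$parent_id]] + 1L
    port_used[[g$parent_id]] <- k
    parent <- mods[[g$parent_id]]
    port_id <- paste0("vx", k)
    if (!port_id %in% parent$ports$id) {
      stop_bondnet(paste0("segment '", g$parent_id, "' has more children than ",
                          "branch ports"), "bondnet_fixture")
    }
    mods[[g$parent_id]] <- annotate(parent, port_id, "flow",
                                    paste0("inlet_", g$segment_id))
  }
  plan <- list(
    name = "network",
    children = purrr::map(geometry$segment_id, function(id) list(module = id))
  )
  list(modules = mods, plan = plan, geometry = geometry)
}

#' Deterministic five-segment toy arterial tree
#'
#' A fixed miniature network used throughout the tests: one initial root
#' (r = 0.01 m, l = 0.1 m), a bifurcating and a plain intermediate
#' (r = 0.007 m, l = 0.08 m) and two terminals (r = 0.005 m, l = 0.05 m),
#' fully annotated, with its 4-merge composition plan. Identical on every
#' call.
#'
#' @inheritParams segment_modules
#' @return As [segment_modules()].
#' @export
#' @examples
#' toy <- toy_tree()
#' length(toy$modules)       # 5
#' plan_size(toy$plan)$n_merges  # 4
toy_tree <- function(props = vessel_properties(), ...) {
  geometry <- tibble::tibble(
    segment_id = c("root", "bif", "mid", "t1", "t2"),
    kind = c("initial", "intermediate", "intermediate", "terminal", "terminal"),
    length_m = c(0.10, 0.08, 0.08, 0.05, 0.05),
    radius_m = c(0.010, 0.007, 0.007, 0.005, 0.005),
    parent_id = c(NA, "root", "bif", "bif", "mid")
  )
  out <- segment_modules(geometry, props, ...)
  out$plan$name <- "toy"
  out
}

#' Seed-reproducible random arterial tree
#'
#' Generates a random tree of vessel segments respecting a maximum branching
#' factor: the root is an initial segment, leaves are terminals, radii
#' shrink by a fixed child/parent ratio per generation and lengths follow a
#' fixed length/radius ratio. Geometry, modules, annotations and plan are
#' fully determined by the arguments (same seed, same tree); the seed is an
#' explicit argument, never global state.
#'
#' @param n_segments Total number of segments (>= 1).
#' @param max_branching Maximum children per segment; must not exceed the
#'   template's branch port count (4).
#' @param seed Integer seed.
#' @param root_radius Root radius, m.
#' @param radius_ratio Child/parent radius ratio per generation.
#' @param length_radius_ratio Segment length as a multiple of its radius.
#' @param props A [vessel_properties()] object.
#' @param ... Passed to [make_segment()].
#' @return As [segment_modules()].
#' @export
random_tree <- function(n_segments, max_branching = 2, seed = 1,
                        root_radius = 0.01, radius_ratio = 0.8,
                        length_radius_ratio = 10,
                        props = vessel_properties(), ...) {
  if (n_segments < 1) stop_bondnet("n_segments must be >= 1", "bondnet_fixture")
  if (max_branching < 1) {
    stop_bondnet("max_branching must be >= 1", "bondnet_fixture")
  }
  if (max_branching > 4) {
    stop_bondnet("max_branching exceeds the template branch port capacity (4)",
                 "bondnet_fixture")
  }
  parent <- rep(NA_integer_, n_segments)
  depth <- integer(n_segments)
  withr::with_seed(seed, {
    n_children <- integer(n_segments)
    for (i in seq_len(n_segments)[-1]) {
      open <- which(n_children[seq_len(i - 1)] < max_branching)
      p <- if (length(open) == 1) open else sample(open, 1)
      parent[i] <- p
      n_children[p] <- n_children[p] + 1L
      depth[i] <- depth[p] + 1L
    }
  })
  ids <- sprintf("s%02d", seq_len(n_segments))
  is_leaf <- !(seq_len(n_segments) %in% parent)
  kind <- ifelse(seq_len(n_segments) == 1, "initial",
                 ifelse(is_leaf, "terminal", "intermediate"))
  radius <- root_radius * radius_ratio^depth
  geometry <- tibble::tibble(
    segment_id = ids,
    kind = kind,
    length_m = length_radius_ratio * radius,
    radius_m = radius,
    parent_id = ifelse(is.na(parent), NA_character_, ids[parent])
  )
  out <- segment_modules(geometry, props, ...)
  out$plan$name <- paste0("rand", seed)
  out
}

# Internal wiring identical to the templates, but written independently of
# the merge machinery: one flat module with real bonds between parent outlet
# zero-junctions and child inlet one-junctions. Serves as the monolithic
# reference against which composed networks are checked.

#' Build a whole network monolithically
#'
#' Constructs the entire vessel tree as a single module with explicit bonds
#' between segments instead of port bindings. The composed (merged) network
#' and the monolithic one must generate ODE systems with identical dynamics;
#' the monolithic route is the reference for that equivalence.
#'
#' @inheritParams segment_modules
#' @param name Module name.
#' @param terminal_resistance,venous_pressure Terminal boundary parameters,
#'   as in [make_segment()].
#' @param inflow External inflow function name for the root `Sf`.
#' @return A `bg_module` with no ports.
#' @export
monolithic_tree <- function(geometry, props = vessel_properties(),
                            name = "mono", terminal_resistance = 3e8,
                            venous_pressure = 0, inflow = "cardiac_inflow") {
  comps <- list(); juncs <- list(); bonds <- list()
  add <- function(lst, x) c(lst, list(x))
  for (i in seq_len(nrow(geometry))) {
    g <- geometry[i, ]
    id <- g$segment_id
    par <- segment_params(tibble::tibble(l = g$length_m, r = g$radius_m), props)
    p <- function(x) paste0(id, ".", x)
    juncs <- add(juncs, bg_junction(p("j_in"), "one"))
    comps <- add(comps, bg_component(p("R"), "R", par$R, units = "J.s.m-6"))
    comps <- add(comps, bg_component(p("I"), "I", par$I, units = "J.s2.m-6"))
    bonds <- add(bonds, bg_bond(p("b_r"), p("j_in"), p("R")))
    bonds <- add(bonds, bg_bond(p("b_i"), p("j_in"), p("I")))
    hub <- if (g$kind == "terminal") p("j_mid") else p("j_out")
    juncs <- add(juncs, bg_junction(hub, "zero"))
    bonds <- add(bonds, bg_bond(p("b_io"), p("j_in"), hub))
    wall <- function(tag, at, C_val) {
      juncs <<- add(juncs, bg_junction(p(paste0("j_wall", tag)), "one"))
      comps <<- add(comps, bg_component(p(paste0("C", tag)), "C", C_val,
                                        units = "m6.J-1"))
      bonds <<- add(bonds, bg_bond(p(paste0("b_w", tag)), at,
                                   p(paste0("j_wall", tag))))
      bonds <<- add(bonds, bg_bond(p(paste0("b_c", tag)),
                                   p(paste0("j_wall", tag)),
                                   p(paste0("C", tag))))
    }
    if (g$kind == "initial") {
      # mirror the template: compliance split across source and outlet nodes
      juncs <- add(juncs, bg_junction(p("j_src"), "zero"))
      comps <- add(comps, bg_component(p("Sf"), "Sf", param_ref = inflow,
                                       units = "m3.s-1"))
      bonds <- add(bonds, bg_bond(p("b_sf"), p("Sf"), p("j_src")))
      bonds <- add(bonds, bg_bond(p("b_si"), p("j_src"), p("j_in")))
      wall("_a", p("j_src"), par$C / 2)
      wall("_b", p("j_out"), par$C / 2)
    } else {
      wall("", hub, par$C)
    }
    if (g$kind == "terminal") {
      juncs <- add(juncs, bg_junction(p("j_term"), "one"))
      comps <- add(comps, bg_component(p("R_term"), "R", terminal_resistance,
                                       units = "J.s.m-6"))
      comps <- add(comps, bg_component(p("Se"), "Se", venous_pressure,
                                       units = "J.m-3"))
      bonds <- add(bonds, bg_bond(p("b_mt"), p("j_mid"), p("j_term")))
      bonds <- add(bonds, bg_bond(p("b_rt"), p("j_term"), p("R_term")))
      bonds <- add(bonds, bg_bond(p("b_se"), p("j_term"), p("Se")))
    }
    if (!is.na(g$parent_id)) {
      bonds <- add(bonds, bg_bond(paste0("b_link.", g$parent_id, ".", id),
                                  paste0(g$parent_id, ".j_out"), p("j_in")))
    }
  }
  bg_module(name,
            dplyr::bind_rows(comps), dplyr::bind_rows(juncs),
            dplyr::bind_rows(bonds))
}

#' The shipped seven-subdivision composition plan
#'
#' Reads the hierarchical composition plan for the anatomically detailed
#' open-loop arterial network shipped with the package. Its top level holds
#' the seven lumped subdivisions (heart outflow, head and neck, trunk, and
#' the four limbs); the left limbs are composed once and mirrored to the
#' right by cloning. The leaf entries name representative segment module
#' files only — the full published topology and geometry are an optional
#' external input, so the shipped plan documents the hierarchy, not the
#' complete segment inventory.
#'
#' @return A plan list (see [read_plan()]).
#' @export
adan_plan <- function() {
  read_plan(system.file("extdata", "adan_open_loop_plan.json",
                        package = "bondnet"))
}
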