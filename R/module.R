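#' One-port bond-graph components
#'
#' Constructors for the rows of a module's component table. A component is a
#' one-port element attached to the network by exactly one bond:
#' \describe{
#'   \item{R}{viscous resistance, constitutive law `u = R v` (J s m^-6)}
#'   \item{C}{compliance, `u = q / C` with stored volume state `q` (m^6 J^-1)}
#'   \item{I}{inertance, `u = I dv/dt` with flow state `v` (J s^2 m^-6)}
#'   \item{Se}{source of potential, fixed `u` (J m^-3, may be 0 or negative)}
#'   \item{Sf}{source of flow, fixed `v` (m^3 s^-1) or a named time function}
#' }
#' `C` and `I` components carry a state (`<id>.q`, `<id>.v` respectively);
#' sources carry none. `param` must be positive for R, C and I.
#'
#' @param id Element identifier, unique within the module.
#' @param kind One of `"R"`, `"C"`, `"I"`, `"Se"`, `"Sf"`.
#' @param param Numeric parameter value, or `NA` when `param_ref` is given.
#' @param param_ref For `Sf` (or `Se`): the name of an externally supplied time
#'   function, or (after a source mapping) the name of another variable in the
#'   composed module whose value drives this source.
#' @param units Unit string recorded verbatim alongside the value.
#' @return A one-row tibble.
#' @export
#' @examples
#' bg_component("C", "C", 1.3e-9, units = "m6.J-1")
bg_component <- function(id, kind, param = NA_real_, param_ref = NA_character_,
                         units = NA_character_) {
  stopifnot(is.character(id), length(id) == 1)
  tibble::tibble(
    id = id, kind = kind, param = as.numeric(param),
    param_ref = param_ref, units = units,
    state_id = dplyr::case_when(
      kind == "C" ~ paste0(id, ".q"),
      kind == "I" ~ paste0(id, ".v"),
      TRUE ~ NA_character_
    )
  )
}

#' Junctions
#'
#' A `"zero"` junction shares a common potential `u` among its bonds and its
#' flows sum to zero (Kirchhoff current law analogue); a `"one"` junction
#' shares a common flow `v` and its potentials sum to zero. The junction's
#' shared variable is addressed as `<id>.u` or `<id>.v` accordingly.
#'
#' @param id Element identifier.
#' @param kind `"zero"` or `"one"`.
#' @return A one-row tibble.
#' @export
bg_junction <- function(id, kind) {
  tibble::tibble(id = id, kind = kind)
}

#' Bonds
#'
#' A bond connects two endpoints (components or junctions) and carries the
#' co-variables `u` (potential, J m^-3) and `v` (flow, m^3 s^-1); their product
#' is power. Positive power flows tail to head. A bond into a junction
#' contributes with sign `+` to that junction's sum equation, out with `-`.
#'
#' @param id Element identifier.
#' @param tail,head Endpoint element ids.
#' @return A one-row tibble.
#' @export
bg_bond <- function(id, tail, head) {
  tibble::tibble(id = id, tail = tail, head = head)
}

#' Auxiliary port variables
#'
#' A port is a zero-defaulted extra term in a junction's conservation
#' equation. A `"flow"` port attaches to a zero-junction and enters its
#' flow-sum with sign `-` (an implicit bond towards a downstream module); a
#' `"potential"` port attaches to a one-junction and enters its potential-sum
#' with sign `+` (pressure received from upstream). Unbound ports contribute
#' exactly zero, so an isolated module runs unchanged; binding a port to
#' another module's variable at merge time realises the extra bond of the
#' coupling without editing the module definition.
#'
#' @param id Element identifier (also the port's variable name).
#' @param junction Id of the junction the port attaches to.
#' @param kind `"flow"` or `"potential"`.
#' @param binding `NA` (unbound, value 0) or a namespaced variable name.
#' @return A one-row tibble.
#' @export
bg_port <- function(id, junction, kind, binding = NA_character_) {
  tibble::tibble(id = id, junction = junction, kind = kind, binding = binding)
}

empty_annotations <- function() {
  tibble::tibble(variable = character(), property_term = character(),
                 entity_term = character())
}

#' Build a validated bond-graph module
#'
#' Assembles component, junction, bond and port tables into a module and
#' checks every structural invariant (referential integrity, unique ids, one
#' bond per component, port/junction kind agreement, positive R/C/I
#' parameters, connectedness). Invalid input is rejected with the full list of
#' violations; use [validate_module()] to obtain the list without an error.
#'
#' @param name Module name; used as the namespace prefix when composed.
#' @param components,junctions,bonds,ports Tibbles built by row-binding
#'   [bg_component()], [bg_junction()], [bg_bond()], [bg_port()]. `ports` may
#'   be `NULL`.
#' @param annotations Optional annotation table (see [annotate()]).
#' @return An object of class `bg_module`.
#' @export
#' @examples
#' m <- bg_module("wk",
#'   components = dplyr::bind_rows(
#'     bg_component("Sf", "Sf", 1e-5),
#'     bg_component("C", "C", 1e-9)
#'   ),
#'   junctions = bg_junction("j0", "zero"),
#'   bonds = dplyr::bind_rows(bg_bond("b1", "Sf", "j0"), bg_bond("b2", "j0", "C")),
#'   ports = bg_port("vx1", "j0", "flow")
#' )
bg_module <- function(name, components, junctions, bonds, ports = NULL,
                      annotations = NULL) {
  m <- structure(
    list(
      name = name,
      components = tibble::as_tibble(components),
      junctions = tibble::as_tibble(junctions),
      bonds = tibble::as_tibble(bonds),
      ports = if (is.null(ports) || nrow(tibble::as_tibble(ports)) == 0) {
        bg_port(character(0), character(0), character(0), character(0))
      } else {
        tibble::as_tibble(ports)
      },
      annotations = annotations %||% empty_annotations(),
      meta = list()
    ),
    class = "bg_module"
  )
  viol <- validate_module(m)
  if (length(viol) > 0) {
    stop_bondnet(
      paste0("invalid module '", name, "':\n",
             paste0("  - ", viol, collapse = "\n")),
      "bondnet_invalid_module"
    )
  }
  m
}

#' List structural violations of a module
#'
#' Checks every type invariant and returns a character vector of violations,
#' each naming the offending element and the rule; an empty vector means the
#' module is well formed. Never raises.
#'
#' @param m A `bg_module` (or an unvalidated structure of the same shape).
#' @return Character vector of violation messages (possibly empty).
#' @export
validate_module <- function(m) {
  v <- character(0)
  co <- m$components; ju <- m$junctions; bo <- m$bonds; po <- m$ports

  ids <- c(co$id, ju$id, bo$id, po$id)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) v <- c(v, paste0("id '", d, "': duplicate id"))

  bad_kind <- co$id[!co$kind %in% c("R", "C", "I", "Se", "Sf")]
  for (id in bad_kind) v <- c(v, paste0("component ", id, ": unknown kind"))
  bad_jkind <- ju$id[!ju$kind %in% c("zero", "one")]
  for (id in bad_jkind) v <- c(v, paste0("junction ", id, ": unknown kind"))

  rci <- co[co$kind %in% c("R", "C", "I"), ]
  bad_par <- rci$id[is.na(rci$param) | rci$param <= 0]
  for (id in bad_par) v <- c(v, paste0("component ", id, ": nonpositive parameter"))
  bad_ref <- rci$id[!is.na(rci$param_ref)]
  for (id in bad_ref) v <- c(v, paste0("component ", id, ": param_ref only allowed on sources"))
  src <- co[co$kind %in% c("Se", "Sf"), ]
  bad_src <- src$id[is.na(src$param) & is.na(src$param_ref)]
  for (id in bad_src) v <- c(v, paste0("component ", id, ": source needs param or param_ref"))

  endpoints <- c(co$id, ju$id)
  for (i in seq_len(nrow(bo))) {
    for (e in c(bo$tail[i], bo$head[i])) {
      if (!e %in% endpoints) {
        v <- c(v, paste0("bond ", bo$id[i], ": dangling endpoint '", e, "'"))
      }
    }
    if (bo$tail[i] %in% co$id && bo$head[i] %in% co$id) {
      v <- c(v, paste0("bond ", bo$id[i], ": connects two components"))
    }
  }

  deg <- table(c(bo$tail, bo$head))
  for (id in co$id) {
    n <- if (id %in% names(deg)) deg[[id]] else 0L
    if (n == 0) v <- c(v, paste0("component ", id, ": no bond"))
    if (n > 1) v <- c(v, paste0("component ", id, ": multiple bonds"))
  }

  for (i in seq_len(nrow(po))) {
    j <- ju[ju$id == po$junction[i], ]
    if (nrow(j) == 0) {
      v <- c(v, paste0("port ", po$id[i], ": unknown junction '", po$junction[i], "'"))
    } else {
      want <- if (po$kind[i] == "flow") "zero" else "one"
      if (!po$kind[i] %in% c("flow", "potential")) {
        v <- c(v, paste0("port ", po$id[i], ": unknown port kind"))
      } else if (j$kind != want) {
        v <- c(v, paste0("port ", po$id[i], ": port/junction mismatch (",
                         po$kind[i], " port on ", j$kind, "-junction)"))
      }
    }
  }

  # connectedness over components + junctions via bonds
  nodes <- endpoints
  if (length(nodes) > 1 && nrow(bo) > 0) {
    # union-find on node indices
    parent <- seq_along(nodes)
    root <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    idx <- setNames(seq_along(nodes), nodes)
    for (i in seq_len(nrow(bo))) {
      if (bo$tail[i] %in% nodes && bo$head[i] %in% nodes) {
        a <- root(idx[[bo$tail[i]]]); b <- root(idx[[bo$head[i]]])
        if (a != b) parent[a] <- b
      }
    }
    # a bound port couples its junction to the junction owning the bound
    # variable, exactly as an added bond would
    for (i in seq_len(nrow(po))) {
      if (is.na(po$binding[i])) next
      jt <- sub("\\.(u|v)$", "", po$binding[i])
      if (po$junction[i] %in% nodes && jt %in% nodes) {
        a <- root(idx[[po$junction[i]]]); b <- root(idx[[jt]])
        if (a != b) parent[a] <- b
      }
    }
    roots <- vapply(seq_along(nodes), root, integer(1))
    if (length(unique(roots)) > 1) v <- c(v, "module: graph not connected")
  } else if (length(nodes) > 1 && nrow(bo) == 0) {
    v <- c(v, "module: graph not connected")
  }

  ann <- m$annotations
  if (nrow(ann) > 0) {
    known <- module_variables(m)
    for (i in seq_len(nrow(ann))) {
      if (!ann$variable[i] %in% known) {
        v <- c(v, paste0("annotation on '", ann$variable[i], "': unknown variable"))
      }
    }
  }
  v
}

#' Annotatable variables of a module
#'
#' The namespaced variable names that can carry annotations or port bindings:
#' global time `t`, each junction's shared variable (`<junction>.u` for a
#' zero-junction, `<junction>.v` for a one-junction), port ids, component ids
#' (for source and parameter annotations) and component state ids.
#'
#' @param m A `bg_module`.
#' @return Character vector of variable names.
#' @export
module_variables <- function(m) {
  jvar <- ifelse(m$junctions$kind == "zero",
                 paste0(m$junctions$id, ".u"),
                 paste0(m$junctions$id, ".v"))
  c("t", jvar, m$ports$id, m$components$id,
    m$components$state_id[!is.na(m$components$state_id)])
}

junction_var <- function(m, j_id) {
  kind <- m$junctions$kind[m$junctions$id == j_id]
  paste0(j_id, if (kind == "zero") ".u" else ".v")
}

#' @export
print.bg_module <- function(x, ...) {
  cat("<bg_module> ", x$name, "\n", sep = "")
  cat("  components: ", nrow(x$components),
      " (", paste(sort(unique(x$components$kind)), collapse = ", "), ")\n", sep = "")
  cat("  junctions:  ", nrow(x$junctions), "\n", sep = "")
  cat("  bonds:      ", nrow(x$bonds), "\n", sep = "")
  unb <- sum(is.na(x$ports$binding))
  cat("  ports:      ", nrow(x$ports), " (", unb, " unbound)\n", sep = "")
  cat("  annotations:", nrow(x$annotations), "\n")
  invisible(x)
}

#' @export
format.bg_module <- function(x, ...) {
  paste0("<bg_module '", x$name, "': ", nrow(x$components), " components, ",
         nrow(x$junctions), " junctions, ", nrow(x$bonds), " bonds, ",
         nrow(x$ports), " ports>")
}
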