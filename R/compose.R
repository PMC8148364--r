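ANNOT_PROPERTIES <- c("potential", "flow", "time")

valid_property <- function(p) {
  p %in% ANNOT_PROPERTIES | grepl("^parameter:.+", p)
}

#' Attach a semantic annotation to a module variable
#'
#' Records an annotation triple (variable, physical-property term, entity
#' term) on a module. The property vocabulary is closed: `potential`, `flow`,
#' `time` or `parameter:<name>`; the entity term is an opaque string (for
#' instance an anatomy term identifier). Annotations are the merge keys used
#' by [suggest_mappings()]: two modules annotating variables with the same
#' entity and compatible properties are candidates for coupling.
#' Re-annotating a variable replaces its triple.
#'
#' @param m A `bg_module`.
#' @param variable A variable name from [module_variables()].
#' @param property_term Property token from the closed vocabulary.
#' @param entity_term Opaque entity identifier string.
#' @return The module with the triple recorded.
#' @export
#' @examples
#' seg <- make_segment("intermediate", "brachial", list(l = 0.1, r = 0.004))
#' seg <- annotate(seg, "j_in.v", "flow", "brachial_inlet")
annotate <- function(m, variable, property_term, entity_term) {
  if (!variable %in% module_variables(m)) {
    stop_bondnet(paste0("unknown variable '", variable, "'"), "bondnet_annotation")
  }
  if (!valid_property(property_term)) {
    stop_bondnet(paste0("unknown property_term '", property_term,
                        "' (vocabulary: potential, flow, time, parameter:<name>)"),
                 "bondnet_annotation")
  }
  ann <- m$annotations[m$annotations$variable != variable, ]
  m$annotations <- dplyr::bind_rows(
    ann,
    tibble::tibble(variable = variable, property_term = property_term,
                   entity_term = entity_term)
  )
  m
}

variable_role <- function(m, var) {
  if (var == "t") return("time")
  if (var %in% m$ports$id) {
    return(paste0(m$ports$kind[m$ports$id == var], "_port"))
  }
  if (var %in% m$components$id) {
    k <- m$components$kind[m$components$id == var]
    if (k %in% c("Sf", "Se")) return("source")
    return("parameter")
  }
  "variable"
}

#' Suggest semantic overlaps between two annotated modules
#'
#' Detects candidate couplings by matching annotation triples across two
#' modules. An *exact* proposal is emitted when both sides annotate the same
#' entity term with the same property term and exactly one side is a port or
#' a source (the attachment point); only unbound ports are considered. The
#' global time variable is always proposed. *Partial* proposals (property
#' term agreement only, for ports/sources without an exact match) are
#' advisory and are never auto-accepted.
#'
#' @param a,b Annotated `bg_module`s.
#' @param partial Include advisory partial matches (default `TRUE`).
#' @return A tibble of proposals, exact before partial, then lexicographic;
#'   columns `source_var`/`target_var` (unprefixed variable names in `a`/`b`),
#'   `property`, `entity`, `score` (`exact`/`partial`), `port_side`
#'   (`"a"`/`"b"`: which side holds the port or source) and `port_role`.
#' @export
suggest_mappings <- function(a, b, partial = TRUE) {
  decorate <- function(m) {
    ann <- m$annotations
    ann$role <- vapply(ann$variable, function(v) variable_role(m, v), character(1))
    ann$attach <- ann$role %in% c("flow_port", "potential_port", "source")
    # a bound port is no longer available for coupling
    bound <- m$ports$id[!is.na(m$ports$binding)]
    ann[!(ann$variable %in% bound), ]
  }
  aa <- decorate(a); bb <- decorate(b)

  out <- tibble::tibble(source_var = character(), target_var = character(),
                        property = character(), entity = character(),
                        score = character(), port_side = character(),
                        port_role = character())

  if (nrow(aa) > 0 && nrow(bb) > 0) {
    j <- dplyr::inner_join(aa, bb, by = c("property_term", "entity_term"),
                           suffix = c(".a", ".b"),
                           relationship = "many-to-many")
    j <- j[xor(j$attach.a, j$attach.b) & j$property_term != "time", ]
    if (nrow(j) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        source_var = j$variable.a, target_var = j$variable.b,
        property = j$property_term, entity = j$entity_term,
        score = "exact",
        port_side = ifelse(j$attach.a, "a", "b"),
        port_role = ifelse(j$attach.a, j$role.a, j$role.b)
      ))
    }
  }

  # global time is always unifiable
  out <- dplyr::bind_rows(out, tibble::tibble(
    source_var = "t", target_var = "t", property = "time", entity = "t",
    score = "exact", port_side = NA_character_, port_role = "time"
  ))

  if (partial && nrow(aa) > 0 && nrow(bb) > 0) {
    matched_a <- out$source_var; matched_b <- out$target_var
    pj <- dplyr::inner_join(aa, bb, by = "property_term",
                            suffix = c(".a", ".b"),
                            relationship = "many-to-many")
    pj <- pj[xor(pj$attach.a, pj$attach.b) &
               pj$entity_term.a != pj$entity_term.b &
               pj$property_term != "time" &
               !(pj$variable.a %in% matched_a) &
               !(pj$variable.b %in% matched_b), ]
    if (nrow(pj) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        source_var = pj$variable.a, target_var = pj$variable.b,
        property = pj$property_term,
        entity = paste0(pj$entity_term.a, "~", pj$entity_term.b),
        score = "partial",
        port_side = ifelse(pj$attach.a, "a", "b"),
        port_role = ifelse(pj$attach.a, pj$role.a, pj$role.b)
      ))
    }
  }

  ord <- order(out$score != "exact", out$source_var, out$target_var,
               method = "radix")
  out[ord, ]
}

ns_prefix <- function(prefix, ids) {
  as.character(ifelse(is.na(ids) | ids == "t", ids, paste0(prefix, ".", ids)))
}

# Prefix every element id (and internal references) of a module.
ns_module <- function(m, prefix) {
  internal_vars <- module_variables(m)
  ns_ref <- function(x) {
    as.character(ifelse(!is.na(x) & x %in% setdiff(internal_vars, "t"),
                        paste0(prefix, ".", x), x))
  }
  co <- m$components
  co$id <- ns_prefix(prefix, co$id)
  co$param_ref <- ns_ref(co$param_ref)
  co$state_id <- as.character(ifelse(is.na(co$state_id), co$state_id,
                                     paste0(prefix, ".", co$state_id)))
  ju <- m$junctions; ju$id <- ns_prefix(prefix, ju$id)
  bo <- m$bonds
  bo$id <- ns_prefix(prefix, bo$id)
  bo$tail <- ns_prefix(prefix, bo$tail)
  bo$head <- ns_prefix(prefix, bo$head)
  po <- m$ports
  po$id <- ns_prefix(prefix, po$id)
  po$junction <- ns_prefix(prefix, po$junction)
  po$binding <- ns_ref(po$binding)
  ann <- m$annotations
  if (nrow(ann) > 0) {
    ann$variable <- as.character(ifelse(ann$variable == "t", "t",
                                        paste0(prefix, ".", ann$variable)))
  }
  m$components <- co; m$junctions <- ju; m$bonds <- bo; m$ports <- po
  m$annotations <- ann
  m
}

#' Merge two modules by binding auxiliary port variables
#'
#' Produces a new module containing both sub-networks, each namespaced by its
#' module name (`<module>.<element>`), with the accepted mappings realised as
#' port bindings. Accepting one *flow* mapping couples the pair in both
#' directions at once: the upstream flow port is bound to the downstream
#' inlet junction flow, and the downstream inlet's potential port `u_x` is
#' automatically bound to the potential of the junction holding the upstream
#' port — the reciprocal mapping is implied, so a join can never be left
#' half-coupled (which would break energy conservation at the seam).
#' A *source* mapping redirects an `Sf`/`Se` source to follow another
#' module's variable. Time is unified implicitly. Unbound ports remain
#' exposed on the result.
#'
#' @param a,b `bg_module`s with distinct names.
#' @param accepted Rows of a [suggest_mappings()] result to realise
#'   (default: none — the disjoint union sharing only time). Partial
#'   proposals cannot be accepted.
#' @param name Name of the merged module.
#' @return A validated `bg_module`; `meta$n_merges` accumulates the number
#'   of pairwise merges that produced it.
#' @export
merge_modules <- function(a, b, accepted = NULL, name = paste0(a$name, "_", b$name)) {
  if (identical(a$name, b$name)) {
    stop_bondnet(paste0("duplicate namespace '", a$name,
                        "': rename one side (see clone_module)"),
                 "bondnet_namespace")
  }
  # leaf modules are namespaced once by their module name; a composite's
  # elements already carry their leaf prefixes and keep them, so a variable
  # is always addressed as <leaf module>.<element> however deep the plan
  comp_a <- isTRUE(a$meta$composite)
  comp_b <- isTRUE(b$meta$composite)
  A <- if (comp_a) a else ns_module(a, a$name)
  B <- if (comp_b) b else ns_module(b, b$name)

  merged <- structure(
    list(
      name = name,
      components = dplyr::bind_rows(A$components, B$components),
      junctions = dplyr::bind_rows(A$junctions, B$junctions),
      bonds = dplyr::bind_rows(A$bonds, B$bonds),
      ports = dplyr::bind_rows(A$ports, B$ports),
      annotations = dplyr::distinct(dplyr::bind_rows(A$annotations, B$annotations)),
      meta = list(composite = TRUE,
                  n_merges = (a$meta$n_merges %||% 0L) +
                    (b$meta$n_merges %||% 0L) + 1L)
    ),
    class = "bg_module"
  )

  bind_port <- function(mod, port_id, target) {
    i <- which(mod$ports$id == port_id)
    if (length(i) != 1) {
      stop_bondnet(paste0("port '", port_id, "' not found"), "bondnet_merge")
    }
    if (!is.na(mod$ports$binding[i])) {
      stop_bondnet(paste0("port '", port_id, "' already bound"), "bondnet_merge")
    }
    mod$ports$binding[i] <- target
    mod
  }

  if (!is.null(accepted) && nrow(accepted) > 0) {
    if (any(accepted$score == "partial")) {
      stop_bondnet("partial proposals are advisory and cannot be accepted",
                   "bondnet_merge")
    }
    for (i in seq_len(nrow(accepted))) {
      row <- accepted[i, ]
      if (row$property == "time") next
      pa <- if (comp_a) row$source_var else ns_prefix(a$name, row$source_var)
      pb <- if (comp_b) row$target_var else ns_prefix(b$name, row$target_var)
      port_var <- if (row$port_side == "a") pa else pb
      other_var <- if (row$port_side == "a") pb else pa
      role <- row$port_role
      if (role == "flow_port") {
        if (row$property != "flow") {
          stop_bondnet("incompatible proposal: flow port with non-flow property",
                       "bondnet_merge")
        }
        merged <- bind_port(merged, port_var, other_var)
        # reciprocal potential binding: u_x on the downstream inlet junction
        jn_down <- sub("\\.v$", "", other_var)
        if (!jn_down %in% merged$junctions$id) {
          stop_bondnet(paste0("incompatible proposal: '", other_var,
                              "' is not a junction flow variable"), "bondnet_merge")
        }
        cand <- merged$ports[merged$ports$junction == jn_down &
                               merged$ports$kind == "potential" &
                               is.na(merged$ports$binding), ]
        if (nrow(cand) == 0) {
          stop_bondnet(paste0("no unbound potential port on junction '",
                              jn_down, "' for the reciprocal mapping"),
                       "bondnet_merge")
        }
        if (nrow(cand) > 1) {
          stop_bondnet(paste0("ambiguous reciprocal mapping on '", jn_down, "'"),
                       "bondnet_merge")
        }
        jn_up <- merged$ports$junction[merged$ports$id == port_var]
        merged <- bind_port(merged, cand$id, paste0(jn_up, ".u"))
      } else if (role == "potential_port") {
        stop_bondnet("accept the flow mapping; the potential binding is implied",
                     "bondnet_merge")
      } else if (role == "source") {
        ci <- which(merged$components$id == port_var)
        merged$components$param_ref[ci] <- other_var
        merged$components$param[ci] <- NA_real_
      } else {
        stop_bondnet(paste0("incompatible proposal role '", role, "'"),
                     "bondnet_merge")
      }
    }
  }

  viol <- validate_module(merged)
  # a merge with no accepted couplings is a disjoint union: connectedness
  # across the two halves is not required of it
  viol <- viol[viol != "module: graph not connected"]
  if (length(viol) > 0) {
    stop_bondnet(paste0("merge produced an invalid module:\n",
                        paste0("  - ", viol, collapse = "\n")), "bondnet_merge")
  }
  merged
}

#' Clone a module under a new namespace
#'
#' Deep-copies a module with every element id prefixed and every annotation
#' entity term rewritten, so that structurally identical sub-networks (for
#' instance the two arms or the two legs) are built once and reused. The
#' clone is deterministic: simulated with identical inputs it reproduces the
#' original's traces exactly.
#'
#' @param m A `bg_module`.
#' @param prefix Non-empty id prefix (applied as `<prefix><id>`).
#' @param entity_renamer Function applied to each annotation entity term
#'   (e.g. `function(e) sub("^left_", "right_", e)`); default identity.
#' @return The cloned `bg_module`, named `<prefix><name>`.
#' @export
clone_module <- function(m, prefix, entity_renamer = identity) {
  if (!is.character(prefix) || nchar(prefix) == 0) {
    stop_bondnet("clone prefix must be non-empty (ids would collide)",
                 "bondnet_clone")
  }
  pre <- function(x) as.character(ifelse(is.na(x) | x == "t", x, paste0(prefix, x)))
  internal <- setdiff(module_variables(m), "t")
  pre_ref <- function(x) {
    as.character(ifelse(!is.na(x) & x %in% internal, paste0(prefix, x), x))
  }
  out <- m
  out$name <- paste0(prefix, m$name)
  out$components$id <- pre(m$components$id)
  out$components$param_ref <- pre_ref(m$components$param_ref)
  out$components$state_id <- as.character(
    ifelse(is.na(m$components$state_id), NA_character_,
           paste0(prefix, m$components$state_id)))
  out$junctions$id <- pre(m$junctions$id)
  out$bonds$id <- pre(m$bonds$id)
  out$bonds$tail <- pre(m$bonds$tail)
  out$bonds$head <- pre(m$bonds$head)
  out$ports$id <- pre(m$ports$id)
  out$ports$junction <- pre(m$ports$junction)
  out$ports$binding <- pre_ref(m$ports$binding)
  if (nrow(m$annotations) > 0) {
    out$annotations$variable <- as.character(
      ifelse(m$annotations$variable == "t", "t",
             paste0(prefix, m$annotations$variable)))
    out$annotations$entity_term <- vapply(m$annotations$entity_term,
                                          entity_renamer, character(1),
                                          USE.NAMES = FALSE)
  }
  if (identical(out$name, m$name)) {
    stop_bondnet("clone prefix produced a colliding name", "bondnet_clone")
  }
  out
}

#' Execute a hierarchical composition plan
#'
#' A composition plan is an ordered tree whose leaves are modules and whose
#' internal nodes are lumped modules. `lump()` walks the tree depth-first
#' left-to-right, merging each node's children pairwise (n children require
#' n-1 binary merges) and auto-accepting every *exact* proposal between the
#' running composite and the next child; ambiguity (several exact proposals
#' competing for one port) is an error rather than a guess. The result
#' exposes only the still-unbound ports.
#'
#' @param plan A plan node: either `list(module = <name-or-path>)` (leaf) or
#'   `list(name = <chr>, children = list(...))`. See [read_plan()].
#' @param modules Named list of `bg_module`s resolving leaf names; leaves
#'   not found here are read from disk as module JSON paths.
#' @param base_dir Directory against which leaf paths are resolved.
#' @return The lumped `bg_module`; `meta$n_merges` records the total number
#'   of pairwise merges executed.
#' @export
lump <- function(plan, modules = list(), base_dir = ".") {
  resolve <- function(node, path) {
    if (!is.null(node$module)) {
      ref <- node$module
      if (ref %in% names(modules)) return(modules[[ref]])
      file <- file.path(base_dir, ref)
      if (file.exists(file)) return(read_module(file))
      stop_bondnet(paste0("plan leaf '", ref, "' (at ", path,
                          ") matches no module or file"), "bondnet_plan")
    }
    kids <- node$children
    if (is.null(kids) || length(kids) == 0) {
      stop_bondnet(paste0("plan node at ", path, " has no children"),
                   "bondnet_plan")
    }
    acc <- resolve(kids[[1]], paste0(path, "/1"))
    if (length(kids) == 1) {
      if (!is.null(node$name)) acc$name <- node$name
      return(acc)
    }
    for (i in seq_along(kids)[-1]) {
      nxt <- resolve(kids[[i]], paste0(path, "/", i))
      sugg <- suggest_mappings(acc, nxt, partial = FALSE)
      sugg <- sugg[sugg$score == "exact" & sugg$property != "time", ]
      if (nrow(sugg) > 0) {
        key <- ifelse(sugg$port_side == "a", sugg$source_var, sugg$target_var)
        amb <- unique(key[duplicated(key)])
        if (length(amb) > 0) {
          stop_bondnet(paste0("ambiguous mappings at ", path, " for port(s): ",
                              paste(amb, collapse = ", ")), "bondnet_plan")
        }
      }
      nm <- if (i == length(kids)) (node$name %||% paste0(acc$name, "_", nxt$name))
            else paste0(node$name %||% "lump", "..", i)
      acc <- tryCatch(
        merge_modules(acc, nxt, accepted = sugg, name = nm),
        error = function(e) {
          stop_bondnet(paste0("merge failed at plan path ", path, "/", i, ": ",
                              conditionMessage(e)), "bondnet_plan")
        }
      )
    }
    acc
  }
  resolve(plan, path = "")
}
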