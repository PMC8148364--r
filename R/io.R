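MODULE_SCHEMA_KEYS <- list(
  components = c("id", "kind", "param", "param_ref", "units"),
  junctions = c("id", "kind"),
  bonds = c("id", "tail", "head"),
  ports = c("id", "junction", "kind", "binding")
)

#' Write a module to its JSON exchange document
#'
#' The exchange format (schema shipped at
#' `system.file("extdata", "module-schema.json", package = "bondnet")`) has
#' top-level keys `name`, `components[]`, `junctions[]`, `bonds[]`,
#' `ports[]`, `annotations[]`; all ids are strings and parameter unit
#' strings are recorded verbatim alongside the values.
#'
#' @param m A `bg_module`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_module <- function(m, path) {
  viol <- validate_module(m)
  viol <- viol[viol != "module: graph not connected"]
  if (length(viol) > 0) {
    stop_bondnet(paste0("refusing to write invalid module:\n",
                        paste0("  - ", viol, collapse = "\n")), "bondnet_io")
  }
  doc <- list(
    name = m$name,
    components = m$components[MODULE_SCHEMA_KEYS$components],
    junctions = m$junctions[MODULE_SCHEMA_KEYS$junctions],
    bonds = m$bonds[MODULE_SCHEMA_KEYS$bonds],
    ports = m$ports[MODULE_SCHEMA_KEYS$ports],
    annotations = m$annotations
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

schema_fail <- function(pointer, msg) {
  stop_bondnet(paste0("module schema violation at ", pointer, ": ", msg),
               "bondnet_schema")
}

#' Read a module from its JSON exchange document
#'
#' Validates the document against the exchange schema while reading (unknown
#' kinds, missing keys and broken references are reported with their JSON
#' location) and returns a fully validated module. `write_module()` then
#' `read_module()` round-trips to a deeply equal module, unit strings
#' included.
#'
#' @param path JSON file path.
#' @return A `bg_module`.
#' @export
read_module <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$name) || !is.character(doc$name)) {
    schema_fail("/name", "missing or non-string")
  }
  as_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)

  tab <- function(key, required_cols, kinds = NULL) {
    raw <- doc[[key]]
    if (is.null(raw) || (is.data.frame(raw) && nrow(raw) == 0) ||
        length(raw) == 0) {
      return(NULL)
    }
    df <- tibble::as_tibble(raw)
    for (col in required_cols) {
      if (!col %in% names(df)) schema_fail(paste0("/", key), paste0("missing field '", col, "'"))
    }
    if (!is.null(kinds)) {
      bad <- which(!df$kind %in% kinds)
      if (length(bad) > 0) {
        schema_fail(paste0("/", key, "/", bad[1] - 1, "/kind"),
                    paste0("unknown kind '", df$kind[bad[1]], "'"))
      }
    }
    df
  }

  co <- tab("components", c("id", "kind"), kinds = c("R", "C", "I", "Se", "Sf"))
  components <- if (is.null(co)) {
    tibble::tibble(id = character(0), kind = character(0), param = numeric(0),
                   param_ref = character(0), units = character(0),
                   state_id = character(0))
  } else {
    purrr::pmap_dfr(
      list(co$id, co$kind,
           if ("param" %in% names(co)) co$param else NA_real_,
           if ("param_ref" %in% names(co)) co$param_ref else NA_character_,
           if ("units" %in% names(co)) co$units else NA_character_),
      function(id, kind, param, ref, units) {
        bg_component(as.character(id), kind,
                     if (is.null(param)) NA_real_ else as.numeric(param),
                     as_chr(ref), as_chr(units))
      }
    )
  }
  ju <- tab("junctions", c("id", "kind"), kinds = c("zero", "one"))
  junctions <- if (is.null(ju)) bg_junction(character(0), character(0)) else {
    bg_junction(as.character(ju$id), ju$kind)
  }
  bo <- tab("bonds", c("id", "tail", "head"))
  bonds <- if (is.null(bo)) bg_bond(character(0), character(0), character(0)) else {
    bg_bond(as.character(bo$id), as.character(bo$tail), as.character(bo$head))
  }
  po <- tab("ports", c("id", "junction", "kind"), kinds = c("flow", "potential"))
  ports <- if (is.null(po)) NULL else {
    bg_port(as.character(po$id), as.character(po$junction), po$kind,
            if ("binding" %in% names(po)) as.character(po$binding) else NA_character_)
  }
  an <- doc$annotations
  annotations <- if (is.null(an) || length(an) == 0) NULL else {
    an <- tibble::as_tibble(an)
    for (col in c("variable", "property_term", "entity_term")) {
      if (!col %in% names(an)) schema_fail("/annotations", paste0("missing field '", col, "'"))
    }
    bad <- which(!vapply(an$property_term, valid_property, logical(1)))
    if (length(bad) > 0) {
      schema_fail(paste0("/annotations/", bad[1] - 1, "/property_term"),
                  paste0("'", an$property_term[bad[1]], "' not in vocabulary"))
    }
    an[c("variable", "property_term", "entity_term")]
  }

  m <- tryCatch(
    bg_module(doc$name, components, junctions, bonds, ports, annotations),
    error = function(e) schema_fail("/", conditionMessage(e))
  )
  m
}

#' Round-trip a module through its JSON document
#'
#' Writes `m` to a temporary file and reads it back; the result is deeply
#' equal to the input (ids, parameters, unit strings, port bindings and
#' annotations included). Mostly useful as a serialization self-check.
#'
#' @param m A `bg_module`.
#' @return The re-read `bg_module`.
#' @export
roundtrip <- function(m) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_module(m, f)
  read_module(f)
}

#' Read / write a composition plan
#'
#' Plan JSON is a tree `{"name": .., "children": [...]}` whose leaves are
#' `{"module": <name-or-path>}` entries; see [lump()].
#'
#' @param path File path.
#' @return `read_plan()`: a nested plan list; `write_plan()`: `path`.
#' @export
read_plan <- function(path) {
  plan <- jsonlite::read_json(path, simplifyVector = FALSE)
  check <- function(node, ptr) {
    if (!is.null(node$module)) return(invisible(NULL))
    if (is.null(node$children)) {
      schema_fail(ptr, "plan node needs 'module' or 'children'")
    }
    for (i in seq_along(node$children)) {
      check(node$children[[i]], paste0(ptr, "/children/", i - 1))
    }
  }
  check(plan, "")
  plan
}

#' @rdname read_plan
#' @param plan A plan list.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(plan, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Number of leaves and merge steps of a plan
#'
#' Composing `n` modules requires `n - 1` binary merges; this helper counts
#' both for any plan tree.
#'
#' @param plan A plan list (see [read_plan()]).
#' @return A list with `n_leaves` and `n_merges`.
#' @export
plan_size <- function(plan) {
  count <- function(node) {
    if (!is.null(node$module)) return(1L)
    sum(vapply(node$children, count, integer(1)))
  }
  n <- count(plan)
  list(n_leaves = n, n_merges = max(n - 1L, 0L))
}
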