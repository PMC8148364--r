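#' Conservation equations at a junction
#'
#' Returns the symbolic conservation relations a junction imposes, as linear
#' forms over the module's bond and port variables. For a zero-junction the
#' potentials of all incident bonds are equal to the junction potential and
#' the signed flows sum to zero; for a one-junction the flows are equal and
#' the signed potentials sum to zero. A bond oriented into the junction enters
#' the sum with `+`, out with `-`. Every flow port on a zero-junction adds
#' `-`(bound value) to the flow sum and every potential port on a one-junction
#' adds `+`(bound value) to the potential sum; unbound ports contribute the
#' constant 0 but are kept as explicit zero-valued terms so the augmentation
#' is visible.
#'
#' The power residual of the junction, `sum_i u_i v_i` signed by orientation,
#' is identically zero once the equalities are substituted into the sum
#' equation, which is how junction structure enforces energy conservation.
#'
#' @param m A `bg_module`.
#' @param j_id Id of a junction in `m`.
#' @return An object of class `bg_balance` with fields `junction`, `kind`,
#'   `shared` (the junction variable name), `equalities` (tibble with columns
#'   `lhs`, `rhs`), and `sum_terms` (tibble with columns `term`, `coef`,
#'   `role` in `bond`/`port`; unbound ports have `term = NA` and the role
#'   records their presence).
#' @export
junction_balance <- function(m, j_id) {
  j <- m$junctions[m$junctions$id == j_id, ]
  if (nrow(j) == 0) {
    stop_bondnet(paste0("junction '", j_id, "' not in module"), "bondnet_lookup")
  }
  inc <- m$bonds[m$bonds$tail == j_id | m$bonds$head == j_id, ]
  if (nrow(inc) == 0) {
    stop_bondnet(paste0("isolated junction '", j_id, "'"), "bondnet_isolated_junction")
  }
  sigma <- ifelse(inc$head == j_id, 1, -1)
  shared <- junction_var(m, j_id)
  eq_co <- if (j$kind == "zero") ".u" else ".v"
  sum_co <- if (j$kind == "zero") ".v" else ".u"

  equalities <- tibble::tibble(lhs = paste0(inc$id, eq_co), rhs = shared)

  sum_terms <- tibble::tibble(
    term = paste0(inc$id, sum_co),
    coef = sigma,
    role = "bond"
  )
  want_port_kind <- if (j$kind == "zero") "flow" else "potential"
  po <- m$ports[m$ports$junction == j_id & m$ports$kind == want_port_kind, ]
  if (nrow(po) > 0) {
    port_sign <- if (j$kind == "zero") -1 else +1
    sum_terms <- dplyr::bind_rows(
      sum_terms,
      tibble::tibble(
        term = ifelse(is.na(po$binding), NA_character_, po$binding),
        coef = port_sign,
        role = ifelse(is.na(po$binding), "port_unbound", "port")
      )
    )
  }
  structure(
    list(junction = j_id, kind = j$kind, shared = shared,
         equalities = equalities, sum_terms = sum_terms),
    class = "bg_balance"
  )
}

#' @export
print.bg_balance <- function(x, ...) {
  cat("<bg_balance> ", x$kind, "-junction ", x$junction, "\n", sep = "")
  if (nrow(x$equalities) > 0) {
    cat("  ", paste(unique(c(x$equalities$lhs, x$equalities$rhs)), collapse = " = "),
        "\n", sep = "")
  }
  terms <- purrr::pmap_chr(x$sum_terms, function(term, coef, role) {
    lab <- if (is.na(term)) "0" else term
    paste0(if (coef < 0) "- " else "+ ", lab)
  })
  cat("  ", sub("^\\+ ", "", paste(terms, collapse = " ")), " = 0\n", sep = "")
  invisible(x)
}

# Sum equation as a linear form over bond/external variable names.
balance_linform <- function(bal) {
  tm <- bal$sum_terms[bal$sum_terms$role != "port_unbound", ]
  if (nrow(tm) == 0) return(lf_const(0))
  Reduce(lf_add, purrr::map2(tm$term, tm$coef, lf_var))
}
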