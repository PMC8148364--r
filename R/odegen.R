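#' Assemble the ODE system of a composed module
#'
#' Reduces a module's junction structure and constitutive laws to an explicit
#' linear state-space system by exact symbolic elimination. The states are
#' the stored volume `q` of every `C` (with `dq/dt` the net flow into its
#' branch and `u = q/C`) and the flow `v` of every `I` (with `dv/dt = u/I`).
#' All junction variables and bond co-variables are algebraic: the junction
#' equalities, signed sum equations (including auxiliary port terms),
#' constitutive relations and source constraints form a square linear system
#' that is solved once for the coefficient matrix expressing every algebraic
#' variable over `(1, states, inputs)`; algebraic loops (R-only cycles) are
#' handled by the same linear solve. Variable ordering is lexicographic, so
#' the generated system is reproducible.
#'
#' Unbound ports are treated as the constant 0 and recorded in
#' `sys$port_warnings` rather than raised, so an isolated module with
#' exposed ports is still runnable.
#'
#' @param m A validated `bg_module` whose ports are unbound or bound to
#'   variables inside `m`.
#' @return An object of class `bg_ode` with fields `states` (tibble: `id`,
#'   `kind` `q`/`v`, `component`, `param`), `A`, `B`, `b0` (state-space
#'   matrices `dx/dt = A x + B w + b0`), `inputs` (tibble: `id`, `kind`,
#'   `value`, `ref`), `outputs` (matrix mapping `(1, states, inputs)` to
#'   every junction and bond variable), `x_names`, `params`, `module` and
#'   `port_warnings`.
#' @export
#' @examples
#' seg <- make_segment("intermediate", "s1", list(l = 0.1, r = 0.01))
#' sys <- assemble_ode(seg)
#' nrow(sys$states)  # one C + one I -> 2 states
assemble_ode <- function(m) {
  viol <- validate_module(m)
  # a disjoint union (merge with no accepted couplings) still assembles;
  # every other violation is fatal
  viol <- viol[viol != "module: graph not connected"]
  if (length(viol) > 0) {
    stop_bondnet(paste0("module does not validate:\n",
                        paste0("  - ", viol, collapse = "\n")),
                 "bondnet_assemble")
  }
  co <- m$components; ju <- m$junctions; bo <- m$bonds; po <- m$ports

  st <- co[co$kind %in% c("C", "I"), ]
  states <- tibble::tibble(
    id = st$state_id,
    kind = ifelse(st$kind == "C", "q", "v"),
    component = st$id,
    param = st$param
  )
  states <- states[order(states$id, method = "radix"), ]

  # algebraic unknowns: junction shared vars + u/v of every bond
  jvars <- vapply(ju$id, function(j) junction_var(m, j), character(1))
  xnames <- lex_sort(c(jvars, paste0(bo$id, ".u"), paste0(bo$id, ".v")))
  nx <- length(xnames)
  xi <- setNames(seq_len(nx), xnames)

  # inputs: sources with numeric value or an external function reference
  src <- co[co$kind %in% c("Se", "Sf"), ]
  ext <- src[is.na(src$param_ref) | !(src$param_ref %in% xnames), ]
  inputs <- tibble::tibble(
    id = ext$id, kind = ext$kind, value = ext$param, ref = ext$param_ref
  )
  inputs <- inputs[order(inputs$id, method = "radix"), ]
  ni <- nrow(inputs)
  wi <- setNames(seq_len(max(ni, 0)), inputs$id)

  si <- setNames(seq_len(nrow(states)), states$id)
  ns <- nrow(states)
  nb <- 1 + ns + ni # basis: const, states, inputs

  M <- matrix(0, 0, nx)
  Rhs <- matrix(0, 0, nb)
  add_row <- function(xcoef, bcoef) {
    M <<- rbind(M, xcoef)
    Rhs <<- rbind(Rhs, bcoef)
  }
  xrow <- function(...) {
    r <- numeric(nx)
    terms <- list(...)
    for (t in terms) r[xi[[t$var]]] <- r[xi[[t$var]]] + t$coef
    r
  }
  brow_const <- function(val = 0) { r <- numeric(nb); r[1] <- val; r }
  brow_state <- function(id, coef) { r <- numeric(nb); r[1 + si[[id]]] <- coef; r }
  brow_input <- function(id, coef) { r <- numeric(nb); r[1 + ns + wi[[id]]] <- coef; r }

  port_warnings <- character(0)

  # junction equations
  for (k in seq_len(nrow(ju))) {
    j_id <- ju$id[k]
    bal <- junction_balance(m, j_id)
    for (i in seq_len(nrow(bal$equalities))) {
      add_row(xrow(list(var = bal$equalities$lhs[i], coef = 1),
                   list(var = bal$equalities$rhs[i], coef = -1)),
              brow_const(0))
    }
    r <- numeric(nx); rb <- numeric(nb)
    for (i in seq_len(nrow(bal$sum_terms))) {
      tm <- bal$sum_terms$term[i]
      if (is.na(tm)) {
        port_warnings <- c(port_warnings,
                           paste0("junction ", j_id,
                                  ": unbound port treated as 0"))
        next
      }
      if (!tm %in% xnames) {
        stop_bondnet(paste0("junction ", j_id, ": bound variable '", tm,
                            "' is not internal to the module"),
                     "bondnet_assemble")
      }
      r[xi[[tm]]] <- r[xi[[tm]]] + bal$sum_terms$coef[i]
    }
    add_row(r, rb)
  }

  # constitutive equations; sigma_in = +1 when the bond points into the component
  for (k in seq_len(nrow(co))) {
    c_id <- co$id[k]
    b <- bo[bo$tail == c_id | bo$head == c_id, ]
    sigma_in <- if (b$head == c_id) 1 else -1
    bu <- paste0(b$id, ".u"); bv <- paste0(b$id, ".v")
    kind <- co$kind[k]
    if (kind == "R") {
      # u_b = R * sigma_in * v_b
      add_row(xrow(list(var = bu, coef = 1),
                   list(var = bv, coef = -co$param[k] * sigma_in)),
              brow_const(0))
    } else if (kind == "C") {
      # u_b = q / C
      add_row(xrow(list(var = bu, coef = 1)),
              brow_state(co$state_id[k], 1 / co$param[k]))
    } else if (kind == "I") {
      # bond flow equals the stored flow state
      add_row(xrow(list(var = bv, coef = sigma_in)),
              brow_state(co$state_id[k], 1))
    } else if (kind == "Se") {
      if (!is.na(co$param_ref[k]) && co$param_ref[k] %in% xnames) {
        add_row(xrow(list(var = bu, coef = 1),
                     list(var = co$param_ref[k], coef = -1)), brow_const(0))
      } else {
        add_row(xrow(list(var = bu, coef = 1)), brow_input(c_id, 1))
      }
    } else if (kind == "Sf") {
      # flow leaves the source along its bond
      sigma_src <- if (b$tail == c_id) 1 else -1
      if (!is.na(co$param_ref[k]) && co$param_ref[k] %in% xnames) {
        add_row(xrow(list(var = bv, coef = sigma_src),
                     list(var = co$param_ref[k], coef = -1)), brow_const(0))
      } else {
        add_row(xrow(list(var = bv, coef = sigma_src)), brow_input(c_id, 1))
      }
    }
  }

  if (nrow(M) != nx) {
    stop_bondnet(paste0("algebraic system is not square (", nrow(M),
                        " equations, ", nx, " unknowns)"), "bondnet_assemble")
  }
  # equilibrate rows and columns: junction sums mix coefficients spanning
  # many orders of magnitude (R ~ r^-4), which is harmless mathematically
  # but fails naive condition checks on deep trees
  r_s <- pmax(apply(abs(M), 1, max), .Machine$double.xmin)
  M1 <- M / r_s
  c_s <- pmax(apply(abs(M1), 2, max), .Machine$double.xmin)
  M2 <- sweep(M1, 2, c_s, "/")
  X <- tryCatch(solve(M2, Rhs / r_s) / c_s, error = function(e) {
    stop_bondnet(paste0("singular algebraic subsystem: ", conditionMessage(e)),
                 "bondnet_assemble")
  })
  rownames(X) <- xnames
  colnames(X) <- c("(const)", states$id, inputs$id)

  # state derivatives
  A <- matrix(0, ns, ns, dimnames = list(states$id, states$id))
  B <- matrix(0, ns, ni, dimnames = list(states$id, inputs$id))
  b0 <- setNames(numeric(ns), states$id)
  for (k in seq_len(nrow(st))) {
    c_id <- st$id[k]
    b <- bo[bo$tail == c_id | bo$head == c_id, ]
    sigma_in <- if (b$head == c_id) 1 else -1
    sid <- st$state_id[k]
    if (st$kind[k] == "C") {
      lf <- sigma_in * X[paste0(b$id, ".v"), ]
    } else {
      lf <- (sigma_in / st$param[k]) * X[paste0(b$id, ".u"), ]
    }
    b0[sid] <- lf[1]
    if (ns > 0) A[sid, ] <- lf[1 + seq_len(ns)]
    if (ni > 0) B[sid, ] <- lf[1 + ns + seq_len(ni)]
  }

  structure(
    list(states = states, A = A, B = B, b0 = b0, inputs = inputs,
         outputs = X, x_names = xnames,
         params = co[, c("id", "kind", "param", "param_ref", "units")],
         module = m, port_warnings = unique(port_warnings)),
    class = "bg_ode"
  )
}

#' Evaluate the right-hand side of an assembled system
#'
#' @param sys A `bg_ode`.
#' @param state Named numeric vector over `sys$states$id` (names optional if
#'   ordered), the state point.
#' @param input_values Named list/vector overriding input values by source id
#'   or by external reference name (e.g. `cardiac_inflow = 5e-5`).
#' @return Named numeric vector of state derivatives.
#' @export
evaluate_rhs <- function(sys, state, input_values = list()) {
  s <- resolve_state(sys, state)
  w <- resolve_inputs(sys, input_values, t = 0)
  drop(sys$A %*% s + (if (length(w) > 0) sys$B %*% w else 0) + sys$b0)
}

resolve_state <- function(sys, state) {
  ids <- sys$states$id
  if (!is.null(names(state))) {
    miss <- setdiff(ids, names(state))
    if (length(miss) > 0) {
      stop_bondnet(paste0("state missing: ", paste(miss, collapse = ", ")),
                   "bondnet_simulate")
    }
    state <- state[ids]
  } else if (length(state) != length(ids)) {
    stop_bondnet("state vector has wrong length", "bondnet_simulate")
  }
  as.numeric(state)
}

# Numeric input vector at time t. input_values may bind by source id or by
# the external reference name; entries may be numbers, functions of t, or
# bg_beat waveforms.
resolve_inputs <- function(sys, input_values, t) {
  inp <- sys$inputs
  if (nrow(inp) == 0) return(numeric(0))
  input_values <- as.list(input_values)
  vapply(seq_len(nrow(inp)), function(k) {
    key <- if (!is.na(inp$ref[k])) inp$ref[k] else inp$id[k]
    v <- input_values[[inp$id[k]]] %||% input_values[[key]]
    if (is.null(v)) {
      if (!is.na(inp$value[k])) return(inp$value[k])
      stop_bondnet(paste0("input '", key, "' not supplied"), "bondnet_simulate")
    }
    if (inherits(v, "bg_beat")) return(beat_flow(v, t))
    if (is.function(v)) return(v(t))
    as.numeric(v)
  }, numeric(1))
}

#' @export
print.bg_ode <- function(x, ...) {
  cat("<bg_ode> from module '", x$module$name, "'\n", sep = "")
  cat("  states: ", nrow(x$states), " (",
      sum(x$states$kind == "q"), " q, ", sum(x$states$kind == "v"), " v)\n",
      sep = "")
  cat("  inputs: ", nrow(x$inputs), "\n", sep = "")
  cat("  algebraic variables: ", length(x$x_names), "\n", sep = "")
  if (length(x$port_warnings) > 0) {
    cat("  notes: ", length(x$port_warnings), " unbound port(s) held at 0\n",
        sep = "")
  }
  invisible(x)
}

#' Human-readable equation listing
#'
#' Renders the state equations (and optionally the algebraic output map) of
#' an assembled system as plain text.
#'
#' @param sys A `bg_ode`.
#' @param outputs Include the algebraic variable expressions (default FALSE).
#' @return Character vector of equation lines.
#' @export
ode_equations <- function(sys, outputs = FALSE) {
  basis <- c("(const)", sys$states$id, sys$inputs$id)
  line <- function(lhs, coefs) {
    lf <- setNames(as.numeric(coefs), basis)
    paste0(lhs, " = ", lf_format(lf_trim(lf, tol = 1e-300)))
  }
  eqs <- vapply(seq_len(nrow(sys$states)), function(k) {
    co <- c(sys$b0[k], sys$A[k, ], if (ncol(sys$B) > 0) sys$B[k, ])
    line(paste0("d(", sys$states$id[k], ")/dt"), co)
  }, character(1))
  if (outputs) {
    eqs <- c(eqs, vapply(seq_along(sys$x_names), function(k) {
      line(sys$x_names[k], sys$outputs[k, ])
    }, character(1)))
  }
  eqs
}

#' Export an assembled system as JSON expression trees
#'
#' Writes a machine-readable description of the system: each derivative and
#' algebraic output as `{const, terms: [{var, coef}]}` linear expression
#' trees, plus the state, input and parameter tables.
#'
#' @param sys A `bg_ode`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_ode_json <- function(sys, path) {
  basis <- c("(const)", sys$states$id, sys$inputs$id)
  expr_tree <- function(coefs) {
    nz <- which(abs(coefs) > 0 & basis != "(const)")
    list(const = as.numeric(coefs[1]),
         terms = purrr::map(nz, function(i) list(var = basis[i],
                                                 coef = as.numeric(coefs[i]))))
  }
  derivs <- purrr::map(seq_len(nrow(sys$states)), function(k) {
    expr_tree(c(sys$b0[k], sys$A[k, ], if (ncol(sys$B) > 0) sys$B[k, ]))
  })
  names(derivs) <- sys$states$id
  outs <- purrr::map(seq_along(sys$x_names), function(k) expr_tree(sys$outputs[k, ]))
  names(outs) <- sys$x_names
  doc <- list(
    module = sys$module$name,
    states = sys$states,
    inputs = sys$inputs,
    derivs = derivs,
    outputs = outs
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Audit per-junction power balance on a trajectory
#'
#' Evaluates the signed power residual `sum_i u_i v_i` of every junction at
#' every stored time of a simulation, including the power carried through
#' bound auxiliary ports. Junction structure makes these residuals
#' identically zero for a consistent trajectory (energy is neither created
#' nor destroyed at a junction), so any residual beyond rounding indicates a
#' corrupted or externally perturbed trace.
#'
#' @param sys The `bg_ode` that produced the trajectory.
#' @param sim A `bg_sim` result from [simulate_ode()] on `sys`.
#' @return A tibble of class `bg_audit` with one row per junction: columns
#'   `junction`, `kind`, `max_abs_residual` (J s^-1), `scale` (max |u v|
#'   term at the junction) and `max_rel_residual`.
#' @export
power_audit <- function(sys, sim) {
  m <- sys$module
  need <- sys$x_names
  if (!all(need %in% names(sim))) {
    stop_bondnet("trajectory does not carry this system's variables",
                 "bondnet_audit")
  }
  rows <- purrr::map_dfr(m$junctions$id, function(j_id) {
    bal <- junction_balance(m, j_id)
    inc <- m$bonds[m$bonds$tail == j_id | m$bonds$head == j_id, ]
    sigma <- ifelse(inc$head == j_id, 1, -1)
    res <- 0; scale <- 0
    for (i in seq_len(nrow(inc))) {
      p <- sigma[i] * sim[[paste0(inc$id[i], ".u")]] * sim[[paste0(inc$id[i], ".v")]]
      res <- res + p
      scale <- pmax(scale, abs(p))
    }
    jv <- sim[[bal$shared]]
    pts <- bal$sum_terms[bal$sum_terms$role == "port", ]
    for (i in seq_len(nrow(pts))) {
      bound <- sim[[pts$term[i]]]
      p <- pts$coef[i] * jv * bound
      res <- res + p
      scale <- pmax(scale, abs(p))
    }
    sc <- max(scale, 0)
    tibble::tibble(
      junction = j_id,
      kind = bal$kind,
      max_abs_residual = max(abs(res)),
      scale = sc,
      max_rel_residual = if (sc > 0) max(abs(res)) / sc else max(abs(res))
    )
  })
  class(rows) <- c("bg_audit", class(rows))
  rows
}

#' @method glance bg_audit
#' @export
glance.bg_audit <- function(x, ...) {
  tibble::tibble(
    n_junctions = nrow(x),
    max_abs_residual = max(x$max_abs_residual),
    max_rel_residual = max(x$max_rel_residual)
  )
}
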