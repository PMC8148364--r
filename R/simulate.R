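#' Two-term Gaussian cardiac beat waveform
#'
#' A periodic volumetric inflow built from two Gaussian terms,
#' \deqn{f(t) = \sum_{i=1}^{2} a_i \exp\!\big[-\big((t \bmod T - b_i)/c_i\big)^2\big],}
#' the standard compact fit for a single-peak ventricular ejection wave.
#' The package defaults (`a = (4.2e-4, 0.8e-4)` m^3/s, `b = (0.15, 0.30)` s,
#' `c = (0.08, 0.12)` s, `T = 1` s) produce a physiologically shaped ejection
#' of roughly 76 mL per beat at 60 bpm; they are this package's own choice of
#' a plausible waveform, not a fit to any published recording, and every
#' value is user-configurable (see [read_waveform()]).
#'
#' @param a Peak amplitudes of the two terms, m^3 s^-1.
#' @param b Peak centres, s.
#' @param c Peak widths, s (nonzero).
#' @param period Beat period `T` in s (> 0).
#' @return An object of class `bg_beat`.
#' @export
#' @examples
#' w <- beat_waveform()
#' beat_flow(w, c(0, 0.15, 0.5, 1.15))
beat_waveform <- function(a = base::c(4.2e-4, 0.8e-4), b = base::c(0.15, 0.30),
                          c = base::c(0.08, 0.12), period = 1.0) {
  stopifnot(length(a) == length(b), length(b) == length(c))
  if (any(c == 0)) stop_bondnet("Gaussian width c must be nonzero", "bondnet_waveform")
  if (period <= 0) stop_bondnet("period must be positive", "bondnet_waveform")
  structure(list(terms = tibble::tibble(a = a, b = b, c = c), period = period),
            class = "bg_beat")
}

#' Evaluate a beat waveform
#'
#' Evaluates the two-term Gaussian inflow at times `t`, periodically extended
#' with period `T` (`f(t + T) = f(t)`).
#'
#' @param w A [beat_waveform()].
#' @param t Times in s (vectorised).
#' @return Flow in m^3 s^-1.
#' @export
beat_flow <- function(w, t) {
  x <- t %% w$period
  out <- numeric(length(x))
  for (i in seq_len(nrow(w$terms))) {
    out <- out + w$terms$a[i] * exp(-((x - w$terms$b[i]) / w$terms$c[i])^2)
  }
  out
}

#' Read / write a waveform parameter file
#'
#' JSON format: `{"terms": [{"a":..,"b":..,"c":..}, ...], "period": ..}`.
#'
#' @param path File path.
#' @return `read_waveform()`: a `bg_beat`; `write_waveform()`: `path`.
#' @export
read_waveform <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- tibble::as_tibble(doc$terms)
  beat_waveform(a = tm$a, b = tm$b, c = tm$c, period = doc$period %||% 1.0)
}

#' @rdname read_waveform
#' @param w A `bg_beat`.
#' @export
write_waveform <- function(w, path) {
  jsonlite::write_json(list(terms = w$terms, period = w$period), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Integrate an assembled system
#'
#' Integrates `dx/dt = A x + B w(t) + b0` from given initial states (default
#' all zero) over `[0, t_end]` with a stiff-capable adaptive scheme
#' (deSolve's `lsoda`), and stores the states together with every junction
#' and bond variable on a uniform output grid.
#'
#' @param sys A `bg_ode`.
#' @param inputs Named list binding external inputs by source id or reference
#'   name; values may be numbers, functions of time, or [beat_waveform()]
#'   objects. Constant source parameters are used automatically.
#' @param t_end End time, s (> 0).
#' @param dt Output grid spacing, s (default 1 ms).
#' @param init Initial state: `NULL` (all zero) or a (named) numeric vector.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integrator name.
#' @return A tibble of class `bg_sim`: column `time` plus one column per
#'   state (`q` in m^3, `v` in m^3/s) and per algebraic variable (junction
#'   and bond potentials in J m^-3, flows in m^3 s^-1).
#' @export
#' @examples
#' seg <- make_segment("initial", "root", list(l = 0.1, r = 0.01))
#' sys <- assemble_ode(seg)
#' sim <- simulate_ode(sys, inputs = list(cardiac_inflow = 1e-5), t_end = 0.1)
simulate_ode <- function(sys, inputs = list(), t_end, dt = 1e-3, init = NULL,
                         rtol = 1e-8, atol = 1e-12, method = "lsoda") {
  if (t_end <= 0) stop_bondnet("t_end must be positive", "bondnet_simulate")
  ids <- sys$states$id
  ns <- length(ids)
  y0 <- if (is.null(init)) setNames(numeric(ns), ids) else {
    setNames(resolve_state(sys, init), ids)
  }
  times <- seq(0, t_end, by = dt)
  has_inp <- nrow(sys$inputs) > 0

  w_at <- function(t) resolve_inputs(sys, inputs, t)
  # fail early on missing inputs
  if (has_inp) invisible(w_at(0))

  deriv <- function(t, y, parms) {
    dy <- sys$A %*% y + sys$b0
    if (has_inp) dy <- dy + sys$B %*% w_at(t)
    if (any(!is.finite(dy))) {
      stop_bondnet(paste0("non-finite state derivative at t = ", t),
                   "bondnet_simulate")
    }
    list(drop(dy))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop_bondnet(paste0("solver failure near t = ", max(sol[, "time"])),
                 "bondnet_simulate")
  }
  tgrid <- sol[, "time"]
  Y <- sol[, ids, drop = FALSE]
  W <- if (has_inp) {
    wm <- vapply(tgrid, w_at, numeric(nrow(sys$inputs)))
    if (is.null(dim(wm))) wm <- matrix(wm, nrow = 1)
    t(wm)
  } else {
    matrix(0, length(tgrid), 0)
  }
  basis <- cbind(1, Y, W)
  X <- basis %*% t(sys$outputs)
  out <- tibble::as_tibble(as.data.frame(cbind(time = tgrid, Y, X)))
  attr(out, "state_ids") <- ids
  attr(out, "var_names") <- sys$x_names
  class(out) <- c("bg_sim", class(out))
  out
}

#' Extract the final steady cycle of a simulation
#'
#' Returns the last window of length `period` (for instance the 9-10 s
#' window of a 10 s run), time-shifted to start at 0, so that post-transient
#' cycles can be compared across models. Applying it again with the same
#' period is the identity.
#'
#' @param res A `bg_sim`.
#' @param period Cycle length in s.
#' @return A `bg_sim` covering `[0, period]`.
#' @export
last_cycle <- function(res, period) {
  span <- max(res$time) - min(res$time)
  tol <- 1e-9 * max(period, 1)
  if (span < period - tol) {
    stop_bondnet("trajectory shorter than one period", "bondnet_simulate")
  }
  t0 <- max(res$time) - period
  keep <- res$time >= t0 - tol
  out <- res[keep, ]
  out$time <- out$time - t0
  out
}

#' @export
print.bg_sim <- function(x, ...) {
  cat("<bg_sim> ", nrow(x), " time points over [",
      format(min(x$time)), ", ", format(max(x$time)), "] s, ",
      ncol(x) - 1, " traces\n", sep = "")
  NextMethod()
}

#' Write simulation traces as CSV
#'
#' @param res A `bg_sim`.
#' @param path Output CSV (column 1 time, one column per variable).
#' @param variables Subset of trace names (default: all).
#' @return `path`, invisibly.
#' @export
write_traces <- function(res, path, variables = NULL) {
  cols <- c("time", variables %||% setdiff(names(res), "time"))
  utils::write.csv(as.data.frame(res)[cols], path, row.names = FALSE)
  invisible(path)
}
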