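#' Normalised root-mean-square error between two traces
#'
#' \deqn{\mathrm{NRMSE} = 100 \times
#'   \frac{\sqrt{\sum_i (\hat y_i - y_i)^2 / n}}{y_{max} - y_{min}}}
#' where `y` is the reference series; normalisation is by the reference's
#' max-min range and the result is reported in percent. Scale-invariant
#' (`nrmse(k*test, k*ref) == nrmse(test, ref)` for `k != 0`) and undefined
#' for a constant reference.
#'
#' @param test Numeric series under test.
#' @param reference Numeric reference series, same length (>= 2).
#' @return NRMSE in percent.
#' @export
#' @examples
#' nrmse(c(1, 2, 3), c(0, 1, 2))  # RMSE 1 over range 2 -> 50
nrmse <- function(test, reference) {
  if (length(test) != length(reference)) {
    stop_bondnet("length mismatch", "bondnet_nrmse")
  }
  if (length(reference) < 2) {
    stop_bondnet("need at least 2 points", "bondnet_nrmse")
  }
  if (any(!is.finite(test)) || any(!is.finite(reference))) {
    stop_bondnet("non-finite values", "bondnet_nrmse")
  }
  rng <- max(reference) - min(reference)
  if (rng == 0) stop_bondnet("zero range in reference series", "bondnet_nrmse")
  100 * sqrt(mean((test - reference)^2)) / rng
}

#' Compare two simulation runs variable by variable
#'
#' Computes per-variable NRMSE between two runs, with `b` as the reference.
#' If the time grids differ, both runs are linearly interpolated onto the
#' coarser grid restricted to the overlapping time span.
#'
#' @param a,b `bg_sim` results (`b` is the reference).
#' @param variables Trace names to compare (default: all traces common to
#'   both runs).
#' @return A tibble of class `bg_comparison` with columns `variable`,
#'   `nrmse_percent`, `n` and `ref_range`; `glance()` gives the summary
#'   maximum.
#' @export
compare_runs <- function(a, b, variables = NULL) {
  common <- intersect(setdiff(names(a), "time"), setdiff(names(b), "time"))
  defaulted <- is.null(variables)
  variables <- variables %||% common
  missing <- setdiff(variables, common)
  if (length(missing) > 0) {
    stop_bondnet(paste0("variable(s) absent from both runs: ",
                        paste(missing, collapse = ", ")), "bondnet_compare")
  }
  t0 <- max(min(a$time), min(b$time))
  t1 <- min(max(a$time), max(b$time))
  if (t1 <= t0) stop_bondnet("time grids do not overlap", "bondnet_compare")
  ga <- a$time[a$time >= t0 & a$time <= t1]
  gb <- b$time[b$time >= t0 & b$time <= t1]
  grid <- if (length(ga) <= length(gb)) ga else gb
  same_grid <- length(a$time) == length(b$time) && all(a$time == b$time)

  pick <- function(run, var) {
    if (same_grid) return(run[[var]])
    approx(run$time, run[[var]], xout = grid)$y
  }
  out <- purrr::map_dfr(variables, function(v) {
    ya <- pick(a, v); yb <- pick(b, v)
    if (defaulted && max(yb) - min(yb) == 0) {
      # constant reference traces (e.g. held-at-zero ports) carry no range
      # to normalise by; silently dropped unless requested explicitly
      return(NULL)
    }
    tibble::tibble(
      variable = v,
      nrmse_percent = nrmse(ya, yb),
      n = length(yb),
      ref_range = max(yb) - min(yb)
    )
  })
  class(out) <- c("bg_comparison", class(out))
  out
}

#' @method glance bg_comparison
#' @export
glance.bg_comparison <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x),
    max_nrmse_percent = max(x$nrmse_percent),
    mean_nrmse_percent = mean(x$nrmse_percent)
  )
}
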