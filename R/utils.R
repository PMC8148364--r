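# Locale-independent sort so generated systems are byte-reproducible.
lex_sort <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

# A linear form is a named numeric vector of coefficients over variable names,
# with the reserved name "(const)" for the constant term.
lf_const <- function(x = 0) c("(const)" = x)

lf_var <- function(name, coef = 1) setNames(coef, name)

lf_add <- function(a, b) {
  nm <- union(names(a), names(b))
  out <- setNames(numeric(length(nm)), nm)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out
}

lf_scale <- function(a, k) a * k

# Drop zero coefficients (keeps prints tidy); constant kept if nonzero.
lf_trim <- function(a, tol = 0) {
  keep <- abs(a) > tol | (names(a) == "(const)" & a != 0)
  a[keep]
}

lf_format <- function(a, digits = 6) {
  a <- lf_trim(a)
  if (length(a) == 0) return("0")
  parts <- purrr::imap_chr(as.list(a), function(coef, nm) {
    sgn <- if (coef < 0) "- " else "+ "
    mag <- abs(coef)
    if (nm == "(const)") {
      paste0(sgn, format(mag, digits = digits))
    } else if (mag == 1) {
      paste0(sgn, nm)
    } else {
      paste0(sgn, format(mag, digits = digits), "*", nm)
    }
  })
  sub("^\\+ ", "", paste(parts, collapse = " "))
}

stop_bondnet <- function(msg, class) {
  abort(msg, class = c(class, "bondnet_error"))
}
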