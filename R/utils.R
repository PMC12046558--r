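# small internal vector helpers shared across modules

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v, what = "vector") {
  n <- .vnorm(v)
  if (n < 1e-10) stop("degenerate zero-length ", what, call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Wrap angles into the interval (-180, 180]
#'
#' Torsion angles and angle differences are reported on the chemist's
#' convention of a half-open degree interval centred on zero.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped into (-180, 180].
#' @examples
#' wrap_angle(c(190, -190, 540, 180, -180))
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

# ASCII arm-state tokens in canonical order; display maps to Greek
.STATE_TOKENS <- c("a", "a'", "b", "b'")

.state_rank <- function(tokens) {
  r <- match(tokens, .STATE_TOKENS)
  if (anyNA(r)) {
    stop("invalid arm state token(s): ",
         paste(tokens[is.na(r)], collapse = ", "),
         " (expected one of a, a', b, b')", call. = FALSE)
  }
  r
}

#' Pretty-print a conformer label with Greek letters
#'
#' Converts the package's ASCII arm-state tokens (`a`, `a'`, `b`, `b'`)
#' into the conventional Greek notation (alpha, alpha-prime, beta,
#' beta-prime) used for paddlewheel conformers.
#'
#' @param label character vector of labels such as `"aabb"` or `"aaaa'"`.
#' @return character vector with Greek letters.
#' @export
format_label <- function(label) {
  out <- gsub("a", "\u03b1", label, fixed = TRUE)
  out <- gsub("b", "\u03b2", out, fixed = TRUE)
  gsub("'", "\u2032", out, fixed = TRUE)
}
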