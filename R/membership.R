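#' Pi-type membership function
#'
#' Builds a plateau membership with smooth quadratic S/Z ramps on both flanks,
#' the shape used for every fuzzy input variable in the risk engine. The
#' function is 0 outside `[a, d]`, 1 on the plateau `[b, c]`, and crosses 0.5
#' exactly at the ramp midpoints `(a+b)/2` and `(c+d)/2`. Infinite `a = b`
#' (or `c = d`) produce an open shoulder: the plateau extends to the universe
#' edge on that side.
#'
#' @param a,b left ramp feet/shoulder (`a <= b`); use `-Inf` for an open left
#'   shoulder.
#' @param c,d right shoulder/feet (`c <= d`); use `Inf` for an open right
#'   shoulder.
#' @param name optional label for the fuzzy set.
#' @return An object of class `pi_mf`: a function of `x` returning membership
#'   degrees in `[0, 1]`, with the parameters attached.
#' @examples
#' normal_ct <- pi_mf(35, 36, 37.5, 38.5, name = "Normal")
#' normal_ct(c(34, 35.5, 37, 38, 39))
#' @export
pi_mf <- function(a, b, c, d, name = NULL) {
  stopifnot(a <= b, b <= c, c <= d)
  f <- function(x) {
    y <- numeric(length(x))
    y[x >= b & x <= c] <- 1
    if (is.finite(a) && a < b) {
      m <- (a + b) / 2
      i <- x > a & x < m
      y[i] <- 2 * ((x[i] - a) / (b - a))^2
      i <- x >= m & x < b
      y[i] <- 1 - 2 * ((x[i] - b) / (b - a))^2
    } else if (!is.finite(b)) {
      y[x <= c] <- 1
    }
    if (is.finite(d) && c < d) {
      m <- (c + d) / 2
      i <- x > c & x < m
      y[i] <- 1 - 2 * ((x[i] - c) / (d - c))^2
      i <- x >= m & x < d
      y[i] <- 2 * ((x[i] - d) / (d - c))^2
    } else if (!is.finite(c)) {
      y[x >= b] <- 1
    }
    y
  }
  structure(f, class = c("pi_mf", "membership"),
            params = c(a = a, b = b, c = c, d = d), name = name)
}

#' Triangular membership function
#'
#' Linear-flank membership used for the risk-level output sets: 0 outside
#' `[a, c]`, 1 only at the apex `b`.
#'
#' @param a,b,c left foot, apex and right foot (`a <= b <= c`).
#' @param name optional label for the fuzzy set.
#' @return An object of class `tri_mf`: a function of `x` returning
#'   membership degrees in `[0, 1]`.
#' @examples
#' safe <- tri_mf(0, 5, 10.5, name = "Safe")
#' safe(c(0, 5, 8))
#' @export
tri_mf <- function(a, b, c, name = NULL) {
  stopifnot(a <= b, b <= c, a < c)
  f <- function(x) {
    y <- numeric(length(x))
    if (b > a) {
      i <- x > a & x <= b
      y[i] <- (x[i] - a) / (b - a)
    } else {
      y[x == b] <- 1
    }
    if (c > b) {
      i <- x > b & x < c
      y[i] <- (c - x[i]) / (c - b)
    }
    y
  }
  structure(f, class = c("tri_mf", "membership"),
            params = c(a = a, b = b, c = c), name = name)
}

#' @export
print.membership <- function(x, ...) {
  p <- attr(x, "params")
  nm <- attr(x, "name")
  cat(sprintf("<%s%s> %s\n", class(x)[1],
              if (is.null(nm)) "" else paste0(" '", nm, "'"),
              paste(names(p), signif(p, 6), sep = "=", collapse = " ")))
  invisible(x)
}
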