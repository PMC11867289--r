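# Constrained cubic Bezier representation of the tissue residue function
# R(t), with analytic MTT, transit-time density h(t) = -dR/dt, and CTH.
#
# Control points: P0 = (0, 1), P1 = (p1x, p1y), P2 = (p2x, p2y),
# P3 = (t_end, 0). The orderings 0 <= p1x <= p2x <= t_end and
# 1 >= p1y >= p2y >= 0 make x(s) non-decreasing and y(s) non-increasing,
# so the curve is the graph of a non-increasing function from R(0) = 1 to
# R(t_end) = 0, and h integrates to exactly 1. Five coordinates are free.

#' Constrained Bezier residue function
#'
#' @param p1x,p2x Abscissae of the two interior control points (seconds),
#'   with `0 <= p1x <= p2x <= t_end`.
#' @param p1y,p2y Ordinates of the interior control points, with
#'   `1 >= p1y >= p2y >= 0`.
#' @param t_end Support endpoint in seconds (`R(t_end) = 0`), `> 0`.
#' @return An object of class `bezier_residue`.
#' @export
bezier_residue <- function(p1x, p1y, p2x, p2y, t_end) {
  eps <- 1e-12
  if (!(t_end > 0)) stop("t_end must be positive")
  if (!(p1x >= -eps && p1x <= p2x + eps && p2x <= t_end + eps)) {
    stop("control point abscissae must satisfy 0 <= p1x <= p2x <= t_end")
  }
  if (!(p1y <= 1 + eps && p2y <= p1y + eps && p2y >= -eps)) {
    stop("control point ordinates must satisfy 1 >= p1y >= p2y >= 0")
  }
  structure(list(p1x = max(p1x, 0), p1y = min(p1y, 1),
                 p2x = min(max(p2x, p1x), t_end), p2y = max(min(p2y, p1y), 0),
                 t_end = t_end),
            class = "bezier_residue")
}

#' @export
print.bezier_residue <- function(x, ...) {
  cat(sprintf(
    "Bezier residue: P1 = (%.4g, %.4g), P2 = (%.4g, %.4g), t_end = %.4g s\n",
    x$p1x, x$p1y, x$p2x, x$p2y, x$t_end))
  cat(sprintf("  MTT = %.4g s, CTH = %.4g s^2\n", mtt(x), cth(x)))
  invisible(x)
}

# curve point and derivative in Bezier parameter s (vectorised over s)
.bezier_xy <- function(res, s) {
  u <- 1 - s
  x <- 3 * u^2 * s * res$p1x + 3 * u * s^2 * res$p2x + s^3 * res$t_end
  y <- u^3 + 3 * u^2 * s * res$p1y + 3 * u * s^2 * res$p2y
  xp <- 3 * (u^2 * res$p1x + 2 * u * s * (res$p2x - res$p1x) +
               s^2 * (res$t_end - res$p2x))
  yp <- 3 * (u^2 * (res$p1y - 1) + 2 * u * s * (res$p2y - res$p1y) +
               s^2 * (0 - res$p2y))
  list(x = x, y = y, xp = xp, yp = yp)
}

# Invert x(s) = t for t in [0, t_end]: safeguarded Newton with a bisection
# bracket, vectorised over t. x'(s) >= 0 can touch 0 only at isolated
# points, so bisection always makes progress. Tolerance 1e-10 in s.
.bezier_solve_s <- function(res, t) {
  n <- length(t)
  lo <- numeric(n)
  hi <- rep(1, n)
  s <- pmin(pmax(t / res$t_end, 0), 1)  # linear-curve initial guess
  for (iter in seq_len(100)) {
    b <- .bezier_xy(res, s)
    f <- b$x - t
    lo <- ifelse(f < 0, s, lo)
    hi <- ifelse(f > 0, s, hi)
    step_ok <- b$xp > 1e-14
    s_new <- ifelse(step_ok, s - f / pmax(b$xp, 1e-14), (lo + hi) / 2)
    # fall back to bisection when Newton leaves the bracket
    s_new <- ifelse(s_new <= lo | s_new >= hi, (lo + hi) / 2, s_new)
    if (max(abs(s_new - s)) < 1e-10) {
      s <- s_new
      break
    }
    s <- s_new
  }
  s
}

#' Evaluate the residue function
#'
#' @param residue A [bezier_residue].
#' @param t Times in seconds (vectorised), `>= 0`.
#' @return R(t) in `[0, 1]`; 1 at `t = 0`, 0 for `t >= t_end`.
#' @export
evaluate_residue <- function(residue, t) {
  stopifnot(inherits(residue, "bezier_residue"))
  out <- numeric(length(t))
  inside <- t > 0 & t < residue$t_end
  out[t <= 0] <- 1
  if (any(inside)) {
    s <- .bezier_solve_s(residue, t[inside])
    out[inside] <- pmin(pmax(.bezier_xy(residue, s)$y, 0), 1)
  }
  out
}

# h(t) at arbitrary times; -y'(s)/x'(s) along the curve, with isolated
# zeros of x' handled by a small parameter offset
.density_at <- function(residue, tau) {
  out <- numeric(length(tau))
  inside <- tau >= 0 & tau < residue$t_end
  if (any(inside)) {
    s <- .bezier_solve_s(residue, tau[inside])
    b <- .bezier_xy(residue, s)
    flat <- b$xp < 1e-12
    if (any(flat)) {
      s2 <- pmin(pmax(s[flat] + 1e-6, 1e-6), 1 - 1e-6)
      b2 <- .bezier_xy(residue, s2)
      b$xp[flat] <- b2$xp
      b$yp[flat] <- b2$yp
    }
    out[inside] <- pmax(-b$yp / pmax(b$xp, 1e-12), 0)
  }
  out
}

#' Transit-time distribution h(t) = -dR/dt
#'
#' Evaluates the capillary transit-time density along the Bezier curve as
#' `-y'(s)/x'(s)`. The construction guarantees `h >= 0` and
#' `integral h dt = R(0) - R(t_end) = 1`.
#'
#' @param residue A [bezier_residue].
#' @param tau Optional evaluation grid (seconds); defaults to a uniform
#'   grid of `n` points on `[0, t_end]`.
#' @param n Grid size when `tau` is not supplied.
#' @return A `data.frame` with columns `tau` and `density`.
#' @export
transit_time_density <- function(residue, tau = NULL, n = 512) {
  stopifnot(inherits(residue, "bezier_residue"))
  # a genuinely vertical segment (x constant over an s-interval) has no
  # density representation; it requires all four abscissae to coincide
  if (residue$t_end <= 0 || (residue$p1x == 0 && residue$p2x == 0 &&
                             residue$t_end < 1e-12)) {
    stop("degenerate residue: vertical segment has no transit-time density")
  }
  if (is.null(tau)) tau <- seq(0, residue$t_end, length.out = n)
  data.frame(tau = tau, density = .density_at(residue, tau))
}

# Gauss-Legendre nodes on [0,1]; n = 6 is exact for polynomials of
# degree <= 11, covering both moment integrands below
.gl6 <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- pracma::gaussLegendre(6, 0, 1)
    g
  }
})

#' Mean transit time of a residue function
#'
#' `MTT = integral_0^inf R(t) dt`, computed in Bezier parameter space as
#' `integral_0^1 y(s) x'(s) ds` with fixed-order Gauss-Legendre quadrature
#' (the integrand is a degree-5 polynomial, so the rule is exact).
#'
#' @param residue A [bezier_residue].
#' @return MTT in seconds.
#' @export
mtt <- function(residue) {
  stopifnot(inherits(residue, "bezier_residue"))
  g <- .gl6()
  b <- .bezier_xy(residue, g$x)
  sum(g$w * b$y * b$xp)
}

#' Capillary transit time heterogeneity
#'
#' The central second moment of the transit-time distribution,
#' `CTH = integral (t - MTT)^2 h(t) dt`, computed exactly in parameter
#' space as `integral_0^1 (x(s) - MTT)^2 (-y'(s)) ds` (degree-8
#' polynomial integrand). By default the squared-seconds second moment is
#' returned; `as_sd = TRUE` returns its square root (the
#' standard-deviation convention used in parts of the CTH literature).
#'
#' @param residue A [bezier_residue].
#' @param as_sd If `TRUE` return the standard deviation (seconds) instead
#'   of the variance (seconds squared).
#' @return CTH in s^2 (default) or s (`as_sd = TRUE`).
#' @export
cth <- function(residue, as_sd = FALSE) {
  stopifnot(inherits(residue, "bezier_residue"))
  m <- mtt(residue)
  g <- .gl6()
  b <- .bezier_xy(residue, g$x)
  v <- sum(g$w * (b$x - m)^2 * (-b$yp))
  if (as_sd) sqrt(max(v, 0)) else v
}

#' Serialise a residue function to / from JSON
#'
#' Records are flat objects `{p1x, p1y, p2x, p2y, t_end}`.
#'
#' @param residue A [bezier_residue].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `residue_to_json`: a JSON string (or `path` invisibly);
#'   `residue_from_json`: a [bezier_residue].
#' @export
residue_to_json <- function(residue, path = NULL) {
  stopifnot(inherits(residue, "bezier_residue"))
  js <- jsonlite::toJSON(unclass(residue), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname residue_to_json
#' @param x A JSON string or path to a JSON file.
#' @export
residue_from_json <- function(x) {
  rec <- jsonlite::fromJSON(x)
  bezier_residue(rec$p1x, rec$p1y, rec$p2x, rec$p2y, rec$t_end)
}

# Optimiser-facing reparameterisation: (a, b, c, d) in [0,1]^4 plus t_end
# turn the ordering constraints into simple box bounds.
#   p1x = a * t_end;  p2x = p1x + b * (t_end - p1x)
#   p1y = 1 - c;      p2y = p1y * (1 - d)
.theta_to_residue <- function(a, b, c, d, t_end) {
  p1x <- a * t_end
  p2x <- p1x + b * (t_end - p1x)
  p1y <- 1 - c
  p2y <- p1y * (1 - d)
  bezier_residue(p1x, p1y, p2x, p2y, t_end)
}

#' Linear residue function with a given mean transit time
#'
#' A degenerate Bezier curve with collinear control points realising
#' `R(t) = 1 - t/t_end` on `[0, t_end]`, i.e. a uniform transit-time
#' distribution with `MTT = t_end / 2`. Handy as a simple, fully
#' analytic ground truth.
#'
#' @param mtt Target mean transit time in seconds.
#' @return A [bezier_residue] with `t_end = 2 * mtt`.
#' @export
linear_residue <- function(mtt) {
  stopifnot(mtt > 0)
  t_end <- 2 * mtt
  bezier_residue(t_end / 3, 2 / 3, 2 * t_end / 3, 1 / 3, t_end)
}
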