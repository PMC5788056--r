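#' Conic ellipse fit of a target-hand phase plot
#'
#' Fits the conic `a u^2 + 2 b u v + c v^2 + 2 d u + 2 e v + f = 0` to
#' paired target/hand position samples by direct least squares with the
#' ellipse-specific constraint (the Fitzgibbon constraint, solved with the
#' numerically stable partitioned eigensystem), then extracts the centre,
#' the counterclockwise major-axis angle, and the major-axis slope and
#' intercept — the diagnostics that separate a gain/mechanical
#' representation (slope > 1) from a spatial shift (intercept > 0).
#'
#' The centre is `o_u = (c d - b e) / (b^2 - a c)`,
#' `o_v = (a e - b d) / (b^2 - a c)`; the rotation angle uses the
#' four-case arccotangent rule conditioned on `a` vs `c` (with the
#' arccotangent on (-pi/2, pi/2]), mapped into [0, pi); slope = tan(theta)
#' and intercept = o_v - slope * o_u.
#'
#' Near-collinear scatter (minor/major axis ratio < `degeneracy_ratio`)
#' falls back to the principal axis of the centred scatter, with the line
#' through the centroid; exactly collinear input is an error.
#'
#' @param u Target positions, cm (abscissa).
#' @param v Hand positions, cm (ordinate), same length as `u`.
#' @param degeneracy_ratio Axis ratio below which the principal-axis
#'   fallback is used (default 1e-3).
#' @return Object of class `ellipse_fit`: list with `conic` (named a..f),
#'   `center` c(o_u, o_v), `theta` (rad, in [0, pi)), `slope`, `intercept`
#'   (cm), `axes` c(semi_major, semi_minor), and `fallback` (logical).
#' @export
fit_ellipse <- function(u, v, degeneracy_ratio = 1e-3) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("u and v must have the same length")
  ok <- is.finite(u) & is.finite(v)
  u <- u[ok]; v <- v[ok]
  if (length(u) < 6L)
    stop("insufficient data: at least 6 points are required")
  um <- mean(u); vm <- mean(v)
  sv <- svd(cbind(u - um, v - vm))$d
  if (sv[2] <= sv[1] * 1e-12)
    stop("degenerate fit: points are exactly collinear; the principal-axis ",
         "fallback applies only to near-collinear (noisy) scatter")

  fit <- halir_flusser(u, v)
  if (is.null(fit)) return(principal_axis_fallback(u, v))
  cf <- fit # named a,b,c,d,e,f in the 2b/2d/2e parameterization
  # normalize so the quadratic form is positive definite (conic is defined
  # up to a global sign)
  if (cf["a"] < 0) cf <- -cf
  disc <- cf["b"]^2 - cf["a"] * cf["c"]
  o_u <- (cf["c"] * cf["d"] - cf["b"] * cf["e"]) / disc
  o_v <- (cf["a"] * cf["e"] - cf["b"] * cf["d"]) / disc
  # semi-axes from the centred form: F0 + [u v] Q [u v]' = 0
  F0 <- cf["a"] * o_u^2 + 2 * cf["b"] * o_u * o_v + cf["c"] * o_v^2 +
    2 * cf["d"] * o_u + 2 * cf["e"] * o_v + cf["f"]
  Q <- matrix(c(cf["a"], cf["b"], cf["b"], cf["c"]), 2L)
  lam <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values # decreasing
  if (any(lam <= 0) || F0 >= 0) return(principal_axis_fallback(u, v))
  semi_major <- sqrt(-F0 / lam[2])
  semi_minor <- sqrt(-F0 / lam[1])
  if (semi_minor / semi_major < degeneracy_ratio)
    return(principal_axis_fallback(u, v))
  theta <- conic_angle(cf["a"], cf["b"], cf["c"])
  new_ellipse_fit(conic = cf, center = c(o_u, o_v), theta = theta,
                  axes = c(semi_major, semi_minor), fallback = FALSE)
}

# Major-axis angle of conic a u^2 + 2 b u v + c v^2 (positive-definite
# normalization), by the four-case arccotangent rule; acot is the Matlab
# convention atan(1/x) with range (-pi/2, 0) U (0, pi/2].
conic_angle <- function(a, b, c) {
  acot <- function(x) atan(1 / x)
  scale <- abs(a) + abs(c)
  theta <-
    if (abs(b) < 1e-12 * scale) {
      if (a <= c) 0 else pi / 2
    } else if (abs(a - c) < 1e-12 * scale) {
      if (b < 0) pi / 4 else 3 * pi / 4
    } else if (a < c) {
      0.5 * acot((a - c) / (2 * b))
    } else {
      pi / 2 + 0.5 * acot((a - c) / (2 * b))
    }
  theta %% pi
}

new_ellipse_fit <- function(conic, center, theta, axes, fallback) {
  slope <- tan(theta)
  structure(list(conic = conic, center = unname(center), theta = unname(theta),
                 slope = unname(slope),
                 intercept = unname(center[2] - slope * center[1]),
                 axes = unname(axes), fallback = fallback),
            class = "ellipse_fit")
}

# Direct least-squares ellipse fit (partitioned scatter-matrix eigensystem).
# Returns named conic coefficients in the 2b/2d/2e convention, or NULL if
# no ellipse solution exists.
halir_flusser <- function(u, v) {
  # centre and scale for conditioning; coefficients mapped back afterwards
  mu <- mean(u); mv <- mean(v)
  s <- max(stats::sd(u), stats::sd(v))
  if (!is.finite(s) || s == 0) return(NULL)
  x <- (u - mu) / s; y <- (v - mv) / s
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(NULL)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eig <- eigen(M)
  ev <- Re(eig$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  good <- which(cond > 0)
  if (!length(good)) return(NULL)
  a1 <- ev[, good[1]]
  coef_s <- c(a1, Tm %*% a1) # A,B,C,D,E,F in scaled frame
  # undo scaling: x = (u-mu)/s, y = (v-mv)/s
  A <- coef_s[1] / s^2
  B <- coef_s[2] / s^2
  C <- coef_s[3] / s^2
  D <- coef_s[4] / s - 2 * A * mu - B * mv
  E <- coef_s[5] / s - 2 * C * mv - B * mu
  F <- coef_s[6] + A * mu^2 + B * mu * mv + C * mv^2 -
    coef_s[4] * mu / s - coef_s[5] * mv / s
  c(a = A, b = B / 2, c = C, d = D / 2, e = E / 2, f = F)
}

# Near-degenerate scatter: slope from the first principal axis of the
# centred scatter, line through the centroid.
principal_axis_fallback <- function(u, v) {
  um <- mean(u); vm <- mean(v)
  eg <- eigen(stats::cov(cbind(u, v)), symmetric = TRUE)
  pc <- eg$vectors[, 1]
  theta <- atan2(pc[2], pc[1]) %% pi
  axes <- sqrt(pmax(eg$values, 0))
  new_ellipse_fit(conic = c(a = NA_real_, b = NA_real_, c = NA_real_,
                            d = NA_real_, e = NA_real_, f = NA_real_),
                  center = c(um, vm), theta = theta,
                  axes = axes, fallback = TRUE)
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit>%s center (%.3f, %.3f) cm, theta %.4f rad\n  slope %.4f, intercept %.4f cm\n",
    if (x$fallback) " [principal-axis fallback]" else "",
    x$center[1], x$center[2], x$theta, x$slope, x$intercept))
  invisible(x)
}
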