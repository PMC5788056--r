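# shared fixture builders

sine_traj <- function(A = 8, T_cycle = 5, rate = 200, dur = T_cycle,
                      phase = 0, center = 0) {
  t <- (0:round(dur * rate)) / rate
  trajectory(x = rep(0, length(t)),
             y = center + A * sin(2 * pi * t / T_cycle + phase),
             t = t, rate = rate)
}

# parametric rotated ellipse point cloud
ellipse_points <- function(theta, a = 3, b = 1, center = c(0, 0), n = 400) {
  tt <- seq(0, 2 * pi, length.out = n)
  u <- a * cos(tt); v <- b * sin(tt)
  cbind(center[1] + u * cos(theta) - v * sin(theta),
        center[2] + u * sin(theta) + v * cos(theta))
}

# independent lag oracle: literal shift-and-normalized-product search
brute_force_lag <- function(h, g, rate, max_lag = 2) {
  h <- h - mean(h); g <- g - mean(g)
  n <- length(h)
  K <- round(max_lag * rate)
  best <- -Inf; best_m <- 0L
  for (m in -K:K) {
    if (m >= 0) { hs <- h[1:(n - m)]; gs <- g[(1 + m):n] }
    else { hs <- h[(1 - m):n]; gs <- g[1:(n + m)] }
    v <- as.numeric(crossprod(hs, gs)) /
      sqrt(as.numeric(crossprod(hs)) * as.numeric(crossprod(gs)))
    if (v > best) { best <- v; best_m <- m }
  }
  best_m / rate
}
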