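# small shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# arc length of an ordered polyline (n x 3)
polyline_arc <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

cum_arc <- function(p) {
  if (nrow(p) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))))
}

# linear interpolation of positions (and optionally scalars) at arc position s
interp_along <- function(p, s_target, scalars = NULL) {
  s <- cum_arc(p)
  s_target <- min(max(s_target, 0), s[length(s)])
  i <- findInterval(s_target, s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(p) - 1L)
  h <- s[i + 1] - s[i]
  t <- if (h > 0) (s_target - s[i]) / h else 0
  pos <- p[i, ] + t * (p[i + 1, ] - p[i, ])
  out <- list(position = pos, arc = s_target, index = i, frac = t)
  if (!is.null(scalars)) out$value <- scalars[i] + t * (scalars[i + 1] - scalars[i])
  out
}

# run an expression with a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# normal draw truncated to mean +/- 3 sd and an optional hard floor
rtnorm3 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- max(mean - 3 * sd, lower)
  hi <- min(mean + 3 * sd, upper)
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

rotate_about_axis <- function(v, axis, angle_rad) {
  a <- unitize(axis)
  v * cos(angle_rad) + pracma_cross(a, v) * sin(angle_rad) +
    a * sum(a * v) * (1 - cos(angle_rad))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

angle_between_deg <- function(u, v) {
  cu <- unitize(u); cv <- unitize(v)
  d <- sum(cu * cv)
  acos(min(1, max(-1, d))) * 180 / pi
}
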