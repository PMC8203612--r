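#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic operation in the pipeline draws its seed deterministically
#' from the global run seed and a short stage tag, so that stages can be rerun
#' independently and two runs with the same global seed are identical.
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag (e.g. `"stage1"`, `"slide0007"`).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 131 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# largest-remainder apportionment of n units to non-negative weights
largest_remainder <- function(weights, n) {
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  if (sum(weights) == 0) stop("all-zero weights", call. = FALSE)
  target <- weights / sum(weights) * n
  base <- floor(target)
  left <- n - sum(base)
  if (left > 0) {
    frac <- target - base
    # stable: ties broken by position
    idx <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# vectorized RGB (n x 3, in [0,1]) -> HSV (n x 3, h in [0,1))
rgb_to_hsv_mat <- function(rgb) {
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / d[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / d[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / d[hb] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  cbind(h = h, s = s, v = mx)
}

# vectorized HSV -> RGB, inverse of rgb_to_hsv_mat
hsv_to_rgb_mat <- function(hsv) {
  h <- (hsv[, 1] %% 1) * 6; s <- hsv[, 2]; v <- hsv[, 3]
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- numeric(length(h)); g <- r; b <- r
  for (k in 0:5) {
    m <- i == k
    if (!any(m)) next
    ch <- switch(as.character(k),
      "0" = cbind(v[m], t[m], p[m]),
      "1" = cbind(q[m], v[m], p[m]),
      "2" = cbind(p[m], v[m], t[m]),
      "3" = cbind(p[m], q[m], v[m]),
      "4" = cbind(t[m], p[m], v[m]),
      "5" = cbind(v[m], p[m], q[m]))
    r[m] <- ch[, 1]; g[m] <- ch[, 2]; b[m] <- ch[, 3]
  }
  cbind(r = r, g = g, b = b)
}
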