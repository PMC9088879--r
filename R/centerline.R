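#' Vessel centerline: an ordered 3D polyline with arc length and tangents
#'
#' Points are world coordinates in mm, ordered from the ostium (arc length 0)
#' distally. Unit tangents are computed by central differences and
#' renormalised.
#'
#' @param points n x 3 numeric matrix of ordered points (mm).
#' @return Object of class `centerline` with `points` (n x 3), `arc`
#'   (cumulative arc length, mm) and `tangents` (n x 3 unit vectors).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stopf("centerline needs an n x 3 matrix with n >= 2")
  seg <- diff(points)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len < 1e-12))
    stopf("consecutive centerline points must be distinct")
  arc <- c(0, cumsum(seg_len))
  tan <- matrix(0, nrow(points), 3L)
  tan[1, ] <- seg[1, ] / seg_len[1]
  n <- nrow(points)
  tan[n, ] <- seg[n - 1L, ] / seg_len[n - 1L]
  if (n > 2L) {
    mid <- points[3:n, , drop = FALSE] - points[1:(n - 2L), , drop = FALSE]
    tan[2:(n - 1L), ] <- mid / sqrt(rowSums(mid^2))
  }
  structure(list(points = points, arc = arc, tangents = tan),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm\n",
              nrow(x$points), max(x$arc)))
  invisible(x)
}

#' @export
length.centerline <- function(x) nrow(x$points)

arc_length <- function(cl) max(cl$arc)

# Interpolated point and tangent at arc position s (vectorised over s).
centerline_at <- function(cl, s) {
  if (any(s < -1e-9 | s > arc_length(cl) + 1e-9))
    stopf("arc position out of range [0, %.3f]", arc_length(cl))
  s <- pmin(pmax(s, 0), arc_length(cl))
  j <- findInterval(s, cl$arc, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), nrow(cl$points) - 1L)
  t_frac <- (s - cl$arc[j]) / (cl$arc[j + 1L] - cl$arc[j])
  p <- cl$points[j, , drop = FALSE] * (1 - t_frac) +
    cl$points[j + 1L, , drop = FALSE] * t_frac
  tn <- cl$tangents[j, , drop = FALSE] * (1 - t_frac) +
    cl$tangents[j + 1L, , drop = FALSE] * t_frac
  tn <- tn / sqrt(rowSums(tn^2))
  list(point = p, tangent = tn)
}

# Parallel-transported orthonormal frames (u, v) along the centerline, by
# the double-reflection method. The initial in-plane axis is the first
# canonical axis not parallel to the first tangent, orthogonalised.
centerline_frames <- function(cl) {
  n <- nrow(cl$points)
  t1 <- cl$tangents[1, ]
  u <- NULL
  for (k in 1:3) {
    e <- c(0, 0, 0); e[k] <- 1
    cand <- e - sum(e * t1) * t1
    if (sqrt(sum(cand^2)) > 1e-6) { u <- cand / sqrt(sum(cand^2)); break }
  }
  U <- matrix(0, n, 3L)
  U[1, ] <- u
  for (i in seq_len(n - 1L)) {
    p0 <- cl$points[i, ]; p1 <- cl$points[i + 1L, ]
    t0 <- cl$tangents[i, ]; t1i <- cl$tangents[i + 1L, ]
    v1 <- p1 - p0
    c1 <- sum(v1 * v1)
    uL <- U[i, ] - (2 / c1) * sum(v1 * U[i, ]) * v1
    tL <- t0 - (2 / c1) * sum(v1 * t0) * v1
    v2 <- t1i - tL
    c2 <- sum(v2 * v2)
    un <- if (c2 < 1e-14) uL else uL - (2 / c2) * sum(v2 * uL) * v2
    un <- un - sum(un * t1i) * t1i
    U[i + 1L, ] <- un / sqrt(sum(un^2))
  }
  V <- cbind(cl$tangents[, 2] * U[, 3] - cl$tangents[, 3] * U[, 2],
             cl$tangents[, 3] * U[, 1] - cl$tangents[, 1] * U[, 3],
             cl$tangents[, 1] * U[, 2] - cl$tangents[, 2] * U[, 1])
  list(u = U, v = V)
}

# Orthogonal projection of points onto a polyline. Returns, per point, the
# arc position `s` of the nearest polyline point and the distance `r` to it.
# Nearest node is found by (chunked) exhaustive search, then refined by exact
# projection onto the two incident segments; for a straight polyline the
# result is exact.
project_to_polyline <- function(points, cl, chunk = 200000L) {
  P <- as.matrix(points)
  Q <- cl$points
  arc <- cl$arc
  n <- nrow(Q)
  m <- nrow(P)
  s_out <- numeric(m)
  r_out <- numeric(m)
  chunk_rows <- max(1L, min(m, chunk %/% n + 1L))
  q2 <- rowSums(Q^2)
  start <- 1L
  while (start <= m) {
    end <- min(m, start + chunk_rows - 1L)
    Pc <- P[start:end, , drop = FALSE]
    # nearest node via |p|^2 - 2 p.q + |q|^2
    cross <- Pc %*% t(Q)
    d2 <- outer(rowSums(Pc^2), q2, "+") - 2 * cross
    j <- max.col(-d2, ties.method = "first")
    best_s <- arc[j]
    best_d2 <- d2[cbind(seq_len(nrow(Pc)), j)]
    for (off in c(-1L, 0L)) {
      a <- j + off
      ok <- a >= 1L & a + 1L <= n
      if (!any(ok)) next
      A <- Q[a[ok], , drop = FALSE]
      B <- Q[a[ok] + 1L, , drop = FALSE]
      AB <- B - A
      len2 <- rowSums(AB^2)
      t_par <- rowSums((Pc[ok, , drop = FALSE] - A) * AB) / len2
      t_par <- pmin(pmax(t_par, 0), 1)
      proj <- A + AB * t_par
      dd2 <- rowSums((Pc[ok, , drop = FALSE] - proj)^2)
      ss <- arc[a[ok]] + t_par * sqrt(len2)
      better <- dd2 < best_d2[ok] - 1e-15
      idx_ok <- which(ok)[better]
      best_d2[idx_ok] <- dd2[better]
      best_s[idx_ok] <- ss[better]
    }
    s_out[start:end] <- best_s
    r_out[start:end] <- sqrt(pmax(best_d2, 0))
    start <- end + 1L
  }
  list(s = s_out, r = r_out)
}
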