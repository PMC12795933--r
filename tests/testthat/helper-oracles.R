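# Independent brute-force oracles. These deliberately avoid the package's
# own computational paths: distances by constrained minimisation, rendering
# by per-face intersection in R, histograms by a literal double loop.

# point-triangle distance by minimising |p - (a + u ab + v ac)| over the
# barycentric simplex: unconstrained 2x2 solve, then the three edges.
oracle_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  G <- matrix(c(sum(ab * ab), sum(ab * ac), sum(ab * ac), sum(ac * ac)), 2, 2)
  rhs <- c(sum(ab * ap), sum(ac * ap))
  cands <- list()
  dt <- G[1, 1] * G[2, 2] - G[1, 2]^2
  if (abs(dt) > 1e-18) {
    uv <- solve(G, rhs)
    if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
      cands <- c(cands, list(a + uv[1] * ab + uv[2] * ac))
  }
  seg <- function(q0, q1) {
    d <- q1 - q0
    t <- sum((p - q0) * d) / sum(d * d)
    q0 + min(1, max(0, t)) * d
  }
  cands <- c(cands, list(seg(a, b), seg(a, c), seg(b, c)))
  sqrt(min(vapply(cands, function(q) sum((p - q)^2), 0)))
}

oracle_closest_mesh_dist <- function(p, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  min(vapply(seq_len(nrow(f)), function(i)
    oracle_point_triangle(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]), 0))
}

# off-plan distance by dense sampling of the line parameter + refinement
oracle_off_plan <- function(tip, entry, target) {
  d <- target - entry
  f <- function(s) sqrt(sum((tip - (entry + s * d))^2))
  grid <- seq(-50, 50, length.out = 4001)
  vals <- vapply(grid, f, 0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  stats::optimize(f, c(lo, hi), tol = 1e-12)$objective
}

# first-hit depth by Moller-Trumbore over every face, per pixel
oracle_render_depth <- function(mesh, cam) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  o <- cam$pose$t
  out <- matrix(0, cam$height, cam$width)
  for (vv in seq_len(cam$height)) {
    for (uu in seq_len(cam$width)) {
      dc <- c((uu - 1 - cam$cx) / cam$fx, (vv - 1 - cam$cy) / cam$fy, 1)
      dir <- as.numeric(cam$pose$R %*% dc)
      pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
                  dir[3] * e2[, 1] - dir[1] * e2[, 3],
                  dir[1] * e2[, 2] - dir[2] * e2[, 1])
      det <- rowSums(e1 * pv)
      s <- matrix(o, nrow(a), 3, byrow = TRUE) - a
      u <- rowSums(s * pv) / det
      qv <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
                  s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
                  s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
      w <- rowSums(qv * matrix(dir, nrow(a), 3, byrow = TRUE)) / det
      t <- rowSums(e2 * qv) / det
      hit <- abs(det) > 1e-14 & u >= 0 & u <= 1 & w >= 0 & (u + w) <= 1 &
        t > 1e-9 & t <= cam$max_range_mm
      if (any(hit)) out[vv, uu] <- min(t[hit])
    }
  }
  out
}

# per-voxel majority vote with a clamped cubic window, literal loops
oracle_median_smooth <- function(arr, half) {
  d <- dim(arr)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    w <- arr[max(1, i - half[1]):min(d[1], i + half[1]),
             max(1, j - half[2]):min(d[2], j + half[2]),
             max(1, k - half[3]):min(d[3], k + half[3])]
    out[i, j, k] <- 2 * sum(w) > length(w)
  }
  out
}

# literal-formula SPFH/FPFH double loop (same formula, independent code)
oracle_fpfh <- function(P, N, radius) {
  n <- nrow(P)
  bin1 <- function(x) min(10, max(0, floor((x + 1) / 2 * 11)))
  bin3 <- function(x) min(10, max(0, floor((x + pi) / (2 * pi) * 11)))
  nbrs <- lapply(seq_len(n), function(i) {
    d <- sqrt(rowSums(sweep(P, 2, P[i, ])^2))
    setdiff(which(d <= radius), i)
  })
  spfh <- matrix(0, n, 33)
  for (i in seq_len(n)) {
    for (j in nbrs[[i]]) {
      d <- P[j, ] - P[i, ]
      len <- sqrt(sum(d^2))
      if (len < 1e-12) next
      d <- d / len
      u <- N[i, ]
      v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
             d[1] * u[2] - d[2] * u[1])
      vn <- sqrt(sum(v^2))
      if (vn < 1e-12) next
      v <- v / vn
      w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      alpha <- sum(v * N[j, ])
      phi <- sum(u * d)
      theta <- atan2(sum(w * N[j, ]), sum(u * N[j, ]))
      spfh[i, bin1(alpha) + 1] <- spfh[i, bin1(alpha) + 1] + 1
      spfh[i, 11 + bin1(phi) + 1] <- spfh[i, 11 + bin1(phi) + 1] + 1
      spfh[i, 22 + bin3(theta) + 1] <- spfh[i, 22 + bin3(theta) + 1] + 1
    }
  }
  fpfh <- matrix(0, n, 33)
  for (i in seq_len(n)) {
    acc <- spfh[i, ]
    k <- length(nbrs[[i]])
    if (k > 0) {
      wsum <- rep(0, 33)
      for (j in nbrs[[i]]) {
        wj <- sqrt(sum((P[j, ] - P[i, ])^2))
        if (wj > 1e-12) wsum <- wsum + spfh[j, ] / wj
      }
      acc <- acc + wsum / k
    }
    for (b in 0:2) {
      s <- sum(acc[(11 * b + 1):(11 * b + 11)])
      if (s > 0) acc[(11 * b + 1):(11 * b + 11)] <- acc[(11 * b + 1):(11 * b + 11)] / s
    }
    fpfh[i, ] <- acc
  }
  fpfh
}

# Spearman by average ranks then the Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# voxel downsampling by explicit bucket means
oracle_downsample <- function(points, s) {
  lo <- apply(points, 2, min)
  key <- apply(floor(sweep(points, 2, lo) / s), 1, paste, collapse = "/")
  out <- t(vapply(sort(unique(key)), function(k)
    colMeans(points[key == k, , drop = FALSE]), numeric(3)))
  dimnames(out) <- NULL
  out
}
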