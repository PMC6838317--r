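# Delaunay triangulation by Bowyer-Watson insertion.
# Returns the unique edge list (two-column matrix of point indices).
# Collinear inputs fall back to the chain graph along the line.

delaunay_edges <- function(xy) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (anyDuplicated(xy)) {
    rlang::abort("Duplicate coordinates are not allowed in a triangulation.",
                 class = "subsidydiet_error_invalid_input")
  }
  if (n < 2) return(matrix(integer(0), ncol = 2))
  if (n == 2) return(matrix(c(1L, 2L), ncol = 2))

  # collinearity: area of every triple with the two extreme points ~ 0
  ctr <- sweep(xy, 2, colMeans(xy))
  sv <- svd(ctr)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    ord <- order(ctr %*% svd(ctr)$v[, 1])
    return(cbind(ord[-n], ord[-1]))
  }

  span <- max(apply(xy, 2, function(v) diff(range(v))))
  cx <- mean(range(xy[, 1])); cy <- mean(range(xy[, 2]))
  big <- 50 * span
  super <- rbind(
    c(cx - big, cy - big), c(cx + big, cy - big), c(cx, cy + big)
  )
  pts <- rbind(xy, super)
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3)
  cc <- circumcircle(pts, tri)

  for (i in seq_len(n)) {
    px <- pts[i, 1]; py <- pts[i, 2]
    d2 <- (cc$x - px)^2 + (cc$y - py)^2
    bad <- which(d2 <= cc$r2 * (1 + 1e-12))
    if (length(bad) == 0) bad <- which.min(d2 - cc$r2)  # numeric safety net
    bad_tri <- tri[bad, , drop = FALSE]
    edges <- rbind(
      bad_tri[, c(1, 2), drop = FALSE],
      bad_tri[, c(2, 3), drop = FALSE],
      bad_tri[, c(3, 1), drop = FALSE]
    )
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    cc$x <- cc$x[-bad]; cc$y <- cc$y[-bad]; cc$r2 <- cc$r2[-bad]
    new_tri <- cbind(boundary, i)
    new_cc <- circumcircle(pts, new_tri)
    tri <- rbind(tri, new_tri)
    cc$x <- c(cc$x, new_cc$x); cc$y <- c(cc$y, new_cc$y)
    cc$r2 <- c(cc$r2, new_cc$r2)
  }

  keep <- rowSums(tri > n) == 0
  tri <- tri[keep, , drop = FALSE]
  edges <- rbind(
    tri[, c(1, 2), drop = FALSE],
    tri[, c(2, 3), drop = FALSE],
    tri[, c(3, 1), drop = FALSE]
  )
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  unique(edges)
}

circumcircle <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[abs(d) < 1e-300] <- 1e-300
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(x = ux, y = uy, r2 = (ux - ax)^2 + (uy - ay)^2)
}
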