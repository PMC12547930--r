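# Independent brute-force oracles. These deliberately use naive loops and
# third-party routines (mgcv::in.out) rather than the package's vectorised /
# compiled code paths.

# point-in-polygon via mgcv (strict interior; used on polygons whose pixel
# centres are safely off the boundary)
oracleInOut <- function(vertices, gridShape) {
  nr <- gridShape[1]; nc <- gridShape[2]
  pts <- cbind(rep(0:(nr - 1), times = nc), rep(0:(nc - 1), each = nr))
  bnd <- rbind(vertices, vertices[1, ])
  matrix(mgcv::in.out(bnd, pts), nr, nc)
}

# exhaustive 3x3-square erosion
oracleErode <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    keep <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !mask[r2, c2])
        keep <- FALSE
    }
    out[r, c] <- keep
  }
  out
}

# chessboard distance of each foreground pixel to the nearest background
# (outside the grid counts as background)
oracleChessboardToBg <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  bg <- rbind(bg,
              cbind(0, 0:(nc + 1)), cbind(nr + 1, 0:(nc + 1)),
              cbind(0:(nr + 1), 0), cbind(0:(nr + 1), nc + 1))
  fg <- which(mask, arr.ind = TRUE)
  d <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg)))
    d[i] <- min(pmax(abs(bg[, 1] - fg[i, 1]), abs(bg[, 2] - fg[i, 2])))
  d
}

# brute-force tiler: one window per wall pixel with the documented anchor
# rule (wall pixel at window position (3,3), 0-based), dedupe, drop clipped
oracleTileAnchors <- function(wallMask, side = 8) {
  nr <- nrow(wallMask); nc <- ncol(wallMask)
  seen <- character(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!wallMask[r, c]) next
    a <- c(r - 1 - 3, c - 1 - 3)
    if (a[1] < 0 || a[2] < 0 || a[1] + side > nr || a[2] + side > nc) next
    seen <- union(seen, paste(a[1], a[2]))
  }
  seen
}

# pair-enumeration GLCM (symmetric, normalised) for one (dr, dc) offset
oracleGlcm <- function(lv, ng, dr, dc) {
  nr <- nrow(lv); nc <- ncol(lv)
  m <- matrix(0, ng, ng)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    m[lv[r, c], lv[r2, c2]] <- m[lv[r, c], lv[r2, c2]] + 1
    m[lv[r2, c2], lv[r, c]] <- m[lv[r2, c2], lv[r, c]] + 1
  }
  if (sum(m) > 0) m / sum(m) else m
}

# run enumeration for one direction
oracleGlrlm <- function(lv, ng, dr, dc) {
  nr <- nrow(lv); nc <- ncol(lv)
  m <- matrix(0, ng, max(nr, nc))
  done <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (done[r, c]) next
    rp <- r - dr; cp <- c - dc
    inb <- rp >= 1 && rp <= nr && cp >= 1 && cp <= nc
    if (inb && lv[rp, cp] == lv[r, c]) next   # not a run start
    len <- 0; r2 <- r; c2 <- c
    while (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
           lv[r2, c2] == lv[r, c]) {
      done[r2, c2] <- TRUE; len <- len + 1; r2 <- r2 + dr; c2 <- c2 + dc
    }
    m[lv[r, c], len] <- m[lv[r, c], len] + 1
  }
  m
}

# 8-connected flood-fill zone enumeration; returns data.frame(level, size,
# distance) with distance = min chessboard distance to outside the window
oracleZones <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  seen <- matrix(FALSE, nr, nc)
  out <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0]) next
    g <- lv[r0, c0]
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    px <- list()
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      px[[length(px) + 1]] <- p
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!seen[r2, c2] && lv[r2, c2] == g) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
    d <- min(vapply(px, function(p)
      min(p[1] - 1, p[2] - 1, nr - p[1], nc - p[2]) + 1, numeric(1)))
    out[[length(out) + 1]] <- data.frame(level = g, size = length(px),
                                         distance = d)
  }
  do.call(rbind, out)
}

oracleZoneMatrix <- function(lv, ng, what = c("size", "distance")) {
  what <- match.arg(what)
  z <- oracleZones(lv)
  m <- matrix(0, ng, max(z[[what]]))
  for (i in seq_len(nrow(z))) m[z$level[i], z[[what]][i]] <-
      m[z$level[i], z[[what]][i]] + 1
  m
}

# per-pixel NGTDM sums and counts
oracleNgtdm <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  s <- numeric(ng); n <- numeric(ng)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
        nb <- c(nb, lv[r2, c2])
    }
    g <- lv[r, c]
    if (length(nb)) s[g] <- s[g] + abs(g - mean(nb))
    n[g] <- n[g] + 1
  }
  list(s = s, n = n)
}

# per-pixel NGLDM dependence counts (alpha = 0), columns = count + 1
oracleNgldm <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  m <- matrix(0, ng, 9)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          lv[r2, c2] == lv[r, c]) k <- k + 1
    }
    m[lv[r, c], k + 1] <- m[lv[r, c], k + 1] + 1
  }
  m
}

# O(n^2) pair-counting AUC, ties count 1/2
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# all-cut-points Youden search (classify positive at score >= t; ties to
# the lowest threshold)
oracleYouden <- function(scores, labels) {
  best <- NULL
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J)
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   J = J)
  }
  best
}

# geometry helpers ------------------------------------------------------------

discMask <- function(size, centre, radius) {
  r <- matrix(0:(size - 1), size, size)
  c <- t(r)
  (r - centre[1])^2 + (c - centre[2])^2 <= radius^2
}

circleContour <- function(centre, radius, nVertices = 64, sliceIndex = 1L) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1)[-(nVertices + 1)]
  ContourPolygon(cbind(centre[1] + radius * sin(th),
                       centre[2] + radius * cos(th)), sliceIndex)
}

randomLevels <- function(nr, nc, ng) {
  matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
}
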