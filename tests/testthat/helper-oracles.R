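# Independent brute-force oracles, deliberately literal: these re-derive
# results from first principles and never share code with the package.

# Literal triple-loop 26-neighbour ratio detector.
bruteDetect <- function(vol, mask = NULL, threshold = 0.20,
                        mode = c("each-neighbor", "mean-of-neighbors")) {
  mode <- match.arg(mode)
  d <- dim(vol)
  if (is.null(mask)) mask <- array(TRUE, d)
  out <- array(FALSE, d)
  for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
    nb <- numeric(0); allIn <- mask[x, y, z]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- c(nb, vol[x + dx, y + dy, z + dz])
      allIn <- allIn && mask[x + dx, y + dy, z + dz]
    }
    if (!allIn) next
    out[x, y, z] <- if (mode == "each-neighbor")
      all(vol[x, y, z] >= (1 + threshold) * nb)
    else vol[x, y, z] >= (1 + threshold) * mean(nb)
  }
  out
}

# Literal flood-fill connected components over a logical 3D array; returns
# a list of coordinate matrices, one per component.
bruteComponents <- function(flag, connectivity = 26) {
  d <- dim(flag)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                 "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                 "26" = offs)
  seen <- array(FALSE, d)
  comps <- list()
  idx <- which(flag, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    start <- idx[s, ]
    if (seen[start[1], start[2], start[3]]) next
    queue <- matrix(start, 1, 3)
    seen[start[1], start[2], start[3]] <- TRUE
    members <- queue
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (flag[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue <- rbind(queue, nb)
          members <- rbind(members, nb)
        }
      }
    }
    comps[[length(comps) + 1]] <- members[order(members[, 3], members[, 2],
                                                members[, 1]), , drop = FALSE]
  }
  comps
}

# Closed-form chi-squared upper tail for even df = 2k:
# P(X > x) = exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!
chisqUpperEvenDf <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Textbook pooled-variance two-sample t on two scalar samples.
scalarStudentT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = na + nb - 2, p = 2 * pt(-abs(tt), na + nb - 2))
}

# Literal Holm step-down adjustment.
holmOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# small random integer volume for detection tests
randomVolume <- function(d, seed, lo = 80, hi = 160) {
  withr::with_seed(seed, array(sample(lo:hi, prod(d), TRUE), d))
}
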