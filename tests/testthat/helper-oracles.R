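# independent brute-force oracles, deliberately written as naive loops
# so they share no code path with the package kernels

# naive O(n^2) molecular-mechanics energy: Coulomb + LJ with 1-2/1-3
# exclusion and 1-4 scaling derived by explicit path search
naiveNonbonded <- function(xyz, ff, config) {
  n <- nrow(xyz)
  # bond graph adjacency list
  adj <- vector("list", n)
  b <- ff@bonds
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  # shortest bond-path length up to 3 via BFS
  pathlen <- function(i, j) {
    if (i == j) return(0L)
    frontier <- i
    seen <- i
    for (depth in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- setdiff(nxt, seen)
      if (j %in% nxt) return(depth)
      if (!length(nxt)) return(99L)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    99L
  }
  ele <- 0; vdw <- 0
  p <- ff@atoms
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pl <- pathlen(i, j)
    if (pl <= 2L) next
    se <- if (pl == 3L) config@scaleEE14 else 1
    sl <- if (pl == 3L) config@scaleLJ14 else 1
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ele <- ele + se * config@coulombConstant * p$charge[i] *
      p$charge[j] / r
    sig <- (p$lj_sigma[i] + p$lj_sigma[j]) / 2
    eps <- sqrt(p$lj_epsilon[i] * p$lj_epsilon[j])
    vdw <- vdw + sl * 4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  c(electrostatic = ele, vdw = vdw)
}

# naive bonded energy with explicit per-term loops
naiveBonded <- function(xyz, ff) {
  e <- 0
  for (r in seq_len(nrow(ff@bonds))) {
    b <- ff@bonds[r, ]
    d <- sqrt(sum((xyz[b$i, ] - xyz[b$j, ])^2))
    e <- e + b$kb * (d - b$r0)^2
  }
  for (r in seq_len(nrow(ff@angles))) {
    g <- ff@angles[r, ]
    v1 <- xyz[g$i, ] - xyz[g$j, ]
    v2 <- xyz[g$k, ] - xyz[g$j, ]
    th <- acos(max(-1, min(1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2)))))
    e <- e + g$ka * (th - g$theta0)^2
  }
  for (r in seq_len(nrow(ff@dihedrals))) {
    d <- ff@dihedrals[r, ]
    b1 <- xyz[d$j, ] - xyz[d$i, ]
    b2 <- xyz[d$k, ] - xyz[d$j, ]
    b3 <- xyz[d$l, ] - xyz[d$k, ]
    cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
    phi <- atan2(sum(m1 * n2), sum(n1 * n2))
    e <- e + d$barrier * (1 + cos(d$periodicity * phi - d$phase))
  }
  e
}

# brute-force best rotation about z over a 1-degree grid (after
# centroid alignment): independent check of the Kabsch optimum for
# motions confined to the z-axis
gridRotationRmsd <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  best <- Inf
  for (deg in seq(0, 359, by = 1)) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    r <- sqrt(mean(rowSums((mc %*% t(R) - rc)^2)))
    best <- min(best, r)
  }
  best
}
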