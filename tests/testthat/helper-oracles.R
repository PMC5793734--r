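# Independent oracles, deliberately naive: direct translations of the
# published definitions, sharing no code with the package implementation.

# --- backbone H-bond / secondary structure oracle --------------------------

oracle_backbone <- function(struct) {
  a <- struct$atoms
  n <- length(unique(a$res_idx))
  get <- function(name) {
    m <- matrix(NA_real_, n, 3)
    for (r in seq_len(n)) {
      row <- a[a$res_idx == r & a$atom == name, c("x", "y", "z")]
      if (nrow(row) >= 1) m[r, ] <- as.numeric(row[1, ])
    }
    m
  }
  list(N = get("N"), CA = get("CA"), C = get("C"), O = get("O"),
       resname = a$resname[!duplicated(a$res_idx)])
}

oracle_hbonds <- function(struct) {
  bb <- oracle_backbone(struct)
  n <- nrow(bb$N)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (bb$resname[i] == "PRO") next
    co <- bb$C[i - 1, ] - bb$O[i - 1, ]
    if (anyNA(co) || anyNA(bb$N[i, ])) next
    if (sqrt(sum((bb$N[i, ] - bb$C[i - 1, ])^2)) >= 2.5) next
    H[i, ] <- bb$N[i, ] + co / sqrt(sum(co^2))
  }
  hb <- matrix(FALSE, n, n)
  dd <- function(p, q) sqrt(sum((p - q)^2))
  for (don in seq_len(n)) {
    for (acc in seq_len(n)) {
      if (abs(don - acc) < 2 || anyNA(H[don, ]) || anyNA(bb$O[acc, ])) next
      e <- 27.888 * (1 / dd(bb$O[acc, ], bb$N[don, ]) +
                     1 / dd(bb$C[acc, ], H[don, ]) -
                     1 / dd(bb$O[acc, ], H[don, ]) -
                     1 / dd(bb$C[acc, ], bb$N[don, ]))
      hb[don, acc] <- e < -0.5
    }
  }
  hb
}

oracle_ss <- function(struct) {
  n <- length(unique(struct$atoms$res_idx))
  if (n < 3) return(rep("C", n))
  hb <- oracle_hbonds(struct)
  hbond <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  ss <- rep("C", n)
  helixify <- function(ss, len, sym) {
    for (i in seq_len(n)) {
      if (hbond(i + len, i) && hbond(i + 1 + len, i + 1)) {
        for (k in (i + 1):(i + len)) if (ss[k] == "C") ss[k] <- sym
      }
    }
    ss
  }
  ss <- helixify(ss, 4, "H")
  marked <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 2) next
      para <- (hbond(i + 1, j) && hbond(j, i - 1)) ||
              (hbond(j + 1, i) && hbond(i, j - 1))
      anti <- (hbond(i, j) && hbond(j, i)) ||
              (hbond(i - 1, j + 1) && hbond(j - 1, i + 1))
      if (para || anti) marked[i] <- marked[j] <- TRUE
    }
  }
  for (i in seq_len(n)) if (marked[i] && ss[i] == "C") ss[i] <- "E"
  drop_short <- function(ss, sym, m) {
    r <- rle(ss); r$values[r$values == sym & r$lengths < m] <- "C"
    inverse.rle(r)
  }
  ss <- drop_short(ss, "E", 2)
  ss <- helixify(ss, 3, "G")
  ss <- drop_short(ss, "G", 3)
  drop_short(ss, "H", 4)
}

# --- contacts: all-pairs scan ----------------------------------------------

oracle_contacts <- function(struct, cutoff) {
  a <- struct$atoms
  n <- length(unique(a$res_idx))
  out <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(n - 1)) {
    xi <- as.matrix(a[a$res_idx == i, c("x", "y", "z")])
    for (j in (i + 1):n) {
      xj <- as.matrix(a[a$res_idx == j, c("x", "y", "z")])
      dmin <- Inf
      for (p in seq_len(nrow(xi))) {
        for (q in seq_len(nrow(xj))) {
          dmin <- min(dmin, sqrt(sum((xi[p, ] - xj[q, ])^2)))
        }
      }
      if (dmin <= cutoff) {
        out[[i]] <- c(out[[i]], j)
        out[[j]] <- c(out[[j]], i)
      }
    }
  }
  lapply(out, sort)
}

# --- SASA: equal-area z/phi dense grid (Archimedes), plus closed forms -----

oracle_sasa_atoms <- function(xyz, elements, probe = 1.4, nz = 180, np = 360) {
  radii <- unname(c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[elements])
  radii[is.na(radii)] <- 1.70
  radii <- radii + probe
  z <- seq(-1 + 1 / nz, 1 - 1 / nz, length.out = nz)
  phi <- seq(0, 2 * pi, length.out = np + 1)[-(np + 1)]
  grid <- cbind(
    rep(sqrt(1 - z^2), each = np) * cos(phi),
    rep(sqrt(1 - z^2), each = np) * sin(phi),
    rep(z, each = np)
  )
  vapply(seq_len(nrow(xyz)), function(i) {
    pts <- sweep(grid * radii[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(pts))
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 >= radii[j]^2
    }
    4 * pi * radii[i]^2 * mean(free)
  }, numeric(1))
}

# Exposed area of sphere 1 (radius r1) occluded by sphere 2 (radius r2)
# at centre distance d: full area minus the spherical cap inside sphere 2.
analytic_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  x <- (d^2 + r1^2 - r2^2) / (2 * d)   # distance to the intersection plane
  h <- r1 - x                          # cap height on sphere 1
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# --- column RMSD: direct pairwise formula ----------------------------------

oracle_pairwise_rmsd <- function(points) {
  n <- nrow(points)
  d2 <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- c(d2, sum((points[i, ] - points[j, ])^2))
    }
  }
  sqrt(mean(d2))
}

# --- unweighted Kabsch reference via bio3d ---------------------------------

oracle_unweighted_fit <- function(mobile, fixed) {
  # bio3d works on flat xyz vectors
  m <- as.vector(t(mobile))
  f <- as.vector(t(fixed))
  fitted <- bio3d::fit.xyz(fixed = f, mobile = matrix(m, nrow = 1),
                           fixed.inds = seq_along(f),
                           mobile.inds = seq_along(m))
  matrix(fitted[1, ], ncol = 3, byrow = TRUE)
}
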