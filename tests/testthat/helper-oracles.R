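# Independent brute-force oracles. These recompute everything from scratch
# from raw weight matrices and never call the package's cached-graph code
# paths.

# random symmetric weight matrix with NA non-edges; uniform weights are
# almost surely tie-free ("generic")
random_graph_weights <- function(n, p_edge = 0.85, wmin = 0.4, wmax = 3.2) {
  w <- matrix(NA_real_, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, wmin, wmax)
      }
    }
  }
  rownames(w) <- colnames(w) <- sprintf("v%02d", seq_len(n))
  w
}

avg_of <- function(w) {
  ut <- w[upper.tri(w)]
  e <- sum(!is.na(ut))
  if (e == 0) NA_real_ else sum(ut, na.rm = TRUE) / e
}

# brute-force greedy outlier rejection: rebuilds every candidate subgraph
# from scratch on every iteration; same decision rules as the spec'd
# algorithm (strict decrease, tie -> larger incident weight -> smallest id)
shrink_oracle <- function(w, threshold = 1.5, tol = 1e-12) {
  ids <- rownames(w)
  active <- seq_len(nrow(w))
  removed <- character()
  removed_avg <- numeric()
  finish <- function(status) {
    sub <- w[active, active, drop = FALSE]
    list(status = status, surviving = ids[active], removed = removed,
         removed_avg = removed_avg, final_avg = avg_of(sub))
  }
  sub <- w[active, active, drop = FALSE]
  if (length(active) < 2 || is.na(avg_of(sub))) return(finish("empty"))
  repeat {
    avg <- avg_of(w[active, active, drop = FALSE])
    if (avg < threshold) return(finish("stable"))
    probes <- vapply(active, function(v) {
      rest <- setdiff(active, v)
      avg_of(w[rest, rest, drop = FALSE])
    }, numeric(1))
    cand <- which(!is.na(probes) & (avg - probes) > tol)
    if (!length(cand)) return(finish("diverging"))
    best <- cand[probes[cand] <= min(probes[cand]) + tol]
    if (length(best) > 1) {
      wv <- vapply(active[best], function(v) {
        sum(w[v, active], na.rm = TRUE)
      }, numeric(1))
      best <- best[wv >= max(wv) - tol]
      if (length(best) > 1) best <- best[order(ids[active[best]])]
    }
    v <- active[best[[1]]]
    removed <- c(removed, ids[v])
    active <- setdiff(active, v)
    removed_avg <- c(removed_avg, avg_of(w[active, active, drop = FALSE]))
    if (length(active) < 2 || is.na(avg_of(w[active, active, drop = FALSE])))
      return(finish("empty"))
  }
}

# exhaustive centroid scan straight off the weight matrix
centroid_oracle <- function(w, min_degree_fraction = 0.5, tol = 1e-12) {
  ids <- rownames(w)
  n <- nrow(w)
  if (n == 0) return(NULL)
  deg <- rowSums(!is.na(w))
  wv <- rowSums(w, na.rm = TRUE)
  min_deg <- max(1, ceiling(min_degree_fraction * (n - 1)))
  elig <- which(deg >= min_deg)
  if (!length(elig)) return(NULL)
  aw <- wv[elig] / deg[elig]
  best <- elig[aw <= min(aw) + tol]
  if (length(best) > 1) {
    best <- best[wv[best] <= min(wv[best]) + tol]
    if (length(best) > 1) best <- best[order(ids[best])]
  }
  ids[best[[1]]]
}

# grid + simplex search over SO(3) (ZYZ Euler angles) for the minimal RMSD
# superposition of centered point sets: an optimization-based alternative to
# the closed-form SVD solution
grid_rmsd_oracle <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  rotz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
  roty <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  f <- function(p) {
    r <- rotz(p[1]) %*% roty(p[2]) %*% rotz(p[3])
    sqrt(mean(rowSums((a0 %*% t(r) - b0)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                      b = seq(0, pi, length.out = 7),
                      c = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(grid, 1, f)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- optim(start, f, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# ideal alpha-helix Calpha trace (radius 2.3 A, rise 1.5 A, 100 deg/residue)
helix_ca <- function(n, radius = 2.3, rise = 1.5, turn = 100) {
  t <- (seq_len(n) - 1) * turn * pi / 180
  cbind(x = radius * cos(t), y = radius * sin(t),
        z = (seq_len(n) - 1) * rise)
}

# fragment with a given Calpha trace and flat torsions
make_frag <- function(id, start, ca, phi = -57, psi = -47,
                      source_id = "synthA") {
  n <- nrow(ca)
  fragment(id, source_id, start, start + n - 1,
           cbind(phi = rep(phi, n), psi = rep(psi, n)), ca)
}

# random rigid transform applied to a coordinate matrix
rigid_transform <- function(ca) {
  ang <- runif(3, 0, 2 * pi)
  rotz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
  roty <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  r <- rotz(ang[1]) %*% roty(ang[2]) %*% rotz(ang[3])
  sweep(ca %*% t(r), 2, runif(3, -20, 20), `+`)
}

# wraparound-aware angle comparison
expect_angle_equal <- function(a, b, tol = 1e-6) {
  d <- abs(a - b)
  d <- pmin(d, 360 - d)
  expect_true(all(d <= tol))
}
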