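# Independent oracles used by the tests: brute-force k-nearest neighbours,
# and exhaustive minimum-weight triangulation by enumerating every
# triangulation of the loop polygon (Catalan many), scoring each bottom-up
# with the same neighbour conventions as the dynamic programme but through
# an entirely separate code path.

brute_knn <- function(P, k) {
  n <- nrow(P)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(P) - P[i, ])^2))
    d[i] <- Inf
    out[i, ] <- order(d)[seq_len(k)]
  }
  out
}

# Weight triple of triangle over loop indices (i, m, k), wound (k, m, i),
# with dihedral deviations against the supplied neighbour normals.
oracle_phi <- function(P, i, m, k, nb_normals) {
  u <- P[m, ] - P[k, ]
  v <- P[i, ] - P[k, ]
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  a2 <- sqrt(sum(cr^2))
  e <- c(sqrt(sum((P[m, ] - P[k, ])^2)), sqrt(sum((P[i, ] - P[m, ])^2)),
         sqrt(sum((P[i, ] - P[k, ])^2)))
  if (a2 < 1e-12 * max(e)^2 || min(e) == 0)
    return(list(w = c(0, 180, 0), normal = c(NA, NA, NA)))
  nrm <- cr / a2
  cosang <- c((e[2]^2 + e[3]^2 - e[1]^2) / (2 * e[2] * e[3]),
              (e[1]^2 + e[3]^2 - e[2]^2) / (2 * e[1] * e[3]),
              (e[1]^2 + e[2]^2 - e[3]^2) / (2 * e[1] * e[2]))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  beta <- 0
  if (!is.null(nb_normals) && nrow(nb_normals) > 0) {
    for (r in seq_len(nrow(nb_normals))) {
      nn <- nb_normals[r, ]
      if (any(is.na(nn))) next
      beta <- max(beta,
                  acos(min(1, max(-1, sum(nrm * nn)))) * 180 / pi)
    }
  }
  list(w = c(min(ang), beta, a2 / 2), normal = nrm)
}

# Enumerate all triangulations of the polygon 1..n and return the minimum
# total weight under the lexicographic order and min/max/sum accumulation.
# edge_normal: row r is the mesh normal across loop edge (r, r+1), row n
# across the closing edge (n, 1). Memoizes the full option list per (i, k):
# each option is a candidate sub-triangulation's (weight, top normal).
oracle_min_triangulation <- function(P, edge_normal) {
  n <- nrow(P)
  memo <- vector("list", n * n)
  options_of <- function(i, k) {
    id <- (i - 1) * n + k
    if (!is.null(memo[[id]])) return(memo[[id]])
    if (k == i + 1) {
      res <- list(list(w = c(60, 0, 0), normal = edge_normal[i, ]))
      memo[[id]] <- res
      return(res)
    }
    res <- list()
    for (m in (i + 1):(k - 1)) {
      left <- options_of(i, m)
      right <- options_of(m, k)
      for (ol in left) for (orr in right) {
        nb <- rbind(ol$normal, orr$normal)
        if (i == 1 && k == n) nb <- rbind(nb, edge_normal[n, ])
        ph <- oracle_phi(P, i, m, k, nb)
        w <- add_weights(add_weights(ol$w, orr$w), ph$w)
        res[[length(res) + 1]] <- list(w = w, normal = ph$normal)
      }
    }
    memo[[id]] <- res
    res
  }
  opts <- options_of(1, n)
  best <- opts[[1]]$w
  for (o in opts[-1]) if (compare_weights(o$w, best) < 0) best <- o$w
  best
}

# Random warped loop for DP-oracle comparisons: points around a circle with
# radial jitter and out-of-plane warp, plus random mesh-edge normals.
random_loop <- function(n, warp = 0.5, jitter = 0.3) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- 1 + stats::runif(n, -jitter, jitter)
  P <- cbind(r * cos(th), r * sin(th), warp * stats::rnorm(n))
  en <- matrix(stats::rnorm(3 * n), n, 3)
  en <- en / sqrt(rowSums(en^2))
  list(positions = P, edge_normal = en)
}
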