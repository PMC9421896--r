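# Independent oracles used to check the package implementations.

# Horn quaternion-eigenvalue RMSD (independent of the SVD-based Kabsch path)
quatRMSD <- function(X, Y) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  S <- crossprod(X, Y)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(X)
  sqrt(max(0, msd))
}

# exhaustive simple-path enumeration for the anchor-separation bound
allPathsShortest <- function(nVertices, edges, weights, from, to) {
  adj <- vector("list", nVertices)
  for (q in seq_len(nrow(edges))) {
    i <- edges[q, 1]; j <- edges[q, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, weights[q]))
    adj[[j]] <- rbind(adj[[j]], c(i, weights[q]))
  }
  best <- Inf
  visited <- logical(nVertices)
  dfs <- function(v, acc) {
    if (acc >= best) return()
    if (v == to) { best <<- acc; return() }
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (!is.null(nb))
      for (q in seq_len(nrow(nb)))
        if (!visited[nb[q, 1]]) dfs(nb[q, 1], acc + nb[q, 2])
    visited[v] <<- FALSE
  }
  dfs(from, 0)
  best
}

# direct numeric integration of the radial Boltzmann density for two beads
# interacting through U(r) (includes the r^2 Jacobian)
boltzmannReference <- function(uFun, edges, kT, rMax = 14, dr = 0.005) {
  r <- seq(max(1e-3, min(edges) - 1), rMax, by = dr)
  u <- uFun(r)
  w <- r^2 * exp(-(u - min(u)) / kT)
  p <- vapply(seq_len(length(edges) - 1), function(i)
    sum(w[r >= edges[i] & r < edges[i + 1]]), numeric(1))
  p / sum(w[r >= edges[1] & r < edges[length(edges)]])
}

# exhaustive representative search: all-pairs quaternion RMSD, argmin of sums
exhaustiveRepresentative <- function(coordsList) {
  m <- length(coordsList)
  if (m == 1) return(list(index = 1, sums = 0))
  rm <- matrix(0, m, m)
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    r <- quatRMSD(coordsList[[a]], coordsList[[b]])
    rm[a, b] <- r; rm[b, a] <- r
  }
  sums <- rowSums(rm)
  list(index = which(sums == min(sums))[1], sums = sums)
}

# central-difference gradient of an energy function
numericGradient <- function(energyFun, x, h = 1e-5, idx = seq_along(x)) {
  g <- numeric(length(idx))
  for (q in seq_along(idx)) {
    xp <- x; xp[idx[q]] <- xp[idx[q]] + h
    xm <- x; xm[idx[q]] <- xm[idx[q]] - h
    g[q] <- (energyFun(xp) - energyFun(xm)) / (2 * h)
  }
  g
}
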