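# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the package code paths.

# Union-find connected-component count over positive labels, 26-connectivity.
oracle_count_components <- function(vol) {
  dims <- dim(vol)
  idx <- which(vol > 0)
  if (length(idx) == 0) return(0)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pos <- arrayInd(idx, dims)
  key <- setNames(seq_along(idx), idx)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (a in seq_along(idx)) {
    p <- pos[a, ]
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (any(q < 1) || any(q > dims)) next
      j <- q[1] + dims[1] * ((q[2] - 1) + dims[2] * (q[3] - 1))
      b <- key[as.character(j)]
      if (!is.na(b) && vol[idx[b]] == vol[idx[a]]) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  length(unique(vapply(seq_along(idx), find, integer(1))))
}

# Exhaustive-search linear assignment for small k.
oracle_assignment <- function(cost) {
  k <- nrow(cost)
  perms <- gtools_permutations(k)
  best <- NULL
  best_cost <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    cc <- sum(cost[cbind(seq_len(k), p)])
    if (cc < best_cost) {
      best_cost <- cc
      best <- p
    }
  }
  list(perm = best, cost = best_cost)
}

# All permutations of 1..n (recursive; fine for n <= 6).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Direct double-loop silhouette computation (no shared code with the
# package implementation).
oracle_silhouette <- function(points, labels) {
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(points) - points[i, ])^2))
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (length(same) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(di[same])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(di[labels == l])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}
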