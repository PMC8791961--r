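# Brute-force graph oracles shared by the covnet unit tests and the
# acceptance suite: path-enumeration metrics and exhaustive-partition
# modularity, independent of the igraph-backed production code.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[d[s, nxt] == Inf & nxt != s]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# all shortest paths between every pair by depth-first enumeration
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  bet <- numeric(n)
  paths_between <- function(a, b) {
    # enumerate shortest paths a -> b recursively
    if (a == b) return(list(a))
    out <- list()
    for (v in which(adj[a, ] > 0)) {
      if (is.finite(d[v, b]) && d[a, b] == d[v, b] + 1) {
        for (p in paths_between(v, b)) out <- c(out, list(c(a, p)))
      }
    }
    out
  }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (!is.finite(d[a, b])) next
    ps <- paths_between(a, b)
    for (p in ps) {
      inner <- setdiff(p, c(a, b))
      for (v in inner) bet[v] <- bet[v] + 1 / length(ps)
    }
  }
  bet
}

oracle_efficiencies <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  nodal <- rowSums(inv) / (n - 1)
  glob <- sum(inv) / (n * (n - 1))
  loc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    ds <- oracle_distances(sub)
    invs <- 1 / ds
    diag(invs) <- 0
    invs[is.infinite(ds)] <- 0
    sum(invs) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  list(nodal = nodal, global = glob, local = loc)
}

random_adj <- function(n, p = 0.45) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# exhaustive best-partition modularity via restricted-growth enumeration
oracle_best_modularity <- function(adj) {
  n <- nrow(adj)
  m <- sum(adj) / 2
  if (m == 0) return(0)
  deg <- rowSums(adj)
  best <- -Inf
  part <- integer(n)
  recurse <- function(i, maxlab) {
    if (i > n) {
      e_c <- vapply(seq_len(maxlab), function(c) {
        sel <- part == c
        sum(adj[sel, sel, drop = FALSE]) / 2
      }, numeric(1))
      d_c <- vapply(seq_len(maxlab), function(c) sum(deg[part == c]),
                    numeric(1))
      q <- sum(e_c / m - (d_c / (2 * m))^2)
      if (q > best) best <<- q
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      part[i] <<- lab
      recurse(i + 1, max(maxlab, lab))
    }
  }
  recurse(1, 0)
  best
}

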