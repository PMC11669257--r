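# Independent brute-force oracles used to cross-check the package's graph,
# phylogeny and multiple-testing machinery. These deliberately share no
# code path with the implementation (no igraph, no ape distance helpers).

# --- graph utilities on a 0/1 adjacency matrix --------------------------

random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1L, p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}

graph_from_adjacency_named <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

bfs_distances_oracle <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(a[v, ] > 0)
        new <- nb[dist[nb] > dist[v] + 1]
        dist[new] <- dist[v] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
  }
  d
}

# Brandes-style accumulation written from the path-counting definition:
# betweenness(v) = sum over ordered pairs (s, t) of sigma_st(v)/sigma_st,
# halved for undirected graphs.
betweenness_oracle <- function(a) {
  n <- nrow(a)
  bc <- rep(0, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    sigma <- rep(0, n); sigma[s] <- 1
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(a[v, ] > 0)) {
          if (dist[w] < 0) { dist[w] <- dist[v] + 1L; nxt <- c(nxt, w) }
          if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    delta <- rep(0, n)
    for (w in rev(order_visited)) {
      for (v in which(a[w, ] > 0)) {
        if (dist[v] == dist[w] - 1L) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2
}

eigenvector_oracle <- function(a) {
  # principal eigenvector of the largest component, scaled to max 1,
  # zero elsewhere; uses the closed-form dense eigendecomposition
  n <- nrow(a)
  comp <- rep(0L, n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0) next
      comp[v] <- cid
      stack <- c(stack, which(a[v, ] > 0 & comp == 0L))
    }
  }
  largest <- which.max(tabulate(comp))
  idx <- which(comp == largest)
  out <- rep(0, n)
  if (length(idx) == 1) { out[idx] <- 1; return(out) }
  ev <- eigen(a[idx, idx], symmetric = TRUE)
  v <- abs(ev$vectors[, 1])
  out[idx] <- v / max(v)
  out
}

efficiency_oracle <- function(a) {
  d <- bfs_distances_oracle(a)
  n <- nrow(a)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  sum(inv) * 2 / (n * (n - 1))
}

zi_pi_oracle <- function(a, modules) {
  # explicit per-node recount over the edge list
  n <- nrow(a)
  edges <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  k_to_mod <- function(i, m) {
    sum(vapply(seq_len(nrow(edges)), function(e) {
      r <- edges[e, 1]; c <- edges[e, 2]
      (r == i && modules[c] == m) || (c == i && modules[r] == m)
    }, logical(1)))
  }
  zi <- pi_ <- numeric(n)
  for (m in unique(modules)) {
    members <- which(modules == m)
    kin <- vapply(members, function(i) k_to_mod(i, m), numeric(1))
    s <- sqrt(mean((kin - mean(kin))^2))
    zi[members] <- if (s > 0) (kin - mean(kin)) / s else 0
  }
  for (i in seq_len(n)) {
    ktot <- sum(a[i, ])
    if (ktot == 0) { pi_[i] <- 0; next }
    shares <- vapply(unique(modules), function(m) k_to_mod(i, m), numeric(1))
    pi_[i] <- 1 - sum((shares / ktot)^2)
  }
  list(zi = zi, pi = pi_)
}

# --- phylogeny oracles --------------------------------------------------

patristic_oracle <- function(tree) {
  # path enumeration over the tree graph, independent of ape's cophenetic
  n_nodes <- max(tree$edge)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; l <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, l))
    adj[[b]] <- rbind(adj[[b]], c(a, l))
  }
  ntip <- length(tree$tip.label)
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(ntip)) {
    dist <- rep(NA_real_, n_nodes); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (r in seq_len(nrow(adj[[v]]))) {
          w <- adj[[v]][r, 1]
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + adj[[v]][r, 2]
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    D[s, ] <- dist[seq_len(ntip)]
  }
  D
}

bmntd_oracle <- function(m, D, abundance_weighted = TRUE) {
  # explicit double loop over samples and taxa
  S <- ncol(m)
  out <- matrix(0, S, S, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(S)) for (k in seq_len(S)) {
    if (j == k) next
    pj <- which(m[, j] > 0); pk <- which(m[, k] > 0)
    fj <- if (abundance_weighted) m[pj, j] / sum(m[, j]) else
      rep(1 / length(pj), length(pj))
    fk <- if (abundance_weighted) m[pk, k] / sum(m[, k]) else
      rep(1 / length(pk), length(pk))
    term_j <- sum(fj * vapply(pj, function(i) min(D[i, pk]), numeric(1)))
    term_k <- sum(fk * vapply(pk, function(i) min(D[i, pj]), numeric(1)))
    out[j, k] <- (term_j + term_k) / 2
  }
  out
}

# --- multiple testing ---------------------------------------------------

bh_oracle <- function(p) {
  # step-up: adjusted p_(i) = min over j >= i of min(1, p_(j) * m / j)
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, p[o] * m / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# --- small fixture builders --------------------------------------------

toy_table <- function() {
  m <- matrix(c(5L, 0L, 3L,
                2L, 4L, 1L), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  asv_table(m, data.frame(sample_id = c("s1", "s2"),
                          group = c("a", "a")))
}

two_tip_tree <- function(bl = 1) {
  ape::read.tree(text = sprintf("(t1:%g,t2:%g);", bl, bl))
}

make_clique <- function(n, prefix = "c") {
  g <- igraph::make_full_graph(n)
  igraph::set_vertex_attr(g, "name", value = paste0(prefix, seq_len(n)))
}

recovery_fixture <- function(seed = 7) {
  cfg <- synth_config(group_sizes = c(all = 60), filtering_strength = 0,
                      occupancy = 1, seed = seed)
  simulate_dataset(cfg)
}
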