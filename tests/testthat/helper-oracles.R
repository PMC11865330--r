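# Independent brute-force implementations used as oracles, written with
# plain loops so they share no code path with the package internals.

make_net <- function(edges, extra_nodes = character(0)) {
  nodes <- unique(c(edges$from, edges$to, extra_nodes))
  structure(list(nodes = nodes, edges = edges, threshold = 0.01,
                 n_isolated_dropped = 0L),
            class = "signed_network")
}

random_signed_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(
    from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
    r = round(stats::runif(sum(keep), -1, 1), 3),
    stringsAsFactors = FALSE)
  edges <- edges[abs(edges$r) > 1e-6, , drop = FALSE]
  connected <- unique(c(edges$from, edges$to))
  structure(list(nodes = nodes[nodes %in% connected], edges = edges,
                 threshold = 0.01,
                 n_isolated_dropped = n - length(connected)),
            class = "signed_network")
}

# synchronous wMIS cascade by direct edge-list scanning
oracle_cascade_survivors <- function(net, ab, targets) {
  alive <- setdiff(net$nodes, targets)
  repeat {
    if (!length(alive)) break
    wm <- vapply(alive, function(v) {
      nb <- c(net$edges$to[net$edges$from == v],
              net$edges$from[net$edges$to == v])
      rr <- c(net$edges$r[net$edges$from == v],
              net$edges$r[net$edges$to == v])
      ok <- nb %in% alive
      nb <- nb[ok]; rr <- rr[ok]
      if (!length(nb)) return(NA_real_)
      sum(ab[nb] * rr) / sum(ab[nb])
    }, numeric(1))
    dead <- alive[is.na(wm) | wm <= 0]
    if (!length(dead)) break
    alive <- setdiff(alive, dead)
  }
  sort(alive)
}

oracle_connectedness <- function(m) {
  pos <- numeric(nrow(m)); neg <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- c(); q <- c()
    for (j in seq_len(ncol(m))) {
      if (j == i) next
      if (m[i, j] > 0) p <- c(p, m[i, j])
      if (m[i, j] < 0) q <- c(q, m[i, j])
    }
    pos[i] <- if (length(p)) sum(p) / length(p) else 0
    neg[i] <- if (length(q)) sum(q) / length(q) else 0
  }
  list(pos = pos, neg = neg)
}

oracle_zipi <- function(net, mem) {
  nodes <- net$nodes
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(net$edges))) {
    adj[net$edges$from[e], net$edges$to[e]] <- 1
    adj[net$edges$to[e], net$edges$from[e]] <- 1
  }
  zi <- pi_ <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    ki <- sum(adj[i, ])
    kw <- sum(adj[i, names(mem)[mem == mem[nodes[i]]]])
    peers <- nodes[mem[nodes] == mem[nodes[i]]]
    kws <- vapply(peers, function(v) {
      sum(adj[v, names(mem)[mem == mem[v]]])
    }, numeric(1))
    sdv <- stats::sd(kws)
    zi[i] <- if (is.na(sdv) || sdv == 0) 0 else (kw - mean(kws)) / sdv
    s <- 0
    for (m in unique(mem)) {
      kim <- sum(adj[i, names(mem)[mem == m]])
      s <- s + (kim / ki)^2
    }
    pi_[i] <- 1 - s
  }
  data.frame(node = nodes, zi = zi, pi = pi_, stringsAsFactors = FALSE)
}

# mean shortest path on the largest component plus average local
# clustering, by hand (BFS + triangle counting)
oracle_topology <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(net$edges))) {
    adj[net$edges$from[e], net$edges$to[e]] <- TRUE
    adj[net$edges$to[e], net$edges$from[e]] <- TRUE
  }
  deg <- rowSums(adj)
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    links <- 0
    for (a in nb) for (b in nb) if (a < b && adj[a, b]) links <- links + 1
    links / choose(length(nb), 2)
  }, numeric(1))
  # BFS distances
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ])) {
        if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; queue <- c(queue, w) }
      }
    }
    dist[s, ] <- d
  }
  comp_sizes <- integer(0)
  seen <- rep(FALSE, n)
  comp_id <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    cid <- cid + 1
    members <- which(is.finite(dist[s, ]))
    seen[members] <- TRUE
    comp_id[members] <- cid
    comp_sizes <- c(comp_sizes, length(members))
  }
  big <- which(comp_id == which.max(comp_sizes))
  dd <- dist[big, big]
  list(mean_degree = mean(deg),
       clustering = mean(cc),
       mean_path = mean(dd[upper.tri(dd)]))
}

oracle_core <- function(genus_rel, criteria) {
  n_g <- nrow(genus_rel); n_s <- ncol(genus_rel)
  out <- data.frame(genus = rownames(genus_rel), ubiquitous = FALSE,
                    abundant = FALSE, frequent = FALSE,
                    stringsAsFactors = FALSE)
  for (g in seq_len(n_g)) {
    out$ubiquitous[g] <- sum(genus_rel[g, ] > 0) / n_s > criteria$ubiquity_frac
    out$abundant[g] <- mean(genus_rel[g, ]) > criteria$abundant_cutoff
    hits <- 0
    for (s in seq_len(n_s)) {
      worse_or_equal <- sum(genus_rel[, s] >= genus_rel[g, s])
      if (worse_or_equal / n_g <= criteria$frequent_rank_quantile) {
        hits <- hits + 1
      }
    }
    out$frequent[g] <- hits / n_s > criteria$frequent_sample_frac
  }
  out$core <- out$ubiquitous & out$abundant & out$frequent
  out
}

oracle_wmd <- function(profile) {
  s <- 0; tot <- sum(profile$copies)
  for (i in seq_len(nrow(profile))) {
    s <- s + profile$density[i] * profile$copies[i] / tot
  }
  s
}
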