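#' Prevalence filter
#'
#' Retains taxa with nonzero abundance in at least `min_frac` of samples.
#' Correlation-based networks degrade badly for taxa dominated by zeros,
#' so half-prevalence is the conventional default.
#'
#' @param table An [abundance_table()] or taxon x sample matrix.
#' @param min_frac Minimum occupancy fraction, default 0.5.
#' @return Filtered object of the same kind.
#' @export
prevalence_filter <- function(table, min_frac = 0.5) {
  counts <- as_count_matrix(table)
  keep <- rowMeans(counts > 0) >= min_frac
  if (inherits(table, "abundance_table")) {
    abundance_table(counts[keep, , drop = FALSE],
                    table$taxonomy[keep, , drop = FALSE])
  } else {
    counts[keep, , drop = FALSE]
  }
}

#' Pearson correlation matrix of log-transformed abundances
#'
#' Zeros are replaced by half the smallest nonzero value in the table (a
#' scale-stable pseudo-abundance) before taking logs; correlations are then
#' plain Pearson on the log scale, which is invariant to per-taxon
#' multiplicative rescaling. Constant taxa get correlation 0 to all
#' partners and are recorded in the `"flagged"` attribute; the diagonal is
#' always 1.
#'
#' @param table An [abundance_table()] or taxon x sample matrix (counts or
#'   relative abundances), at least 4 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  x <- as_count_matrix(table)
  if (ncol(x) < 4) stop("need at least 4 samples", call. = FALSE)
  nz <- x[x > 0]
  if (!length(nz)) stop("all-zero table", call. = FALSE)
  pseudo <- min(nz) / 2
  lx <- x
  lx[x == 0] <- pseudo
  lx <- log(lx)
  r <- suppressWarnings(stats::cor(t(lx)))
  flagged <- rownames(x)[apply(lx, 1, stats::sd) == 0]
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "flagged") <- flagged
  r
}

#' Build a signed co-occurrence network from a correlation matrix
#'
#' Keeps every pair with `|r| >= threshold` as a signed weighted edge;
#' nodes left without any edge are dropped and counted.
#'
#' @param r Symmetric correlation matrix with named rows/columns.
#' @param threshold Correlation cutoff in (0, 1).
#' @return Object of class `signed_network`: `nodes`, `edges` (data.frame
#'   `from`, `to`, `r` with `from < to`), `threshold`,
#'   `n_isolated_dropped`.
#' @export
build_network <- function(r, threshold) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  ids <- rownames(r) %||% sprintf("node_%d", seq_len(nrow(r)))
  idx <- which(abs(r) >= threshold & upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      r = r[idx], stringsAsFactors = FALSE)
  connected <- unique(c(edges$from, edges$to))
  nodes <- ids[ids %in% connected]
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 n_isolated_dropped = length(ids) - length(nodes)),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf(
    "signed_network: %d nodes, %d edges (%.0f%% positive), |r| >= %.2f; %d isolated dropped\n",
    length(x$nodes), nrow(x$edges),
    if (nrow(x$edges)) 100 * mean(x$edges$r > 0) else 0,
    x$threshold, x$n_isolated_dropped))
  invisible(x)
}

# igraph view of a signed network; weights are |r| (igraph community and
# path algorithms require non-negative weights), sign kept as an attribute.
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    transform(net$edges, weight = abs(net$edges$r), sign = sign(net$edges$r)),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  g
}

#' Detect network modules by greedy modularity maximisation
#'
#' Runs fast-greedy modularity optimisation on the |r|-weighted graph.
#' The algorithm is deterministic; disconnected components never share a
#' module.
#'
#' @param net A [build_network()] result.
#' @return List with `membership` (named integer vector, node -> module)
#'   and `modularity` (Q of the returned partition).
#' @export
detect_modules <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (length(net$nodes) == 0L) {
    return(list(membership = integer(0), modularity = NA_real_))
  }
  g <- as_igraph(net)
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  mem <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(mem), names(mem)),
       modularity = igraph::modularity(g, igraph::membership(cl),
                                       weights = igraph::E(g)$weight))
}

#' Classify a node role from its Zi and Pi values
#'
#' The rule is: `Zi >= 2.5` makes a hub, `Pi >= 0.62` makes a connector;
#' both give a network hub, neither a peripheral node. Module hubs,
#' connectors and network hubs are all "key" nodes.
#'
#' @param zi,pi Numeric vectors (recycled to common length).
#' @param zi_threshold,pi_threshold Role thresholds.
#' @return Character vector: "peripheral", "connector", "module hub" or
#'   "network hub".
#' @export
classify_node_role <- function(zi, pi, zi_threshold = 2.5,
                               pi_threshold = 0.62) {
  hub <- zi >= zi_threshold
  con <- pi >= pi_threshold
  ifelse(hub & con, "network hub",
         ifelse(hub, "module hub",
                ifelse(con, "connector", "peripheral")))
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' Degrees are unweighted (binary adjacency), following the original
#' Guimera-Amaral formulation: `Zi` is the z-score of a node's
#' within-module degree relative to its module (0 when the module's
#' within-degree spread is zero), and `Pi = 1 - sum_t (k_it / k_i)^2` over
#' modules t. Roles follow [classify_node_role()].
#'
#' @param net A [build_network()] result.
#' @param membership Named module assignment covering all nodes (e.g. from
#'   [detect_modules()]).
#' @param weighted Use |r|-weighted degrees instead of binary ones.
#' @return data.frame: `node`, `module`, `degree`, `zi`, `pi`, `role`.
#' @export
compute_zipi <- function(net, membership, weighted = FALSE) {
  stopifnot(inherits(net, "signed_network"))
  nodes <- net$nodes
  if (!all(nodes %in% names(membership))) {
    stop("membership must cover all network nodes", call. = FALSE)
  }
  mem <- membership[nodes]
  w <- if (weighted) abs(net$edges$r) else rep(1, nrow(net$edges))
  # k_it: node x module incident weight
  mods <- sort(unique(mem))
  kit <- matrix(0, length(nodes), length(mods),
                dimnames = list(nodes, as.character(mods)))
  for (e in seq_len(nrow(net$edges))) {
    f <- net$edges$from[e]; t_ <- net$edges$to[e]
    kit[f, as.character(mem[t_])] <- kit[f, as.character(mem[t_])] + w[e]
    kit[t_, as.character(mem[f])] <- kit[t_, as.character(mem[f])] + w[e]
  }
  k <- rowSums(kit)
  k_within <- kit[cbind(seq_along(nodes), match(mem, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    in_m <- mem == m
    mu <- mean(k_within[in_m])
    sdv <- stats::sd(k_within[in_m])
    zi[in_m] <- if (is.na(sdv) || sdv == 0) 0 else (k_within[in_m] - mu) / sdv
  }
  pi <- 1 - rowSums((kit / k)^2)
  data.frame(node = nodes, module = unname(mem), degree = unname(k),
             zi = zi, pi = unname(pi),
             role = classify_node_role(zi, pi),
             stringsAsFactors = FALSE)
}

#' Topological summary of a signed network
#'
#' @param net A [build_network()] result with at least one node.
#' @return List: `n_nodes`, `n_edges`, `mean_degree`, `clustering`
#'   (average local clustering coefficient), `mean_path` (mean shortest
#'   path on the largest connected component, unweighted),
#'   `positive_edge_frac`, and `neighbors` (per-node neighbour id lists).
#' @export
topology_summary <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (length(net$nodes) == 0L) stop("empty network", call. = FALSE)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  nb <- igraph::adjacent_vertices(g, igraph::V(g))
  neighbors <- lapply(nb, function(v) igraph::V(g)$name[as.integer(v)])
  names(neighbors) <- igraph::V(g)$name
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       mean_degree = mean(igraph::degree(g)),
       clustering = igraph::transitivity(g, type = "localaverage",
                                         isolates = "zero"),
       mean_path = igraph::mean_distance(sub, weights = NA),
       positive_edge_frac = if (nrow(net$edges)) mean(net$edges$r > 0)
                            else NA_real_,
       neighbors = neighbors)
}
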