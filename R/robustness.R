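# Dense signed adjacency matrix of a network (0 where no edge).
signed_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    A[cbind(i, j)] <- net$edges$r
    A[cbind(j, i)] <- net$edges$r
  }
  A
}

#' Abundance-weighted mean interaction strength (wMIS)
#'
#' For node i, `wMIS_i = sum_j b_j s_ij / sum_j b_j` over its surviving
#' neighbours j, where `b_j` is the neighbour's relative abundance and
#' `s_ij` the signed edge correlation. A node with no surviving neighbour
#' has undefined wMIS (returned as `NA`; cascade semantics treat it as
#' isolated).
#'
#' @param net A [build_network()] result.
#' @param abundances Named numeric vector, taxon -> relative abundance,
#'   covering the network's nodes.
#' @param node Node id to evaluate.
#' @param alive Optional character vector of currently surviving nodes
#'   (default: all nodes).
#' @return Single numeric wMIS value (NA when isolated).
#' @export
compute_wmis <- function(net, abundances, node, alive = net$nodes) {
  stopifnot(inherits(net, "signed_network"), node %in% net$nodes)
  A <- signed_adjacency(net)
  wmis_from_adjacency(A, abundances[net$nodes], match(node, net$nodes),
                      net$nodes %in% alive)
}

# wMIS for one node index given adjacency, abundance vector and a logical
# survival mask; NA when the node has no surviving neighbour.
wmis_from_adjacency <- function(A, b, i, alive_mask) {
  s <- A[i, ]
  nb <- which(s != 0 & alive_mask)
  nb <- nb[nb != i]
  if (!length(nb)) return(NA_real_)
  sum(b[nb] * s[nb]) / sum(b[nb])
}

#' Simulate a wMIS-driven extinction cascade
#'
#' The target nodes are removed, then extinction is iterated synchronously
#' to a fixed point: at each step the wMIS of every survivor is computed
#' over surviving neighbours, and all nodes with `wMIS <= 0` or with no
#' surviving neighbour (isolated) are removed together. With
#' `single_pass = TRUE` only one extinction sweep is applied.
#'
#' @param net A [build_network()] result.
#' @param abundances Named numeric vector, taxon -> relative abundance.
#' @param targets Character vector of initially removed node ids (subset
#'   of the network's nodes; may be empty, which yields the baseline
#'   pruning of the untouched network).
#' @param single_pass Stop after the first extinction sweep.
#' @return List of class `cascade_result`: `removed_ids`, `extinct_ids`,
#'   `surviving_frac`, `trajectory` (extinctions per iteration).
#' @export
simulate_removal_cascade <- function(net, abundances, targets = character(0),
                                     single_pass = FALSE) {
  stopifnot(inherits(net, "signed_network"))
  if (!all(targets %in% net$nodes)) {
    stop("targets must be a subset of network nodes", call. = FALSE)
  }
  nodes <- net$nodes
  n <- length(nodes)
  A <- signed_adjacency(net)
  b <- abundances[nodes]
  if (anyNA(b)) stop("abundances must cover all network nodes", call. = FALSE)
  alive <- !(nodes %in% targets)
  trajectory <- integer(0)
  repeat {
    idx_alive <- which(alive)
    if (!length(idx_alive)) break
    wmis <- vapply(idx_alive, function(i) wmis_from_adjacency(A, b, i, alive),
                   numeric(1))
    dying <- idx_alive[is.na(wmis) | wmis <= 0]
    if (!length(dying)) break
    alive[dying] <- FALSE
    trajectory <- c(trajectory, length(dying))
    if (single_pass) break
  }
  extinct <- setdiff(nodes[!alive], targets)
  structure(list(removed_ids = targets,
                 extinct_ids = extinct,
                 surviving_frac = sum(alive) / n,
                 trajectory = trajectory),
            class = "cascade_result")
}

#' Random-removal robustness curve
#'
#' For each removal fraction, draws `n_rep` uniform random target sets,
#' runs the extinction cascade and summarises the surviving fraction.
#'
#' @param net A [build_network()] result.
#' @param abundances Named numeric vector, taxon -> relative abundance.
#' @param fracs Removal fractions in `[0, 1)`.
#' @param n_rep Replicates per fraction.
#' @param seed Integer seed; target sets are drawn from per-replicate
#'   sub-seeds so `n_rep = 1` reproduces a single cascade call.
#' @return data.frame: `frac`, `mean_surviving`, `sd_surviving`.
#' @export
random_removal_curve <- function(net, abundances, fracs, n_rep = 20,
                                 seed = 1) {
  stopifnot(all(fracs >= 0), all(fracs < 1))
  n <- length(net$nodes)
  rows <- lapply(fracs, function(f) {
    k <- if (f == 0) 0L else max(1L, round(f * n))
    surv <- vapply(seq_len(n_rep), function(rep) {
      targets <- if (k == 0) character(0) else
        with_seed(sub_seed(seed, sprintf("removal_%g_%d", f, rep)),
                  sample(net$nodes, k))
      simulate_removal_cascade(net, abundances, targets)$surviving_frac
    }, numeric(1))
    data.frame(frac = f, mean_surviving = mean(surv),
               sd_surviving = stats::sd(surv))
  })
  do.call(rbind, rows)
}
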