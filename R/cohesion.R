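#' Null-model-corrected pairwise correlations ("taxa shuffle")
#'
#' For every ordered taxon pair (i, j), the observed Pearson correlation is
#' corrected by subtracting the mean correlation between i and a
#' column-shuffled j over `n_iter` independent shuffles (each taxon's
#' abundances permuted across samples). The two directed corrections are
#' averaged into a symmetric matrix. Note that the mean of a Pearson
#' correlation over all permutations of one vector is -1/(n-1), so the
#' corrected value of an unrelated pair is centred at +1/(n-1) for fresh
#' data but exactly at 0 for taxa-shuffled data, which is the reference
#' frame of the null calibration. Constant taxa are flagged and get
#' corrected correlation 0.
#'
#' @param rel Taxon x sample relative abundance matrix (>= 5 samples).
#' @param n_iter Number of null iterations (>= 50; default 200).
#' @param seed Integer seed.
#' @param log_transform Correlate log-transformed abundances (zeros
#'   replaced by half the smallest nonzero value), the same scale the
#'   co-occurrence network uses. Log correlations are far less skewed
#'   under the permutation null than linear-scale ones for heavy-tailed
#'   abundance data, so the null-corrected values are better centred;
#'   set FALSE for plain linear-scale Pearson.
#' @return Symmetric corrected correlation matrix, zero diagonal, with
#'   attributes `"flagged"` (constant taxa) and `"mc_se"` (Monte-Carlo
#'   standard error of the null mean, averaged over pairs).
#' @export
null_corrected_correlations <- function(rel, n_iter = 200, seed = 1,
                                        log_transform = TRUE) {
  stopifnot(is.matrix(rel))
  if (ncol(rel) < 5) stop("need at least 5 samples", call. = FALSE)
  if (n_iter < 50) stop("n_iter must be >= 50", call. = FALSE)
  if (log_transform) {
    nz <- rel[rel > 0]
    if (length(nz)) {
      pseudo <- min(nz) / 2
      rel[rel == 0] <- pseudo
      rel <- log(rel)
    }
  }
  X <- t(rel)                                 # samples x taxa
  constant <- apply(X, 2, stats::sd) == 0
  robs <- suppressWarnings(stats::cor(X))
  robs[is.na(robs)] <- 0
  n_s <- nrow(X)
  acc <- matrix(0, ncol(X), ncol(X))
  acc2 <- matrix(0, ncol(X), ncol(X))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      Xp <- apply(X, 2, sample, size = n_s)
      rn <- suppressWarnings(stats::cor(X, Xp))  # [i, j] = cor(x_i, perm x_j)
      rn[is.na(rn)] <- 0
      acc <- acc + rn
      acc2 <- acc2 + rn^2
    }
  })
  null_mean <- acc / n_iter
  null_var <- pmax(acc2 / n_iter - null_mean^2, 0)
  corrected <- robs - null_mean
  corrected <- (corrected + t(corrected)) / 2
  corrected[constant, ] <- 0
  corrected[, constant] <- 0
  diag(corrected) <- 0
  dimnames(corrected) <- list(rownames(rel), rownames(rel))
  attr(corrected, "flagged") <- rownames(rel)[constant]
  attr(corrected, "mc_se") <- mean(sqrt(null_var / n_iter))
  corrected
}

#' Per-taxon positive and negative connectedness
#'
#' A taxon's positive connectedness is the mean of its strictly positive
#' corrected correlations to all partners; negative connectedness the mean
#' of the strictly negative ones. Empty sets give 0.
#'
#' @param corrected Symmetric corrected correlation matrix with zero
#'   diagonal (from [null_corrected_correlations()]).
#' @return data.frame: `taxon_id`, `pos` (>= 0), `neg` (<= 0).
#' @export
connectedness <- function(corrected) {
  stopifnot(is.matrix(corrected), nrow(corrected) == ncol(corrected))
  pos <- apply(corrected, 1, function(x) {
    v <- x[x > 0]
    if (length(v)) mean(v) else 0
  })
  neg <- apply(corrected, 1, function(x) {
    v <- x[x < 0]
    if (length(v)) mean(v) else 0
  })
  data.frame(taxon_id = rownames(corrected) %||%
               sprintf("taxon_%d", seq_len(nrow(corrected))),
             pos = unname(pos), neg = unname(neg),
             stringsAsFactors = FALSE)
}

#' Per-sample positive and negative cohesion
#'
#' Cohesion sums each taxon's relative abundance times its (positive or
#' negative) connectedness: positive cohesion proxies potential
#' cooperation, negative cohesion potential competition, and total
#' cohesion is positive plus |negative|.
#'
#' @param rel Taxon x sample relative abundance matrix.
#' @param conn [connectedness()] result aligned to the table's taxa.
#' @return data.frame: `sample_id`, `pos` (>= 0), `neg` (<= 0), `total`.
#' @export
sample_cohesion <- function(rel, conn) {
  stopifnot(is.matrix(rel), is.data.frame(conn))
  idx <- match(rownames(rel), conn$taxon_id)
  if (anyNA(idx)) stop("connectedness does not cover all taxa", call. = FALSE)
  cpos <- colSums(rel * conn$pos[idx])
  cneg <- colSums(rel * conn$neg[idx])
  data.frame(sample_id = colnames(rel) %||%
               sprintf("S%d", seq_len(ncol(rel))),
             pos = unname(cpos), neg = unname(cneg),
             total = unname(cpos + abs(cneg)),
             stringsAsFactors = FALSE)
}

#' One-call cohesion pipeline
#'
#' Runs [null_corrected_correlations()], [connectedness()] and
#' [sample_cohesion()] on a relative abundance matrix.
#'
#' @inheritParams null_corrected_correlations
#' @return List with `corrected`, `connectedness`, `cohesion`.
#' @export
cohesion_analysis <- function(rel, n_iter = 200, seed = 1,
                              log_transform = TRUE) {
  corrected <- null_corrected_correlations(rel, n_iter = n_iter, seed = seed,
                                           log_transform = log_transform)
  conn <- connectedness(corrected)
  list(corrected = corrected, connectedness = conn,
       cohesion = sample_cohesion(rel, conn))
}
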