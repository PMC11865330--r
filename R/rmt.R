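#' Random-matrix-theory correlation threshold selection
#'
#' For each candidate cutoff `t`, the correlation matrix is hard-thresholded
#' (`|r| < t` set to 0), its eigenvalue spectrum computed, near-degenerate
#' eigenvalues collapsed, and the spectrum unfolded by a smooth spline fit
#' to the cumulative eigenvalue staircase. The nearest-neighbour spacing
#' distribution (NNSD) of the unfolded spectrum is then scored against the
#' Poisson law `exp(-s)` (the RMT signature of non-random, modular
#' structure) and, for diagnostics, against the Wigner-Dyson law
#' `(pi/2) s exp(-pi s^2 / 4)` (the signature of a noise-dominated
#' spectrum). The selected threshold is the smallest `t` whose NNSD is
#' consistent with Poisson by a chi-square test.
#'
#' @param r Symmetric correlation matrix (at least 30 x 30 for a
#'   meaningful spectrum; smaller matrices warn and return `fallback`).
#' @param t_grid Candidate thresholds, default `seq(0.30, 0.99, 0.01)`.
#' @param p_threshold Chi-square p-value above which the NNSD counts as
#'   Poisson-consistent (default 0.05).
#' @param n_bins Spacing histogram bins over `[0, 3]` plus an open tail
#'   bin (default 12, giving >= 10 informative bins).
#' @param min_spacings Minimum unfolded spacings needed to test a
#'   threshold (default 30).
#' @param fallback Threshold returned (flagged) when the matrix is too
#'   small or no candidate qualifies.
#' @return List: `threshold`, `no_transition` flag, `small_matrix` flag,
#'   and `diagnostics` (per-t data.frame with eigenvalue/spacing counts
#'   and Poisson / Wigner-Dyson goodness-of-fit p-values).
#' @export
select_rmt_threshold <- function(r, t_grid = seq(0.30, 0.99, by = 0.01),
                                 p_threshold = 0.05, n_bins = 12,
                                 min_spacings = 30, fallback = 0.70) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (nrow(r) < 30) {
    warning("matrix smaller than 30 x 30: spectrum too short for RMT, ",
            "returning fallback threshold", call. = FALSE)
    return(list(threshold = fallback, no_transition = TRUE,
                small_matrix = TRUE, diagnostics = NULL))
  }
  diag_rows <- lapply(t_grid, function(t) {
    m <- r
    m[abs(m) < t] <- 0
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    sp <- unfolded_spacings(ev)
    if (length(sp) < min_spacings) {
      return(data.frame(t = t, n_eigen = length(ev), n_spacings = length(sp),
                        poisson_p = NA_real_, wigner_p = NA_real_))
    }
    data.frame(t = t, n_eigen = length(ev), n_spacings = length(sp),
               poisson_p = nnsd_gof(sp, "poisson", n_bins),
               wigner_p = nnsd_gof(sp, "wigner", n_bins))
  })
  diagnostics <- do.call(rbind, diag_rows)
  ok <- which(!is.na(diagnostics$poisson_p) &
                diagnostics$poisson_p > p_threshold)
  if (length(ok)) {
    list(threshold = diagnostics$t[ok[1L]], no_transition = FALSE,
         small_matrix = FALSE, diagnostics = diagnostics)
  } else {
    list(threshold = max(t_grid), no_transition = TRUE,
         small_matrix = FALSE, diagnostics = diagnostics)
  }
}

# Collapse near-degenerate eigenvalues, unfold the spectrum with a smooth
# spline fit to the cumulative staircase, and return nearest-neighbour
# spacings normalised to unit mean.
unfolded_spacings <- function(ev, degeneracy_tol = 1e-8) {
  ev <- sort(ev)
  keep <- c(TRUE, diff(ev) > degeneracy_tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < 5) return(numeric(0))
  df <- min(10, max(4, floor(n / 4)))
  fit <- stats::smooth.spline(ev, seq_len(n), df = df)
  unfolded <- stats::predict(fit, ev)$y
  sp <- diff(unfolded)
  sp <- sp[sp > 0]
  if (!length(sp)) return(numeric(0))
  sp / mean(sp)
}

# Chi-square goodness of fit of unit-mean spacings to the Poisson or
# Wigner-Dyson NNSD, binned over [0, 3] with an open tail bin.
nnsd_gof <- function(sp, law = c("poisson", "wigner"), n_bins = 12) {
  law <- match.arg(law)
  breaks <- c(seq(0, 3, length.out = n_bins + 1), Inf)
  obs <- table(cut(sp, breaks, include.lowest = TRUE))
  cdf <- switch(law,
                poisson = function(s) 1 - exp(-s),
                wigner = function(s) 1 - exp(-pi * s^2 / 4))
  p <- diff(cdf(breaks))
  p[length(p)] <- 1 - cdf(3)
  expected <- length(sp) * p
  # merge ultra-sparse tail bins into their neighbour for test validity
  stat <- sum((as.numeric(obs) - expected)^2 / pmax(expected, 1e-12))
  stats::pchisq(stat, df = length(p) - 1, lower.tail = FALSE)
}
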