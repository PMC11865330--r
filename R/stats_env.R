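#' Correlation with Fisher-z confidence interval
#'
#' Pearson (default) or Spearman correlation with a two-sided p-value and,
#' for Pearson, a Fisher-z 95% confidence interval.
#'
#' @param x,y Finite numeric vectors of equal length >= 4.
#' @param method "pearson" or "spearman".
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return List: `r`, `p`, `ci` (length-2; collapses to `r` when
#'   `|r| = 1`, NA for Spearman), `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  r <- unname(ct$estimate)
  ci <- if (method != "pearson") {
    c(NA_real_, NA_real_)
  } else if (abs(r) >= 1 - 1e-15) {
    c(r, r)
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    tanh(c(z - q * se, z + q * se))
  }
  list(r = r, p = ct$p.value, ci = ci, n = n)
}

# Adjusted (or raw) R^2 of y regressed on a set of predictor columns.
subset_r2 <- function(y, X, cols, adjusted) {
  fit <- stats::lm(y ~ ., data = X[, cols, drop = FALSE])
  s <- summary(fit)
  if (adjusted) s$adj.r.squared else s$r.squared
}

#' Variance partitioning over up to three predictors
#'
#' Fits least squares for every non-empty predictor subset and decomposes
#' the full model's (adjusted) R^2 into unique fractions per predictor,
#' shared fractions per predictor pair and triple (by inclusion-exclusion
#' over the subset R^2 values), and a residual fraction. The unique
#' ("individual") fractions are what conditional variance-partitioning
#' diagrams report; fractions can be slightly negative with adjusted R^2
#' and are reported as-is.
#'
#' @param y Numeric response.
#' @param X data.frame of 1-3 numeric predictors (`n > ncol(X) + 1`).
#' @param adjusted Use adjusted R^2 (default) rather than raw R^2.
#' @return List of class `vpa_result`: `unique` (named), `shared` (named
#'   by subsets such as "x1:x2"), `full_r2`, `residual`, and the per-subset
#'   `subset_r2` table.
#' @export
variance_partition <- function(y, X, adjusted = TRUE) {
  X <- as.data.frame(X)
  p <- ncol(X)
  stopifnot(p >= 1, p <= 3, length(y) > p + 1)
  nm <- names(X)
  xm <- as.matrix(X)
  if (p > 1) {
    cond <- kappa(cbind(1, scale(xm)), exact = TRUE)
    if (!is.finite(cond) || cond > 1e8) {
      warning("predictors are (near-)collinear; fractions reported as-is",
              call. = FALSE)
    }
  }
  subsets <- unlist(lapply(seq_len(p), function(k) {
    utils::combn(nm, k, simplify = FALSE)
  }), recursive = FALSE)
  r2 <- vapply(subsets, function(s) subset_r2(y, X, s, adjusted), numeric(1))
  names(r2) <- vapply(subsets, paste, character(1), collapse = ":")
  full <- r2[paste(nm, collapse = ":")]
  get <- function(s) {
    if (!length(s)) return(0)
    unname(r2[paste(intersect(nm, s), collapse = ":")])
  }
  uniq <- vapply(nm, function(v) unname(full) - get(setdiff(nm, v)), numeric(1))
  shared <- numeric(0)
  if (p == 2) {
    shared <- stats::setNames(get(nm[1]) + get(nm[2]) - unname(full),
                              paste(nm, collapse = ":"))
  } else if (p == 3) {
    pair_names <- utils::combn(nm, 2, simplify = FALSE)
    shared_pairs <- vapply(pair_names, function(pr) {
      k <- setdiff(nm, pr)
      get(c(pr[1], k)) + get(c(pr[2], k)) - get(k) - unname(full)
    }, numeric(1))
    names(shared_pairs) <- vapply(pair_names, paste, character(1),
                                  collapse = ":")
    triple <- sum(vapply(nm, get, numeric(1))) -
      sum(vapply(pair_names, get, numeric(1))) + unname(full)
    shared <- c(shared_pairs,
                stats::setNames(triple, paste(nm, collapse = ":")))
  }
  structure(list(unique = uniq, shared = shared,
                 full_r2 = unname(full), residual = 1 - unname(full),
                 subset_r2 = r2, adjusted = adjusted),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat(sprintf("Variance partitioning (%s R^2 = %.3f)\n",
              if (x$adjusted) "adjusted" else "raw", x$full_r2))
  cat("unique fractions:\n")
  print(round(x$unique, 4))
  if (length(x$shared)) {
    cat("shared fractions:\n")
    print(round(x$shared, 4))
  }
  cat(sprintf("residual: %.4f\n", x$residual))
  invisible(x)
}

#' Free ammonia concentration at equilibrium
#'
#' NH3 = TAN / (1 + 10^(pKa - pH)) with the temperature-dependent
#' dissociation constant pKa(T) = 0.09018 + 2729.92 / T_K (Emerson 1975).
#' Mass balance holds: NH3 + NH4+ = TAN.
#'
#' @param tan Total ammonium nitrogen, mol/L (>= 0).
#' @param ph pH value(s).
#' @param temperature_c Temperature in degrees Celsius, within `[0, 60]`.
#' @return Free ammonia, mol/L (vectorised).
#' @export
free_ammonia <- function(tan, ph, temperature_c = 25) {
  if (any(!is.finite(tan)) || any(!is.finite(ph)) ||
      any(!is.finite(temperature_c))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(tan < 0)) stop("total ammonium must be >= 0", call. = FALSE)
  if (any(temperature_c < 0 | temperature_c > 60)) {
    stop("temperature must be within [0, 60] degrees C", call. = FALSE)
  }
  tk <- temperature_c + 273.15
  pka <- 0.09018 + 2729.92 / tk
  tan / (1 + 10^(pka - ph))
}

#' Potential nitrification rate from a NOx time series
#'
#' Ordinary least-squares slope of summed nitrite + nitrate concentration
#' against time.
#'
#' @param time_days Numeric time points (>= 3, at least two distinct).
#' @param nox Concentration series (same length), e.g. mg N / kg.
#' @return List: `slope` (concentration per day), `r2`, `fit` (the lm).
#' @export
nitrification_rate <- function(time_days, nox) {
  stopifnot(length(time_days) == length(nox))
  if (length(time_days) < 3) stop("need at least 3 time points", call. = FALSE)
  if (length(unique(time_days)) < 2) {
    stop("time points must not be a single repeated value", call. = FALSE)
  }
  fit <- stats::lm(nox ~ time_days)
  list(slope = unname(stats::coef(fit)[2]),
       r2 = summary(fit)$r.squared,
       fit = fit)
}
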