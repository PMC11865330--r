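# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed and a label, so each
# generated artifact consumes its own RNG stream and adding an artifact
# never perturbs the others. Result is a valid 32-bit integer seed.
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(label)
  h <- sum(codes * ((seq_along(codes) %% 29L) + 3L))
  as.integer((abs(seed) * 1009 + h * 97) %% 2147483629)
}

# Evaluate code with a temporary RNG state; the caller's stream is restored
# on exit so library functions never disturb user-level reproducibility.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Extract the numeric count matrix from either an abundance_table or a
# plain taxon x sample matrix.
as_count_matrix <- function(table) {
  if (inherits(table, "abundance_table")) table$counts else {
    stopifnot(is.matrix(table), is.numeric(table))
    table
  }
}
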