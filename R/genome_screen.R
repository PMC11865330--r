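#' Classify genomes as cobalamin-dependent and/or -synthesizing
#'
#' A genome is cobalamin-dependent (CD) when it encodes at least one of
#' mutA, metH or rsmB, and cobalamin-synthesizing (CS) when all three
#' pathway steps (A: corrin ring, B: final synthesis and repair, C:
#' dimethylbenzimidazole synthesis) are complete. Partial step sets are
#' reported for the intermediate class.
#'
#' @param features data.frame with `genome_id` and logical columns `mutA`,
#'   `metH`, `rsmB`, `stepA`, `stepB`, `stepC`.
#' @return data.frame: `genome_id`, `is_cd`, `is_cs`, `partial_steps`
#'   (comma-separated step letters present).
#' @export
classify_cd_cs <- function(features) {
  need <- c("genome_id", "mutA", "metH", "rsmB", "stepA", "stepB", "stepC")
  stopifnot(is.data.frame(features), all(need %in% names(features)))
  gene_cols <- c("mutA", "metH", "rsmB")
  step_cols <- c("stepA", "stepB", "stepC")
  if (anyNA(features[, c(gene_cols, step_cols)])) {
    stop("feature booleans must be total (no NA)", call. = FALSE)
  }
  is_cd <- rowSums(features[, gene_cols, drop = FALSE]) > 0
  steps <- as.matrix(features[, step_cols, drop = FALSE])
  is_cs <- rowSums(steps) == 3
  partial <- apply(steps, 1, function(x) {
    paste(c("A", "B", "C")[as.logical(x)], collapse = ",")
  })
  data.frame(genome_id = features$genome_id,
             is_cd = unname(is_cd), is_cs = unname(is_cs),
             partial_steps = unname(partial),
             stringsAsFactors = FALSE)
}

#' Per-sample cobalamin supply and demand summary
#'
#' Sums the relative abundance of CD and CS genomes per sample and splits
#' the CS abundance among supplier labels (e.g. the fraction of supply
#' attributable to comammox-labelled genomes). Group means are reported
#' when metadata with a `group` column is given.
#'
#' @param classification Output of [classify_cd_cs()].
#' @param abundance Genome x sample relative abundance matrix.
#' @param labels Named character vector genome_id -> label (e.g.
#'   "comammox"/"other"), or a `features` data.frame with a `label`
#'   column.
#' @param meta Optional metadata data.frame with `sample_id` and `group`.
#' @return List with `per_sample` (data.frame: `sample_id`, `relab_cd`,
#'   `relab_cs`, one `share_<label>` column per label; shares are NA and
#'   flagged where a sample has zero CS abundance) and `group_means`
#'   (NULL without metadata).
#' @export
supply_demand_summary <- function(classification, abundance, labels,
                                  meta = NULL) {
  stopifnot(is.matrix(abundance))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$genome_id)
  }
  ids <- rownames(abundance)
  stopifnot(all(ids %in% classification$genome_id), all(ids %in% names(labels)))
  cls <- classification[match(ids, classification$genome_id), ]
  if (!any(cls$is_cs)) stop("no CS genome in the catalogue", call. = FALSE)
  relab_cd <- colSums(abundance[cls$is_cd, , drop = FALSE])
  cs_ab <- abundance[cls$is_cs, , drop = FALSE]
  relab_cs <- colSums(cs_ab)
  lab_cs <- labels[ids][cls$is_cs]
  share <- sapply(sort(unique(labels[ids])), function(l) {
    num <- colSums(cs_ab[lab_cs == l, , drop = FALSE])
    ifelse(relab_cs > 0, num / relab_cs, NA_real_)
  })
  per_sample <- data.frame(sample_id = colnames(abundance),
                           relab_cd = unname(relab_cd),
                           relab_cs = unname(relab_cs),
                           zero_cs = relab_cs == 0,
                           stringsAsFactors = FALSE)
  for (l in colnames(share)) per_sample[[paste0("share_", l)]] <- share[, l]
  group_means <- NULL
  if (!is.null(meta)) {
    stopifnot(all(c("sample_id", "group") %in% names(meta)))
    g <- meta$group[match(per_sample$sample_id, meta$sample_id)]
    num_cols <- setdiff(names(per_sample), c("sample_id", "zero_cs"))
    group_means <- stats::aggregate(per_sample[num_cols], list(group = g),
                                    mean, na.rm = TRUE)
  }
  list(per_sample = per_sample, group_means = group_means)
}

#' Sum gene-set expression (TPM) per sample
#'
#' Per-sample totals of transcripts-per-million over named gene sets, e.g.
#' cobalamin biosynthesis genes vs dependence genes. Genes listed in a set
#' but absent from the matrix are skipped with a warning.
#'
#' @param tpm Gene x sample TPM matrix; each column should total at most
#'   1e6 (1% tolerance).
#' @param gene_sets Named list of character vectors of gene ids.
#' @return Set x sample matrix of totals.
#' @export
gene_set_tpm <- function(tpm, gene_sets) {
  stopifnot(is.matrix(tpm), is.list(gene_sets), length(gene_sets) > 0)
  if (any(colSums(tpm) > 1e6 * 1.01)) {
    stop("TPM columns must sum to <= 1e6 (1% tolerance)", call. = FALSE)
  }
  out <- t(vapply(gene_sets, function(genes) {
    missing <- setdiff(genes, rownames(tpm))
    if (length(missing)) {
      warning(sprintf("skipping %d unknown gene(s): %s", length(missing),
                      paste(utils::head(missing, 3), collapse = ", ")),
              call. = FALSE)
    }
    present <- intersect(genes, rownames(tpm))
    colSums(tpm[present, , drop = FALSE])
  }, numeric(ncol(tpm))))
  colnames(out) <- colnames(tpm)
  out
}
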