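#' Rarefy a count table to even depth
#'
#' Subsamples each sample (column) without replacement to exactly `depth`
#' reads. Samples with fewer reads than `depth` are dropped with a warning.
#' Subsampling is delegated to [vegan::rrarefy()] under a fixed seed.
#'
#' @param table An [abundance_table()] or taxon x sample count matrix.
#' @param depth Target reads per sample (> 0).
#' @param seed Integer seed making the subsample reproducible.
#' @return Object of the same kind as the input with every retained column
#'   summing exactly to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1) {
  counts <- as_count_matrix(table)
  stop_if_not_scalar_number(depth, "depth")
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  depth <- as.integer(depth)
  keep <- colSums(counts) >= depth
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) with fewer than %d reads",
                    sum(!keep), depth), call. = FALSE)
    counts <- counts[, keep, drop = FALSE]
  }
  if (ncol(counts) == 0L) stop("no samples at or above depth", call. = FALSE)
  rare <- withCallingHandlers(
    with_seed(seed, t(vegan::rrarefy(t(counts), depth))),
    warning = function(w) {
      # vegan advises about pre-transformed counts; our inputs are counts
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  dimnames(rare) <- dimnames(counts)
  if (inherits(table, "abundance_table")) {
    abundance_table(rare, table$taxonomy)
  } else {
    rare
  }
}

#' Convert counts to relative abundances
#'
#' Each column is divided by its sum; idempotent on already-relative input.
#'
#' @param table An [abundance_table()] or taxon x sample matrix with
#'   strictly positive column sums.
#' @return Same kind as the input, columns summing to 1.
#' @export
to_relative <- function(table) {
  counts <- as_count_matrix(table)
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    stop("degenerate sample: all-zero column(s) ",
         paste(colnames(counts)[cs <= 0], collapse = ", "), call. = FALSE)
  }
  rel <- sweep(counts, 2, cs, "/")
  if (inherits(table, "abundance_table")) abundance_table(rel, table$taxonomy)
  else rel
}

#' Aggregate a table to genus level
#'
#' Row-sums counts over the `genus` column of the taxonomy.
#'
#' @param table An [abundance_table()].
#' @return Genus x sample numeric matrix.
#' @export
aggregate_genus <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  rowsum(table$counts, group = table$taxonomy$genus)
}

#' Core-genus screening criteria
#'
#' Three predicates jointly define a core genus: *ubiquitous* (present in
#' more than `ubiquity_frac` of samples), *overall abundant* (by default,
#' mean relative abundance above `abundant_cutoff`; alternatively the top
#' `abundant_cutoff` quantile of genera by mean abundance), and *frequently
#' abundant* (abundance rank within the top `frequent_rank_quantile` of
#' genera in more than `frequent_sample_frac` of samples).
#'
#' @param ubiquity_frac Fraction of samples a genus must occur in (strictly
#'   more than), default 0.80.
#' @param abundant_mode `"mean_above"` (default) or `"top_quantile"`.
#' @param abundant_cutoff Mean-relative-abundance cutoff (default 0.001,
#'   i.e. 0.1%) for `"mean_above"`; top fraction for `"top_quantile"`.
#' @param frequent_rank_quantile Rank quantile a genus must reach within a
#'   sample to count as abundant there (default 0.80: not in the bottom
#'   20%).
#' @param frequent_sample_frac Fraction of samples in which the rank rule
#'   must hold (strictly more than), default 0.50.
#' @return A `core_criteria` list.
#' @export
core_criteria <- function(ubiquity_frac = 0.80,
                          abundant_mode = c("mean_above", "top_quantile"),
                          abundant_cutoff = 0.001,
                          frequent_rank_quantile = 0.80,
                          frequent_sample_frac = 0.50) {
  abundant_mode <- match.arg(abundant_mode)
  vals <- c(ubiquity_frac, abundant_cutoff, frequent_rank_quantile,
            frequent_sample_frac)
  if (any(vals <= 0) || any(vals > 1)) {
    stop("all criteria fractions must lie in (0, 1]", call. = FALSE)
  }
  structure(list(ubiquity_frac = ubiquity_frac,
                 abundant_mode = abundant_mode,
                 abundant_cutoff = abundant_cutoff,
                 frequent_rank_quantile = frequent_rank_quantile,
                 frequent_sample_frac = frequent_sample_frac),
            class = "core_criteria")
}

#' Screen for core genera
#'
#' Applies the three [core_criteria()] predicates to a genus-level relative
#' abundance matrix and returns the per-criterion truth table alongside the
#' set of genera passing all three.
#'
#' @param genus_rel Genus x sample relative abundance matrix (e.g.
#'   `to_relative(aggregate_genus(table))`).
#' @param criteria A [core_criteria()] object.
#' @return List with `core` (character vector of core genera) and `flags`
#'   (data.frame: genus, ubiquitous, abundant, frequent, core).
#' @export
screen_core_genera <- function(genus_rel, criteria = core_criteria()) {
  stopifnot(inherits(criteria, "core_criteria"))
  if (is.null(dim(genus_rel)) || nrow(genus_rel) == 0L) {
    return(list(core = character(0),
                flags = data.frame(genus = character(0),
                                   ubiquitous = logical(0),
                                   abundant = logical(0),
                                   frequent = logical(0),
                                   core = logical(0))))
  }
  n_samp <- ncol(genus_rel)
  ubiquitous <- rowMeans(genus_rel > 0) > criteria$ubiquity_frac
  mean_ab <- rowMeans(genus_rel)
  abundant <- if (criteria$abundant_mode == "mean_above") {
    mean_ab > criteria$abundant_cutoff
  } else {
    mean_ab >= stats::quantile(mean_ab, 1 - criteria$abundant_cutoff)
  }
  # per-sample rank fraction: 0 = most abundant genus in that sample
  rank_frac <- apply(genus_rel, 2, function(x) rank(-x, ties.method = "max")) /
    nrow(genus_rel)
  in_top <- rank_frac <= criteria$frequent_rank_quantile
  frequent <- rowMeans(in_top) > criteria$frequent_sample_frac
  core <- ubiquitous & abundant & frequent
  flags <- data.frame(genus = rownames(genus_rel),
                      ubiquitous = unname(ubiquitous),
                      abundant = unname(abundant),
                      frequent = unname(frequent),
                      core = unname(core),
                      stringsAsFactors = FALSE)
  list(core = rownames(genus_rel)[core], flags = flags)
}

#' Screen lineage members correlated with a guild marker
#'
#' Within a supplied lineage subset, selects taxa whose relative abundance
#' is Pearson-correlated with a per-sample marker series (e.g. comammox
#' amoA copies) at `r >= r_min` and `p <= p_max` (two-sided). This is the
#' correlation screen used to nominate potential-comammox taxa among
#' Nitrospira lineage members.
#'
#' @param rel Taxon x sample relative abundance matrix.
#' @param lineage_filter Character vector of candidate taxon ids (rows of
#'   `rel`).
#' @param marker Numeric vector, one value per sample.
#' @param r_min,p_max Selection thresholds.
#' @return List with `selected` taxon ids, `stats` (per-candidate r and p)
#'   and `group_abundance` (per-sample sum of the selected taxa, for
#'   downstream correlation with pH).
#' @export
screen_pc_taxa <- function(rel, lineage_filter, marker,
                           r_min = 0.5, p_max = 0.05) {
  stopifnot(is.matrix(rel), length(marker) == ncol(rel))
  if (stats::sd(marker) == 0) {
    stop("marker is constant: correlation undefined", call. = FALSE)
  }
  cand <- intersect(lineage_filter, rownames(rel))
  stats_df <- do.call(rbind, lapply(cand, function(tx) {
    x <- rel[tx, ]
    if (stats::sd(x) == 0) {
      data.frame(taxon_id = tx, r = NA_real_, p = NA_real_)
    } else {
      ct <- stats::cor.test(x, marker, method = "pearson")
      data.frame(taxon_id = tx, r = unname(ct$estimate), p = ct$p.value)
    }
  }))
  if (is.null(stats_df)) {
    stats_df <- data.frame(taxon_id = character(0), r = numeric(0),
                           p = numeric(0))
  }
  sel <- stats_df$taxon_id[!is.na(stats_df$r) &
                             stats_df$r >= r_min & stats_df$p <= p_max]
  group_ab <- if (length(sel)) colSums(rel[sel, , drop = FALSE]) else
    stats::setNames(rep(0, ncol(rel)), colnames(rel))
  list(selected = sel, stats = stats_df, group_abundance = group_ab)
}

#' Classify the dominant ammonia oxidizer per sample
#'
#' Each sample is labelled by the guild with the largest copy number; a
#' guild's share is its copies divided by the summed copies of all guilds.
#' Ties are broken alphabetically and flagged; all-zero samples are
#' unclassifiable.
#'
#' @param guild_copies data.frame or matrix of non-negative per-sample
#'   copies with one column per guild (a `sample_id` column, if present,
#'   is carried through).
#' @return data.frame with `dominant`, one `share_*` column per guild,
#'   `tie` and `unclassifiable` flags.
#' @export
classify_dominant_oxidizer <- function(guild_copies) {
  df <- as.data.frame(guild_copies, stringsAsFactors = FALSE)
  ids <- df$sample_id
  df$sample_id <- NULL
  mat <- as.matrix(df)
  if (any(mat < 0)) stop("guild copies must be non-negative", call. = FALSE)
  guilds <- sort(colnames(mat))
  mat <- mat[, guilds, drop = FALSE]
  tot <- rowSums(mat)
  shares <- mat / ifelse(tot == 0, NA_real_, tot)
  winner <- character(nrow(mat))
  tie <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    if (tot[i] == 0) {
      winner[i] <- NA_character_
      next
    }
    top <- guilds[mat[i, ] == max(mat[i, ])]
    tie[i] <- length(top) > 1L
    winner[i] <- top[1L]     # alphabetical winner on ties
  }
  out <- data.frame(dominant = winner, tie = tie,
                    unclassifiable = tot == 0,
                    stringsAsFactors = FALSE)
  for (g in guilds) out[[paste0("share_", g)]] <- unname(shares[, g])
  if (!is.null(ids)) out <- cbind(data.frame(sample_id = ids,
                                             stringsAsFactors = FALSE), out)
  out
}

#' Assign rrn copy numbers by best available taxonomic rank
#'
#' Each taxon is matched against a lookup of (name, rank, copies) entries:
#' species first, then genus, then family. Unmatched taxa are flagged (and
#' later excluded from the community mean copy number) rather than erred.
#'
#' @param taxonomy data.frame with `taxon_id` and lineage columns (any of
#'   `species`, `genus`, `family`).
#' @param lookup data.frame with columns `name`, `rank` (one of "species",
#'   "genus", "family") and `copies` (>= 1).
#' @return data.frame: `taxon_id`, `copies` (NA when unmatched),
#'   `provenance` ("species"/"genus"/"family"/"unmatched").
#' @export
assign_rrn <- function(taxonomy, lookup) {
  stopifnot(is.data.frame(lookup), nrow(lookup) > 0,
            all(c("name", "rank", "copies") %in% names(lookup)))
  if (any(lookup$copies < 1)) stop("rrn copies must be >= 1", call. = FALSE)
  copies <- rep(NA_real_, nrow(taxonomy))
  prov <- rep("unmatched", nrow(taxonomy))
  for (rk in c("species", "genus", "family")) {
    if (!rk %in% names(taxonomy)) next
    sub <- lookup[lookup$rank == rk, , drop = FALSE]
    if (!nrow(sub)) next
    hit <- match(taxonomy[[rk]], sub$name)
    use <- !is.na(hit) & is.na(copies)
    copies[use] <- sub$copies[hit[use]]
    prov[use] <- rk
  }
  n_un <- sum(prov == "unmatched")
  if (n_un > 0) {
    message(sprintf("assign_rrn: %d taxa unmatched at all ranks", n_un))
  }
  data.frame(taxon_id = taxonomy$taxon_id, copies = copies,
             provenance = prov, stringsAsFactors = FALSE)
}

#' Community mean rrn copy number per sample
#'
#' Abundance-weighted mean of per-taxon rrn copy numbers. By default the
#' weighting is renormalised over matched taxa, so unmatched taxa do not
#' bias the mean downward; `renormalize = FALSE` gives the raw weighted
#' sum over matched taxa instead.
#'
#' @param rel Taxon x sample relative abundance matrix.
#' @param rrn Output of [assign_rrn()], or a named numeric vector mapping
#'   taxon ids to copies.
#' @param renormalize Divide by the matched-abundance mass (default TRUE).
#' @param min_coverage Warn when matched taxa cover less than this fraction
#'   of a sample's abundance.
#' @return Named numeric vector of per-sample MCN values (NA where no
#'   matched taxon has abundance).
#' @export
compute_mcn <- function(rel, rrn, renormalize = TRUE, min_coverage = 0.5) {
  stopifnot(is.matrix(rel))
  if (is.data.frame(rrn)) {
    rrn <- stats::setNames(rrn$copies, rrn$taxon_id)
  }
  rrn <- rrn[!is.na(rrn)]
  matched <- intersect(rownames(rel), names(rrn))
  if (!length(matched)) {
    return(stats::setNames(rep(NA_real_, ncol(rel)), colnames(rel)))
  }
  sub <- rel[matched, , drop = FALSE]
  w <- rrn[matched]
  mass <- colSums(sub)
  cov_frac <- mass / colSums(rel)
  if (any(cov_frac < min_coverage)) {
    warning(sprintf("%d sample(s) have < %.0f%% of abundance matched to rrn",
                    sum(cov_frac < min_coverage), 100 * min_coverage),
            call. = FALSE)
  }
  num <- colSums(sub * w)
  mcn <- if (renormalize) num / ifelse(mass == 0, NA_real_, mass) else num
  mcn[mass == 0] <- NA_real_
  stats::setNames(mcn, colnames(rel))
}
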