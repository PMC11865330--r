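#' Write an abundance table to TSV
#'
#' One row per taxon: `taxon_id`, lineage columns, then one column per
#' sample.
#'
#' @param table An [abundance_table()].
#' @param file Output path.
#' @export
write_abundance_table <- function(table, file) {
  stopifnot(inherits(table, "abundance_table"))
  df <- cbind(table$taxonomy, as.data.frame(table$counts))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an abundance table from TSV
#'
#' Inverse of [write_abundance_table()]: non-numeric leading columns are
#' taken as taxonomy, the rest as samples.
#'
#' @param file Input path.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  is_num <- vapply(df, is.numeric, logical(1))
  tax <- df[!is_num]
  counts <- as.matrix(df[is_num])
  rownames(counts) <- tax$taxon_id
  abundance_table(counts, tax)
}

#' Write all simulated artifacts to a directory
#'
#' Emits the abundance table, metadata, rrn lookup, guild amoA copies,
#' genome features + abundance, SIP fractions (all TSV) and, when
#' jsonlite is available, the planted truth as JSON.
#'
#' @param sim A [simulate_study()] result.
#' @param outdir Output directory (created if missing).
#' @return The output directory, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "acidonet_simulation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_abundance_table(sim$table, file.path(outdir, "abundance.tsv"))
  tsv(sim$meta, "metadata.tsv")
  tsv(sim$truth$rrn_lookup, "rrn_lookup.tsv")
  tsv(sim$amoa, "guild_amoa.tsv")
  tsv(sim$genomes$features, "genome_features.tsv")
  tsv(cbind(genome_id = rownames(sim$genomes$abundance),
            as.data.frame(sim$genomes$abundance)), "genome_abundance.tsv")
  tsv(sim$sip, "sip_fractions.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- sim$truth
    truth$rrn_lookup <- NULL
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE)
  }
  invisible(outdir)
}
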