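counts_fixture <- function(seed = 1, n_taxa = 25, n_samples = 8,
                           depth = 3000) {
  set.seed(seed)
  m <- matrix(0L, n_taxa, n_samples,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("S", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    p <- stats::rlnorm(n_taxa)
    m[, j] <- stats::rmultinom(1, depth + 150L * j, p / sum(p))
  }
  m
}

test_that("rarefaction returns exact depths and hypergeometric means", {
  m <- counts_fixture()
  r <- rarefy(m, 1000, seed = 2)
  expect_true(all(colSums(r) == 1000))
  expect_true(all(r <= m))
  # column already exactly at depth is returned unchanged
  dmin <- min(colSums(m))
  jmin <- which.min(colSums(m))
  same <- rarefy(m, dmin, seed = 1)
  expect_equal(same[, jmin], m[, jmin])
  # short samples are dropped with a warning
  expect_warning(rarefy(m, max(colSums(m)), seed = 1), "fewer than")
  # expected count of a taxon ~ depth * proportion (hypergeometric mean)
  t1 <- vapply(1:200, function(s) {
    rarefy(m[, 1, drop = FALSE], 1000, seed = s)["t1", 1]
  }, numeric(1))
  expected <- 1000 * m["t1", 1] / sum(m[, 1])
  expect_lt(abs(mean(t1) - expected) / expected, 0.02)
  expect_error(rarefy(m, 0), "depth")
})

test_that("relative abundance conversion is exact and idempotent", {
  m <- counts_fixture(3)
  rel <- to_relative(m)
  expect_true(all(abs(colSums(rel) - 1) < 1e-9))
  expect_equal(to_relative(rel), rel)
  expect_equal(unname(to_relative(matrix(c(2, 2), 2))[, 1]), c(0.5, 0.5))
  bad <- m; bad[, 2] <- 0
  expect_error(to_relative(bad), "degenerate")
})

test_that("core-genus screening matches brute-force predicate evaluation", {
  crit <- core_criteria()
  for (s in 1:10) {
    set.seed(100 + s)
    g <- matrix(stats::rlnorm(30 * 12), 30, 12,
                dimnames = list(paste0("g", 1:30), paste0("S", 1:12)))
    g[sample(length(g), 80)] <- 0
    g <- sweep(g, 2, colSums(g), "/")
    got <- screen_core_genera(g, crit)$flags
    want <- oracle_core(g, crit)
    expect_equal(got$ubiquitous, want$ubiquitous)
    expect_equal(got$abundant, want$abundant)
    expect_equal(got$frequent, want$frequent)
    expect_equal(got$core, want$core)
  }
})

test_that("a single planted core genus is recovered exactly", {
  n_s <- 10
  ids <- c("core", "rare", "patchy", "tiny", paste0("fill", 1:6))
  g <- matrix(0, 10, n_s, dimnames = list(ids, paste0("S", 1:n_s)))
  g["core", ] <- 0.9                      # everywhere, abundant, top-ranked
  g["rare", 1:3] <- 0.2                   # fails ubiquity (3/10 samples)
  g["patchy", ] <- c(0.5, 0.5, rep(1e-6, 8))  # bottom-ranked in 8 samples
  g["tiny", ] <- 5e-4                     # present but below 0.1% mean
  for (i in 1:6) g[paste0("fill", i), ] <- (2 + i) * 1e-4  # below 0.1% too
  g <- sweep(g, 2, colSums(g), "/")
  res <- screen_core_genera(g, core_criteria())
  expect_identical(res$core, "core")
  flags <- res$flags
  expect_false(flags$ubiquitous[flags$genus == "rare"])
  expect_false(flags$abundant[flags$genus == "tiny"])
  expect_false(flags$frequent[flags$genus == "patchy"])
})

test_that("marker-correlated taxon screening selects and protects correctly", {
  set.seed(7)
  n <- 36
  marker <- stats::rlnorm(n)
  rel <- rbind(copy = marker / sum(marker),
               indep = stats::runif(n),
               other = stats::runif(n))
  colnames(rel) <- paste0("S", 1:n)
  res <- screen_pc_taxa(rel, c("copy", "indep"), marker, r_min = 0.5)
  expect_true("copy" %in% res$selected)
  expect_equal(res$stats$r[res$stats$taxon_id == "copy"], 1, tolerance = 1e-9)
  expect_error(screen_pc_taxa(rel, "copy", rep(1, n)), "constant")
  # type-I control: an unrelated taxon passes p <= 0.05 (r_min 0) rarely
  hits <- vapply(1:100, function(s) {
    set.seed(200 + s)
    rel2 <- rbind(x = stats::runif(n))
    colnames(rel2) <- paste0("S", 1:n)
    length(screen_pc_taxa(rel2, "x", marker, r_min = 0, p_max = 0.05)$selected)
  }, numeric(1))
  expect_lte(mean(hits), 0.10)
})

test_that("planted comammox-like taxon is recovered by the marker screen", {
  hits <- vapply(1:20, function(s) {
    spec <- community_spec(seed = s)
    comm <- generate_community(spec, generate_metadata(spec))
    rel <- to_relative(comm$table$counts)
    k <- comm$truth$keystone_id
    set.seed(s)
    marker <- rel[k, ] * stats::rlnorm(ncol(rel), 0, 0.15)  # qPCR-style proxy
    lineage <- c(k, sample(setdiff(rownames(rel), k), 3))
    k %in% screen_pc_taxa(rel, lineage, marker, r_min = 0.5)$selected
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("dominant-oxidizer classification handles shares, ties and zeros", {
  g <- data.frame(AOA = c(10, 50, 0), AOB = c(10, 50, 0),
                  comammox = c(80, 0, 0))
  res <- classify_dominant_oxidizer(g)
  expect_identical(res$dominant[1], "comammox")
  expect_equal(res$share_comammox[1], 0.8)
  expect_identical(res$dominant[2], "AOA")   # alphabetical tie-break
  expect_true(res$tie[2])
  expect_true(res$unclassifiable[3])
  expect_true(is.na(res$dominant[3]))
  expect_equal(rowSums(res[1:2, c("share_AOA", "share_AOB",
                                  "share_comammox")]),
               c(1, 1), ignore_attr = TRUE)
})

test_that("comammox dominance frequency matches its planted level", {
  # base levels place the comammox/AOA crossover near pH 7.45, so about
  # 60% of the even pH grid is comammox-dominant by design
  fr <- vapply(1:20, function(s) {
    spec <- community_spec(seed = s)
    meta <- generate_metadata(spec)
    am <- generate_guild_amoa(meta, spec)
    mean(classify_dominant_oxidizer(am)$dominant == "comammox")
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.60), 0.10)
})

test_that("rrn assignment falls back through ranks and flags unmatched", {
  tax <- data.frame(taxon_id = c("a", "b", "c", "d"),
                    species = c("s1", NA, NA, NA),
                    genus = c("g1", "g2", NA, "gX"),
                    family = c("f1", "f2", "f3", "fX"),
                    stringsAsFactors = FALSE)
  lk <- data.frame(name = c("s1", "g1", "g2", "f3"),
                   rank = c("species", "genus", "genus", "family"),
                   copies = c(4, 2, 1, 6), stringsAsFactors = FALSE)
  res <- suppressMessages(assign_rrn(tax, lk))
  expect_equal(res$copies, c(4, 1, 6, NA))
  expect_equal(res$provenance, c("species", "genus", "family", "unmatched"))
  # all members of a single-operon genus get one copy
  spec <- community_spec(seed = 2)
  comm <- generate_community(spec, generate_metadata(spec))
  rr <- suppressMessages(assign_rrn(comm$table$taxonomy,
                                    comm$truth$rrn_lookup))
  nitro <- comm$table$taxonomy$genus == "Nitrospira"
  expect_true(all(rr$copies[nitro] == 1))
})

test_that("MCN is an abundance-weighted mean with sane bounds", {
  rel <- matrix(c(1, 0.5, 0.5), nrow = 3,
                dimnames = list(c("a", "b", "c"), "S1"))
  rel <- to_relative(rel)
  expect_equal(unname(compute_mcn(rel[1, , drop = FALSE],
                                  c(a = 1))), 1)
  rel2 <- matrix(c(0.5, 0.5), 2, dimnames = list(c("a", "b"), "S1"))
  expect_equal(unname(compute_mcn(rel2, c(a = 1, b = 3))), 2)
  # invariant: counts and relative abundances give identical MCN
  m <- counts_fixture(11)
  rrn <- stats::setNames(sample(1:7, nrow(m), replace = TRUE), rownames(m))
  expect_equal(compute_mcn(m, rrn), compute_mcn(to_relative(m), rrn))
  # renormalisation keeps MCN within the rrn range despite unmatched taxa
  rrn_part <- rrn[1:10]
  mcn <- suppressWarnings(compute_mcn(to_relative(m), rrn_part))
  expect_true(all(mcn >= min(rrn_part) & mcn <= max(rrn_part)))
})

test_that("MCN rises with pH in communities planted with low-rrn acid taxa", {
  rs <- vapply(1:15, function(s) {
    spec <- community_spec(seed = s)
    meta <- generate_metadata(spec)
    comm <- generate_community(spec, meta)
    rel <- to_relative(comm$table$counts)
    rr <- suppressMessages(assign_rrn(comm$table$taxonomy,
                                      comm$truth$rrn_lookup))
    stats::cor(compute_mcn(rel, rr), meta$ph)
  }, numeric(1))
  expect_true(all(rs > 0.2))
  expect_gt(mean(rs), 0.5)
})
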