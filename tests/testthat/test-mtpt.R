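# Plastid-derived segment (MTPT) detection and summaries.

mtpt_fixture <- function(seed = 501, n_sub = 0L, block_len = 500L) {
  set.seed(seed)
  plastid_seq <- rnd_dna(8000)
  block <- substr(plastid_seq, 2001, 2000 + block_len)
  if (n_sub > 0L) {
    ch <- strsplit(block, "")[[1L]]
    pos <- seq(50L, by = 100L, length.out = n_sub)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
    block <- paste(ch, collapse = "")
  }
  mito_seq <- paste0(rnd_dna(6000), block, rnd_dna(6000))
  list(mito = list(mt = circular_sequence("mt", mito_seq)),
       plastid = list(pt = circular_sequence("pt", plastid_seq)),
       m_start = 6001L, m_end = 6000L + block_len,
       p_start = 2001L, p_end = 2000L + block_len)
}

test_that("a verbatim plastid block is recovered at identity 1", {
  fx <- mtpt_fixture()
  hits <- find_homologous_segments(fx$mito, fx$plastid)
  expect_gte(nrow(hits), 1L)
  top <- hits[which.max(hits$aligned_length), ]
  expect_equal(top$identity, 1.0)
  expect_lte(top$m_start, fx$m_start)
  expect_gte(top$m_end, fx$m_end)
})

test_that("a slightly diverged block remains a single high-identity locus", {
  fx <- mtpt_fixture(502, n_sub = 2L)
  hits <- filter_hits(find_homologous_segments(fx$mito, fx$plastid))
  mg <- merge_and_summarize(hits, 12500, 8000)
  expect_equal(mg$summary$n_loci, 1L)
  expect_gt(mg$loci$identity_min, 0.99)
  expect_lt(mg$loci$identity_min, 1.0)
})

test_that("unrelated random genomes produce no filtered hits", {
  set.seed(503)
  mito <- list(mt = circular_sequence("mt", rnd_dna(12000)))
  plastid <- list(pt = circular_sequence("pt", rnd_dna(8000)))
  hits <- filter_hits(find_homologous_segments(mito, plastid))
  expect_equal(nrow(hits), 0L)
})

test_that("length and identity filters are inclusive and monotone", {
  h <- data.frame(plastid_id = "pt", p_start = 1L, p_end = 200L,
                  mito_id = "mt", m_start = 1L, m_end = 200L, strand = "+",
                  aligned_length = c(99L, 150L, 100L, 250L),
                  identity = c(0.95, 0.79, 0.80, 0.92),
                  evalue = 1e-10, bitscore = 100)
  kept <- filter_hits(h)
  expect_equal(kept$aligned_length, c(100L, 250L))   # 99 bp and 79% excluded
  # monotone in both thresholds
  for (ml in c(100, 150, 200)) for (mi in c(0.8, 0.9, 0.95)) {
    a <- filter_hits(h, ml, mi)
    b <- filter_hits(h, ml + 50, mi)
    c_ <- filter_hits(h, ml, min(1, mi + 0.05))
    expect_true(all(b$aligned_length %in% a$aligned_length))
    expect_true(all(c_$aligned_length %in% a$aligned_length))
  }
})

test_that("genome fractions reproduce the published arithmetic", {
  # one locus totalling 28,175 bp over the published genome lengths
  h <- data.frame(plastid_id = "pt", p_start = 1L, p_end = 28175L,
                  mito_id = "mt", m_start = 1001L, m_end = 29175L,
                  strand = "+", aligned_length = 28175L, identity = 0.95,
                  evalue = 0, bitscore = 1000)
  mg <- merge_and_summarize(h, mito_len = 182239 + 165055, plastid_len = 150604)
  expect_equal(mg$summary$total_length, 28175L)
  expect_equal(mg$summary$pct_of_mito, 8.11)
  expect_equal(mg$summary$pct_of_plastid, 18.71)
  expect_equal(genome_fraction(49955, 182239 + 165055), 14.38)
  # empty input
  mg0 <- merge_and_summarize(h[0, ], 1000, 1000)
  expect_equal(mg0$summary$n_loci, 0L)
  expect_equal(mg0$summary$pct_of_mito, 0)
})

test_that("overlapping and abutting hits merge; distant ones do not", {
  h <- data.frame(plastid_id = "pt", p_start = c(1, 151, 1000), p_end = c(200, 400, 1100),
                  mito_id = "mt", m_start = c(101L, 251L, 5001L),
                  m_end = c(300L, 500L, 5101L), strand = "+",
                  aligned_length = c(200L, 250L, 101L), identity = 0.9,
                  evalue = 0, bitscore = 10)
  mg <- merge_and_summarize(h, 10000, 2000)
  expect_equal(mg$summary$n_loci, 2L)
  expect_equal(mg$loci$locus_id, c("MTPT01", "MTPT02"))
  expect_equal(mg$loci$length, c(400L, 101L))
  expect_equal(mg$loci$n_hits, c(2L, 1L))
})

test_that("contained plastid genes are flagged intact or fragment", {
  h <- data.frame(plastid_id = "pt", p_start = 1000L, p_end = 2000L,
                  mito_id = "mt", m_start = 100L, m_end = 1100L, strand = "+",
                  aligned_length = 1001L, identity = 0.95, evalue = 0,
                  bitscore = 100)
  mg <- merge_and_summarize(h, 10000, 5000)
  feats <- data.frame(seq_id = "pt", feature_type = c("gene", "gene", "tRNA"),
                      start = c(1200L, 1800L, 3000L), end = c(1500L, 2300L, 3100L),
                      strand = "+", gene_name = c("inside", "straddle", "outside"),
                      exon_rank = NA_integer_, stringsAsFactors = FALSE)
  ann <- annotate_contained(mg, h, feats)
  expect_equal(nrow(ann), 2L)
  expect_true(ann$intact[ann$gene_name == "inside"])
  expect_false(ann$intact[ann$gene_name == "straddle"])
  expect_false("outside" %in% ann$gene_name)
})

test_that("planted insertions are recovered locus-for-locus with >=95% overlap", {
  sim <- make_genome(seed = 13)
  hits <- filter_hits(find_homologous_segments(sim$genome, sim$plastid))
  mito_len <- sum(vapply(sim$genome, function(x) x$length, 1L))
  mg <- merge_and_summarize(hits, mito_len, sim$plastid$plastid$length)
  truth <- sim$truth$mtpts
  expect_equal(mg$summary$n_loci, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    l <- mg$loci[mg$loci$mito_id == t$chrom, ]
    expect_equal(nrow(l), 1L)
    ov <- min(l$end, t$end) - max(l$start, t$start) + 1L
    expect_gte(ov / (t$end - t$start + 1L), 0.95)
  }
})
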