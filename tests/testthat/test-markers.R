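# Intron extraction, alignment, polymorphic sites and marker regions.

test_that("introns are the gaps between consecutive exon ranks", {
  toy <- toy_two_exon_gene("+")
  intr <- extract_introns(toy$genome, toy$features)
  expect_equal(nrow(intr), 1L)
  expect_equal(intr$intron_label, "toyi12")
  expect_equal(intr$sequence, toy$intron_plus)
  expect_equal(c(intr$start, intr$end), toy$intron_iv)
})

test_that("minus-strand genes yield coding-strand intron sequences", {
  toy <- toy_two_exon_gene("-")
  intr <- extract_introns(toy$genome, toy$features)
  expect_equal(nrow(intr), 1L)
  expect_equal(intr$intron_label, "toyi12")
  expect_equal(intr$sequence, rc_chr(toy$intron_plus))
})

test_that("single-exon genes yield no introns; bad annotations error", {
  toy <- toy_two_exon_gene("+")
  single <- toy$features[toy$features$exon_rank %in% 1L | is.na(toy$features$exon_rank), ]
  expect_equal(nrow(extract_introns(toy$genome, single)), 0L)
  overlapping <- toy$features
  overlapping$start[3] <- overlapping$end[2] - 5L   # exon2 overlaps exon1
  expect_error(extract_introns(toy$genome, overlapping),
               class = "annotation_error")
  trans <- toy$features
  trans$seq_id[3] <- "other"
  expect_message(out <- extract_introns(toy$genome, trans), "trans-spliced")
  expect_equal(nrow(out), 0L)
})

test_that("alignment handles identity, substitutions and a 65 bp deletion", {
  set.seed(701)
  base <- rnd_dna(800)
  same <- c(a = base, b = base, c = base)
  aln <- align_introns(same)
  expect_equal(length(unique(nchar(aln))), 1L)
  expect_false(any(grepl("-", unclass(aln))))
  # single substitution: gap-free, one polymorphic column
  mut <- base
  substr(mut, 400, 400) <- if (substr(base, 400, 400) == "A") "C" else "A"
  aln2 <- align_introns(c(a = base, b = mut, c = base))
  expect_false(any(grepl("-", unclass(aln2))))
  sites2 <- find_polymorphic_sites(aln2)
  expect_equal(nrow(sites2), 1L)
  expect_equal(sites2$site_type, "SNP")
  expect_equal(sites2$col_start, 400L)
  # 65 bp contiguous deletion: a single 65-column gap run in that row
  del <- paste0(substr(base, 1, 299), substr(base, 365, 800))
  aln3 <- align_introns(c(a = base, b = del, c = base))
  gaps <- gregexpr("-+", unclass(aln3)[["b"]])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 65L)
  expect_false(any(grepl("-", unclass(aln3)[["a"]])))
  sites3 <- find_polymorphic_sites(aln3)
  expect_equal(nrow(sites3), 1L)
  expect_equal(sites3$site_type, "indel")
  expect_equal(sites3$col_end - sites3$col_start + 1L, 65L)
  expect_equal(sites3$alleles[[1]][["b"]], "")
  # all rows preserve their input residues
  for (nm in names(aln3))
    expect_equal(gsub("-", "", unclass(aln3)[[nm]]),
                 c(a = base, b = del, c = base)[[nm]])
})

test_that("empty sequences are rejected", {
  expect_error(align_introns(c(a = "ACGT", b = "")), class = "input_error")
})

test_that("polymorphic sites record which species pairs they distinguish", {
  aln <- structure(c(a = "ACGTACGT", b = "ACCTACGT", c = "ACGTACGT"),
                   class = "intron_alignment")
  sites <- find_polymorphic_sites(aln)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$discriminates, "a|b;b|c")
  # identical rows: nothing
  aln0 <- structure(c(a = "ACGT", b = "ACGT"), class = "intron_alignment")
  expect_equal(nrow(find_polymorphic_sites(aln0)), 0L)
  # N is not polymorphic evidence
  alnN <- structure(c(a = "ANGT", b = "ACGT", c = "ACGT"),
                    class = "intron_alignment")
  expect_equal(nrow(find_polymorphic_sites(alnN)), 0L)
})

test_that("marker regions are flanked, clamped and grouped", {
  set.seed(702)
  base <- rnd_dna(2000)
  mut <- base
  substr(mut, 1000, 1000) <- if (substr(base, 1000, 1000) == "A") "C" else "A"
  aln <- align_introns(c(a = base, b = mut))
  sites <- find_polymorphic_sites(aln)
  reg <- build_marker_regions(sites, aln, flank = 300)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$length, 601L)                        # 300 + 1 + 300
  expect_equal(reg$sequence, substr(base, 700, 1300))
  # a site 50 bp from the start clamps at position 1
  mut2 <- base
  substr(mut2, 50, 50) <- if (substr(base, 50, 50) == "A") "C" else "A"
  aln2 <- align_introns(c(a = base, b = mut2))
  reg2 <- build_marker_regions(find_polymorphic_sites(aln2), aln2, flank = 300)
  expect_equal(reg2$start, 1L)
  expect_equal(reg2$end, 350L)
  # two SNPs 100 bp apart merge into one region containing both
  mut3 <- base
  for (p in c(900L, 1000L))
    substr(mut3, p, p) <- if (substr(base, p, p) == "A") "C" else "A"
  aln3 <- align_introns(c(a = base, b = mut3))
  sites3 <- find_polymorphic_sites(aln3)
  expect_equal(nrow(sites3), 2L)
  reg3 <- build_marker_regions(sites3, aln3, flank = 300)
  expect_equal(nrow(reg3), 1L)
  expect_equal(reg3$site_indices, "1,2")
  expect_equal(c(reg3$start, reg3$end), c(600L, 1300L))
})

test_that("planted trio divergence is recovered site for site", {
  sim <- make_genome(seed = 21)
  trio <- make_species_trio(sim$genome, sim$features, subs_per_intron = 4,
                            seed = 22)
  introns_by_sp <- Map(function(g, f) extract_introns(g, f),
                       trio$genomes, trio$features)
  labs <- unique(introns_by_sp[[1]]$intron_label)
  total_snp <- 0L; total_indel <- 0L
  for (lab in labs) {
    seqs <- vapply(introns_by_sp, function(d)
      d$sequence[d$intron_label == lab], "")
    aln <- align_introns(seqs)
    sites <- find_polymorphic_sites(aln, lab)
    t_sub <- sum(trio$truth$kind == "substitution" & trio$truth$intron_label == lab)
    t_del <- sum(trio$truth$kind == "deletion" & trio$truth$intron_label == lab)
    expect_equal(sum(sites$site_type == "SNP"), t_sub)
    expect_equal(sum(sites$site_type == "indel"), t_del)
    # the union of sites distinguishes all three species
    pairs <- unlist(strsplit(sites$discriminates, ";"))
    expect_setequal(unique(pairs), c("sp1|sp2", "sp1|sp3", "sp2|sp3"))
    total_snp <- total_snp + sum(sites$site_type == "SNP")
    total_indel <- total_indel + sum(sites$site_type == "indel")
  }
  expect_equal(total_snp, sum(trio$truth$kind == "substitution"))
  expect_equal(total_indel, 2L)   # one 4 bp and one 65 bp deletion
  # zero divergence gives zero sites
  seqs0 <- vapply(introns_by_sp[[1]]$sequence[1], identity, "")
  aln0 <- align_introns(c(sp1 = seqs0, sp2 = seqs0, sp3 = seqs0))
  expect_equal(nrow(find_polymorphic_sites(aln0)), 0L)
})
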