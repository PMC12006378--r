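# C-to-U RNA editing calling, effect annotation and summaries.

test_that("call thresholds are inclusive on both coverage and frequency", {
  cols <- pileup_columns(
    ref_id = "g", pos = 1:5, ref_base = c("C", "C", "A", "C", "C"),
    A = c(0L, 0L, 25L, 0L, 0L),
    C = c(2L, 9L, 0L, 40L, 18L),
    G = 0L,
    T = c(2L, 1L, 25L, 0L, 2L))
  called <- call_editing_sites(cols)
  # pos 1: depth 4 < 5 -> no; pos 2: freq 1/10 = 0.1 -> yes (inclusive);
  # pos 3: ref A -> no; pos 4: no T -> no; pos 5: 2/20 = 0.1 -> yes
  expect_equal(called$pos, c(2L, 5L))
  expect_equal(called$frequency, c(0.1, 0.1))
  # monotone in both thresholds
  expect_equal(nrow(call_editing_sites(cols, min_depth = 21)), 0L)
  expect_equal(nrow(call_editing_sites(cols, min_freq = 0.11)), 0L)
})

test_that("flanked references mark flanking sites as non-CDS", {
  cols <- pileup_columns("g", pos = c(50L, 150L, 420L), ref_base = "C",
                         C = 5L, T = 5L)
  called <- call_editing_sites(cols, flank = 100, cds_lengths = c(g = 300L))
  expect_equal(called$in_cds, c(FALSE, TRUE, FALSE))
  expect_equal(called$cds_pos, c(-50L, 50L, 320L))
})

test_that("codon effects cover stop-gain, start-gain, synonymous, nonsynonymous", {
  site <- function(pos) data.frame(gene = "g", ref_id = "g", pos = pos,
                                   cds_pos = pos, in_cds = TRUE, depth = 20L,
                                   t_count = 10L, frequency = 0.5,
                                   stringsAsFactors = FALSE)
  # CAA -> TAA (Gln -> stop) and CGA -> TGA (Arg -> stop)
  a <- annotate_effect(site(1L), c(g = "CAAGGG"))
  expect_equal(a$effect, "stop_gain")
  expect_equal(a$ref_codon, "CAA"); expect_equal(a$edited_codon, "TAA")
  b <- annotate_effect(site(1L), c(g = "CGAGGG"))
  expect_equal(b$effect, "stop_gain")
  expect_equal(b$edited_codon, "TGA")
  # ACG -> ATG at codon 1 is a start gain
  c_ <- annotate_effect(site(2L), c(g = "ACGGGG"))
  expect_equal(c_$effect, "start_gain")
  # ACG -> ATG at an internal codon is plain nonsynonymous (Thr -> Met)
  d <- annotate_effect(site(5L), c(g = "GGGACG"))
  expect_equal(d$effect, "nonsynonymous")
  # CCA -> CTA: Pro -> Leu
  e <- annotate_effect(site(2L), c(g = "CCAGGG"))
  expect_equal(e$effect, "nonsynonymous")
  expect_equal(e$aa_ref, "P"); expect_equal(e$aa_edit, "L")
  # GCC -> GCT: synonymous
  f <- annotate_effect(site(3L), c(g = "GCCGGG"))
  expect_equal(f$effect, "synonymous")
  expect_equal(f$codon_position, 3L)
  # coordinate and base sanity errors
  expect_error(annotate_effect(site(9L), c(g = "CAAGGG")),
               class = "coordinate_error")
  expect_error(annotate_effect(site(1L), c(g = "AAAGGG")),
               class = "coordinate_error")
  expect_error(annotate_effect(site(1L), c(g = "CAAGG")),
               class = "input_error")
})

test_that("annotated sites round-trip: re-translating the edited codon", {
  set.seed(601)
  cds <- c(g = random_dna(300))
  pos <- pick_editing_positions(cds[["g"]], 8)
  sites <- data.frame(gene = "g", ref_id = "g", pos = pos, cds_pos = pos,
                      in_cds = TRUE, depth = 30L, t_count = 15L,
                      frequency = 0.5, stringsAsFactors = FALSE)
  ann <- annotate_effect(sites, cds)
  for (i in seq_len(nrow(ann))) {
    expect_equal(substr(ann$ref_codon[i], ann$codon_position[i],
                        ann$codon_position[i]), "C")
    expect_equal(Biostrings::GENETIC_CODE[[ann$edited_codon[i]]], ann$aa_edit[i])
    # edited codon differs from the reference codon exactly at codon_position
    diff <- which(strsplit(ann$ref_codon[i], "")[[1]] !=
                    strsplit(ann$edited_codon[i], "")[[1]])
    expect_equal(diff, ann$codon_position[i])
  }
})

test_that("DNA variants are called and excluded from editing sites", {
  cols <- pileup_columns("g", pos = 1:3, ref_base = c("C", "G", "C"),
                         A = c(0L, 2L, 0L), C = c(20L, 0L, 25L),
                         G = c(0L, 27L, 0L), T = c(10L, 0L, 0L))
  vars <- call_dna_variants(cols)
  expect_equal(vars$pos, 1L)
  expect_equal(vars$alt_base, "T")
  sites <- data.frame(gene = "g", ref_id = "g", pos = c(1L, 3L),
                      cds_pos = c(1L, 3L), in_cds = TRUE, depth = 30L,
                      t_count = 10L, frequency = 0.33, stringsAsFactors = FALSE)
  expect_message(kept <- exclude_dna_variants(sites, vars), "removed")
  expect_equal(kept$pos, 3L)
  # disjoint and empty variant sets leave sites unchanged
  expect_equal(nrow(exclude_dna_variants(sites, vars[0, ])), 2L)
})

test_that("summary arithmetic reproduces published percentages", {
  # reconstruct a 457-site composition: 46 synonymous, 2 stop-gains,
  # 409 other nonsynonymous; 151/258/48 sites at codon positions 1/2/3;
  # 133 Pro->Leu, 89 Ser->Leu, 65 Ser->Phe
  n <- 457
  eff <- c(rep("synonymous", 46), rep("stop_gain", 2), rep("nonsynonymous", 409))
  aa_ref <- c(rep("A", 46), "Q", "R", rep("P", 133), rep("S", 89 + 65),
              rep("H", 409 - 133 - 89 - 65))
  aa_edit <- c(rep("A", 46), "*", "*", rep("L", 133 + 89), rep("F", 65),
               rep("Y", 409 - 133 - 89 - 65))
  cpos <- rep(1:3, times = c(151, 258, 48))
  sites <- data.frame(gene = "g", codon_position = cpos, effect = eff,
                      aa_ref = aa_ref, aa_edit = aa_edit,
                      stringsAsFactors = FALSE)
  s <- summarize_editing(sites)
  expect_equal(s$n_total, 457L)
  expect_equal(s$n_synonymous + s$n_nonsynonymous + s$n_stop_gain +
                 s$n_start_gain, s$n_total)
  expect_equal(s$pct_synonymous, 10.07)                      # 46/457
  expect_equal(s$by_codon_position$pct[2], 56.46)            # 258/457
  chg <- s$by_aa_change
  expect_equal(chg$count[chg$change == "Pro->Leu"], 133L)
  expect_equal(chg$pct[chg$change == "Pro->Leu"], 29.10)     # 133/457
  expect_equal(chg$count[chg$change == "Ser->Leu"], 89L)
  # empty input gives an all-zero summary
  s0 <- summarize_editing(sites[0, ])
  expect_equal(s0$n_total, 0L)
  expect_equal(s0$pct_synonymous, 0)
})

test_that("planted editing sites are recovered from simulated pileups", {
  set.seed(602)
  cds <- c(cox2 = random_dna(300), nad9 = random_dna(240))
  p1 <- pick_editing_positions(cds[["cox2"]], 3)
  p2 <- pick_editing_positions(cds[["nad9"]], 2)
  truth <- data.frame(gene = c(rep("cox2", 3), rep("nad9", 2)),
                      pos = c(p1, p2), frequency = c(0.5, 0.25, 0.8, 0.15, 0.6))
  pp <- simulate_pileups(cds, truth, depth = 40, seed = 603)
  called <- call_editing_sites(pp$rna)
  expect_equal(nrow(called), nrow(truth))
  expect_setequal(paste(called$gene, called$pos),
                  paste(truth$gene, truth$pos))
  # estimated frequencies within 3 binomial standard deviations of truth
  m <- match(paste(called$gene, called$pos), paste(truth$gene, truth$pos))
  p <- truth$frequency[m]
  expect_true(all(abs(called$frequency - p) <= 3 * sqrt(p * (1 - p) / 40) + 1e-9))
})

test_that("a SAM pileup feeds the caller end to end", {
  ref <- c(gx = "ACGTACGTCCGGTTAA")
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- c("ACGTACGTCCGGTTAA", "ACGTACGTTCGGTTAA", "ACGTACGTTCGGTTAA")
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:gx\tLN:%d", nchar(ref)),
             vapply(seq_along(reads), function(i)
               paste(sprintf("r%d", i), 0, "gx", 1, 60,
                     paste0(nchar(reads[i]), "M"), "*", 0, 0,
                     reads[i], strrep("I", nchar(reads[i])), sep = "\t"), ""))
  writeLines(lines, sam)
  cols <- pileup_from_sam(sam, ref)
  c9 <- cols[cols$pos == 9L, ]
  expect_equal(c9$C, 1L)
  expect_equal(c9$T, 2L)
  called <- call_editing_sites(cols, min_depth = 3)
  expect_equal(called$pos, 9L)
  expect_equal(called$frequency, 2 / 3)
})
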