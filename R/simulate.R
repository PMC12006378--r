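# Synthetic-data generator: desk-scale two-chromosome circular genomes with
# planted dispersed repeats, plastid-derived insertions and multi-exon gene
# models; long-read mixtures over recombination configurations; RNA/DNA
# pileups with planted editing sites and SNPs; and a diverged species trio
# for intron-marker discovery. Every planted feature is returned in a truth
# table and every function is fully reproducible from its seed.
#
# Defaults emulate the study system scaled to desk size: two circular
# chromosomes of 40 kb + 30 kb (about 1/5 of the real assembly), background
# GC content 44%, and three cross-chromosome recombinogenic repeats -- a
# long direct one, a mid-size inverted one and a short direct one --
# mirroring the 13.3 kb / 1.9 kb / 123 bp trio of the real genome.

#' Random DNA string at a given GC content
#'
#' @param n length in bp.
#' @param gc GC fraction (default 0.44, matching the study genome).
#' @return residue string.
#' @export
random_dna <- function(n, gc = 0.44) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# mutate a string to approximately the requested identity (substitutions at
# distinct positions, never recreating the original base)
.mutate_to_identity <- function(s, identity) {
  n <- nchar(s)
  k <- round((1 - identity) * n)
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "")[[1L]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Default planted-repeat specification
#'
#' Three cross-chromosome repeat pairs: 2,600 bp direct, 1,000 bp inverted
#' and 150 bp direct (the study's recombinogenic trio scaled to the desk
#' genome).
#'
#' @return list of per-repeat specs (`length`, `orientation`).
#' @export
default_repeat_specs <- function() {
  list(list(length = 2600L, orientation = "direct"),
       list(length = 1000L, orientation = "inverted"),
       list(length = 150L, orientation = "direct"))
}

#' Default planted-MTPT specification
#'
#' Two plastid-derived insertions: 800 bp at 98% identity and 1,200 bp at
#' 100% identity.
#'
#' @return list of per-insertion specs (`length`, `identity`).
#' @export
default_mtpt_specs <- function() {
  list(list(length = 800L, identity = 0.98),
       list(length = 1200L, identity = 1.0))
}

#' Generate a synthetic two-chromosome mitogenome with known ground truth
#'
#' Builds circular chromosomes of the requested lengths containing planted
#' dispersed repeat pairs (copy 1 on chromosome 1, copy 2 on chromosome 2),
#' plastid blocks copied from a generated plastome at the requested
#' identity, and multi-exon gene models (exons 300 bp, CDS a multiple of
#' 3), all separated by random spacer sequence. Fully reproducible from
#' `seed`.
#'
#' @param chrom_lengths two chromosome lengths in bp (default 40,000 and
#'   30,000).
#' @param repeat_specs list of repeat specs (see [default_repeat_specs()]).
#' @param mtpt_specs list of MTPT specs (see [default_mtpt_specs()]).
#' @param plastid_length plastome length in bp (default 20,000).
#' @param gc background GC content (default 0.44).
#' @param seed integer seed.
#' @return list with `genome` (two `CircularSequence`), `plastid` (one),
#'   `features`, `plastid_features` (feature data.frames) and `truth`
#'   (list of data.frames `repeats`, `mtpts`, `genes`).
#' @export
make_genome <- function(chrom_lengths = c(40000L, 30000L),
                        repeat_specs = default_repeat_specs(),
                        mtpt_specs = default_mtpt_specs(),
                        plastid_length = 20000L, gc = 0.44, seed = 1L) {
  set.seed(seed)
  stopifnot(length(chrom_lengths) == 2L)
  plastid_seq <- random_dna(plastid_length, gc)

  rep_seqs <- lapply(repeat_specs, function(r) random_dna(r$length, gc))

  # plastid source blocks, non-overlapping, deterministic placement
  p_off <- 1500L
  mtpt_blocks <- list()
  for (i in seq_along(mtpt_specs)) {
    m <- mtpt_specs[[i]]
    src_start <- p_off
    src_end <- src_start + m$length - 1L
    if (src_end > plastid_length) stop_input("plastid too short for MTPT specs")
    block <- substr(plastid_seq, src_start, src_end)
    mtpt_blocks[[i]] <- list(p_start = src_start, p_end = src_end,
                             identity = m$identity,
                             seq = .mutate_to_identity(block, m$identity))
    p_off <- src_end + 2000L
  }

  # plastid annotations: one gene inside each MTPT source block, one outside
  pf <- list()
  for (i in seq_along(mtpt_blocks)) {
    b <- mtpt_blocks[[i]]
    if (b$p_end - b$p_start + 1L >= 400L) {
      pf[[length(pf) + 1L]] <- data.frame(
        seq_id = "plastid", feature_type = "gene",
        start = b$p_start + 100L, end = b$p_start + 399L, strand = "+",
        gene_name = paste0("pgene", i), exon_rank = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  # a gene straddling the first block's right edge (fragment, intact = FALSE)
  b1 <- mtpt_blocks[[1L]]
  pf[[length(pf) + 1L]] <- data.frame(
    seq_id = "plastid", feature_type = "gene",
    start = b1$p_end - 149L, end = b1$p_end + 150L, strand = "+",
    gene_name = "pgene_frag", exon_rank = NA_integer_, stringsAsFactors = FALSE)
  # and one far from any block
  pf[[length(pf) + 1L]] <- data.frame(
    seq_id = "plastid", feature_type = "gene",
    start = plastid_length - 600L, end = plastid_length - 301L, strand = "+",
    gene_name = "pgene_out", exon_rank = NA_integer_, stringsAsFactors = FALSE)
  plastid_features <- do.call(rbind, pf)

  # gene models: blocks of exons/introns as (type, length) runs
  gene_models <- list(
    list(name = "nad9", strand = "+", exons = c(300L, 300L, 300L),
         introns = c(700L, 900L)),
    list(name = "cox2", strand = "-", exons = c(300L, 300L),
         introns = c(800L)),
    list(name = "atp1", strand = "+", exons = c(900L), introns = integer()))

  build_gene_block <- function(gm) {
    n_ex <- length(gm$exons)
    pieces <- character(2L * n_ex - 1L)
    kinds <- character(2L * n_ex - 1L)
    for (i in seq_len(n_ex)) {
      pieces[2L * i - 1L] <- random_dna(gm$exons[i], gc)
      kinds[2L * i - 1L] <- "exon"
      if (i < n_ex) {
        pieces[2L * i] <- random_dna(gm$introns[i], gc)
        kinds[2L * i] <- "intron"
      }
    }
    list(seq = paste(pieces, collapse = ""), pieces = pieces, kinds = kinds, gm = gm)
  }

  # chromosome layouts: alternating random spacers and planted blocks
  blocks1 <- list(list(kind = "spacer", len = 3000L))
  blocks2 <- list(list(kind = "spacer", len = 2500L))
  gb <- lapply(gene_models, build_gene_block)
  add <- function(lst, kind, seq = NULL, len = NULL, payload = NULL) {
    c(lst, list(list(kind = kind, seq = seq,
                     len = if (is.null(len)) nchar(seq) else len,
                     payload = payload)))
  }
  # chromosome 1: R1c1, gene1, R2c1, MTPT1, gene2, R3c1
  blocks1 <- add(blocks1, "repeat", rep_seqs[[1L]], payload = list(rep = 1L, copy = 1L))
  blocks1 <- c(blocks1, list(list(kind = "spacer", len = 3000L)))
  blocks1 <- add(blocks1, "gene", gb[[1L]]$seq, payload = gb[[1L]])
  blocks1 <- c(blocks1, list(list(kind = "spacer", len = 2500L)))
  blocks1 <- add(blocks1, "repeat", rep_seqs[[2L]], payload = list(rep = 2L, copy = 1L))
  blocks1 <- c(blocks1, list(list(kind = "spacer", len = 3000L)))
  blocks1 <- add(blocks1, "mtpt", mtpt_blocks[[1L]]$seq, payload = list(mtpt = 1L))
  blocks1 <- c(blocks1, list(list(kind = "spacer", len = 2500L)))
  blocks1 <- add(blocks1, "gene", gb[[2L]]$seq, payload = gb[[2L]])
  blocks1 <- c(blocks1, list(list(kind = "spacer", len = 2000L)))
  blocks1 <- add(blocks1, "repeat", rep_seqs[[3L]], payload = list(rep = 3L, copy = 1L))
  # chromosome 2: R1c2, MTPT2, R2c2 (inverted -> rc), gene3, R3c2
  blocks2 <- add(blocks2, "repeat", rep_seqs[[1L]],
                 payload = list(rep = 1L, copy = 2L))
  blocks2 <- c(blocks2, list(list(kind = "spacer", len = 3000L)))
  blocks2 <- add(blocks2, "mtpt", mtpt_blocks[[2L]]$seq, payload = list(mtpt = 2L))
  blocks2 <- c(blocks2, list(list(kind = "spacer", len = 3000L)))
  r2seq <- if (repeat_specs[[2L]]$orientation == "inverted")
    reverse_complement(rep_seqs[[2L]]) else rep_seqs[[2L]]
  blocks2 <- add(blocks2, "repeat", r2seq, payload = list(rep = 2L, copy = 2L))
  blocks2 <- c(blocks2, list(list(kind = "spacer", len = 2500L)))
  blocks2 <- add(blocks2, "gene", gb[[3L]]$seq, payload = gb[[3L]])
  blocks2 <- c(blocks2, list(list(kind = "spacer", len = 2000L)))
  r3seq <- if (repeat_specs[[3L]]$orientation == "inverted")
    reverse_complement(rep_seqs[[3L]]) else rep_seqs[[3L]]
  blocks2 <- add(blocks2, "repeat", r3seq, payload = list(rep = 3L, copy = 2L))

  finalize <- function(blocks, target_len, chrom_id) {
    used <- sum(vapply(blocks, function(b) as.integer(b$len), 1L))
    if (used >= target_len) stop_input("chromosome layout exceeds %d bp", target_len)
    blocks <- c(blocks, list(list(kind = "spacer", len = target_len - used)))
    pos <- 1L
    seq_parts <- character(length(blocks))
    placed <- list()
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      s <- if (b$kind == "spacer") random_dna(b$len, gc) else b$seq
      seq_parts[i] <- s
      placed[[i]] <- list(kind = b$kind, start = pos, end = pos + nchar(s) - 1L,
                          payload = b$payload %||% NULL)
      pos <- pos + nchar(s)
    }
    list(seq = paste(seq_parts, collapse = ""), placed = placed,
         chrom_id = chrom_id)
  }
  ch1 <- finalize(blocks1, chrom_lengths[1L], "chr1")
  ch2 <- finalize(blocks2, chrom_lengths[2L], "chr2")

  # truth tables and feature table from placements
  truth_repeats <- list(); truth_mtpts <- list(); features <- list()
  for (ch in list(ch1, ch2)) {
    for (p in ch$placed) {
      if (p$kind == "repeat") {
        r <- p$payload
        truth_repeats[[length(truth_repeats) + 1L]] <- data.frame(
          rep = r$rep, copy = r$copy, chrom = ch$chrom_id,
          start = p$start, end = p$end,
          orientation = repeat_specs[[r$rep]]$orientation,
          length = repeat_specs[[r$rep]]$length, stringsAsFactors = FALSE)
      } else if (p$kind == "mtpt") {
        m <- p$payload$mtpt
        truth_mtpts[[length(truth_mtpts) + 1L]] <- data.frame(
          mtpt = m, chrom = ch$chrom_id, start = p$start, end = p$end,
          p_start = mtpt_blocks[[m]]$p_start, p_end = mtpt_blocks[[m]]$p_end,
          identity = mtpt_blocks[[m]]$identity, stringsAsFactors = FALSE)
      } else if (p$kind == "gene") {
        gmb <- p$payload
        gm <- gmb$gm
        lens <- nchar(gmb$pieces)
        offs <- cumsum(c(0L, lens[-length(lens)]))
        n_ex <- length(gm$exons)
        exon_iv <- list()
        for (i in seq_along(gmb$pieces)) {
          if (gmb$kinds[i] != "exon") next
          exon_iv[[length(exon_iv) + 1L]] <-
            c(p$start + offs[i], p$start + offs[i] + lens[i] - 1L)
        }
        # exon ranks follow the coding direction
        ranks <- if (gm$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
        features[[length(features) + 1L]] <- data.frame(
          seq_id = ch$chrom_id, feature_type = "gene",
          start = p$start, end = p$end, strand = gm$strand,
          gene_name = gm$name, exon_rank = NA_integer_, stringsAsFactors = FALSE)
        for (i in seq_along(exon_iv)) {
          features[[length(features) + 1L]] <- data.frame(
            seq_id = ch$chrom_id, feature_type = "exon",
            start = exon_iv[[i]][1L], end = exon_iv[[i]][2L], strand = gm$strand,
            gene_name = gm$name, exon_rank = ranks[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(genome = list(chr1 = circular_sequence("chr1", ch1$seq),
                     chr2 = circular_sequence("chr2", ch2$seq)),
       plastid = list(plastid = circular_sequence("plastid", plastid_seq)),
       features = do.call(rbind, features),
       plastid_features = plastid_features,
       truth = list(repeats = do.call(rbind, truth_repeats),
                    mtpts = do.call(rbind, truth_mtpts)))
}

# apply substitutions and small indels to a string at the given rates
.mutate_read <- function(s, error_rate) {
  if (error_rate <= 0) return(s)
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  sub_pos <- which(stats::runif(n) < error_rate)
  for (p in sub_pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  indel_rate <- error_rate / 8       # insertions and deletions each at 1/8,
  del_pos <- stats::runif(n) < indel_rate  # jointly 1/4 of the substitution rate
  ins_pos <- stats::runif(n) < indel_rate
  if (any(del_pos) || any(ins_pos)) {
    out <- character(0L)
    for (i in seq_len(n)) {
      if (!del_pos[i]) out <- c(out, ch[i])
      if (ins_pos[i]) out <- c(out, sample(c("A", "C", "G", "T"), 1L))
    }
    ch <- out
  }
  paste(ch, collapse = "")
}

#' Simulate long reads from a mixture of template molecules
#'
#' Each read picks a template by the mixture proportions, a start uniform
#' on the molecule (wrapping if `circular`), a length from a normal
#' distribution (floored at 200 bp), and per-base errors: uniform
#' substitutions plus insertions/deletions at jointly one quarter of the
#' substitution rate -- a crude long-read proxy adequate for anchor-based
#' spanning classification.
#'
#' @param templates named character vector of template sequences (e.g. the
#'   `sequences` of a `ConfigurationSet`).
#' @param n number of reads.
#' @param mixture named proportions over templates (must sum to 1).
#' @param mean_len,sd_len read length distribution (default 2000 +- 300).
#' @param error_rate per-base substitution rate (default 0.05).
#' @param circular treat templates as circular (default FALSE: linear
#'   references, reads truncate at the ends).
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `template`, `start`, `length`).
#' @export
simulate_long_reads <- function(templates, n, mixture,
                                mean_len = 2000, sd_len = 300,
                                error_rate = 0.05, circular = FALSE,
                                seed = 1L) {
  set.seed(seed)
  stopifnot(abs(sum(mixture) - 1) < 1e-9,
            all(names(mixture) %in% names(templates)))
  if (n == 0L) {
    return(list(reads = character(),
                truth = data.frame(read_id = character(), template = character(),
                                   start = integer(), length = integer(),
                                   stringsAsFactors = FALSE)))
  }
  picks <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  reads <- character(n); truth <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- templates[[picks[i]]]
    L <- nchar(tmpl)
    len <- max(200L, as.integer(round(stats::rnorm(1, mean_len, sd_len))))
    start <- sample.int(L, 1L)
    raw <- if (circular) circ_substr(tmpl, start, min(len, L))
           else substr(tmpl, start, min(L, start + len - 1L))
    reads[i] <- .mutate_read(raw, error_rate)
    truth[[i]] <- data.frame(read_id = sprintf("read%05d", i),
                             template = picks[i], start = start,
                             length = nchar(raw), stringsAsFactors = FALSE)
  }
  names(reads) <- sprintf("read%05d", seq_len(n))
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Pick C positions in a CDS suitable for planting editing sites
#'
#' @param cds CDS sequence.
#' @param n number of positions.
#' @param min_gap minimum spacing between picked positions (default 9 bp).
#' @return integer vector of 1-based CDS positions with reference base C.
#' @export
pick_editing_positions <- function(cds, n, min_gap = 9L) {
  cpos <- which(strsplit(cds, "")[[1L]] == "C")
  picked <- integer()
  for (p in cpos) {
    if (!length(picked) || min(abs(picked - p)) > min_gap) picked <- c(picked, p)
    if (length(picked) == n) break
  }
  if (length(picked) < n) stop_input("not enough C positions in CDS")
  picked
}

#' Simulate RNA and DNA pileups with planted editing sites and SNPs
#'
#' RNA pileups carry binomially sampled T counts at the planted editing
#' sites (reference base must be C) and uniform background error
#' elsewhere; DNA pileups carry the planted SNP alleles at their planted
#' frequencies and the same background error.
#'
#' @param cds_seqs named character vector gene -> CDS (or CDS+flank)
#'   sequence.
#' @param editing_truth data.frame `gene`, `pos`, `frequency` (positions on
#'   the reference used for the pileup).
#' @param snp_truth data.frame `gene`, `pos`, `alt`, `frequency`.
#' @param depth per-position coverage (default 30).
#' @param error background per-base error rate (default 0.005, i.e. <= 1%).
#' @param seed integer seed.
#' @return list `rna`, `dna` (pileup data.frames), `truth`.
#' @export
simulate_pileups <- function(cds_seqs, editing_truth = NULL, snp_truth = NULL,
                             depth = 30L, error = 0.005, seed = 1L) {
  set.seed(seed)
  empty_truth <- data.frame(gene = character(), pos = integer(),
                            frequency = numeric(), stringsAsFactors = FALSE)
  editing_truth <- editing_truth %||% empty_truth
  snp_truth <- snp_truth %||% cbind(empty_truth[0, ], alt = character())
  bases <- c("A", "C", "G", "T")
  one_genome <- function(planted, kind) {
    rows <- list()
    for (g in names(cds_seqs)) {
      ch <- strsplit(cds_seqs[[g]], "")[[1L]]
      n <- length(ch)
      cnt <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, bases))
      # background: each read-base errs with prob `error`, uniformly to the
      # three non-reference bases
      err <- stats::rbinom(n, depth, error)
      for (i in seq_len(n)) {
        cnt[i, ch[i]] <- depth - err[i]
        if (err[i] > 0L) {
          alt <- sample(setdiff(bases, ch[i]), err[i], replace = TRUE)
          for (a in alt) cnt[i, a] <- cnt[i, a] + 1L
        }
      }
      pl <- planted[planted$gene == g, , drop = FALSE]
      for (j in seq_len(nrow(pl))) {
        p <- pl$pos[j]
        if (kind == "rna" && ch[p] != "C")
          stop_input("planted editing site %s:%d is not a C", g, p)
        target <- if (kind == "rna") "T" else pl$alt[j]
        k <- stats::rbinom(1L, depth, pl$frequency[j])
        cnt[p, ] <- 0L
        cnt[p, ch[p]] <- depth - k
        cnt[p, target] <- cnt[p, target] + k
      }
      rows[[length(rows) + 1L]] <- pileup_columns(
        g, seq_len(n), ch, A = cnt[, "A"], C = cnt[, "C"],
        G = cnt[, "G"], T = cnt[, "T"])
    }
    do.call(rbind, rows)
  }
  list(rna = one_genome(editing_truth, "rna"),
       dna = one_genome(snp_truth, "dna"),
       truth = list(editing = editing_truth, snp = snp_truth))
}

#' Derive a diverged species trio from a base genome
#'
#' Species 1 is the base genome unchanged. Species 2 and 3 receive planted
#' substitutions and indels inside intron sequences only (exons are held
#' constant); by default species 3 carries one 65 bp deletion in the first
#' intron of the first multi-intron gene, emulating the large diagnostic
#' indel seen between real congeners. Edits keep >= 10 bp clear of intron
#' boundaries and of each other.
#'
#' @param genome named list of `CircularSequence` (the base species).
#' @param features feature table of the base species.
#' @param subs_per_intron substitutions planted per intron per derived
#'   species (default 5).
#' @param big_indel_len length of the single large deletion planted in
#'   species 3 (default 65).
#' @param seed integer seed.
#' @param species_names labels (default sp1/sp2/sp3).
#' @return list with `genomes` (per-species genome lists), `features`
#'   (per-species feature tables, coordinates shifted for indels) and
#'   `truth` (data.frame `species`, `intron_label`, `kind`, `intron_pos`,
#'   `length`).
#' @export
make_species_trio <- function(genome, features, subs_per_intron = 5L,
                              big_indel_len = 65L, seed = 1L,
                              species_names = c("sp1", "sp2", "sp3")) {
  set.seed(seed)
  introns <- extract_introns(genome, features)
  if (!nrow(introns)) stop_input("base genome has no introns")
  truth <- list()
  # plan all edits up front so planted features are recoverable one-for-one:
  # substitution positions are disjoint across the two derived species (and
  # mutually non-adjacent), and each deletion avoids every planted
  # substitution of either species in its intron
  margin <- 12L
  plan <- vector("list", nrow(introns))
  for (t in seq_len(nrow(introns))) {
    ilen <- introns$end[t] - introns$start[t] + 1L
    usable <- (margin + 1L):(ilen - margin)
    repeat {
      pool <- sort(sample(usable, 2L * subs_per_intron))
      if (min(diff(pool)) > 2L) break
    }
    pick <- sample(seq_along(pool), subs_per_intron)
    plan[[t]] <- list(sp2 = pool[pick], sp3 = pool[-pick], all = pool)
  }
  # species 2: substitutions plus one small (4 bp) deletion in the last intron
  # species 3: substitutions plus one big deletion in the first intron
  out_genomes <- list(); out_features <- list()
  out_genomes[[species_names[1L]]] <- genome
  out_features[[species_names[1L]]] <- features
  for (sp_i in 2:3) {
    sp <- species_names[sp_i]
    g <- lapply(genome, function(x) x$residues)
    f <- features
    del_intron <- if (sp_i == 2L) nrow(introns) else 1L
    del_len <- if (sp_i == 2L) 4L else big_indel_len
    ord <- order(match(introns$seq_id, names(g)), -introns$start)
    for (t in ord) {
      intr <- introns[t, ]
      s <- g[[intr$seq_id]]
      iseq <- substr(s, intr$start, intr$end)
      ilen <- nchar(iseq)
      subpos <- plan[[t]][[if (sp_i == 2L) "sp2" else "sp3"]]
      avoid <- plan[[t]]$all
      ch <- strsplit(iseq, "")[[1L]]
      for (p in subpos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        ip <- if (intr$strand == "+") p else ilen - p + 1L
        truth[[length(truth) + 1L]] <- data.frame(
          species = sp, intron_label = intr$intron_label, kind = "substitution",
          intron_pos = ip, length = 1L, stringsAsFactors = FALSE)
      }
      iseq <- paste(ch, collapse = "")
      if (t == del_intron) {
        # deletion well inside the intron, clear of every planted
        # substitution of either derived species
        cand <- (margin + 1L):(ilen - margin - del_len)
        ok <- cand[vapply(cand, function(cs)
          all(avoid < cs - 2L | avoid > cs + del_len + 1L), TRUE)]
        cs <- ok[length(ok) %/% 2L + 1L]
        iseq <- paste0(substr(iseq, 1L, cs - 1L), substr(iseq, cs + del_len, ilen))
        ip <- if (intr$strand == "+") cs else ilen - (cs + del_len - 1L) + 1L
        truth[[length(truth) + 1L]] <- data.frame(
          species = sp, intron_label = intr$intron_label, kind = "deletion",
          intron_pos = ip, length = del_len, stringsAsFactors = FALSE)
        delta <- del_len
        # shift downstream features on this molecule
        after <- f$seq_id == intr$seq_id & f$start > intr$start
        f$start[after] <- f$start[after] - delta
        f$end[f$seq_id == intr$seq_id & f$end > intr$start] <-
          f$end[f$seq_id == intr$seq_id & f$end > intr$start] - delta
      }
      g[[intr$seq_id]] <- paste0(substr(s, 1L, intr$start - 1L), iseq,
                                 substr(s, intr$end + 1L, nchar(s)))
    }
    out_genomes[[sp]] <- Map(function(id, seqstr) circular_sequence(id, seqstr),
                             names(g), g)
    out_features[[sp]] <- f
  }
  list(genomes = out_genomes, features = out_features,
       truth = do.call(rbind, truth))
}
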