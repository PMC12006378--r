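# Detection of mitochondrial plastid sequences (MTPTs): seeded homology
# search between the plastome and the mitogenome (word size 7, e-value
# < 1e-6), length/identity filtering (>= 100 bp and >= 80% identity,
# boundaries inclusive), merging of hits into loci, genome-fraction
# summaries and annotation of plastid genes contained in the loci.
#
# The homology search is delegated to the standard NCBI blastn executable
# (the canonical tool for this step); everything downstream is native.

.hit_columns <- function() {
  data.frame(plastid_id = character(), p_start = integer(), p_end = integer(),
             mito_id = character(), m_start = integer(), m_end = integer(),
             strand = character(), aligned_length = integer(),
             identity = numeric(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Find homologous segments between a mitogenome and a plastome
#'
#' Runs a seeded local-alignment search (blastn, `-task blastn`) with the
#' plastome as query and the mitogenome as subject, both strands, and
#' returns hits below the e-value ceiling in deterministic order
#' (mitochondrial coordinate, then decreasing score). Low-complexity
#' filtering is disabled for determinism.
#'
#' @param mito,plastid named lists of `CircularSequence` (or paths to FASTA
#'   files).
#' @param word_size exact seed length (default 7).
#' @param evalue_max e-value ceiling (default 1e-6).
#' @return data.frame of hits: `plastid_id`, `p_start`, `p_end`, `mito_id`,
#'   `m_start`, `m_end` (always start <= end), `strand` (of the mito hit
#'   relative to the plastid query), `aligned_length`, `identity`
#'   (fraction), `evalue`, `bitscore`.
#' @export
find_homologous_segments <- function(mito, plastid, word_size = 7,
                                     evalue_max = 1e-6) {
  if (Sys.which("blastn") == "")
    stop_input("blastn executable not found on PATH")
  as_path <- function(x, label) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) return(x)
    if (length(x) == 0L) stop_input("empty %s genome", label)
    p <- tempfile(fileext = ".fa"); write_genome(x, p); p
  }
  qfile <- as_path(plastid, "plastid")
  sfile <- as_path(mito, "mito")
  out <- suppressWarnings(system2(
    "blastn",
    c("-task", "blastn", "-word_size", as.character(as.integer(word_size)),
      "-evalue", format(evalue_max, scientific = TRUE),
      "-dust", "no", "-query", qfile, "-subject", sfile,
      "-outfmt", shQuote("6 qseqid sseqid pident length qstart qend sstart send evalue bitscore")),
    stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) stop_input("blastn failed with status %d", status)
  if (!length(out)) return(.hit_columns())
  tab <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("qseqid", "sseqid", "pident", "length",
                                         "qstart", "qend", "sstart", "send",
                                         "evalue", "bitscore"))
  hits <- data.frame(
    plastid_id = tab$qseqid, p_start = tab$qstart, p_end = tab$qend,
    mito_id = tab$sseqid,
    m_start = pmin(tab$sstart, tab$send), m_end = pmax(tab$sstart, tab$send),
    strand = ifelse(tab$sstart <= tab$send, "+", "-"),
    aligned_length = tab$length, identity = tab$pident / 100,
    evalue = tab$evalue, bitscore = tab$bitscore, stringsAsFactors = FALSE)
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  hits <- hits[order(hits$mito_id, hits$m_start, -hits$bitscore), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter homology hits on length and identity
#'
#' Keeps hits with `aligned_length >= min_len` AND `identity >=
#' min_identity` (both boundaries inclusive: a 100 bp hit at exactly 80%
#' identity is retained). Monotone: raising either threshold never adds a
#' hit.
#'
#' @param hits data.frame from [find_homologous_segments()].
#' @param min_len minimum aligned length in bp (default 100).
#' @param min_identity minimum identity fraction (default 0.80).
#' @return the filtered data.frame.
#' @export
filter_hits <- function(hits, min_len = 100, min_identity = 0.80) {
  out <- hits[hits$aligned_length >= min_len &
                hits$identity >= min_identity - 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge filtered hits into MTPT loci and summarise genome fractions
#'
#' Overlapping or abutting mitochondrial intervals are merged into loci,
#' ranked by mitochondrial coordinate and numbered MTPT01, MTPT02, ...
#' The summary reports the locus count, total merged length, and the total
#' as a percentage of the mitogenome and of the plastome (both rounded
#' half-up to 2 decimals; both denominators are reported explicitly).
#'
#' @param hits filtered hits (see [filter_hits()]).
#' @param mito_len total mitogenome length in bp.
#' @param plastid_len plastome length in bp.
#' @return list with `loci` (data.frame `locus_id`, `mito_id`, `start`,
#'   `end`, `length`, `n_hits`, `identity_min`, `hit_rows` list-column of
#'   constituent hit row indices) and `summary` (list `n_loci`,
#'   `total_length`, `pct_of_mito`, `pct_of_plastid`, `mito_len`,
#'   `plastid_len`).
#' @export
merge_and_summarize <- function(hits, mito_len, plastid_len) {
  stopifnot(mito_len > 0, plastid_len > 0)
  if (!nrow(hits)) {
    loci <- data.frame(locus_id = character(), mito_id = character(),
                       start = integer(), end = integer(), length = integer(),
                       n_hits = integer(), identity_min = numeric(),
                       stringsAsFactors = FALSE)
    loci$hit_rows <- list()
    return(list(loci = loci,
                summary = list(n_loci = 0L, total_length = 0L,
                               pct_of_mito = 0, pct_of_plastid = 0,
                               mito_len = mito_len, plastid_len = plastid_len)))
  }
  pieces <- list()
  for (chrom in sort(unique(hits$mito_id))) {
    h <- which(hits$mito_id == chrom)
    ir <- IRanges::IRanges(hits$m_start[h], hits$m_end[h])
    red <- IRanges::reduce(ir)   # merges overlapping and abutting ranges
    ov <- IRanges::findOverlaps(ir, red)
    for (j in seq_along(red)) {
      members <- h[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]]
      pieces[[length(pieces) + 1L]] <- list(
        mito_id = chrom, start = IRanges::start(red)[j], end = IRanges::end(red)[j],
        members = members)
    }
  }
  ord <- order(vapply(pieces, `[[`, "", "mito_id"),
               vapply(pieces, `[[`, 1L, "start"))
  pieces <- pieces[ord]
  loci <- data.frame(
    locus_id = sprintf("MTPT%02d", seq_along(pieces)),
    mito_id = vapply(pieces, `[[`, "", "mito_id"),
    start = vapply(pieces, `[[`, 1L, "start"),
    end = vapply(pieces, `[[`, 1L, "end"),
    stringsAsFactors = FALSE)
  loci$length <- loci$end - loci$start + 1L
  loci$n_hits <- vapply(pieces, function(p) length(p$members), 1L)
  loci$identity_min <- vapply(pieces, function(p) min(hits$identity[p$members]), 1)
  loci$hit_rows <- lapply(pieces, `[[`, "members")
  total <- sum(loci$length)
  list(loci = loci,
       summary = list(n_loci = nrow(loci), total_length = total,
                      pct_of_mito = genome_fraction(total, mito_len),
                      pct_of_plastid = genome_fraction(total, plastid_len),
                      mito_len = mito_len, plastid_len = plastid_len))
}

#' Annotate plastid genes contained in MTPT loci
#'
#' A plastid feature is reported for a locus when its plastid-coordinate
#' interval overlaps the locus's plastid footprint (the union of its
#' constituent hits' plastid intervals); it is `intact` iff the interval is
#' fully covered by that single locus's footprint, otherwise it is a
#' fragment.
#'
#' @param merged result of [merge_and_summarize()].
#' @param hits the same filtered hits passed to [merge_and_summarize()].
#' @param plastid_features feature data.frame in plastid coordinates (see
#'   [read_features()]); typically the gene/tRNA/rRNA/CDS rows.
#' @return data.frame `locus_id`, `gene_name`, `feature_type`, `intact`.
#' @export
annotate_contained <- function(merged, hits, plastid_features) {
  feats <- plastid_features
  res <- list()
  for (i in seq_len(nrow(merged$loci))) {
    rows <- merged$loci$hit_rows[[i]]
    h <- hits[rows, , drop = FALSE]
    for (pid in unique(h$plastid_id)) {
      foot <- IRanges::reduce(IRanges::IRanges(h$p_start[h$plastid_id == pid],
                                               h$p_end[h$plastid_id == pid]))
      f <- feats[feats$seq_id == pid, , drop = FALSE]
      for (j in seq_len(nrow(f))) {
        fr <- IRanges::IRanges(f$start[j], f$end[j])
        inter <- IRanges::intersect(fr, foot)
        cov <- sum(IRanges::width(inter))
        if (cov == 0L) next
        res[[length(res) + 1L]] <- data.frame(
          locus_id = merged$loci$locus_id[i],
          gene_name = f$gene_name[j], feature_type = f$feature_type[j],
          intact = cov == IRanges::width(fr), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(locus_id = character(), gene_name = character(),
                      feature_type = character(), intact = logical(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, res))
}
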