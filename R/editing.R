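# C-to-U RNA editing site calling from strand-resolved pileups over CDS
# references (each CDS plus optional flanking sequence), codon-level effect
# annotation including stop-gain and start-gain, exclusion of genomic DNA
# variants, and summary statistics.
#
# Only coding-strand C->T mismatches are candidate editing events; the
# pileups are assumed to be strand-resolved upstream (strand-specific
# library). Call thresholds are inclusive: coverage >= min_depth and
# frequency >= min_freq.

#' Assemble a pileup-column table
#'
#' @param ref_id reference (gene/CDS) name, recycled.
#' @param pos 1-based positions on the reference.
#' @param ref_base reference base per position.
#' @param A,C,G,T per-base read counts (coding-strand sense).
#' @return data.frame with columns `ref_id`, `pos`, `ref_base`, `A`, `C`,
#'   `G`, `T`, `depth`.
#' @export
pileup_columns <- function(ref_id, pos, ref_base, A = 0L, C = 0L, G = 0L, T = 0L) {
  df <- data.frame(ref_id = ref_id, pos = as.integer(pos),
                   ref_base = toupper(ref_base),
                   A = as.integer(A), C = as.integer(C),
                   G = as.integer(G), T = as.integer(T),
                   stringsAsFactors = FALSE)
  df$depth <- df$A + df$C + df$G + df$T
  df
}

#' Call candidate C-to-U RNA editing sites from RNA pileups
#'
#' A site is called iff the reference base is C, depth >= `min_depth` and
#' the T fraction is >= `min_freq` (both inclusive). Positions inside
#' flanking (non-CDS) reference sequence are recorded (`in_cds = FALSE`)
#' but are excluded from codon annotation downstream.
#'
#' @param columns pileup table (see [pileup_columns()]); positions are on
#'   references consisting of `flank` bp + CDS + `flank` bp.
#' @param min_depth minimum coverage (default 5).
#' @param min_freq minimum edited fraction (default 0.1).
#' @param flank length of the flanking sequence on each side of the CDS in
#'   the reference coordinates (default 0 = references are bare CDS).
#' @param cds_lengths optional named vector of CDS lengths used to flag
#'   positions beyond the CDS 3' end as flanking.
#' @return data.frame of candidate sites: `gene`, `ref_id`, `pos`,
#'   `cds_pos`, `in_cds`, `depth`, `t_count`, `frequency`.
#' @export
call_editing_sites <- function(columns, min_depth = 5, min_freq = 0.1,
                               flank = 0, cds_lengths = NULL) {
  stopifnot(all(c("ref_id", "pos", "ref_base", "T") %in% names(columns)))
  depth <- columns$depth %||% (columns$A + columns$C + columns$G + columns$T)
  freq <- ifelse(depth > 0, columns$T / depth, 0)
  called <- columns$ref_base == "C" & depth >= min_depth &
    freq >= min_freq - 1e-12
  out <- columns[called, c("ref_id", "pos"), drop = FALSE]
  out$cds_pos <- out$pos - as.integer(flank)
  cdslen <- if (is.null(cds_lengths)) rep(Inf, nrow(out))
            else unname(cds_lengths[out$ref_id])
  out$in_cds <- out$cds_pos >= 1L & out$cds_pos <= cdslen
  out$depth <- depth[called]
  out$t_count <- columns$T[called]
  out$frequency <- freq[called]
  out <- cbind(gene = out$ref_id, out)
  rownames(out) <- NULL
  out
}

#' Call DNA variants (SNPs) from DNA pileups
#'
#' Same inclusive thresholds as editing calls: a position is a variant iff
#' depth >= `min_depth` and some non-reference allele reaches frequency >=
#' `min_freq`.
#'
#' @param columns pileup table from DNA alignments.
#' @param min_depth,min_freq thresholds (defaults 5 and 0.1).
#' @return data.frame `ref_id`, `pos`, `ref_base`, `alt_base`, `depth`,
#'   `frequency`.
#' @export
call_dna_variants <- function(columns, min_depth = 5, min_freq = 0.1) {
  depth <- columns$depth %||% (columns$A + columns$C + columns$G + columns$T)
  bases <- c("A", "C", "G", "T")
  res <- list()
  for (i in seq_len(nrow(columns))) {
    if (depth[i] < min_depth) next
    alts <- setdiff(bases, columns$ref_base[i])
    cnt <- vapply(alts, function(b) columns[[b]][i], 1L)
    best <- which.max(cnt)
    f <- cnt[best] / depth[i]
    if (f >= min_freq - 1e-12) {
      res[[length(res) + 1L]] <- data.frame(
        ref_id = columns$ref_id[i], pos = columns$pos[i],
        ref_base = columns$ref_base[i], alt_base = alts[best],
        depth = depth[i], frequency = f, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(ref_id = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      depth = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Stop")

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Annotate the codon-level effect of editing sites
#'
#' For each in-CDS site: codon index = ceiling(cds_pos/3), codon position =
#' ((cds_pos-1) mod 3)+1; the edited codon replaces the C with T at that
#' position. Effects under the standard genetic code: a gained stop codon
#' is `stop_gain`; an ATG gained at codon 1 is `start_gain`; an unchanged
#' amino acid is `synonymous`; anything else `nonsynonymous`. Site names
#' follow the `gene-cdsposition` style, indexing the edited base.
#'
#' @param sites data.frame from [call_editing_sites()] (in-CDS rows are
#'   annotated; flanking rows are dropped with a message).
#' @param cds_seqs named character vector gene -> CDS sequence (length a
#'   multiple of 3).
#' @return data.frame of annotated `EditingSite` records: adds `site_name`,
#'   `codon_index`, `codon_position`, `ref_codon`, `edited_codon`,
#'   `aa_ref`, `aa_edit`, `effect`.
#' @export
annotate_effect <- function(sites, cds_seqs) {
  flanking <- !sites$in_cds
  if (any(flanking))
    message(sum(flanking), " site(s) in flanking sequence excluded from codon annotation")
  sites <- sites[!flanking, , drop = FALSE]
  n <- nrow(sites)
  add <- data.frame(site_name = character(n), codon_index = integer(n),
                    codon_position = integer(n), ref_codon = character(n),
                    edited_codon = character(n), aa_ref = character(n),
                    aa_edit = character(n), effect = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    gene <- sites$gene[i]; p <- sites$cds_pos[i]
    cds <- cds_seqs[[gene]]
    if (is.null(cds)) stop_input("no CDS sequence for gene '%s'", gene)
    if (nchar(cds) %% 3 != 0)
      stop_input("CDS of '%s' is not a multiple of 3", gene)
    if (p < 1L || p > nchar(cds))
      stop_coord("cds_pos %d beyond CDS of '%s' (%d bp)", p, gene, nchar(cds))
    if (substr(cds, p, p) != "C")
      stop_coord("reference base at %s:%d is %s, not C", gene, p, substr(cds, p, p))
    ci <- (p - 1L) %/% 3L + 1L
    cp <- (p - 1L) %% 3L + 1L
    ref_codon <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
    edited <- ref_codon
    substr(edited, cp, cp) <- "T"
    aa_r <- .translate_codon(ref_codon); aa_e <- .translate_codon(edited)
    eff <- if (aa_e == "*" && aa_r != "*") "stop_gain"
           else if (edited == "ATG" && ci == 1L && ref_codon != "ATG") "start_gain"
           else if (aa_e == aa_r) "synonymous"
           else "nonsynonymous"
    add[i, ] <- list(paste0(gene, "-", p), ci, cp, ref_codon, edited,
                     aa_r, aa_e, eff)
  }
  cbind(sites, add)
}

#' Remove editing sites that coincide with DNA variants
#'
#' Any editing site whose (ref_id, pos) matches a DNA variant called at the
#' same thresholds from DNA pileups is removed (it is a genomic SNP, not an
#' editing event) and reported via a message.
#'
#' @param sites editing-site data.frame (called and/or annotated).
#' @param variants data.frame from [call_dna_variants()].
#' @return the filtered site data.frame.
#' @export
exclude_dna_variants <- function(sites, variants) {
  if (!nrow(sites) || !nrow(variants)) return(sites)
  key_s <- paste(sites$ref_id, sites$pos)
  key_v <- paste(variants$ref_id, variants$pos)
  drop <- key_s %in% key_v
  if (any(drop))
    message(sum(drop), " editing site(s) removed as DNA variants: ",
            paste(key_s[drop], collapse = ", "))
  out <- sites[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default hydropathy classification of amino acids
#'
#' Hydrophobic one-letter codes; every other amino acid is treated as
#' hydrophilic. Configurable because published summaries rarely state the
#' scheme used.
#'
#' @return character vector of hydrophobic one-letter codes.
#' @export
default_hydrophobic <- function() c("A", "V", "L", "I", "P", "F", "M", "W")

#' Summarise annotated editing sites
#'
#' Counts and percentages (denominator = total sites, rounded half-up to 2
#' decimals) by effect class, codon position and amino-acid change, plus
#' the number of nonsynonymous changes shifting a hydrophilic residue to a
#' hydrophobic one (reported as a percentage of nonsynonymous changes,
#' which is the conventional denominator for that figure).
#'
#' @param sites annotated editing-site data.frame ([annotate_effect()]).
#' @param hydrophobic one-letter codes treated as hydrophobic.
#' @return object of class `EditingSummary`.
#' @export
summarize_editing <- function(sites, hydrophobic = default_hydrophobic()) {
  n <- nrow(sites)
  pct <- function(k, d = n) if (d > 0) round_half_up(100 * k / d, 2) else 0
  eff <- function(e) sum(sites$effect == e)
  n_syn <- eff("synonymous"); n_nonsyn <- eff("nonsynonymous")
  n_stop <- eff("stop_gain"); n_start <- eff("start_gain")
  by_pos <- data.frame(codon_position = 1:3,
                       count = vapply(1:3, function(p) sum(sites$codon_position == p), 1L))
  by_pos$pct <- pct(by_pos$count)
  if (n > 0) {
    chg <- paste0(.aa3[sites$aa_ref], "->", .aa3[sites$aa_edit])
    tab <- sort(table(chg[sites$effect != "synonymous"]), decreasing = TRUE)
    by_change <- data.frame(change = names(tab), count = as.integer(tab),
                            stringsAsFactors = FALSE)
    by_change$pct <- pct(by_change$count)
  } else {
    by_change <- data.frame(change = character(), count = integer(),
                            pct = numeric(), stringsAsFactors = FALSE)
  }
  ns <- sites$effect == "nonsynonymous" | sites$effect == "stop_gain"
  hydro_shift <- sum(ns & !(sites$aa_ref %in% hydrophobic) &
                       sites$aa_edit %in% hydrophobic & sites$aa_edit != "*")
  structure(list(
    n_total = n,
    n_synonymous = n_syn, pct_synonymous = pct(n_syn),
    n_nonsynonymous = n_nonsyn, pct_nonsynonymous = pct(n_nonsyn),
    n_stop_gain = n_stop, pct_stop_gain = pct(n_stop),
    n_start_gain = n_start, pct_start_gain = pct(n_start),
    by_codon_position = by_pos,
    by_aa_change = by_change,
    n_hydro_shift = hydro_shift,
    pct_hydro_shift = pct(hydro_shift, max(n_nonsyn, 1L))),
    class = "EditingSummary")
}

#' @export
print.EditingSummary <- function(x, ...) {
  cat(sprintf("<EditingSummary> %d sites: %d syn (%.2f%%), %d nonsyn (%.2f%%), %d stop-gain, %d start-gain\n",
              x$n_total, x$n_synonymous, x$pct_synonymous,
              x$n_nonsynonymous, x$pct_nonsynonymous,
              x$n_stop_gain, x$n_start_gain))
  invisible(x)
}

#' Build a pileup table from a SAM/BAM file
#'
#' Convenience wrapper (requires the `Rsamtools` package): converts SAM to
#' BAM if needed, sorts, indexes and piles up with no base-quality or
#' mapping-quality filtering, then returns a [pileup_columns()] table in
#' coding-strand sense.
#'
#' @param sam_path SAM or BAM file of reads aligned to the CDS references.
#' @param ref_seqs named character vector of reference sequences (for the
#'   `ref_base` column).
#' @return pileup data.frame (positions with zero coverage omitted).
#' @export
pileup_from_sam <- function(sam_path, ref_seqs) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop_input("pileup_from_sam requires the Rsamtools package")
  bam <- if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE, indexDestination = TRUE)
  } else sam_path
  pp <- Rsamtools::PileupParam(max_depth = 100000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  res <- Rsamtools::pileup(bam, pileupParam = pp)
  if (!nrow(res)) {
    return(pileup_columns(character(), integer(), character()))
  }
  key <- paste(res$seqnames, res$pos)
  agg <- function(base) {
    v <- tapply(res$count[res$nucleotide == base], key[res$nucleotide == base], sum)
    out <- integer(length(unique(key))); names(out) <- unique(key)
    out[names(v)] <- as.integer(v)
    out
  }
  uk <- unique(key)
  ref_id <- sub(" .*$", "", uk)
  pos <- as.integer(sub("^.* ", "", uk))
  ref_base <- vapply(seq_along(uk), function(i)
    substr(ref_seqs[[ref_id[i]]], pos[i], pos[i]), "")
  pileup_columns(ref_id, pos, ref_base,
                 A = agg("A")[uk], C = agg("C")[uk],
                 G = agg("G")[uk], T = agg("T")[uk])
}
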