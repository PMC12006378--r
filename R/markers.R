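# Interspecific intron markers: extract cis-spliced mitochondrial introns
# from annotated genomes, align orthologous introns across species,
# identify polymorphic loci (SNP columns and indel gap-runs), and emit
# flanked target regions for primer design.

#' Extract introns from an annotated genome
#'
#' For each gene with two or more cis exons on one molecule, the intron
#' between consecutive exon ranks r and r+1 is extracted and labelled
#' `<gene>i<r><r+1>` (e.g. `nad1i23` is the intron between exons 2 and 3).
#' Minus-strand genes yield coding-strand sequences. Genes with exons on
#' different molecules (trans-spliced) are skipped with a message.
#'
#' @param genome named list of `CircularSequence`.
#' @param features feature data.frame (see [read_features()]); exon rows
#'   must carry `gene_name` and `exon_rank`.
#' @return data.frame: `gene`, `intron_label`, `seq_id`, `start`, `end`,
#'   `strand`, `sequence` (genomic coordinates are plus-strand,
#'   start <= end).
#' @export
extract_introns <- function(genome, features) {
  ex <- features[features$feature_type == "exon" & !is.na(features$exon_rank), ,
                 drop = FALSE]
  res <- list()
  for (g in unique(ex$gene_name)) {
    e <- ex[ex$gene_name == g, , drop = FALSE]
    if (nrow(e) < 2L) next
    if (length(unique(e$seq_id)) > 1L) {
      message("gene '", g, "' has exons on multiple molecules (trans-spliced): skipped")
      next
    }
    if (anyDuplicated(e$exon_rank))
      stop_classed("annotation_error", "gene '%s' has duplicate exon ranks", g)
    e <- e[order(e$exon_rank), , drop = FALSE]
    ir <- IRanges::IRanges(e$start, e$end)
    if (!all(IRanges::width(IRanges::reduce(ir)) == IRanges::width(ir)) ||
        length(IRanges::reduce(ir)) != nrow(e))
      stop_classed("annotation_error", "gene '%s' has overlapping exons", g)
    strand <- e$strand[1L]
    seq <- genome[[e$seq_id[1L]]]
    for (k in seq_len(nrow(e) - 1L)) {
      r1 <- e$exon_rank[k]; r2 <- e$exon_rank[k + 1L]
      if (strand == "+") {
        gs <- e$end[k] + 1L; ge <- e$start[k + 1L] - 1L
      } else {
        gs <- e$end[k + 1L] + 1L; ge <- e$start[k] - 1L
      }
      if (gs > ge) next   # adjacent exons, no intron
      iv <- genome_interval(e$seq_id[1L], gs, ge, strand = strand)
      res[[length(res) + 1L]] <- data.frame(
        gene = g, intron_label = paste0(g, "i", r1, r2),
        seq_id = e$seq_id[1L], start = gs, end = ge, strand = strand,
        sequence = extract_interval(seq, iv), stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(gene = character(), intron_label = character(),
                      seq_id = character(), start = integer(), end = integer(),
                      strand = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.msa_scoring <- function(match = 2, mismatch = -1) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                                baseOnly = FALSE)
  m["N", ] <- mismatch; m[, "N"] <- mismatch
  m
}

# parse a pairwise global alignment of s (pattern) vs ref (subject) into
# per-ref-position insertion counts and the gapped strings
.pairwise_to_ref <- function(s, ref, match = 2, mismatch = -1,
                             gap_open = 5, gap_ext = 1) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s), Biostrings::DNAString(ref), type = "global",
    substitutionMatrix = .msa_scoring(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  nref <- nchar(ref)
  # ins[j+1] = inserted bases of s between ref positions j and j+1 (j=0 is
  # before the first ref base); row = characters of s aligned per ref slot
  ins <- integer(nref + 1L)
  slot_chars <- vector("list", 2L * nref + 1L)  # interleaved: gap0, ref1, gap1, ...
  aligned_at_ref <- character(nref)
  ins_chars <- vector("list", nref + 1L)
  for (k in seq_len(nref + 1L)) ins_chars[[k]] <- character()
  j <- 0L
  for (t in seq_along(as_)) {
    if (as_[t] == "-") {
      ins[j + 1L] <- ins[j + 1L] + 1L
      ins_chars[[j + 1L]] <- c(ins_chars[[j + 1L]], ap[t])
    } else {
      j <- j + 1L
      aligned_at_ref[j] <- ap[t]
    }
  }
  list(ins = ins, at_ref = aligned_at_ref, ins_chars = ins_chars)
}

#' Align orthologous introns across species
#'
#' Deterministic progressive multiple alignment: every sequence is aligned
#' globally (affine gap penalties) to the first sequence, and the pairwise
#' alignments are merged on the shared reference coordinate using the
#' once-a-gap-always-a-gap rule. Guide order is the input order. All input
#' residues are preserved in the rows.
#'
#' @param seqs named character vector, one intron sequence per species
#'   (>= 2; the first is the merge reference).
#' @param match,mismatch,gap_open,gap_ext alignment scoring (defaults
#'   +2/-1, open 5, extend 1, penalties positive).
#' @return named character vector of equal-length gapped rows, class
#'   `intron_alignment`.
#' @export
align_introns <- function(seqs, match = 2, mismatch = -1,
                          gap_open = 5, gap_ext = 1) {
  stopifnot(length(seqs) >= 2L)
  if (any(nchar(seqs) == 0L)) stop_input("empty intron sequence")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ref <- toupper(seqs[[1L]])
  nref <- nchar(ref)
  others <- lapply(seqs[-1L], function(s)
    .pairwise_to_ref(toupper(s), ref, match, mismatch, gap_open, gap_ext))
  ins_max <- Reduce(pmax, lapply(others, `[[`, "ins"), integer(nref + 1L))
  build_row <- function(at_ref, ins_chars) {
    parts <- character(0L)
    for (j in 0:nref) {
      k <- j + 1L
      gap_here <- ins_max[k]
      got <- ins_chars[[k]]
      # left-align insertions within their slot, pad with gaps
      parts <- c(parts, got, rep("-", gap_here - length(got)))
      if (j < nref) parts <- c(parts, at_ref[j + 1L])
    }
    paste(parts, collapse = "")
  }
  ref_row <- build_row(strsplit(ref, "")[[1L]],
                       lapply(seq_len(nref + 1L), function(i) character()))
  rows <- c(ref_row, vapply(others, function(o) build_row(o$at_ref, o$ins_chars), ""))
  names(rows) <- names(seqs)
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(rows, class = "intron_alignment")
}

#' Find interspecific polymorphic sites in an intron alignment
#'
#' Gap-free columns with at least two distinct residues are SNP sites (one
#' column each; adjacent variant columns stay separate loci). Maximal runs
#' of columns containing a gap are indel sites (one locus per run; a
#' species' allele in the run is its residues with gaps removed, so a full
#' gap run is the empty string). `N` never counts as polymorphic evidence.
#' Every site records which species pairs it distinguishes.
#'
#' @param aln an `intron_alignment` (named gapped rows).
#' @param intron_label optional label copied onto the output rows.
#' @return data.frame: `intron_label`, `site_index`, `site_type`
#'   (`"SNP"`/`"indel"`), `col_start`, `col_end`, `alleles` (list-column of
#'   named per-species allele strings), `discriminates` (semicolon-joined
#'   species pairs).
#' @export
find_polymorphic_sites <- function(aln, intron_label = NA_character_) {
  species <- names(aln)
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- species
  ncol_ <- ncol(m)
  has_gap <- apply(m == "-", 2, any)
  sites <- list()
  # indel loci: maximal gap-containing column runs
  r <- rle(has_gap)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    cs <- starts[i]; ce <- ends[i]
    alleles <- vapply(species, function(sp)
      gsub("-", "", paste(m[sp, cs:ce], collapse = "")), "")
    if (length(unique(alleles)) < 2L) next
    sites[[length(sites) + 1L]] <- list(type = "indel", cs = cs, ce = ce,
                                        alleles = alleles)
  }
  # SNP loci: gap-free polymorphic columns
  for (j in which(!has_gap)) {
    col <- m[, j]
    obs <- col[col != "N"]
    if (length(unique(obs)) >= 2L) {
      alleles <- stats::setNames(col, species)
      sites[[length(sites) + 1L]] <- list(type = "SNP", cs = j, ce = j,
                                          alleles = alleles)
    }
  }
  if (!length(sites)) {
    out <- data.frame(intron_label = character(), site_index = integer(),
                      site_type = character(), col_start = integer(),
                      col_end = integer(), discriminates = character(),
                      stringsAsFactors = FALSE)
    out$alleles <- list()
    return(out)
  }
  ord <- order(vapply(sites, `[[`, 1L, "cs"))
  sites <- sites[ord]
  pairs <- utils::combn(species, 2, simplify = FALSE)
  disc <- vapply(sites, function(s) {
    d <- Filter(function(p) s$alleles[[p[1L]]] != s$alleles[[p[2L]]], pairs)
    paste(vapply(d, paste, "", collapse = "|"), collapse = ";")
  }, "")
  out <- data.frame(
    intron_label = intron_label,
    site_index = seq_along(sites),
    site_type = vapply(sites, `[[`, "", "type"),
    col_start = vapply(sites, `[[`, 1L, "cs"),
    col_end = vapply(sites, `[[`, 1L, "ce"),
    discriminates = disc, stringsAsFactors = FALSE)
  out$alleles <- lapply(sites, `[[`, "alleles")
  out
}

#' Build flanked marker target regions around polymorphic sites
#'
#' Each site is projected onto the reference species' intron coordinates
#' and expanded by `flank` bp on both sides, clamped to the intron bounds.
#' Sites whose expanded regions overlap or abut (equivalently, sites within
#' `group_within` bp of each other) are grouped into a single region.
#'
#' @param sites data.frame from [find_polymorphic_sites()].
#' @param aln the `intron_alignment` the sites came from.
#' @param reference species whose coordinates anchor the regions (default:
#'   first row of the alignment).
#' @param flank flank length in bp (default 300).
#' @param group_within merge regions whose anchor sites are within this
#'   many bp (default `2 * flank`).
#' @return data.frame: `region_id`, `reference`, `start`, `end`, `length`,
#'   `site_indices`, `sequence` (reference-species subsequence).
#' @export
build_marker_regions <- function(sites, aln, reference = names(aln)[1L],
                                 flank = 300, group_within = 2 * flank) {
  stopifnot(reference %in% names(aln))
  ref_chars <- strsplit(unclass(aln)[[reference]], "")[[1L]]
  refpos <- cumsum(ref_chars != "-")        # alignment column -> ref coordinate
  ref_len <- max(refpos)
  if (!nrow(sites)) {
    return(data.frame(region_id = character(), reference = character(),
                      start = integer(), end = integer(), length = integer(),
                      site_indices = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  anchor_s <- pmax(1L, refpos[sites$col_start])
  anchor_e <- pmax(1L, refpos[sites$col_end])
  rs <- pmax(1L, anchor_s - as.integer(flank))
  re <- pmin(ref_len, anchor_e + as.integer(flank))
  ord <- order(rs, re)
  merged <- list()
  cur <- list(s = rs[ord[1L]], e = re[ord[1L]], idx = sites$site_index[ord[1L]],
              as_ = anchor_s[ord[1L]], ae = anchor_e[ord[1L]])
  for (t in ord[-1L]) {
    overlaps <- rs[t] <= cur$e + 1L
    near <- anchor_s[t] - cur$ae <= group_within
    if (overlaps || near) {
      cur$e <- max(cur$e, re[t]); cur$ae <- max(cur$ae, anchor_e[t])
      cur$idx <- c(cur$idx, sites$site_index[t])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- list(s = rs[t], e = re[t], idx = sites$site_index[t],
                  as_ = anchor_s[t], ae = anchor_e[t])
    }
  }
  merged[[length(merged) + 1L]] <- cur
  ref_seq <- gsub("-", "", unclass(aln)[[reference]])
  data.frame(
    region_id = sprintf("region%02d", seq_along(merged)),
    reference = reference,
    start = vapply(merged, `[[`, 1L, "s"),
    end = vapply(merged, `[[`, 1L, "e"),
    length = vapply(merged, function(x) x$e - x$s + 1L, 1L),
    site_indices = vapply(merged, function(x) paste(x$idx, collapse = ","), ""),
    sequence = vapply(merged, function(x) substr(ref_seq, x$s, x$e), ""),
    stringsAsFactors = FALSE)
}
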