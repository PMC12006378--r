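# Circular-coordinate sequence model: the mitogenomes handled here are
# multisets of circular DNA molecules with 1-based inclusive coordinates and
# explicit strand; an interval crossing the origin carries an explicit
# `wraps` flag instead of the ambiguous start > end encoding.

#' Create a circular (or linear) DNA sequence
#'
#' @param id sequence label.
#' @param residues character string over A/C/G/T/N (lower case accepted,
#'   normalised to upper case).
#' @param circular logical; circular topology (the default for assembled
#'   mitochondrial chromosomes). Linear mode exists for intermediate
#'   artifacts such as configuration references and marker regions.
#' @return an object of class `CircularSequence` with fields `id`,
#'   `residues`, `length`, `circular`.
#' @export
circular_sequence <- function(id, residues, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (nchar(residues) == 0L)
    stop_format("sequence '%s' has zero length", id)
  if (grepl("[^ACGTN]", residues))
    stop_alphabet("sequence '%s' contains non-ACGTN characters", id)
  structure(list(id = id, residues = residues,
                 length = nchar(residues), circular = isTRUE(circular)),
            class = "CircularSequence")
}

#' @export
print.CircularSequence <- function(x, ...) {
  cat(sprintf("<CircularSequence> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Create a genome interval
#'
#' 1-based inclusive coordinates with explicit strand. `wraps = TRUE` marks
#' an interval crossing the circular origin (position `length` joins
#' position 1); only then may `start > end`.
#'
#' @param seq_id id of the molecule the interval lives on.
#' @param start,end 1-based inclusive positions.
#' @param strand `"+"` or `"-"`.
#' @param wraps logical, interval crosses the origin.
#' @return an object of class `GenomeInterval`.
#' @export
genome_interval <- function(seq_id, start, end, strand = "+", wraps = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < 1L)
    stop_coord("interval positions must be >= 1 (got %d..%d)", start, end)
  if (!wraps && start > end)
    stop_coord("start (%d) > end (%d) without wraps", start, end)
  structure(list(seq_id = seq_id, start = start, end = end,
                 strand = strand, wraps = isTRUE(wraps)),
            class = "GenomeInterval")
}

#' Span length of an interval on a molecule
#'
#' @param iv a `GenomeInterval`.
#' @param seq_len length of the molecule it lives on.
#' @return span in bp (end-start+1, or the wrap-around equivalent).
#' @export
span_length <- function(iv, seq_len) {
  if (iv$wraps) seq_len - iv$start + 1L + iv$end else iv$end - iv$start + 1L
}

#' Reverse complement of a residue string
#'
#' Standard Watson-Crick complement, reversed; N maps to N. An involution.
#'
#' @param s residue string over A/C/G/T/N.
#' @return the reverse complement string.
#' @export
reverse_complement <- function(s) {
  s <- toupper(as.character(s))
  if (grepl("[^ACGTN]", s))
    stop_alphabet("reverse_complement: non-ACGTN character in input")
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract the residues of an interval, 5'->3' on the requested strand
#'
#' Minus-strand intervals return the reverse complement of the plus-strand
#' span; wrap-around extraction is only allowed on circular molecules.
#'
#' @param seq a `CircularSequence`.
#' @param iv a `GenomeInterval` on that sequence.
#' @return residue string of length `span_length(iv, seq$length)`.
#' @export
extract_interval <- function(seq, iv) {
  stopifnot(inherits(seq, "CircularSequence"), inherits(iv, "GenomeInterval"))
  if (!identical(iv$seq_id, seq$id))
    stop_coord("interval seq_id '%s' does not match sequence '%s'", iv$seq_id, seq$id)
  L <- seq$length
  if (iv$start > L || iv$end > L)
    stop_coord("interval %d..%d out of bounds for '%s' (%d bp)", iv$start, iv$end, seq$id, L)
  if (iv$wraps && !seq$circular)
    stop_topology("wrap-around interval on non-circular sequence '%s'", seq$id)
  n <- span_length(iv, L)
  out <- circ_substr(seq$residues, iv$start, n)
  if (iv$strand == "-") out <- reverse_complement(out)
  out
}

#' Read a genome from a FASTA file
#'
#' One `CircularSequence` per record, input order preserved, residues
#' uppercased. Record ids are the first whitespace-delimited token of each
#' header.
#'
#' @param path FASTA file.
#' @param circular logical; topology assigned to every record.
#' @return named list of `CircularSequence`.
#' @export
load_genome <- function(path, circular = TRUE) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop_format("cannot read FASTA '%s': %s", path, conditionMessage(e)))
  if (length(ss) == 0L) stop_format("no records in FASTA '%s'", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(Biostrings::width(ss) == 0L))
    stop_format("zero-length record in FASTA '%s'", path)
  out <- Map(function(id, s) circular_sequence(id, s, circular = circular),
             ids, as.character(ss))
  names(out) <- ids
  out
}

#' Write a genome to a FASTA file
#'
#' @param genome named list of `CircularSequence` (or plain named character).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) {
    ss <- Biostrings::DNAStringSet(genome)
  } else {
    ss <- Biostrings::DNAStringSet(vapply(genome, function(x) x$residues, ""))
    names(ss) <- vapply(genome, function(x) x$id, "")
  }
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read long reads from FASTA or FASTQ
#'
#' FASTQ qualities are ignored (classification is alignment-based).
#'
#' @param path reads file; `.fastq`/`.fq` (optionally gzipped) is parsed as
#'   FASTQ, anything else as FASTA.
#' @return named character vector of read sequences.
#' @export
load_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

# ---- feature tables (GFF3) -------------------------------------------------

feature_columns <- c("seq_id", "feature_type", "start", "end", "strand",
                     "gene_name", "exon_rank")

empty_features <- function() {
  data.frame(seq_id = character(), feature_type = character(),
             start = integer(), end = integer(), strand = character(),
             gene_name = character(), exon_rank = integer(),
             stringsAsFactors = FALSE)
}

#' Read gene/exon/CDS annotations from GFF3
#'
#' Returns a plain feature table with the columns used throughout the
#' package: `seq_id`, `feature_type`, `start`, `end`, `strand`,
#' `gene_name`, `exon_rank`. The `gene_name` attribute is taken from
#' `gene_name`, `gene` or `Name` (first present); `exon_rank` from the
#' `exon_rank` attribute where present.
#'
#' @param path GFF3 file.
#' @return feature data.frame.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  pick <- function(cands) {
    for (nm in cands) if (nm %in% colnames(mc)) return(as.character(mc[[nm]]))
    rep(NA_character_, length(gr))
  }
  rank_raw <- pick("exon_rank")
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             feature_type = as.character(mc$type),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             gene_name = pick(c("gene_name", "gene", "Name")),
             exon_rank = suppressWarnings(as.integer(rank_raw)),
             stringsAsFactors = FALSE)
}

#' Write a feature table to GFF3
#'
#' @param features feature data.frame (see [read_features()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    attrs <- sprintf("ID=%s", paste0(features$gene_name, ".", features$feature_type,
                                     ".", seq_len(nrow(features))))
    attrs <- paste0(attrs, ";gene_name=", features$gene_name)
    has_rank <- !is.na(features$exon_rank)
    attrs[has_rank] <- paste0(attrs[has_rank], ";exon_rank=", features$exon_rank[has_rank])
    writeLines(paste(features$seq_id, "mitorecomb", features$feature_type,
                     features$start, features$end, ".", features$strand, ".",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}
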