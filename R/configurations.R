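# Four-configuration references around a repeat. c1 and c2 reproduce the
# as-assembled context of the two repeat copies; c3 and c4 carry switched
# flanks, mimicking the two homologous-recombination products. The canonical
# strand is copy1's plus-strand reading of the core: for an inverted repeat
# the whole copy2 neighbourhood is reverse-complemented first, which swaps
# and complements its flanks.

#' Build the four configuration reference sequences around a repeat
#'
#' @param genome named list of `CircularSequence`.
#' @param rp one repeat pair: a single row of the data.frame returned by
#'   [find_dispersed_repeats()] (or any list with the same fields).
#' @param flank_len flank length in bp on each side of the core
#'   (default 1000; MTPT junction validation conventionally uses 2000).
#' @return an object of class `ConfigurationSet`: list with `repeat_id`,
#'   `flank_len`, `core`, `core_length`, `sequences` (named list c1..c4),
#'   and `provenance` (per-configuration flank sources plus any
#'   overlapping-flank warnings).
#' @export
build_configurations <- function(genome, rp, flank_len = 1000) {
  if (is.data.frame(rp)) {
    stopifnot(nrow(rp) == 1L)
    rp <- as.list(rp)
  }
  stopifnot(flank_len >= 1)
  flank_len <- as.integer(flank_len)
  seq1 <- genome[[rp$chrom1]]; seq2 <- genome[[rp$chrom2]]
  if (is.null(seq1) || is.null(seq2))
    stop_input("repeat chromosomes '%s'/'%s' not in genome", rp$chrom1, rp$chrom2)
  for (s in unique(list(seq1, seq2))) {
    if (flank_len >= s$length)
      stop_topology("flank_len (%d) >= molecule length of '%s' (%d)",
                    flank_len, s$id, s$length)
  }
  L1 <- seq1$length; L2 <- seq2$length
  core_len <- as.integer(rp$core_length)

  # copy1 on the plus strand defines the core
  core <- circ_substr(seq1$residues, rp$start1, core_len)
  left1  <- circ_substr(seq1$residues, rp$start1 - flank_len, flank_len)
  right1 <- circ_substr(seq1$residues, rp$start1 + core_len, flank_len)

  s2 <- rp$start2
  if (identical(rp$orientation, "direct")) {
    left2  <- circ_substr(seq2$residues, s2 - flank_len, flank_len)
    right2 <- circ_substr(seq2$residues, s2 + core_len, flank_len)
  } else {
    # reverse-complement copy2's neighbourhood: its plus-strand right flank
    # becomes the left flank of the re-oriented context and vice versa
    left2  <- reverse_complement(circ_substr(seq2$residues, s2 + core_len, flank_len))
    right2 <- reverse_complement(circ_substr(seq2$residues, s2 - flank_len, flank_len))
  }

  warn <- character()
  if (identical(rp$chrom1, rp$chrom2)) {
    gap_fwd <- (rp$start2 - (rp$start1 + core_len)) %% L1
    gap_rev <- (rp$start1 - (rp$start2 + core_len)) %% L1
    if (min(gap_fwd, gap_rev) < flank_len)
      warn <- c(warn, sprintf(
        "repeat copies closer than flank_len (%d bp) on '%s': flanks overlap the partner copy",
        flank_len, rp$chrom1))
  }

  sequences <- list(
    c1 = paste0(left1, core, right1),
    c2 = paste0(left2, core, right2),
    c3 = paste0(left1, core, right2),
    c4 = paste0(left2, core, right1))
  provenance <- data.frame(
    configuration = c("c1", "c2", "c3", "c4"),
    left_source  = c("copy1", "copy2", "copy1", "copy2"),
    right_source = c("copy1", "copy2", "copy2", "copy1"),
    stringsAsFactors = FALSE)

  structure(list(repeat_id = rp$repeat_id %||% "R??",
                 repeat_pair = rp, flank_len = flank_len,
                 core = core, core_length = core_len,
                 flanks = list(left1 = left1, right1 = right1,
                               left2 = left2, right2 = right2),
                 sequences = sequences, provenance = provenance,
                 warnings = warn),
            class = "ConfigurationSet")
}

#' @export
print.ConfigurationSet <- function(x, ...) {
  cat(sprintf("<ConfigurationSet> %s: core %d bp, flanks %d bp, refs %s bp\n",
              x$repeat_id, x$core_length, x$flank_len,
              paste(unique(nchar(unlist(x$sequences))), collapse = "/")))
  if (length(x$warnings)) cat(" warning:", x$warnings, "\n")
  invisible(x)
}

#' Write a configuration set as a 4-record FASTA
#'
#' Record ids are `<repeat_id>_c1` .. `<repeat_id>_c4`.
#'
#' @param cfg a `ConfigurationSet`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_configurations <- function(cfg, path) {
  ss <- Biostrings::DNAStringSet(unlist(cfg$sequences))
  names(ss) <- paste0(cfg$repeat_id, "_", names(cfg$sequences))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
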