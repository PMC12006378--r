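# Shared fixtures and independent oracles used across the test files.
# Oracles deliberately avoid the package's own code paths: repeats are
# checked against sorted k-mer duplication, recombination products against
# concrete string surgery, SSRs against a direct regex scan.

rnd_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# oracle: does `s` contain any duplicated k-mer (on either strand)?
# Sorted-substring duplication check, independent of the seed-extend code.
has_duplicate_kmer <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(FALSE)
  km <- substring(s, 1:(n - k + 1), k:n)
  rcs <- rc_chr(s)
  km2 <- substring(rcs, 1:(n - k + 1), k:n)
  any(duplicated(km)) || any(km %in% km2)
}

# ---- string-surgery oracle for the recombination algebra -------------------
# Realize a configuration as concrete circular strings (unique random arc
# sequences; the two copies of a repeat share one sequence), perform the
# crossover by cut-and-rejoin on the strings, and re-factor the product
# strings into segment cycles by locating each segment sequence.

make_segment_seqs <- function(segments, arc_len = 60L, rep_len = 40L) {
  seqs <- character(0)
  done <- character(0)
  for (i in seq_len(nrow(segments))) {
    id <- segments$segment_id[i]
    if (segments$kind[i] == "repeat_copy") {
      rid <- segments$repeat_id[i]
      if (rid %in% done) {
        prev <- segments$segment_id[segments$repeat_id %in% rid &
                                      segments$segment_id %in% names(seqs)][1]
        seqs[id] <- seqs[[prev]]
      } else {
        seqs[id] <- rnd_dna(rep_len)
        done <- c(done, rid)
      }
    } else {
      seqs[id] <- rnd_dna(arc_len)
    }
  }
  seqs
}

# crossover on realized circular strings at the repeat midpoints.
# occ: data.frame(circle, offset, orient) for the two copies (offset =
# plus-strand bases before the copy); strings: list of plus-strand circle
# strings; rep_len: repeat length (even).
string_surgery <- function(strings, occ, rep_len) {
  m <- rep_len %/% 2L
  cutpoint <- function(o) {
    # plus-strand position after which the cut falls; homologous cuts fall
    # after m copy-bases read in each copy's own orientation
    if (o$orient == "+") o$offset + m else o$offset + rep_len - m
  }
  lin <- function(ci, cut) {
    s <- strings[[ci]]
    L <- nchar(s)
    p <- (cut %% L) + 1L          # linearise starting just after the cut
    paste0(substr(s, p, L), substr(s, 1L, p - 1L))
  }
  o1 <- occ[1, ]; o2 <- occ[2, ]
  if (o1$circle != o2$circle) {
    f1 <- lin(o1$circle, cutpoint(o1))
    f2 <- lin(o2$circle, cutpoint(o2))
    if (o1$orient == o2$orient) prod <- paste0(f1, f2)
    else prod <- paste0(f1, rc_chr(f2))
    untouched <- setdiff(seq_along(strings), c(o1$circle, o2$circle))
    c(strings[untouched], list(prod))
  } else {
    s <- strings[[o1$circle]]
    L <- nchar(s)
    c1 <- cutpoint(o1) %% L; c2 <- cutpoint(o2) %% L
    if (c1 > c2) { tmp <- o1; o1 <- o2; o2 <- tmp; tmp <- c1; c1 <- c2; c2 <- tmp }
    A <- substr(s, c1 + 1L, c2)                 # arc from cut1 to cut2
    B <- paste0(substr(s, c2 + 1L, L), substr(s, 1L, c1))
    untouched <- setdiff(seq_along(strings), o1$circle)
    if (o1$orient == o2$orient) {
      c(strings[untouched], list(A, B))          # fission
    } else {
      c(strings[untouched], list(paste0(B, rc_chr(A))))  # inversion
    }
  }
}

# re-factor a circular product string into a SegmentCycle by locating every
# unique segment sequence (or its reverse complement) in the doubled
# string. The two copies of a repeat share one sequence, so `useqs` carries
# one entry per repeat_id and the refactored cycle labels copies by their
# repeat_id (physical copies are indistinguishable).
refactor_cycle <- function(prod, useqs) {
  dd <- paste0(prod, prod)
  found <- list()
  for (id in names(useqs)) {
    s <- useqs[[id]]
    for (orient in c("+", "-")) {
      pat <- if (orient == "+") s else rc_chr(s)
      hits <- gregexpr(pat, dd, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      for (h in hits) {
        if (h <= nchar(prod)) {
          found[[length(found) + 1L]] <- list(id = id, pos = h, orient = orient)
        }
      }
    }
  }
  # a palindromic coincidence would double-report; unique on position
  found <- found[!duplicated(vapply(found, `[[`, 1L, "pos"))]
  found <- found[order(vapply(found, `[[`, 1L, "pos"))]
  mitorecomb::segment_cycle(vapply(found, `[[`, "", "id"),
                            vapply(found, `[[`, "", "orient"))
}

# relabel a cycle's repeat copies by their repeat_id for comparison with the
# oracle (copy identities are not physically observable)
relabel_by_repeat <- function(cyc, segments) {
  idx <- match(cyc$segment_id, segments$segment_id)
  ids <- ifelse(!is.na(segments$repeat_id[idx]), segments$repeat_id[idx],
                cyc$segment_id)
  mitorecomb::segment_cycle(ids, cyc$orient)
}

# full oracle: apply one event to a realized configuration, return product
# as a list of SegmentCycle (multiset, copies labelled by repeat_id)
oracle_apply_event <- function(cfg, repeat_id, seqs) {
  copy_ids <- cfg$segments$segment_id[!is.na(cfg$segments$repeat_id) &
                                        cfg$segments$repeat_id == repeat_id]
  rep_len <- nchar(seqs[[copy_ids[1L]]])
  strings <- lapply(cfg$cycles, mitorecomb::realize_cycle, seqs = seqs)
  occ <- do.call(rbind, lapply(seq_along(cfg$cycles), function(ci) {
    cyc <- cfg$cycles[[ci]]
    w <- which(cyc$segment_id %in% copy_ids)
    if (!length(w)) return(NULL)
    lens <- nchar(vapply(cyc$segment_id, function(id) seqs[[id]], ""))
    offs <- cumsum(c(0L, lens[-length(lens)]))
    data.frame(circle = ci, offset = offs[w], orient = cyc$orient[w],
               stringsAsFactors = FALSE)
  }))
  # one sequence entry per arc plus one per repeat_id
  segs <- cfg$segments
  useqs <- seqs[segs$segment_id[segs$kind == "unique_arc"]]
  for (rid in unique(stats::na.omit(segs$repeat_id))) {
    cid <- segs$segment_id[segs$repeat_id %in% rid][1L]
    useqs[[rid]] <- seqs[[cid]]
  }
  prods <- string_surgery(strings, occ, rep_len)
  lapply(prods, refactor_cycle, useqs = useqs)
}

# multiset equality of cycle lists via canonical strings
cycle_multiset_equal <- function(a, b) {
  ca <- sort(vapply(a, mitorecomb:::canonical_cycle_string, ""))
  cb <- sort(vapply(b, mitorecomb:::canonical_cycle_string, ""))
  identical(ca, cb)
}

# random configuration with <= 6 segments and one repeat with two copies
random_configuration <- function() {
  n_arcs <- sample(2:4, 1)
  arc_ids <- paste0("A", seq_len(n_arcs))
  segs <- mitorecomb::segment_table(
    segment_id = c(arc_ids, "Ra", "Rb"),
    length = c(sample(50:120, n_arcs, replace = TRUE), 40, 40),
    kind = c(rep("unique_arc", n_arcs), "repeat_copy", "repeat_copy"),
    repeat_id = c(rep(NA, n_arcs), "R", "R"))
  two_circles <- sample(c(TRUE, FALSE), 1)
  ror <- sample(c("+", "-"), 2, replace = TRUE)
  if (two_circles && n_arcs >= 2) {
    split_at <- sample(seq_len(n_arcs - 1L), 1)
    g1 <- arc_ids[seq_len(split_at)]; g2 <- arc_ids[-seq_len(split_at)]
    c1 <- c("Ra", g1); o1 <- c(ror[1], sample(c("+", "-"), length(g1), replace = TRUE))
    c2 <- c("Rb", g2); o2 <- c(ror[2], sample(c("+", "-"), length(g2), replace = TRUE))
    cycles <- list(mitorecomb::segment_cycle(c1, o1),
                   mitorecomb::segment_cycle(c2, o2))
  } else {
    pos2 <- sample(2:(n_arcs + 1L), 1)
    ids <- append(arc_ids, "Rb", after = pos2 - 1L)
    ids <- c("Ra", ids)
    ors <- sample(c("+", "-"), length(ids), replace = TRUE)
    ors[ids == "Ra"] <- ror[1]; ors[ids == "Rb"] <- ror[2]
    cycles <- list(mitorecomb::segment_cycle(ids, ors))
  }
  mitorecomb::genome_configuration("rand", cycles, segs)
}

# tiny annotated toy genome used by marker and framework tests
toy_two_exon_gene <- function(strand = "+", exon_len = 30L, intron_len = 50L,
                              seed = 42) {
  set.seed(seed)
  lead <- rnd_dna(20); e1 <- rnd_dna(exon_len); intr <- rnd_dna(intron_len)
  e2 <- rnd_dna(exon_len); tail <- rnd_dna(20)
  seqstr <- paste0(lead, e1, intr, e2, tail)
  g <- list(chrT = mitorecomb::circular_sequence("chrT", seqstr))
  s1 <- 21L; e1e <- s1 + exon_len - 1L
  s2 <- e1e + intron_len + 1L; e2e <- s2 + exon_len - 1L
  ranks <- if (strand == "+") c(1L, 2L) else c(2L, 1L)
  feats <- data.frame(
    seq_id = "chrT", feature_type = c("gene", "exon", "exon"),
    start = c(s1, s1, s2), end = c(e2e, e1e, e2e),
    strand = strand, gene_name = "toy",
    exon_rank = c(NA_integer_, ranks), stringsAsFactors = FALSE)
  list(genome = g, features = feats, intron_plus = intr,
       intron_iv = c(e1e + 1L, s2 - 1L))
}
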