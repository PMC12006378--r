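# Segment-cycle algebra of repeat-mediated homologous recombination.
#
# A genome configuration is a multiset of circular chromosomes, each a
# cyclically ordered list of oriented segments (unique arcs and repeat
# copies). A crossover within a repeat cuts both molecules inside the
# repeat and rejoins them with exchanged arms; both repeat copies persist.
# Consequences: copies on two different circles fuse them into one; copies
# on one circle in direct relative orientation fission it into two; copies
# on one circle in inverted relative orientation invert the arc between
# them. Total length is conserved in every case.

#' Define the segment universe of a configuration
#'
#' @param segment_id character vector of segment labels.
#' @param length integer vector of segment lengths (bp, > 0).
#' @param kind `"unique_arc"` or `"repeat_copy"`.
#' @param repeat_id repeat label for repeat copies, NA for arcs.
#' @return data.frame segment table.
#' @export
segment_table <- function(segment_id, length, kind, repeat_id = NA_character_) {
  stopifnot(all(length > 0), all(kind %in% c("unique_arc", "repeat_copy")))
  data.frame(segment_id = segment_id, length = as.numeric(length),
             kind = kind, repeat_id = repeat_id, stringsAsFactors = FALSE)
}

#' Create a segment cycle (one circular chromosome)
#'
#' @param segment_id character vector in cyclic order.
#' @param orient `"+"`/`"-"` per segment.
#' @return data.frame of class `SegmentCycle`.
#' @export
segment_cycle <- function(segment_id, orient = rep("+", length(segment_id))) {
  stopifnot(length(segment_id) >= 1L, all(orient %in% c("+", "-")),
            length(orient) == length(segment_id))
  structure(data.frame(segment_id = segment_id, orient = orient,
                       stringsAsFactors = FALSE),
            class = c("SegmentCycle", "data.frame"))
}

.cycle_strings <- function(cyc) paste0(cyc$segment_id, cyc$orient)

.rotations <- function(v) {
  n <- length(v)
  vapply(seq_len(n), function(r) paste(v[c(r:n, seq_len(r - 1L))], collapse = "|"), "")
}

.revflip <- function(cyc) {
  segment_cycle(rev(cyc$segment_id), rev(ifelse(cyc$orient == "+", "-", "+")))
}

canonical_cycle_string <- function(cyc) {
  f <- .rotations(.cycle_strings(cyc))
  r <- .rotations(.cycle_strings(.revflip(cyc)))
  sort(c(f, r))[1L]
}

#' Equality of segment cycles
#'
#' True iff the two cycles are equal up to rotation, or up to reversal with
#' all orientations flipped (a circle read on the other strand is the same
#' molecule).
#'
#' @param a,b `SegmentCycle` objects.
#' @return logical.
#' @export
cycles_equal <- function(a, b) {
  identical(canonical_cycle_string(a), canonical_cycle_string(b))
}

#' Create a genome configuration
#'
#' @param name configuration label (e.g. `"Mac1"`).
#' @param cycles list of `SegmentCycle`.
#' @param segments segment table from [segment_table()].
#' @return object of class `GenomeConfiguration`.
#' @export
genome_configuration <- function(name, cycles, segments) {
  stopifnot(length(cycles) >= 1L)
  used <- unlist(lapply(cycles, function(c) c$segment_id))
  missing <- setdiff(used, segments$segment_id)
  if (length(missing)) stop_input("segments not in table: %s", paste(missing, collapse = ","))
  rep_ids <- segments$repeat_id[match(used, segments$segment_id)]
  cnt <- table(rep_ids[!is.na(rep_ids)])
  if (any(cnt %% 2 != 0))
    stop_input("each repeat must occur an even number of times (got %s)",
               paste(names(cnt)[cnt %% 2 != 0], collapse = ","))
  structure(list(name = name, cycles = cycles, segments = segments),
            class = "GenomeConfiguration")
}

#' Total length of a configuration (bp)
#' @param cfg a `GenomeConfiguration`.
#' @return numeric total of all segment lengths over all cycles.
#' @export
configuration_length <- function(cfg) {
  sum(vapply(cfg$cycles, function(cyc) {
    sum(cfg$segments$length[match(cyc$segment_id, cfg$segments$segment_id)])
  }, numeric(1)))
}

#' Lengths of the individual chromosomes of a configuration
#' @param cfg a `GenomeConfiguration`.
#' @return numeric vector, one entry per circle.
#' @export
chromosome_lengths <- function(cfg) {
  vapply(cfg$cycles, function(cyc) {
    sum(cfg$segments$length[match(cyc$segment_id, cfg$segments$segment_id)])
  }, numeric(1))
}

# occurrences of the two copies of repeat_id: data.frame(cycle, pos, orient)
.find_copies <- function(cfg, repeat_id) {
  copy_ids <- cfg$segments$segment_id[!is.na(cfg$segments$repeat_id) &
                                        cfg$segments$repeat_id == repeat_id]
  occ <- do.call(rbind, lapply(seq_along(cfg$cycles), function(ci) {
    cyc <- cfg$cycles[[ci]]
    w <- which(cyc$segment_id %in% copy_ids)
    if (!length(w)) return(NULL)
    data.frame(cycle = ci, pos = w, orient = cyc$orient[w], stringsAsFactors = FALSE)
  }))
  if (is.null(occ) || nrow(occ) != 2L)
    stop_classed("event_error",
                 "repeat '%s' must occur exactly twice in the configuration", repeat_id)
  occ
}

.rotate_cycle <- function(cyc, k) {
  n <- nrow(cyc)
  idx <- c(k:n, seq_len(k - 1L))
  segment_cycle(cyc$segment_id[idx], cyc$orient[idx])
}

#' Apply one repeat-mediated recombination event
#'
#' Performs the crossover within the named repeat. Copies on two different
#' circles fuse them; copies on one circle fission it (direct relative
#' orientation) or invert the intervening arc (inverted relative
#' orientation). Both repeat copies persist and total length is conserved.
#'
#' @param cfg a `GenomeConfiguration`.
#' @param repeat_id the mediating repeat.
#' @param name name for the product configuration.
#' @return a new `GenomeConfiguration`.
#' @export
apply_event <- function(cfg, repeat_id, name = paste0(cfg$name, "x", repeat_id)) {
  occ <- .find_copies(cfg, repeat_id)
  cycles <- cfg$cycles
  if (occ$cycle[1L] != occ$cycle[2L]) {
    c1 <- cycles[[occ$cycle[1L]]]; c2 <- cycles[[occ$cycle[2L]]]
    p1 <- occ$pos[1L]; p2 <- occ$pos[2L]
    if (occ$orient[1L] != occ$orient[2L]) {
      # read the second circle on the other strand so the copies match
      c2 <- .revflip(c2)
      p2 <- nrow(c2) - p2 + 1L
    }
    a <- .rotate_cycle(c1, p1)
    b <- .rotate_cycle(c2, p2)
    fused <- segment_cycle(c(a$segment_id, b$segment_id), c(a$orient, b$orient))
    keep <- setdiff(seq_along(cycles), occ$cycle)
    new_cycles <- c(cycles[keep], list(fused))
  } else {
    cyc <- .rotate_cycle(cycles[[occ$cycle[1L]]], min(occ$pos))
    q <- abs(occ$pos[2L] - occ$pos[1L]) + 1L   # position of second copy after rotation
    n <- nrow(cyc)
    if (cyc$orient[1L] == cyc$orient[q]) {
      # direct relative orientation: fission into two circles
      left <- segment_cycle(cyc$segment_id[seq_len(q - 1L)], cyc$orient[seq_len(q - 1L)])
      right <- segment_cycle(cyc$segment_id[q:n], cyc$orient[q:n])
      keep <- setdiff(seq_along(cycles), occ$cycle[1L])
      new_cycles <- c(cycles[keep], list(left, right))
    } else {
      # inverted relative orientation: invert the arc between the copies
      if (q > 2L) {
        mid <- 2L:(q - 1L)
        inv_id <- rev(cyc$segment_id[mid])
        inv_or <- rev(ifelse(cyc$orient[mid] == "+", "-", "+"))
      } else {
        inv_id <- character(); inv_or <- character()
      }
      tail_idx <- if (q < n) (q + 1L):n else integer()
      new_cyc <- segment_cycle(
        c(cyc$segment_id[1L], inv_id, cyc$segment_id[q], cyc$segment_id[tail_idx]),
        c(cyc$orient[1L], inv_or, cyc$orient[q], cyc$orient[tail_idx]))
      keep <- setdiff(seq_along(cycles), occ$cycle[1L])
      new_cycles <- c(cycles[keep], list(new_cyc))
    }
  }
  genome_configuration(name, new_cycles, cfg$segments)
}

#' Enumerate the recombination products of all repeat subsets
#'
#' For every non-empty subset of `repeat_ids`, events are applied
#' sequentially in ascending repeat rank (the order is recorded; for some
#' repeat sets the outcome can depend on it). Subsets are enumerated by
#' increasing size, then lexicographically, and products are named Mic1,
#' Mic2, ... in that order, mirroring the conventional presentation of the
#' seven products of a three-repeat system.
#'
#' @param baseline the major configuration (`GenomeConfiguration`).
#' @param repeat_ids character vector of mediating repeats present in the
#'   baseline.
#' @return list with `products` (named list of `GenomeConfiguration`) and
#'   `summary` data.frame (`subset`, `name`, `order_applied`,
#'   `n_chromosomes`, `chromosome_lengths`, `cycle_notation`).
#' @export
enumerate_products <- function(baseline, repeat_ids) {
  if (!length(repeat_ids)) {
    return(list(products = list(),
                summary = data.frame(subset = character(), name = character(),
                                     order_applied = character(),
                                     n_chromosomes = integer(),
                                     chromosome_lengths = character(),
                                     cycle_notation = character(),
                                     stringsAsFactors = FALSE)))
  }
  repeat_ids <- sort(repeat_ids)
  k <- length(repeat_ids)
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(repeat_ids, m, simplify = FALSE)), recursive = FALSE)
  products <- list(); rows <- list()
  for (s in seq_along(subsets)) {
    sub <- subsets[[s]]
    nm <- paste0("Mic", s)
    cfg <- baseline
    for (r in sub) cfg <- apply_event(cfg, r)
    cfg$name <- nm
    products[[nm]] <- cfg
    rows[[s]] <- data.frame(
      subset = paste(sub, collapse = "+"), name = nm,
      order_applied = paste(sub, collapse = ">"),
      n_chromosomes = length(cfg$cycles),
      chromosome_lengths = paste(chromosome_lengths(cfg), collapse = ","),
      cycle_notation = paste(vapply(cfg$cycles, function(cyc)
        paste(.cycle_strings(cyc), collapse = " "), ""), collapse = " | "),
      stringsAsFactors = FALSE)
  }
  list(products = products, summary = do.call(rbind, rows))
}

#' Realize a segment cycle as a concrete circular sequence
#'
#' Concatenates each segment's sequence (reverse-complemented for `-`
#' orientation) in cycle order.
#'
#' @param cyc a `SegmentCycle`.
#' @param seqs named character vector of segment sequences.
#' @return the circular chromosome's plus-strand string (rotation arbitrary).
#' @export
realize_cycle <- function(cyc, seqs) {
  parts <- vapply(seq_len(nrow(cyc)), function(i) {
    s <- seqs[[cyc$segment_id[i]]]
    if (cyc$orient[i] == "-") reverse_complement(s) else s
  }, "")
  paste(parts, collapse = "")
}

#' Two-chromosome baseline configuration of the study system
#'
#' Builds the major configuration of a two-chromosome mitogenome
#' (182,239 bp + 165,055 bp) carrying one copy of each of three
#' recombinogenic repeats per chromosome: R01 (13,331 bp, direct),
#' R04 (1,928 bp, inverted) and R07 (123 bp, direct), placed in the order
#' observed on the assembled chromosomes. Arc lengths are derived from the
#' published repeat coordinates so that total length is exactly
#' 347,294 bp.
#'
#' @return a `GenomeConfiguration` named `"Mac1"` with two cycles.
#' @export
mac1_configuration <- function() {
  # chromosome 1 (182,239 bp): R04 ~62,558, R01 67,353-80,683, R07 170,622-170,744
  # chromosome 2 (165,055 bp): R07 ~1,118, R01 91,656-104,986, R04 ~155,800 (minus)
  r01 <- 13331; r04 <- 1928; r07 <- 123
  a1 <- 62557                 # chr1 origin .. R04
  a2 <- 67353 - (62558 + r04) # R04 .. R01
  a3 <- 170622 - (80683 + 1)  # R01 .. R07
  a4 <- 182239 - 170744       # R07 .. origin wrap
  u1 <- a1 + a4               # single arc R07 -> R04 through the origin
  b1 <- 1117                  # chr2 origin .. R07
  b2 <- 91656 - (1240 + 1)    # R07 .. R01
  b3 <- 155800 - (104986 + 1) # R01 .. R04
  b4 <- 165055 - (155800 + r04 - 1)
  v1 <- b1 + b4
  segs <- segment_table(
    segment_id = c("u1", "u2", "u3", "v1", "v2", "v3",
                   "R01a", "R01b", "R04a", "R04b", "R07a", "R07b"),
    length = c(u1, a2, a3, v1, b2, b3, r01, r01, r04, r04, r07, r07),
    kind = c(rep("unique_arc", 6), rep("repeat_copy", 6)),
    repeat_id = c(rep(NA, 6), "R01", "R01", "R04", "R04", "R07", "R07"))
  mc1 <- segment_cycle(c("u1", "R04a", "u2", "R01a", "u3", "R07a"))
  mc2 <- segment_cycle(c("v1", "R07b", "v2", "R01b", "v3", "R04b"),
                       c("+", "+", "+", "+", "+", "-"))
  genome_configuration("Mac1", list(mc1, mc2), segs)
}
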