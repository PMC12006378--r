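# Dispersed repeat discovery on circular multichromosomal genomes, plus
# SSR detection with the conventional microsatellite unit-length thresholds.
#
# Dispersed repeats are found as maximal exact matches (seed-and-extend with
# word size = min_len), within and between chromosomes, in both relative
# orientations. Circularity is handled by scanning doubled sequences and
# de-duplicating matches that are rotations of one another. Because matches
# are exact their identity is 1.0; `min_identity` is validated and recorded
# so downstream consumers can recompute/verify it.

# all maximal exact matches of length >= k between linear strings a and b.
# Returns data.frame(start1, end1, start2, end2, len). If `same` is TRUE the
# self-diagonal family (diagonals that are multiples of `period`) is skipped.
maximal_exact_matches <- function(a, b, k, same = FALSE, period = 0L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(data.frame(start1 = integer(), end1 = integer(),
                                          start2 = integer(), end2 = integer(),
                                          len = integer()))
  pa <- seq_len(na - k + 1L); ka <- substring(a, pa, pa + k - 1L)
  pb <- seq_len(nb - k + 1L); kb <- substring(b, pb, pb + k - 1L)
  fa <- split(pa, ka); fb <- split(pb, kb)
  common <- intersect(names(fa), names(fb))
  if (!length(common)) return(data.frame(start1 = integer(), end1 = integer(),
                                         start2 = integer(), end2 = integer(),
                                         len = integer()))
  ga <- fa[common]; gb <- fb[common]
  la <- lengths(ga); lb <- lengths(gb)
  # cross product per shared k-mer, fully vectorised
  ii <- rep(unlist(ga, use.names = FALSE), times = rep(lb, times = la))
  jj <- unlist(gb[rep(seq_along(common), la)], use.names = FALSE)
  d <- jj - ii
  if (same) {
    drop <- if (period > 0L) (d %% period) == 0L else d == 0L
    ii <- ii[!drop]; jj <- jj[!drop]; d <- d[!drop]
  }
  if (!length(ii)) return(data.frame(start1 = integer(), end1 = integer(),
                                     start2 = integer(), end2 = integer(),
                                     len = integer()))
  o <- order(d, ii)
  ii <- ii[o]; jj <- jj[o]; d <- d[o]
  res <- vector("list", 64L); nres <- 0L
  cur_d <- NA_integer_; reach <- -1L
  ext_right <- function(i, j) {
    # longest e with a[i..i+e-1] == b[j..j+e-1]; chunked comparison
    e <- 0L; step <- 256L
    repeat {
      while (i + e + step - 1L <= na && j + e + step - 1L <= nb &&
             substr(a, i + e, i + e + step - 1L) == substr(b, j + e, j + e + step - 1L))
        e <- e + step
      if (step == 1L) break
      step <- max(1L, step %/% 8L)
    }
    e
  }
  ext_left <- function(i, j) {
    e <- 0L
    while (i - e - 1L >= 1L && j - e - 1L >= 1L &&
           substr(a, i - e - 1L, i - e - 1L) == substr(b, j - e - 1L, j - e - 1L))
      e <- e + 1L
    e
  }
  for (t in seq_along(ii)) {
    if (!identical(d[t], cur_d)) { cur_d <- d[t]; reach <- -1L }
    i <- ii[t]
    if (i <= reach) next
    j <- jj[t]
    el <- ext_left(i, j)
    er <- ext_right(i, j)              # includes the seed itself
    s1 <- i - el; len <- el + er
    if (len >= k) {
      nres <- nres + 1L
      if (nres > length(res)) res <- c(res, vector("list", length(res)))
      res[[nres]] <- c(s1, s1 + len - 1L, j - el, j - el + len - 1L, len)
    }
    reach <- s1 + len - 1L
  }
  if (!nres) return(data.frame(start1 = integer(), end1 = integer(),
                               start2 = integer(), end2 = integer(),
                               len = integer()))
  m <- do.call(rbind, res[seq_len(nres)])
  data.frame(start1 = m[, 1], end1 = m[, 2], start2 = m[, 3], end2 = m[, 4],
             len = m[, 5])
}

# map a match interval on a doubled circular string back onto the circle;
# returns list(start, end, wraps) or NULL if it is the redundant second copy
circ_canonical <- function(s, e, L) {
  len <- e - s + 1L
  if (len > L) { e <- s + L - 1L; len <- L }   # cannot exceed one full turn
  if (s > L) { s <- s - L; e <- e - L }
  if (s > L) return(NULL)
  if (e > L) list(start = s, end = e - L, wraps = TRUE)
  else list(start = s, end = e, wraps = FALSE)
}

#' Find dispersed repeat pairs in a circular multichromosomal genome
#'
#' Seed-and-extend discovery of maximal exact repeated pairs, within and
#' between chromosomes, in both relative orientations (direct and inverted).
#' Self-trivial matches are excluded, as are pairs whose two copies overlap
#' on the same molecule. Pairs are ranked by decreasing core length (ties by
#' coordinates) and numbered R01, R02, ...
#'
#' @param genome named list of `CircularSequence`.
#' @param min_len minimum repeat core length in bp (>= 20; default 50).
#' @param min_identity minimum identity in (0.8, 1]; matches are exact so
#'   reported identity is always 1.0, the threshold is recorded for
#'   downstream verification.
#' @return data.frame with columns `repeat_id`, `chrom1`, `start1`, `end1`,
#'   `strand1`, `wraps1`, `chrom2`, `start2`, `end2`, `strand2`, `wraps2`,
#'   `core_length`, `identity`, `orientation`.
#' @export
find_dispersed_repeats <- function(genome, min_len = 50, min_identity = 0.99) {
  if (length(genome) == 0L) stop_input("empty genome")
  stopifnot(min_len >= 20, min_identity > 0.8, min_identity <= 1)
  min_len <- as.integer(min_len)
  ids <- vapply(genome, function(x) x$id, "")
  seqs <- vapply(genome, function(x) x$residues, "")
  lens <- vapply(genome, function(x) x$length, 1L)
  circ <- vapply(genome, function(x) x$circular, TRUE)
  scan <- ifelse(circ, paste0(seqs, seqs), seqs)

  rows <- list()
  add_pair <- function(c1, s1, e1, w1, c2, s2, e2, w2, strand2, len, orient) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom1 = c1, start1 = s1, end1 = e1, strand1 = "+", wraps1 = w1,
      chrom2 = c2, start2 = s2, end2 = e2, strand2 = strand2, wraps2 = w2,
      core_length = len, identity = 1.0, orientation = orient,
      stringsAsFactors = FALSE)
  }

  for (i in seq_along(genome)) for (j in i:length(genome)) {
    Li <- lens[i]; Lj <- lens[j]
    ## direct orientation
    mm <- maximal_exact_matches(scan[i], scan[j], min_len,
                                same = (i == j), period = if (i == j) Li else 0L)
    if (nrow(mm)) for (t in seq_len(nrow(mm))) {
      a <- circ_canonical(mm$start1[t], mm$end1[t], Li)
      b <- circ_canonical(mm$start2[t], mm$end2[t], Lj)
      if (is.null(a) || is.null(b)) next
      len <- min(mm$len[t], Li, Lj)
      if (i == j) {
        # canonical copy order, drop overlapping copies
        p1 <- circ_positions(a$start, a$end, Li, a$wraps)
        p2 <- circ_positions(b$start, b$end, Lj, b$wraps)
        if (length(intersect(p1, p2))) next
        if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
      }
      add_pair(ids[i], a$start, a$end, a$wraps,
               ids[j], b$start, b$end, b$wraps, "+", len, "direct")
    }
    ## inverted orientation: compare against the reverse complement
    rcj <- reverse_complement(scan[j])
    mm <- maximal_exact_matches(scan[i], rcj, min_len, same = FALSE)
    if (nrow(mm)) for (t in seq_len(nrow(mm))) {
      nj <- nchar(rcj)
      # map coordinates on rc back to the plus strand of the doubled string
      s2 <- nj - mm$end2[t] + 1L; e2 <- nj - mm$start2[t] + 1L
      a <- circ_canonical(mm$start1[t], mm$end1[t], Li)
      b <- circ_canonical(s2, e2, Lj)
      if (is.null(a) || is.null(b)) next
      len <- min(mm$len[t], Li, Lj)
      if (i == j) {
        p1 <- circ_positions(a$start, a$end, Li, a$wraps)
        p2 <- circ_positions(b$start, b$end, Lj, b$wraps)
        if (length(intersect(p1, p2))) next   # palindromic self-overlap
        if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
      }
      add_pair(ids[i], a$start, a$end, a$wraps,
               ids[j], b$start, b$end, b$wraps, "-", len, "inverted")
    }
  }

  if (!length(rows)) {
    out <- data.frame(repeat_id = character(), chrom1 = character(),
                      start1 = integer(), end1 = integer(), strand1 = character(),
                      wraps1 = logical(), chrom2 = character(), start2 = integer(),
                      end2 = integer(), strand2 = character(), wraps2 = logical(),
                      core_length = integer(), identity = numeric(),
                      orientation = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  key <- with(out, paste(chrom1, start1, end1, chrom2, start2, end2, orientation))
  out <- out[!duplicated(key), , drop = FALSE]
  # inverted same-molecule pairs are found twice (once from each copy's rc)
  same_inv <- out$chrom1 == out$chrom2 & out$orientation == "inverted"
  key2 <- with(out, paste(chrom1, pmin(start1, start2), pmax(start1, start2),
                          chrom2, core_length, orientation))
  out <- out[!(same_inv & duplicated(key2)), , drop = FALSE]
  # suppress pairs contained in a longer pair on the circle (fragments of a
  # wrap-crossing match surface separately at the scan-string boundaries)
  if (nrow(out) > 1L) {
    Ls <- stats::setNames(lens, ids)
    posset <- function(chrom, s, e, w)
      paste0(chrom, ":", circ_positions(s, e, Ls[[chrom]], w))
    p1 <- lapply(seq_len(nrow(out)), function(i)
      posset(out$chrom1[i], out$start1[i], out$end1[i], out$wraps1[i]))
    p2 <- lapply(seq_len(nrow(out)), function(i)
      posset(out$chrom2[i], out$start2[i], out$end2[i], out$wraps2[i]))
    o <- order(-out$core_length)
    drop <- logical(nrow(out))
    for (a in seq_along(o)) for (b in seq_along(o)) {
      if (a >= b) next
      i <- o[a]; j <- o[b]
      if (drop[i] || out$orientation[i] != out$orientation[j]) next
      if ((all(p1[[j]] %in% p1[[i]]) && all(p2[[j]] %in% p2[[i]])) ||
          (all(p1[[j]] %in% p2[[i]]) && all(p2[[j]] %in% p1[[i]])))
        drop[j] <- TRUE
    }
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(-out$core_length, out$chrom1, out$start1, out$chrom2, out$start2), ,
             drop = FALSE]
  out$repeat_id <- sprintf("R%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("repeat_id", setdiff(names(out), "repeat_id"))]
}

#' Default SSR unit-length thresholds
#'
#' Minimum tandem copy number per motif unit length: 10 for mono-, 5 for
#' di-, 4 for trinucleotide motifs and 3 for tetra-, penta- and
#' hexanucleotide motifs.
#'
#' @return named integer vector (names "1".."6").
#' @export
default_ssr_thresholds <- function() {
  c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
}

# lexicographically minimal rotation of a motif
canonical_motif <- function(m) {
  u <- nchar(m)
  if (u == 1L) return(m)
  rots <- vapply(seq_len(u), function(r) paste0(substr(m, r, u), substr(m, 1L, r - 1L)), "")
  sort(rots)[1L]
}

# TRUE if motif is a whole-number repetition of a shorter unit
is_primitive_motif <- function(m) {
  u <- nchar(m)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && m == strrep(substr(m, 1L, d), u %/% d)) return(FALSE)
  }
  TRUE
}

#' Find simple sequence repeats (SSRs)
#'
#' Maximal perfect tandem runs of 1-6 bp motifs meeting the per-unit-length
#' copy threshold. Motifs are reported in canonical form (lexicographically
#' minimal rotation on the plus strand); strand is not canonicalised.
#' Overlapping candidate runs are resolved greedily by decreasing run length
#' so no two reported SSRs overlap; compound SSRs are not merged.
#'
#' @param genome named list of `CircularSequence`.
#' @param thresholds named integer vector mapping unit length ("1".."6") to
#'   minimum copy number; see [default_ssr_thresholds()].
#' @return data.frame with columns `chrom`, `start`, `end`, `wraps`,
#'   `motif`, `unit_length`, `copies`.
#' @export
find_ssrs <- function(genome, thresholds = default_ssr_thresholds()) {
  if (length(genome) == 0L) stop_input("empty genome")
  stopifnot(all(as.character(1:6) %in% names(thresholds)))
  out <- list()
  for (g in genome) {
    L <- g$length
    s2 <- if (g$circular) paste0(g$residues, g$residues) else g$residues
    n2 <- nchar(s2)
    cands <- list()
    for (u in 1:6) {
      m <- as.integer(thresholds[[as.character(u)]])
      if (L < u * m) next
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, m - 1L)
      hits <- gregexpr(pat, s2, perl = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      for (h in seq_along(hits)) {
        p <- hits[h]; len <- attr(hits, "match.length")[h]
        e <- p + len - 1L
        # extend to the maximal perfect run in this phase
        while (p > 1L && substr(s2, p - 1L, p - 1L) == substr(s2, p + u - 1L, p + u - 1L))
          p <- p - 1L
        while (e < n2 && substr(s2, e + 1L, e + 1L) == substr(s2, e + 1L - u, e + 1L - u))
          e <- e + 1L
        copies <- (e - p + 1L) %/% u
        if (copies < m) next
        e <- p + copies * u - 1L          # whole units only
        motif_raw <- substr(s2, p, p + u - 1L)
        if (!is_primitive_motif(motif_raw)) next
        if (p > L) next                    # duplicate from doubling
        if (e - p + 1L > L) next           # cannot exceed one full turn
        cands[[length(cands) + 1L]] <- data.frame(
          chrom = g$id, start = p, end = if (e > L) e - L else e,
          wraps = e > L, motif = canonical_motif(motif_raw),
          unit_length = u, copies = copies, run_len = copies * u,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(cands)) next
    cand <- do.call(rbind, cands)
    cand <- cand[!duplicated(paste(cand$start, cand$unit_length)), , drop = FALSE]
    # greedy non-overlap resolution, longest runs first
    cand <- cand[order(-cand$run_len, cand$start, cand$unit_length), , drop = FALSE]
    covered <- logical(L)
    keep <- logical(nrow(cand))
    for (t in seq_len(nrow(cand))) {
      pos <- ((cand$start[t] - 1L):(cand$start[t] + cand$run_len[t] - 2L)) %% L + 1L
      if (!any(covered[pos])) { keep[t] <- TRUE; covered[pos] <- TRUE }
    }
    cand <- cand[keep, , drop = FALSE]
    out[[length(out) + 1L]] <- cand
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      wraps = logical(), motif = character(),
                      unit_length = integer(), copies = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "wraps", "motif", "unit_length", "copies")]
}
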