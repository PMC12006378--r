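# Spanning-read classification against the four configuration references and
# the recombination-frequency statistic.
#
# A read supports configuration ci iff it (or its reverse complement) aligns
# across the entire repeat core and reaches at least `min_flank_anchor` bp
# into both flanks at >= `min_identity`, and ci is the unique best-scoring
# qualifying configuration. Classification uses an internal seeded/windowed
# semi-global aligner (Biostrings dynamic programming restricted to the
# junction neighbourhoods), so no external mapper is needed; any semi-global
# aligner reporting coverage and identity satisfies the same contract.

#' Spanning-support criterion
#'
#' @param min_flank_anchor bp the alignment must reach into each flank
#'   beyond the core (default 100).
#' @param min_identity minimum alignment identity (default 0.80).
#' @param require_unique_best if TRUE (default) score ties between
#'   qualifying configurations yield `unassigned`.
#' @param flank_window bp of flank adjacent to the core junction used when
#'   scoring flank identity (capped at the configuration's flank length;
#'   always at least `min_flank_anchor`). Window scoring is what makes
#'   classification fast; flanks identical throughout the window tie and
#'   fall to `unassigned`, which is conservative.
#' @return object of class `SpanningCriterion`.
#' @export
spanning_criterion <- function(min_flank_anchor = 100, min_identity = 0.80,
                               require_unique_best = TRUE, flank_window = 500) {
  stopifnot(min_flank_anchor >= 1, min_identity > 0, min_identity <= 1)
  structure(list(min_flank_anchor = as.integer(min_flank_anchor),
                 min_identity = min_identity,
                 require_unique_best = isTRUE(require_unique_best),
                 flank_window = max(as.integer(flank_window),
                                    as.integer(min_flank_anchor))),
            class = "SpanningCriterion")
}

# substitution matrix treating N as a universal mismatch (N never counts as
# a match in identity computations)
.sub_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
      m["N", ] <- -1; m[, "N"] <- -1
      cache <<- m
    }
    cache
  }
})

# diagonal estimate of where `pattern` sits inside `read` from shared k-mers;
# returns NA if no seed matches
.seed_diagonal <- function(pattern, read, k = 13L, stride = 3L) {
  np <- nchar(pattern); nr <- nchar(read)
  if (np < k || nr < k) return(NA_integer_)
  pp <- seq(1L, np - k + 1L, by = stride)
  kp <- substring(pattern, pp, pp + k - 1L)
  pr <- seq_len(nr - k + 1L)
  kr <- substring(read, pr, pr + k - 1L)
  idx <- split(pr, kr)
  hit <- kp %in% names(idx)
  if (!any(hit)) return(NA_integer_)
  diffs <- unlist(Map(function(kmer, p) idx[[kmer]] - p, kp[hit], pp[hit]),
                  use.names = FALSE)
  as.integer(stats::median(diffs))
}

# count of shared k-mers, used for cheap orientation selection
.kmer_votes <- function(a, b, k = 13L, stride = 5L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(0L)
  pa <- seq(1L, na - k + 1L, by = stride)
  ka <- substring(a, pa, pa + k - 1L)
  pb <- seq_len(nb - k + 1L)
  kb <- unique(substring(b, pb, pb + k - 1L))
  sum(ka %in% kb)
}

# align `core` within `read` near estimated diagonal; returns list(score,
# nmatch, identity, read_start, read_end) or NULL
.align_core <- function(core, read, diag_est) {
  ncore <- nchar(core); nread <- nchar(read)
  slack <- max(50L, ncore %/% 10L)
  if (is.na(diag_est)) { win_s <- 1L; win_e <- nread }
  else {
    win_s <- max(1L, diag_est + 1L - slack)
    win_e <- min(nread, diag_est + ncore + slack)
  }
  if (win_e - win_s + 1L < ncore * 0.5) return(NULL)
  sub <- substr(read, win_s, win_e)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(core), Biostrings::DNAString(sub),
    type = "global-local", substitutionMatrix = .sub_matrix(),
    gapOpening = 2, gapExtension = 1)
  nm <- Biostrings::nmatch(al)
  list(score = Biostrings::score(al), nmatch = nm,
       identity = nm / Biostrings::nchar(al),
       read_start = win_s + IRanges::start(Biostrings::subject(al)) - 1L,
       read_end = win_s + IRanges::end(Biostrings::subject(al)) - 1L)
}

# junction-anchored alignment of a read tail against a flank window.
# `read_part` and `flank_part` are both given junction-first (i.e. already
# reversed for the left side). Returns list(score, coverage, identity).
.align_flank <- function(read_part, flank_part) {
  if (nchar(read_part) == 0L || nchar(flank_part) == 0L)
    return(list(score = -Inf, coverage = 0L, identity = 0))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read_part), Biostrings::DNAString(flank_part),
    type = "overlap", substitutionMatrix = .sub_matrix(),
    gapOpening = 2, gapExtension = 1)
  ps <- IRanges::start(Biostrings::pattern(al))
  ss <- IRanges::start(Biostrings::subject(al))
  # anchored at the junction: the optimal ends-free path must begin at (or
  # within a few error-trimmed bases of) the junction ends of both strings
  if (ps > 10L || ss > 10L) return(list(score = -Inf, coverage = 0L, identity = 0))
  nm <- Biostrings::nmatch(al)
  wid <- Biostrings::nchar(al)
  list(score = Biostrings::score(al),
       coverage = IRanges::end(Biostrings::subject(al)),
       identity = if (wid > 0) nm / wid else 0)
}

.revstr <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")

# classify one oriented read; returns list(label, score) with label NA if no
# configuration qualifies
.classify_oriented <- function(read, cfg, crit) {
  w <- min(crit$flank_window, cfg$flank_len)
  core <- cfg$core
  d <- .seed_diagonal(core, read)
  ca <- .align_core(core, read, d)
  if (is.null(ca) || ca$identity < crit$min_identity) return(NULL)
  read_left <- substr(read, 1L, ca$read_start - 1L)
  read_right <- substr(read, ca$read_end + 1L, nchar(read))
  slack <- ceiling(w * 0.25) + 10L
  rl <- .revstr(substr(read_left, max(1L, nchar(read_left) - (w + slack) + 1L),
                       nchar(read_left)))
  rr <- substr(read_right, 1L, min(nchar(read_right), w + slack))

  fl <- list(copy1 = .revstr(substr(cfg$flanks$left1, cfg$flank_len - w + 1L, cfg$flank_len)),
             copy2 = .revstr(substr(cfg$flanks$left2, cfg$flank_len - w + 1L, cfg$flank_len)))
  fr <- list(copy1 = substr(cfg$flanks$right1, 1L, w),
             copy2 = substr(cfg$flanks$right2, 1L, w))
  aL <- lapply(fl, function(f) .align_flank(rl, f))
  aR <- lapply(fr, function(f) .align_flank(rr, f))
  ok <- function(a) a$coverage >= crit$min_flank_anchor && a$identity >= crit$min_identity

  combos <- list(c1 = c("copy1", "copy1"), c2 = c("copy2", "copy2"),
                 c3 = c("copy1", "copy2"), c4 = c("copy2", "copy1"))
  scores <- vapply(combos, function(co) {
    l <- aL[[co[1L]]]; r <- aR[[co[2L]]]
    if (!ok(l) || !ok(r)) return(NA_real_)
    ca$score + l$score + r$score
  }, numeric(1))
  if (all(is.na(scores))) return(NULL)
  best <- max(scores, na.rm = TRUE)
  winners <- names(scores)[!is.na(scores) & scores == best]
  if (length(winners) > 1L && crit$require_unique_best) return(list(label = NA_character_, score = best))
  list(label = winners[1L], score = best)
}

#' Classify a long read against the four configuration references
#'
#' @param read residue string (the read; its reverse complement is also
#'   considered).
#' @param cfg a `ConfigurationSet` from [build_configurations()].
#' @param crit a `SpanningCriterion`.
#' @return one of `"c1"`, `"c2"`, `"c3"`, `"c4"`, `"unassigned"`.
#' @export
classify_read <- function(read, cfg, crit = spanning_criterion()) {
  read <- toupper(as.character(read))
  if (nchar(read) == 0L) stop_input("empty read")
  if (crit$min_flank_anchor > cfg$flank_len)
    stop_input("min_flank_anchor (%d) exceeds flank_len (%d)",
               crit$min_flank_anchor, cfg$flank_len)
  rc <- reverse_complement(read)
  vf <- .kmer_votes(read, cfg$sequences$c1)
  vr <- .kmer_votes(rc, cfg$sequences$c1)
  if (vf == 0L && vr == 0L) return("unassigned")
  cands <- if (vf >= 4L * max(vr, 1L)) list(read)
           else if (vr >= 4L * max(vf, 1L)) list(rc)
           else list(read, rc)
  results <- Filter(Negate(is.null),
                    lapply(cands, .classify_oriented, cfg = cfg, crit = crit))
  if (!length(results)) return("unassigned")
  best <- results[[which.max(vapply(results, `[[`, 0, "score"))]]
  if (is.na(best$label)) "unassigned" else best$label
}

#' Count spanning support for each configuration
#'
#' @param reads character vector of read sequences (names kept if present).
#' @param cfg a `ConfigurationSet`.
#' @param crit a `SpanningCriterion`.
#' @return object of class `SupportCounts`: list with `repeat_id`, `n1`..
#'   `n4`, `n_unassigned`, and the per-read `labels` vector.
#' @export
count_support <- function(reads, cfg, crit = spanning_criterion()) {
  labels <- vapply(reads, classify_read, "", cfg = cfg, crit = crit,
                   USE.NAMES = FALSE)
  structure(list(repeat_id = cfg$repeat_id,
                 n1 = sum(labels == "c1"), n2 = sum(labels == "c2"),
                 n3 = sum(labels == "c3"), n4 = sum(labels == "c4"),
                 n_unassigned = sum(labels == "unassigned"),
                 labels = labels),
            class = "SupportCounts")
}

#' Bundle four configuration counts into a `SupportCounts` object
#'
#' Convenience constructor for working directly from reported count tables.
#'
#' @param n1,n2,n3,n4 spanning-read counts for c1..c4.
#' @param repeat_id optional label.
#' @param n_unassigned reads failing the spanning criterion.
#' @return object of class `SupportCounts`.
#' @export
support_counts <- function(n1, n2, n3, n4, repeat_id = NA_character_,
                           n_unassigned = 0L) {
  stopifnot(n1 >= 0, n2 >= 0, n3 >= 0, n4 >= 0, n_unassigned >= 0)
  structure(list(repeat_id = repeat_id, n1 = as.integer(n1), n2 = as.integer(n2),
                 n3 = as.integer(n3), n4 = as.integer(n4),
                 n_unassigned = as.integer(n_unassigned), labels = NULL),
            class = "SupportCounts")
}

#' Recombination frequency from spanning-support counts
#'
#' The statistic is pair-based: the parental pair (c1+c2) is compared with
#' the recombinant pair (c3+c4) and the frequency is the minority pair's
#' share of all classified reads, as a percentage rounded half-up to two
#' decimals. Unassigned reads are excluded from the denominator. The value
#' is at most 50 by construction and symmetric under exchanging the two
#' pairs.
#'
#' @param counts a `SupportCounts` object (or anything with fields
#'   `n1`..`n4`).
#' @return object of class `RecombFrequency`: list with `repeat_id`,
#'   `percent`, `minority_pair` (`"parental"` or `"recombinant"`),
#'   `parental`, `recombinant`, `total`.
#' @export
recombination_frequency <- function(counts) {
  n <- c(counts$n1, counts$n2, counts$n3, counts$n4)
  if (sum(n) == 0)
    stop_classed("undefined_statistic",
                 "no classified reads: recombination frequency undefined")
  parental <- counts$n1 + counts$n2
  recombinant <- counts$n3 + counts$n4
  total <- parental + recombinant
  minority <- min(parental, recombinant)
  structure(list(repeat_id = counts$repeat_id,
                 percent = round_half_up(100 * minority / total, 2),
                 minority_pair = if (recombinant <= parental) "recombinant" else "parental",
                 parental = parental, recombinant = recombinant, total = total),
            class = "RecombFrequency")
}

#' @export
print.RecombFrequency <- function(x, ...) {
  cat(sprintf("<RecombFrequency> %s: %.2f%% (minority=%s; parental=%d, recombinant=%d)\n",
              x$repeat_id %||% "?", x$percent, x$minority_pair, x$parental,
              x$recombinant))
  invisible(x)
}

#' Spanning filter over pre-computed alignments
#'
#' Accepts alignments of reads against a 4-record configuration reference
#' (e.g. parsed from a mapper's output) and applies only the spanning filter
#' and unique-best rule: an alignment spans iff it starts at or before
#' `flank_len - min_flank_anchor + 1`, ends at or after
#' `flank_len + core_length + min_flank_anchor`, and has identity >=
#' `min_identity`.
#'
#' @param alignments data.frame with columns `read_id`, `configuration`
#'   (one of c1..c4), `ref_start`, `ref_end` (1-based on the configuration
#'   reference), `identity` (fraction).
#' @param cfg a `ConfigurationSet`.
#' @param crit a `SpanningCriterion`.
#' @return object of class `SupportCounts`.
#' @export
support_from_alignments <- function(alignments, cfg, crit = spanning_criterion()) {
  need <- c("read_id", "configuration", "ref_start", "ref_end", "identity")
  stopifnot(all(need %in% names(alignments)))
  lo <- cfg$flank_len - crit$min_flank_anchor + 1L
  hi <- cfg$flank_len + cfg$core_length + crit$min_flank_anchor
  ok <- alignments$ref_start <= lo & alignments$ref_end >= hi &
    alignments$identity >= crit$min_identity
  span <- alignments[ok, , drop = FALSE]
  labels <- vapply(unique(alignments$read_id), function(rid) {
    h <- span[span$read_id == rid, , drop = FALSE]
    if (!nrow(h)) return("unassigned")
    best <- max(h$identity)
    winners <- unique(h$configuration[h$identity == best])
    if (length(winners) > 1L && crit$require_unique_best) "unassigned" else winners[1L]
  }, "", USE.NAMES = FALSE)
  structure(list(repeat_id = cfg$repeat_id,
                 n1 = sum(labels == "c1"), n2 = sum(labels == "c2"),
                 n3 = sum(labels == "c3"), n4 = sum(labels == "c4"),
                 n_unassigned = sum(labels == "unassigned"), labels = labels),
            class = "SupportCounts")
}
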