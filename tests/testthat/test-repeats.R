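# Dispersed repeat and SSR discovery.

make_planted_pair <- function(seed, block_len = 300L, inverted = FALSE,
                              bg1 = 5000L, bg2 = 3000L) {
  set.seed(seed)
  block <- rnd_dna(block_len)
  s1 <- rnd_dna(bg1); s2 <- rnd_dna(bg2)
  p1 <- 1000L; p2 <- 800L
  ins <- if (inverted) rc_chr(block) else block
  s1 <- paste0(substr(s1, 1, p1 - 1L), block, substr(s1, p1, bg1))
  s2 <- paste0(substr(s2, 1, p2 - 1L), ins, substr(s2, p2, bg2))
  list(genome = list(c1 = circular_sequence("c1", s1),
                     c2 = circular_sequence("c2", s2)),
       p1 = p1, p2 = p2, block_len = block_len)
}

test_that("a planted direct cross-chromosome block is found as one pair", {
  px <- make_planted_pair(101)
  reps <- find_dispersed_repeats(px$genome, min_len = 50)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$orientation, "direct")
  expect_gte(reps$core_length, px$block_len)
  # covers the planted truth (maximal exact match may extend by chance)
  expect_lte(reps$start1, px$p1); expect_gte(reps$end1, px$p1 + px$block_len - 1L)
  expect_lte(reps$start2, px$p2); expect_gte(reps$end2, px$p2 + px$block_len - 1L)
})

test_that("a reverse-complement insertion is found as one inverted pair", {
  px <- make_planted_pair(102, inverted = TRUE)
  reps <- find_dispersed_repeats(px$genome, min_len = 50)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$orientation, "inverted")
  expect_gte(reps$core_length, px$block_len)
})

test_that("repeat-free random sequence yields an empty result", {
  set.seed(103)
  s <- rnd_dna(2000)
  # oracle: confirm absence of any duplicated 50-mer by direct enumeration
  expect_false(has_duplicate_kmer(s, 50))
  g <- list(c1 = circular_sequence("c1", s))
  reps <- find_dispersed_repeats(g, min_len = 50)
  expect_equal(nrow(reps), 0L)
})

test_that("reported pairs have identical extracted sequences", {
  px <- make_planted_pair(104, inverted = TRUE)
  reps <- find_dispersed_repeats(px$genome, min_len = 50)
  for (i in seq_len(nrow(reps))) {
    r <- reps[i, ]
    s1 <- extract_interval(px$genome[[r$chrom1]],
                           genome_interval(r$chrom1, r$start1, r$end1, r$strand1,
                                           wraps = r$wraps1))
    s2 <- extract_interval(px$genome[[r$chrom2]],
                           genome_interval(r$chrom2, r$start2, r$end2, r$strand2,
                                           wraps = r$wraps2))
    expect_equal(s1, s2)   # identity 1 >= any min_identity
  }
})

test_that("the pair set is invariant under rotation of a chromosome origin", {
  px <- make_planted_pair(105)
  reps0 <- find_dispersed_repeats(px$genome, min_len = 50)
  # rotate chromosome 1 so the planted block crosses the origin
  s1 <- px$genome$c1$residues
  rot <- 1100L   # inside the planted block (1000..1299)
  s1r <- paste0(substr(s1, rot + 1L, nchar(s1)), substr(s1, 1L, rot))
  g2 <- list(c1 = circular_sequence("c1", s1r), c2 = px$genome$c2)
  reps1 <- find_dispersed_repeats(g2, min_len = 50)
  expect_equal(nrow(reps1), nrow(reps0))
  expect_equal(sort(reps1$core_length), sort(reps0$core_length))
  expect_equal(sort(reps1$orientation), sort(reps0$orientation))
  expect_true(any(reps1$wraps1))
})

test_that("same-molecule pairs are reported once with non-overlapping copies", {
  set.seed(106)
  block <- rnd_dna(200)
  s <- paste0(rnd_dna(500), block, rnd_dna(800), block, rnd_dna(500))
  g <- list(c1 = circular_sequence("c1", s))
  reps <- find_dispersed_repeats(g, min_len = 50)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$chrom1, "c1")
  expect_equal(reps$chrom2, "c1")
  expect_lt(reps$end1, reps$start2)   # canonical order, disjoint copies
})

test_that("SSR unit thresholds are inclusive at the boundary", {
  set.seed(107)
  ctx <- function(run) paste0(rnd_dna(300), run, rnd_dna(300))
  g10 <- list(c = circular_sequence("c", ctx(strrep("A", 10))))
  hit <- find_ssrs(g10)
  expect_true(any(hit$motif == "A" & hit$copies >= 10))
  g9 <- list(c = circular_sequence("c", ctx(strrep("A", 9))))
  expect_false(any(find_ssrs(g9)$motif == "A"))
  g43 <- list(c = circular_sequence("c", ctx(strrep("AGAT", 3))))
  hit <- find_ssrs(g43)
  expect_true(any(hit$unit_length == 4 & hit$copies == 3))
  g42 <- list(c = circular_sequence("c", ctx(strrep("AGAT", 2))))
  expect_false(any(find_ssrs(g42)$unit_length == 4))
})

test_that("SSR detection matches a brute-force regex scan on short sequences", {
  thr <- default_ssr_thresholds()
  brute <- function(s) {
    # direct scan: every maximal primitive tandem run meeting its threshold
    found <- list()
    n <- nchar(s)
    for (u in 1:6) {
      m <- thr[[as.character(u)]]
      starts <- seq_len(max(0L, n - u * m + 1L))
      for (p in starts) {
        unit <- substr(s, p, p + u - 1L)
        if (grepl("[^ACGT]", unit)) next
        # count copies forward
        cp <- 1L
        while (p + (cp + 1L) * u - 1L <= n &&
               substr(s, p + cp * u, p + (cp + 1L) * u - 1L) == unit) cp <- cp + 1L
        if (cp < m) next
        # maximal on the left in this phase
        if (p > u && substr(s, p - u, p - 1L) == unit) next
        # primitive unit
        prim <- TRUE
        for (d in seq_len(u - 1L)) if (u %% d == 0L &&
                                       unit == strrep(substr(unit, 1, d), u / d)) prim <- FALSE
        if (!prim) next
        found[[length(found) + 1L]] <- c(p, p + cp * u - 1L)
      }
    }
    # same reporting policy as the contract: greedy non-overlap, longest first
    if (!length(found)) return(found)
    lens <- vapply(found, function(x) x[2] - x[1] + 1, 1)
    found <- found[order(-lens, vapply(found, `[`, 1, 1))]
    covered <- logical(n)
    keep <- list()
    for (f in found) {
      if (!any(covered[f[1]:f[2]])) { keep[[length(keep) + 1L]] <- f; covered[f[1]:f[2]] <- TRUE }
    }
    keep
  }
  set.seed(108)
  s <- paste0(rnd_dna(150), strrep("AT", 6), rnd_dna(100),
              strrep("C", 11), rnd_dna(100), strrep("GAT", 4), rnd_dna(150))
  g <- list(c = circular_sequence("c", s, circular = FALSE))
  got <- find_ssrs(g)
  exp <- brute(s)
  expect_equal(nrow(got), length(exp))
  expect_setequal(got$start, vapply(exp, `[`, 1, 1))
  # no two reported SSRs overlap
  if (nrow(got) > 1L) {
    o <- order(got$start)
    expect_true(all(got$start[o][-1L] > got$end[o][-nrow(got)]))
  }
})

test_that("SSR motifs are canonical minimal rotations", {
  set.seed(109)
  s <- paste0(rnd_dna(200), strrep("TCA", 5), rnd_dna(200))
  g <- list(c = circular_sequence("c", s, circular = FALSE))
  got <- find_ssrs(g)
  expect_true("ATC" %in% got$motif)   # minimal rotation of TCA
})

test_that("empty genome raises an input error", {
  expect_error(find_dispersed_repeats(list()), class = "input_error")
  expect_error(find_ssrs(list()), class = "input_error")
})
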