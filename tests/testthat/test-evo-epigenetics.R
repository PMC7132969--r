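# Conservation windows, distance models, neighbor joining and methylation
# interval overlap.

test_that("identical sequences give identity 1 and one whole-alignment block", {
  seqs <- setNames(rep(paste(rep("ACGT", 25), collapse = ""), 8),
                   paste0("sp", 1:8))
  res <- conserved_blocks(msa(seqs))
  expect_true(all(res$profile$score == 1))
  expect_equal(res$blocks, data.frame(start = 1L, end = 100L))
})

test_that("windowed identity separates a conserved prefix from a mutated tail", {
  # columns 1-20 identical; columns 21-100 exactly 50% identity
  a <- c(rep("A", 20), rep(c("A", "A"), 40))
  b <- c(rep("A", 20), rep(c("A", "C"), 40))
  aln <- msa(c(s1 = paste(a, collapse = ""), s2 = paste(b, collapse = "")))
  res <- conserved_blocks(aln, window_size = 10, step = 10, threshold = 0.9)
  expect_equal(res$blocks, data.frame(start = 1L, end = 20L))
  expect_equal(res$profile$score[3:10], rep(0.5, 8))
})

test_that("zero matches give score 0 and no blocks", {
  aln <- msa(c(s1 = strrep("A", 40), s2 = strrep("C", 40)))
  res <- conserved_blocks(aln, window_size = 10, step = 10, threshold = 0.5)
  expect_true(all(res$profile$score == 0))
  expect_equal(nrow(res$blocks), 0L)
})

test_that("windows with an all-gap pair are flagged and excluded from blocks", {
  aln <- msa(c(s1 = paste0(strrep("A", 20), strrep("-", 20)),
               s2 = paste0(strrep("A", 20), strrep("-", 20))))
  res <- conserved_blocks(aln, window_size = 20, step = 20, threshold = 0.5)
  expect_false(res$profile$flagged[1])
  expect_true(res$profile$flagged[2])
  expect_true(is.na(res$profile$score[2]))
  expect_equal(res$blocks, data.frame(start = 1L, end = 20L))
})

test_that("window scores match the double-loop oracle and ignore species order", {
  set.seed(37)
  seqs <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T", "-"), 80, replace = TRUE,
                 prob = c(0.3, 0.25, 0.2, 0.2, 0.05)), collapse = "")
  }, character(1))
  names(seqs) <- paste0("sp", 1:6)
  aln <- msa(seqs)
  res <- conserved_blocks(aln, window_size = 20, step = 10)
  m <- aln$seqs
  for (w in seq_len(nrow(res$profile))) {
    expect_equal(res$profile$score[w],
                 oracle_window_identity(m, res$profile$window_start[w],
                                        res$profile$window_end[w]))
  }
  perm <- sample(names(seqs))
  res2 <- conserved_blocks(msa(seqs[perm]), window_size = 20, step = 10)
  expect_equal(res2$profile, res$profile)
  expect_equal(res2$blocks, res$blocks)
})

test_that("p-distance and JC69 follow their closed forms with pairwise deletion", {
  expect_equal(unname(pairwise_distances(msa(c(a = "ACGT", b = "ACGT")))[1, 2]), 0)
  aln <- msa(c(a = "ACGT", b = "ACGA"))
  expect_equal(unname(pairwise_distances(aln, "p_distance")[1, 2]), 0.25)
  expect_equal(unname(pairwise_distances(aln, "jc69")[1, 2]),
               -0.75 * log(1 - (4 / 3) * 0.25))
  expect_equal(unname(pairwise_distances(aln, "jc69")[1, 2]), 0.3040988,
               tolerance = 1e-6)
  gapped <- msa(c(a = "ACGT", b = "AC-T"))
  expect_equal(unname(pairwise_distances(gapped, "p_distance")[1, 2]), 0)
})

test_that("saturated or incomparable pairs raise errors naming the pair", {
  sat <- msa(c(a = strrep("A", 20), b = strrep("C", 20)))
  expect_error(pairwise_distances(sat, "jc69"), "saturation.*'a'.*'b'")
  nocomp <- msa(c(a = "AC--", b = "--GT"))
  expect_error(pairwise_distances(nocomp), "comparable.*'a'.*'b'")
})

test_that("JC69 dominates p-distance and matches ape::dist.dna", {
  set.seed(41)
  ref <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  seqs <- vapply(1:5, function(i) {
    s <- ref
    mut <- runif(200) < 0.25
    s[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    s[runif(200) < 0.05] <- "-"
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("sp", 1:5)
  aln <- msa(seqs)
  p <- pairwise_distances(aln, "p_distance")
  jc <- pairwise_distances(aln, "jc69")
  off <- upper.tri(p)
  expect_true(all(jc[off] >= p[off]))
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  expect_equal(p[off], as.matrix(ape::dist.dna(bin, model = "raw",
                                               pairwise.deletion = TRUE))[off],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(jc[off], as.matrix(ape::dist.dna(bin, model = "JC69",
                                                pairwise.deletion = TRUE))[off],
               tolerance = 1e-12, ignore_attr = TRUE)
})

nj_worked_matrix <- function() {
  matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
         dimnames = list(LETTERS[1:4], LETTERS[1:4]))
}

test_that("NJ solves the additive 4-taxon worked example exactly", {
  tr <- build_nj_tree(nj_worked_matrix())
  # pendant branch lengths
  pend <- setNames(tr$edge.length[tr$edge[, 2] <= 4], tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(pend[LETTERS[1:4]], c(A = 2, B = 3, C = 4, D = 4))
  # one internal branch of length 3
  expect_equal(tr$edge.length[tr$edge[, 2] > 4], 3)
  # path lengths reproduce the input exactly (additivity)
  expect_equal(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], nj_worked_matrix())
})

test_that("NJ closed forms hold for 2 and 3 taxa", {
  d2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- build_nj_tree(d2)
  expect_equal(sort(tr2$edge.length), c(2.5, 2.5))
  d3 <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- build_nj_tree(d3)
  pend <- setNames(numeric(3), c("A", "B", "C"))
  for (t in names(pend)) {
    pend[t] <- tr3$edge.length[tr3$edge[, 2] == match(t, tr3$tip.label)]
  }
  expect_equal(pend, c(A = (4 + 6 - 8) / 2, B = (4 + 8 - 6) / 2, C = (6 + 8 - 4) / 2))
})

test_that("NJ recovers random additive trees exactly (topology and lengths)", {
  for (seed in 1:40) {
    n <- sample(4:10, 1)
    ref <- random_additive_matrix(n, seed = seed)
    tr <- build_nj_tree(ref$d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref$tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(cophenetic(tr)[rownames(ref$d), colnames(ref$d)], ref$d,
                 tolerance = 1e-8)
    # independent cross-check against ape's NJ implementation
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ape::nj(ref$d))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ rejects invalid matrices and clamps negative branch lengths", {
  bad <- nj_worked_matrix(); bad[1, 2] <- 7
  expect_error(build_nj_tree(bad), "symmetric")
  neg <- nj_worked_matrix(); neg[1, 2] <- -1; neg[2, 1] <- -1
  expect_error(build_nj_tree(neg), "negative")
  # a non-additive matrix that drives one NJ branch negative
  d <- matrix(c(0, 2, 10, 10,
                2, 0, 3, 3,
                10, 3, 0, 1,
                10, 3, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_true(any(attr(tr, "raw_edge_length") < 0))
})

test_that("methylation overlap unions hypomethylated intervals over the query", {
  q <- data.frame(chrom = "chr7", start = 101, end = 200)
  track <- GenomicRanges::GRanges("chr7", IRanges::IRanges(151, 250))
  S4Vectors::mcols(track)$score <- 0.1
  mo <- methylation_overlap(q, track, 0.3)
  expect_equal(mo$overlapped_bp, 50L)
  expect_equal(mo$fraction, 0.5)
  S4Vectors::mcols(track)$score <- 0.6
  expect_equal(methylation_overlap(q, track, 0.3)$overlapped_bp, 0L)
  track2 <- GenomicRanges::GRanges("chr7", IRanges::IRanges(c(101, 141), c(160, 220)))
  S4Vectors::mcols(track2)$score <- c(0.05, 0.2)
  expect_equal(methylation_overlap(q, track2, 0.3)$overlapped_bp, 100L)
})

test_that("overlap matches the brute-force oracle and survives interval splitting", {
  set.seed(43)
  for (rep in 1:20) {
    qs <- sample(1:500, 1); qe <- qs + sample(50:200, 1)
    n <- sample(3:12, 1)
    starts <- sample(1:700, n); ends <- starts + sample(10:100, n, replace = TRUE)
    scores <- round(runif(n), 2)
    thr <- runif(1, 0.1, 0.9)
    track <- GenomicRanges::GRanges("chrS", IRanges::IRanges(starts, ends))
    S4Vectors::mcols(track)$score <- scores
    q <- data.frame(chrom = "chrS", start = qs, end = qe)
    got <- methylation_overlap(q, track, thr)
    expect_equal(got$overlapped_bp,
                 oracle_union_overlap(qs, qe, starts, ends, scores, thr))
    # split every interval at its midpoint: fraction unchanged
    mids <- pmax(starts, floor((starts + ends) / 2))
    splt <- GenomicRanges::GRanges("chrS", IRanges::IRanges(c(starts, mids + 1L),
                                                            c(mids, ends)))
    ok <- BiocGenerics::width(splt) >= 1L
    splt <- splt[ok]
    S4Vectors::mcols(splt)$score <- c(scores, scores)[ok]
    expect_equal(methylation_overlap(q, splt, thr)$fraction, got$fraction)
  }
})

test_that("tracks with silently-missing scores are refused", {
  track <- GenomicRanges::GRanges("chr7", IRanges::IRanges(1, 100))
  S4Vectors::mcols(track)$score <- 0.1
  S4Vectors::mcols(track)$score_missing <- TRUE
  expect_error(methylation_overlap(data.frame(chrom = "chr7", start = 1, end = 50),
                                   track, 0.3), "missing")
})
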