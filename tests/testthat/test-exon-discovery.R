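# Coverage, junction extraction, island calling and novel-exon
# classification, each against brute-force oracles and spec'd examples.

test_that("coverage counts overlapping blocks and leaves splice skips empty", {
  # two single-block reads
  reads <- make_reads(list(matrix(c(11, 15), 1), matrix(c(11, 15), 1)))
  cov <- compute_coverage(reads, data.frame(chrom = "chrS", start = 1, end = 20))
  expect_equal(cov$depth, c(rep(0L, 10), rep(2L, 5), rep(0L, 5)))
  # spliced read: covered blocks 1-5 and 9-12, skip 6-8 uncovered
  reads <- make_reads(list(matrix(c(1, 5, 9, 12), 2, byrow = TRUE)))
  cov <- compute_coverage(reads, data.frame(chrom = "chrS", start = 1, end = 12))
  expect_equal(cov$depth, c(rep(1L, 5), rep(0L, 3), rep(1L, 4)))
})

test_that("coverage equals a per-base brute-force count on random reads", {
  set.seed(7)
  for (rep in 1:20) {
    blocks <- random_blocks(25, 150)
    reads <- make_reads(blocks)
    ws <- sample(1:30, 1); wl <- sample(50:150, 1)
    cov <- compute_coverage(reads, data.frame(chrom = "chrS", start = ws,
                                              end = ws + wl - 1))
    expect_equal(cov$depth, oracle_coverage(blocks, ws, wl))
  }
})

test_that("reads on other chromosomes are skipped and counted", {
  r1 <- make_reads(list(matrix(c(1, 10), 1)), chrom = "chrS")
  r2 <- make_reads(list(matrix(c(1, 10), 1)), chrom = "chrX")
  both <- spliced_reads(c("chrS", "chrX"), c(1, 1), c("10M", "10M"))
  cov <- compute_coverage(both, data.frame(chrom = "chrS", start = 1, end = 10))
  expect_equal(cov$n_other_chrom, 1L)
  expect_equal(cov$depth, rep(1L, 10))
})

test_that("junctions aggregate read support and respect min_support", {
  two <- make_reads(list(matrix(c(101, 150, 351, 400), 2, byrow = TRUE),
                         matrix(c(101, 150, 351, 400), 2, byrow = TRUE)))
  jx <- extract_junctions(two, min_support = 1)
  expect_equal(jx$donor_end, 150L)
  expect_equal(jx$acceptor_start, 351L)
  expect_equal(jx$support, 2L)
  one <- make_reads(list(matrix(c(101, 150, 351, 400), 2, byrow = TRUE)))
  expect_equal(nrow(extract_junctions(one, min_support = 2)), 0L)
  three <- make_reads(list(matrix(c(1, 10, 21, 30, 41, 50), 3, byrow = TRUE)))
  jx3 <- extract_junctions(three, min_support = 1)
  expect_equal(nrow(jx3), 2L)
  expect_equal(jx3$support, c(1L, 1L))
  expect_equal(jx3$donor_end, c(10L, 30L))
})

test_that("junction extraction matches the consecutive-pair oracle on random reads", {
  set.seed(11)
  for (rep in 1:20) {
    blocks <- random_blocks(30, 300, max_blocks = 4L)
    got <- extract_junctions(make_reads(blocks), min_support = 1)
    exp <- oracle_junctions(blocks, 1L)
    expect_equal(got[, c("donor_end", "acceptor_start", "support")], exp,
                 ignore_attr = TRUE)
  }
})

test_that("island calling follows the threshold/merge/length rules", {
  depth <- c(0, 0, 3, 4, 5, 0, 0, 2, 2, 0)
  isl <- call_islands(make_track(depth), min_depth = 2, min_length = 2,
                      merge_gap = 0)
  expect_equal(isl$start, c(3L, 8L))
  expect_equal(isl$end, c(5L, 9L))
  expect_equal(isl$mean_depth, c(4, 2))
  expect_equal(isl$max_depth, c(5L, 2L))
  merged <- call_islands(make_track(depth), min_depth = 2, min_length = 2,
                         merge_gap = 2)
  expect_equal(merged$start, 3L)
  expect_equal(merged$end, 9L)
  # merged span's mean depth is over the whole merged interval
  expect_equal(merged$mean_depth, mean(depth[3:9]))
  expect_equal(nrow(call_islands(make_track(rep(0, 50)))), 0L)
})

test_that("island calling matches the brute-force scan on random tracks", {
  set.seed(13)
  for (rep in 1:50) {
    depth <- rpois(sample(30:120, 1), 2)
    md <- sample(1:4, 1); ml <- sample(1:10, 1); mg <- sample(0:5, 1)
    start <- sample(1:100, 1)
    got <- call_islands(make_track(depth, start = start), md, ml, mg)
    exp <- oracle_islands(depth, md, ml, mg)
    expect_equal(got$start, exp$start + start - 1L)
    expect_equal(got$end, exp$end + start - 1L)
  }
})

test_that("islands are invariant to splitting reads into batches", {
  set.seed(17)
  blocks <- random_blocks(60, 400)
  win <- data.frame(chrom = "chrS", start = 1, end = 400)
  full <- compute_coverage(make_reads(blocks), win)
  idx <- sample(rep(1:3, length.out = 60))
  partial <- Reduce(`+`, lapply(1:3, function(b) {
    compute_coverage(make_reads(blocks[idx == b]), win)$depth
  }))
  expect_equal(full$depth, partial)
  expect_equal(call_islands(full, 2, 5, 3),
               call_islands(make_track(partial), 2, 5, 3))
})

# gene with exons [101,150] and [501,560]; intron carries candidate islands
tol_gene <- function(strand = "+") {
  make_gene(c(101, 501), c(150, 560), strand = strand,
            transcripts = list(tx1 = c(1L, 2L)))
}

jx_df <- function(donor_end, acceptor_start, support = 5L) {
  data.frame(chrom = rep("chrS", length(donor_end)),
             donor_end = donor_end, acceptor_start = acceptor_start,
             support = rep_len(support, length(donor_end)))
}

isl_df <- function(start, end) {
  data.frame(chrom = "chrS", start = start, end = end,
             mean_depth = 10, max_depth = 12L)
}

test_that("an intronic island linked only downstream is a first exon", {
  calls <- call_novel_exons(isl_df(301, 386), tol_gene(), jx_df(386, 501),
                            boundary_tolerance = 0)
  expect_length(calls, 1L)
  expect_equal(calls[[1]]$exon_class, "first_exon")
  expect_equal(nrow(calls[[1]]$upstream_links), 0L)
  expect_equal(calls[[1]]$downstream_links$exon_index, 2L)
})

test_that("islands overlapping annotated exons are discarded", {
  calls <- call_novel_exons(isl_df(121, 140), tol_gene(), jx_df(386, 501))
  expect_length(calls, 0L)
})

test_that("links on both sides make an internal exon", {
  jx <- rbind(jx_df(150, 301), jx_df(386, 501))
  calls <- call_novel_exons(isl_df(301, 386), tol_gene(), jx,
                            boundary_tolerance = 0)
  expect_equal(calls[[1]]$exon_class, "internal")
  expect_equal(calls[[1]]$upstream_links$exon_index, 1L)
  expect_equal(calls[[1]]$downstream_links$exon_index, 2L)
})

test_that("island edges are snapped to linking junction coordinates", {
  calls <- call_novel_exons(isl_df(303, 390), tol_gene(),
                            rbind(jx_df(150, 301), jx_df(386, 501)),
                            boundary_tolerance = 5)
  expect_equal(calls[[1]]$island$start, 301L)
  expect_equal(calls[[1]]$island$end, 386L)
  expect_equal(calls[[1]]$raw_island$start, 303L)
  expect_equal(calls[[1]]$raw_island$end, 390L)
})

test_that("exon class follows the link truth table on both strands", {
  cases <- expand.grid(left = c(FALSE, TRUE), right = c(FALSE, TRUE),
                       strand = c("+", "-"), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    jx <- jx_df(integer(0), integer(0))
    if (cases$left[k]) jx <- rbind(jx, jx_df(150, 301))
    if (cases$right[k]) jx <- rbind(jx, jx_df(386, 501))
    calls <- call_novel_exons(isl_df(301, 386), tol_gene(cases$strand[k]), jx,
                              boundary_tolerance = 0)
    # transcriptional upstream/downstream flip with strand
    up <- if (cases$strand[k] == "+") cases$left[k] else cases$right[k]
    down <- if (cases$strand[k] == "+") cases$right[k] else cases$left[k]
    expected <- if (up && down) "internal" else if (up) "terminal"
      else if (down) "first_exon" else "unlinked"
    expect_equal(calls[[1]]$exon_class, expected,
                 info = paste(cases[k, ], collapse = "/"))
  }
})

test_that("islands beyond the gene span are flagged but still reported", {
  calls <- call_novel_exons(isl_df(601, 700), tol_gene(), jx_df(integer(0), integer(0)))
  expect_length(calls, 1L)
  expect_true("outside_gene_span" %in% calls[[1]]$flags)
  expect_equal(calls[[1]]$exon_class, "unlinked")
})

test_that("planted exon boundaries are recovered within 2 bp at depth >= 20", {
  locus <- simulate_locus(locus_spec())
  truth <- locus$truth$novel_exon
  win <- data.frame(chrom = "chrS", start = 1, end = locus$truth$chrom_length)
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    reads <- simulate_reads(locus, "e67_KO", depth = 50, seed = 300 + s)
    cov <- compute_coverage(reads, win)
    isl <- call_islands(cov)
    jx <- extract_junctions(reads)
    calls <- call_novel_exons(isl, locus$gene, jx)
    stopifnot(length(calls) >= 1L)
    cl <- calls[[1]]
    if (abs(cl$island$start - truth$start) <= 2 &&
        abs(cl$island$end - truth$end) <= 2) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
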