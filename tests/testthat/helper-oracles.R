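# Independent brute-force oracles and fixture builders. These deliberately
# use naive per-base / per-pair algorithms, not the package's code paths.

# --- fixture builders --------------------------------------------------------

# blocks: list of 2-column matrices (start, end; 1-based inclusive) per read
make_reads <- function(blocks, chrom = "chrS") {
  pos <- vapply(blocks, function(b) b[1, 1], numeric(1))
  cigar <- vapply(blocks, function(b) {
    parts <- character(0)
    for (i in seq_len(nrow(b))) {
      parts <- c(parts, paste0(b[i, 2] - b[i, 1] + 1, "M"))
      if (i < nrow(b)) parts <- c(parts, paste0(b[i + 1, 1] - b[i, 2] - 1, "N"))
    }
    paste(parts, collapse = "")
  }, character(1))
  spliced_reads(chrom, pos, cigar)
}

make_track <- function(depth, chrom = "chrS", start = 1L) {
  structure(
    list(window = GenomicRanges::GRanges(chrom,
           IRanges::IRanges(start, start + length(depth) - 1L)),
         depth = as.integer(depth), n_other_chrom = 0L),
    class = "coverage_track")
}

make_gene <- function(exon_starts, exon_ends, strand = "+",
                      transcripts = NULL, chrom = "chrS", gene_id = "g1") {
  transcripts <- transcripts %||% list(tx1 = seq_along(exon_starts))
  gene_model(gene_id, chrom, strand,
             data.frame(start = exon_starts, end = exon_ends), transcripts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random spliced-read block list within [1, span + 3*max_blocks]; consecutive
# blocks keep a gap of >= 3 bp so every junction is a real splice skip
random_blocks <- function(n_reads, span, max_blocks = 3L) {
  lapply(seq_len(n_reads), function(i) {
    k <- sample.int(max_blocks, 1L)
    pts <- sort(sample.int(span, 2L * k))
    m <- matrix(pts, ncol = 2L, byrow = TRUE)
    m + 3L * (seq_len(k) - 1L)
  })
}

# --- oracles -----------------------------------------------------------------

# CIGAR -> reference blocks by walking the reference one operation at a time
oracle_cigar_blocks <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  ref <- pos
  covered <- integer(0)
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      covered <- c(covered, seq(ref, ref + len[i] - 1L))
      ref <- ref + len[i]
    } else if (op[i] == "N") {
      ref <- ref + len[i]
    } # I, S, H, P consume no reference
  }
  covered <- sort(unique(covered))
  if (length(covered) == 0L) return(matrix(numeric(0), ncol = 2L))
  brk <- c(0L, which(diff(covered) > 1L), length(covered))
  t(vapply(seq_len(length(brk) - 1L), function(j) {
    c(covered[brk[j] + 1L], covered[brk[j + 1L]])
  }, numeric(2)))
}

# per-base membership count over a window
oracle_coverage <- function(blocks, win_start, win_len) {
  depth <- integer(win_len)
  for (b in blocks) {
    for (i in seq_len(nrow(b))) {
      for (p in seq(b[i, 1], b[i, 2])) {
        k <- p - win_start + 1L
        if (k >= 1L && k <= win_len) depth[k] <- depth[k] + 1L
      }
    }
  }
  depth
}

# distinct (donor_end, acceptor_start) pairs between consecutive blocks
oracle_junctions <- function(blocks, min_support = 1L) {
  seen <- list()
  for (b in blocks) {
    if (nrow(b) < 2L) next
    per_read <- unique(t(vapply(seq_len(nrow(b) - 1L), function(i) {
      c(b[i, 2], b[i + 1L, 1])
    }, numeric(2))))
    for (r in seq_len(nrow(per_read))) {
      key <- paste(per_read[r, 1], per_read[r, 2])
      seen[[key]] <- (seen[[key]] %||% 0L) + 1L
    }
  }
  if (length(seen) == 0L) {
    return(data.frame(donor_end = integer(0), acceptor_start = integer(0),
                      support = integer(0)))
  }
  parts <- do.call(rbind, strsplit(names(seen), " "))
  out <- data.frame(donor_end = as.integer(parts[, 1]),
                    acceptor_start = as.integer(parts[, 2]),
                    support = as.integer(unlist(seen)))
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$donor_end, out$acceptor_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# threshold scan with gap merging and length filter, by explicit iteration
oracle_islands <- function(depth, min_depth, min_length, merge_gap) {
  above <- depth >= min_depth
  runs <- list()
  i <- 1L
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  # merge runs separated by <= merge_gap sub-threshold bases
  merged <- list()
  for (r in runs) {
    if (length(merged) > 0L &&
        r[1] - merged[[length(merged)]][2] - 1L <= merge_gap) {
      merged[[length(merged)]][2] <- r[2]
    } else merged[[length(merged) + 1L]] <- r
  }
  merged <- Filter(function(r) r[2] - r[1] + 1L >= min_length, merged)
  if (length(merged) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = vapply(merged, `[`, numeric(1), 1),
             end = vapply(merged, `[`, numeric(1), 2))
}

# bp of [qs,qe] covered by the union of intervals with score <= threshold
oracle_union_overlap <- function(qs, qe, starts, ends, scores, threshold) {
  covered <- logical(qe - qs + 1L)
  for (i in seq_along(starts)) {
    if (scores[i] > threshold) next
    lo <- max(qs, starts[i]); hi <- min(qe, ends[i])
    if (lo <= hi) covered[(lo - qs + 1L):(hi - qs + 1L)] <- TRUE
  }
  sum(covered)
}

# mean pairwise identity per window by explicit double loop
oracle_window_identity <- function(m, ws, we) {
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- m[i, ws:we]; b <- m[j, ws:we]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (sum(ok) == 0L) return(NA_real_)
    vals <- c(vals, sum(a[ok] == b[ok]) / sum(ok))
  }
  mean(vals)
}

# naive re-derivation of the guided variant semantics: guide variants plus,
# per novel node, every (upstream prefix) + novel + (downstream guide tail)
# combination through read edges, deduplicated, maximal chains only
oracle_variants <- function(nodes, redges, guides, strand = "+") {
  chains <- lapply(unname(guides), identity)
  for (nv in nodes$node_id[nodes$origin == "novel"]) {
    downs <- list(); ups <- list()
    for (k in which(redges$from == nv)) {
      e <- redges$to[k]
      for (g in guides) {
        if (e %in% g) downs[[length(downs) + 1L]] <- g[match(e, g):length(g)]
      }
    }
    for (k in which(redges$to == nv)) {
      e <- redges$from[k]
      for (g in guides) {
        if (e %in% g) ups[[length(ups) + 1L]] <- g[1:match(e, g)]
      }
    }
    if (length(downs) == 0L && length(ups) == 0L) next
    if (length(downs) == 0L) downs <- list(character(0))
    if (length(ups) == 0L) ups <- list(character(0))
    for (u in ups) for (d in downs) {
      chains[[length(chains) + 1L]] <- c(u, nv, d)
    }
  }
  keys <- vapply(chains, paste, character(1), collapse = ">")
  chains <- chains[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  padded <- paste0(">", keys, ">")
  novelc <- vapply(chains, function(ch) any(ch %in% nodes$node_id[nodes$origin == "novel"]),
                   logical(1))
  keep <- vapply(seq_along(chains), function(i) {
    if (!novelc[i]) return(TRUE)
    !any(vapply(seq_along(chains), function(j) {
      j != i && grepl(padded[i], padded[j], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  chains <- chains[keep]
  if (strand == "-") chains <- lapply(chains, rev)
  sort(vapply(chains, paste, character(1), collapse = ">"))
}

# random binary unrooted tree with positive branch lengths -> additive matrix
random_additive_matrix <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 2))
  list(tree = tr, d = cophenetic(tr))
}

# shared splice-graph fixtures
novel_call <- function(start, end, class = "first_exon") {
  structure(list(island = data.frame(chrom = "chrS", start = start, end = end,
                                     mean_depth = 10, max_depth = 12L),
                 upstream_links = NULL, downstream_links = NULL,
                 exon_class = class, gene_id = "g1", strand = "+",
                 flags = character(0)),
            class = "novel_exon_call")
}

random_graph_case <- function(seed) {
  set.seed(seed)
  k <- sample(3:6, 1)
  starts <- 100L + 200L * (seq_len(k) - 1L)  # comb layout, wide gaps
  ends <- starts + 79L
  n_guides <- sample(1:2, 1)
  guide_idx <- lapply(seq_len(n_guides), function(i) {
    sort(sample(seq_len(k), sample(2:k, 1)))
  })
  names(guide_idx) <- paste0("gu", seq_len(n_guides))
  # well-formed gene models (as produced from GTF) cover every exon with
  # at least one transcript
  uncovered <- setdiff(seq_len(k), unlist(guide_idx))
  if (length(uncovered) > 0L) guide_idx$gu_rest <- sort(uncovered)
  gene <- make_gene(starts, ends, transcripts = guide_idx)
  j <- sample(seq_len(k - 1L), 1)  # novel node in the intron after exon j
  nstart <- ends[j] + 21L; nend <- ends[j] + 100L
  nov <- novel_call(nstart, nend)
  jx <- data.frame(chrom = character(0), donor_end = integer(0),
                   acceptor_start = integer(0), support = integer(0))
  for (e in seq_len(k)) {
    if (runif(1) < 0.4 && ends[e] < nstart) {
      jx <- rbind(jx, data.frame(chrom = "chrS", donor_end = ends[e],
                                 acceptor_start = nstart,
                                 support = sample(2:9, 1)))
    }
    if (runif(1) < 0.4 && starts[e] > nend) {
      jx <- rbind(jx, data.frame(chrom = "chrS", donor_end = nend,
                                 acceptor_start = starts[e],
                                 support = sample(2:9, 1)))
    }
  }
  list(gene = gene, nov = nov, jx = jx)
}
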