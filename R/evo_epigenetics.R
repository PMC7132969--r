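# Windowed conservation over a supplied multi-species alignment, pairwise
# distances (p / JC69, pairwise deletion), neighbor-joining phylogeny, and
# hypomethylated-region overlap.

#' Read a multiple sequence alignment from aligned FASTA
#'
#' All sequences must be the same length, over {A,C,G,T,N,-}; at least two
#' records are required.
#'
#' @param path aligned FASTA path
#' @return an `msa` object: list(seqs = species x column character matrix,
#'   species, aligned_length)
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop2("alignment file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  msa(stats::setNames(as.character(ss), names(ss)))
}

#' Construct an MSA object from named aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences
#' @return an `msa` object
#' @export
msa <- function(seqs) {
  if (length(seqs) < 2L) stop2("an alignment needs >= 2 sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop2("all sequences must be named")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop2("aligned sequences have unequal lengths: ",
          paste(unique(lens), collapse = ", "))
  }
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(m) <- names(seqs)
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0L) stop2("invalid alignment characters: ",
                              paste(bad, collapse = ", "))
  structure(list(seqs = m, species = names(seqs), aligned_length = ncol(m)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d species x %d aligned columns (%s%s)\n",
              length(x$species), x$aligned_length,
              paste(utils::head(x$species, 4), collapse = ", "),
              if (length(x$species) > 4) ", ..." else ""))
  invisible(x)
}

#' Write an MSA as aligned FASTA
#' @param x an `msa` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_msa <- function(x, path) {
  seqs <- apply(x$seqs, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, x$species)), path)
  invisible(path)
}

# Per-pair match / comparable-site counts over a column range.
# Comparable = both characters in {A,C,G,T} (pairwise deletion; N excluded).
pair_site_counts <- function(m, cols = seq_len(ncol(m))) {
  sub <- m[, cols, drop = FALSE]
  valid <- sub %in% c("A", "C", "G", "T")
  dim(valid) <- dim(sub)
  n <- nrow(sub)
  pairs <- utils::combn(n, 2L)
  matches <- integer(ncol(pairs)); comparable <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    both <- valid[i, ] & valid[j, ]
    comparable[k] <- sum(both)
    matches[k] <- sum(both & sub[i, ] == sub[j, ])
  }
  list(pairs = pairs, matches = matches, comparable = comparable)
}

#' Sliding-window conservation profile and conserved blocks
#'
#' Per window, the score is the mean over all sequence pairs of (matching
#' non-gap columns / columns where both are non-gap). Windows where any pair
#' has no comparable column get an undefined (NA) score, are flagged, and
#' are excluded from blocks. Blocks are maximal runs of consecutive windows
#' scoring >= `threshold`, merged into alignment-column intervals (1-based
#' inclusive).
#'
#' @param aln an [msa()] object
#' @param window_size window width in alignment columns (default 20)
#' @param step window step (default 10)
#' @param threshold block threshold on mean pairwise identity (default 0.8)
#' @return a `conservation_result`: list(profile = data.frame(window_start,
#'   window_end, score, flagged), blocks = data.frame(start, end),
#'   window_size, step, threshold)
#' @export
conserved_blocks <- function(aln, window_size = 20L, step = 10L, threshold = 0.8) {
  stopifnot(inherits(aln, "msa"), window_size >= 1L, step >= 1L,
            threshold > 0, threshold <= 1)
  L <- aln$aligned_length
  starts <- seq(1L, L, by = step)
  starts <- starts[starts <= L]
  ends <- pmin(starts + window_size - 1L, L)
  # drop trailing duplicate truncated windows fully contained in the previous
  keep <- !duplicated(ends) | ends - starts + 1L == window_size
  starts <- starts[keep]; ends <- ends[keep]
  scores <- numeric(length(starts)); flagged <- logical(length(starts))
  for (w in seq_along(starts)) {
    pc <- pair_site_counts(aln$seqs, starts[w]:ends[w])
    if (any(pc$comparable == 0L)) {
      scores[w] <- NA_real_; flagged[w] <- TRUE
    } else {
      scores[w] <- mean(pc$matches / pc$comparable)
    }
  }
  profile <- data.frame(window_start = starts, window_end = ends,
                        score = scores, flagged = flagged)
  ok <- !is.na(scores) & scores >= threshold
  blocks <- data.frame(start = integer(0), end = integer(0))
  if (any(ok)) {
    r <- rle(ok)
    run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths + 1L
    hit <- which(r$values)
    blocks <- data.frame(start = starts[run_start[hit]],
                         end = ends[run_end[hit]])
    # overlapping windows can produce overlapping blocks; merge those only
    # (touching-but-separate runs remain distinct blocks)
    ir <- IRanges::reduce(IRanges::IRanges(blocks$start, blocks$end),
                          min.gapwidth = 0L)
    blocks <- data.frame(start = BiocGenerics::start(ir),
                         end = BiocGenerics::end(ir))
  }
  structure(list(profile = profile, blocks = blocks,
                 window_size = window_size, step = step, threshold = threshold),
            class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf("conservation_result: %d windows (size %d, step %d), %d block(s) at threshold %.2f\n",
              nrow(x$profile), x$window_size, x$step, nrow(x$blocks), x$threshold))
  if (nrow(x$blocks) > 0L) {
    cat("  blocks:", paste(sprintf("[%d,%d]", x$blocks$start, x$blocks$end),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Pairwise distances from an alignment
#'
#' p-distance = mismatches / sites where both sequences are unambiguous
#' non-gap (pairwise deletion); jc69 applies the Jukes-Cantor correction
#' `-(3/4) * log(1 - (4/3) * p)`. A pair at or beyond the JC69 saturation
#' point (p >= 0.75), or with no comparable site, is an error naming the
#' pair.
#'
#' @param aln an [msa()] object
#' @param model "jc69" (default) or "p_distance"
#' @return symmetric numeric matrix with species dimnames and zero diagonal
#' @export
pairwise_distances <- function(aln, model = c("jc69", "p_distance")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "msa"))
  pc <- pair_site_counts(aln$seqs)
  n <- length(aln$species)
  d <- matrix(0, n, n, dimnames = list(aln$species, aln$species))
  for (k in seq_len(ncol(pc$pairs))) {
    i <- pc$pairs[1L, k]; j <- pc$pairs[2L, k]
    if (pc$comparable[k] == 0L) {
      stop2("no comparable sites between '", aln$species[i], "' and '",
            aln$species[j], "'")
    }
    p <- 1 - pc$matches[k] / pc$comparable[k]
    if (model == "jc69") {
      if (p >= 0.75) {
        stop2("JC69 saturation (p = ", signif(p, 4), " >= 0.75) between '",
              aln$species[i], "' and '", aln$species[j], "'")
      }
      p <- -0.75 * log(1 - (4 / 3) * p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: iteratively join the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j`, with branch lengths
#' `l_i = d(i,j)/2 + (R_i - R_j) / (2(n-2))` and distance update
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties on Q are broken by the
#' lowest taxon-index pair (input order), making the result deterministic.
#' Negative branch lengths are clamped to 0 with the deficit moved to the
#' sibling branch (the convention common phylogenetics GUIs use); the raw
#' pre-clamp lengths
#' are kept in `attr(tree, "raw_edge_length")`. On an additive matrix the
#' generating tree's topology and branch lengths are recovered exactly.
#'
#' @param d symmetric non-negative matrix with taxon dimnames (or a
#'   [stats::dist])
#' @return an unrooted [ape] `phylo` tree (binary; trifurcating root node)
#' @export
build_nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  taxa <- rownames(d) %||% paste0("t", seq_len(n))
  if (n < 2L) stop2("need >= 2 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop2("distance matrix is not symmetric")
  }
  if (any(d < 0)) stop2("distance matrix has negative entries")
  if (any(!is.finite(d))) stop2("distance matrix has non-finite entries")
  if (n == 2L) {
    txt <- sprintf("(%s:%g,%s:%g);", taxa[1], d[1, 2] / 2, taxa[2], d[1, 2] / 2)
    tr <- ape::read.tree(text = txt)
    attr(tr, "raw_edge_length") <- tr$edge.length
    return(tr)
  }
  # each active node carries a newick fragment (without outer length)
  labels <- taxa
  active <- seq_len(n)
  D <- d
  raw_lengths <- list()
  clamp <- function(li, lj) {
    raw_lengths[[length(raw_lengths) + 1L]] <<- c(li, lj)
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (length(active) > 2L) {
    m <- length(active)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest-index tie-break: scan column-major over upper triangle in order
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    ll <- clamp(li, lj)
    new_label <- sprintf("(%s:%.10g,%s:%.10g)", labels[i], ll[1], labels[j], ll[2])
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1L, m - 1L)
    if (length(keep) > 0L) {
      D2[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
      D2[m - 1L, seq_along(keep)] <- duk[keep]
      D2[seq_along(keep), m - 1L] <- duk[keep]
    }
    D <- D2
    labels <- c(labels[keep], new_label)
    active <- c(active[keep], 0L)
  }
  # two nodes left, joined by a single edge of length D[1,2]
  a <- labels[1L]; b <- labels[2L]; dd <- max(D[1L, 2L], 0)
  raw_lengths[[length(raw_lengths) + 1L]] <- D[1L, 2L]
  if (grepl("^\\(", b)) {
    txt <- sprintf("(%s:%.10g,%s;", a, dd, sub("^\\(", "", b))
  } else if (grepl("^\\(", a)) {
    txt <- sprintf("(%s:%.10g,%s;", b, dd, sub("^\\(", "", a))
  } else {
    txt <- sprintf("(%s:%.10g,%s:%.10g);", a, dd / 2, b, dd / 2)
  }
  tr <- ape::read.tree(text = txt)
  attr(tr, "raw_edge_length") <- unlist(raw_lengths)
  tr
}

#' Overlap of a region with hypomethylated intervals
#'
#' Hypomethylated regions are track intervals with score <= `hypo_threshold`;
#' the overlap is the number of query bases covered by their union.
#' Tracks containing intervals whose score was silently missing (see
#' [read_scored_bed()]) are refused.
#'
#' @param query length-1 GRanges or data.frame with chrom/start/end
#' @param track GRanges with a numeric `score` in `[0,1]` (methylation level)
#' @param hypo_threshold score at or below which an interval counts as
#'   hypomethylated (default 0.3)
#' @return a `methylation_overlap`: list(query, hypo_threshold,
#'   overlapped_bp, fraction, intervals)
#' @export
methylation_overlap <- function(query, track, hypo_threshold = 0.3) {
  query <- as_window(query)
  stopifnot(hypo_threshold >= 0, hypo_threshold <= 1)
  sc <- S4Vectors::mcols(track)$score
  if (is.null(sc)) stop2("track has no score column")
  if (any(sc < 0 | sc > 1)) stop2("methylation scores must be in [0,1]")
  if (!is.null(S4Vectors::mcols(track)$score_missing) &&
      any(S4Vectors::mcols(track)$score_missing)) {
    stop2("track contains intervals with missing methylation scores")
  }
  hypo <- track[sc <= hypo_threshold]
  inter <- GenomicRanges::intersect(
    GenomicRanges::reduce(GenomicRanges::granges(hypo), ignore.strand = TRUE),
    query, ignore.strand = TRUE)
  bp <- sum(BiocGenerics::width(inter))
  structure(
    list(query = query, hypo_threshold = hypo_threshold,
         overlapped_bp = as.integer(bp),
         fraction = bp / BiocGenerics::width(query),
         intervals = inter),
    class = "methylation_overlap"
  )
}

#' @export
print.methylation_overlap <- function(x, ...) {
  cat(sprintf("methylation_overlap %s: %d/%d bp (%.1f%%) under hypomethylated regions (score <= %.2f)\n",
              format_region(as.character(GenomeInfoDb::seqnames(x$query)),
                            BiocGenerics::start(x$query),
                            BiocGenerics::end(x$query)),
              x$overlapped_bp, BiocGenerics::width(x$query),
              100 * x$fraction, x$hypo_threshold))
  invisible(x)
}
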