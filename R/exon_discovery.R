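# Core inference: transcribed intronic islands from coverage, splice
# junctions from N-gapped reads, and novel-exon calls by junction linkage.

#' Per-base read coverage over a window
#'
#' depth[i] counts the aligned read blocks overlapping the i-th base of the
#' window; splice-skip gaps (CIGAR N) contribute nothing. Reads on other
#' chromosomes are skipped and counted.
#'
#' @param reads a `spliced_reads` object
#' @param window a length-1 GRanges (or data.frame with chrom/start/end)
#' @return a `coverage_track`: list with `window` (GRanges) and integer
#'   `depth` of length `width(window)`; `n_other_chrom` counts skipped reads
#' @export
compute_coverage <- function(reads, window) {
  window <- as_window(window)
  blocks <- read_blocks(reads)
  chrom <- as.character(GenomeInfoDb::seqnames(window))
  on_chrom <- as.character(GenomeInfoDb::seqnames(reads$alignments)) == chrom
  n_other <- sum(!on_chrom)
  flat <- unlist(blocks[on_chrom], use.names = FALSE)
  depth <- integer(BiocGenerics::width(window))
  if (length(flat) > 0L) {
    cov <- GenomicRanges::coverage(flat)[[chrom]]
    lo <- BiocGenerics::start(window); hi <- BiocGenerics::end(window)
    cov_len <- length(cov)
    take <- seq(lo, min(hi, cov_len))
    if (lo <= cov_len) {
      depth[seq_along(take)] <- as.integer(cov[take])
    }
  }
  structure(
    list(window = window, depth = depth, n_other_chrom = n_other),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  w <- x$window
  cat(sprintf("coverage_track %s: mean depth %.2f, max %d\n",
              format_region(as.character(GenomeInfoDb::seqnames(w)),
                            BiocGenerics::start(w), BiocGenerics::end(w)),
              mean(x$depth), max(x$depth)))
  invisible(x)
}

as_window <- function(window) {
  if (is.data.frame(window)) {
    window <- GenomicRanges::GRanges(window$chrom,
                                     IRanges::IRanges(window$start, window$end))
  }
  stopifnot(methods::is(window, "GRanges"), length(window) == 1L)
  if (BiocGenerics::width(window) < 1L) stop2("zero-length window")
  window
}

#' Extract splice junctions from spliced reads
#'
#' One junction per distinct (donor_end, acceptor_start) pair observed
#' between consecutive blocks of any read; `support` counts the distinct
#' reads containing it. Coordinates are 1-based inclusive block boundaries:
#' `donor_end` is the last base of the upstream block, `acceptor_start` the
#' first base of the downstream block.
#'
#' @param reads a `spliced_reads` object
#' @param min_support minimum read support to keep a junction (default 2)
#' @return data.frame (chrom, donor_end, acceptor_start, support), sorted by
#'   donor_end then acceptor_start
#' @export
extract_junctions <- function(reads, min_support = 2L) {
  stopifnot(min_support >= 1L)
  introns <- GenomicAlignments::junctions(reads$alignments)
  flat <- unlist(introns, use.names = FALSE)
  if (length(flat) == 0L) {
    return(data.frame(chrom = character(0), donor_end = integer(0),
                      acceptor_start = integer(0), support = integer(0)))
  }
  # one junction may appear once per read only (count distinct reads)
  read_idx <- rep(seq_along(introns), lengths(introns))
  key <- paste(as.character(GenomeInfoDb::seqnames(flat)),
               BiocGenerics::start(flat), BiocGenerics::end(flat), read_idx)
  flat <- flat[!duplicated(key)]
  jk <- paste(as.character(GenomeInfoDb::seqnames(flat)),
              BiocGenerics::start(flat), BiocGenerics::end(flat))
  tab <- table(jk)
  first <- flat[!duplicated(jk)]
  support <- as.integer(tab[match(paste(as.character(GenomeInfoDb::seqnames(first)),
                                        BiocGenerics::start(first),
                                        BiocGenerics::end(first)),
                                  names(tab))])
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(first)),
    donor_end = BiocGenerics::start(first) - 1L,     # intron start - 1
    acceptor_start = BiocGenerics::end(first) + 1L,  # intron end + 1
    support = support,
    stringsAsFactors = FALSE
  )
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$chrom, out$donor_end, out$acceptor_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call transcribed islands from a coverage track
#'
#' Maximal runs of depth >= `min_depth`; runs separated by <= `merge_gap`
#' sub-threshold bases are merged (the merged span's mean depth is computed
#' over the whole merged interval); islands shorter than `min_length` are
#' discarded.
#'
#' @param cov a `coverage_track` from [compute_coverage()]
#' @param min_depth minimum per-base depth (default 2)
#' @param min_length minimum island width in bp (default 50)
#' @param merge_gap maximum sub-threshold gap to bridge (default 10)
#' @return data.frame (chrom, start, end, mean_depth, max_depth), 1-based
#'   inclusive genomic coordinates
#' @export
call_islands <- function(cov, min_depth = 2L, min_length = 50L, merge_gap = 10L) {
  stopifnot(inherits(cov, "coverage_track"),
            min_depth >= 1L, min_length >= 1L, merge_gap >= 0L)
  depth_rle <- S4Vectors::Rle(cov$depth)
  runs <- IRanges::slice(depth_rle, lower = min_depth, rangesOnly = TRUE)
  runs <- IRanges::reduce(runs, min.gapwidth = merge_gap + 1L)
  runs <- runs[BiocGenerics::width(runs) >= min_length]
  offset <- BiocGenerics::start(cov$window) - 1L
  chrom <- as.character(GenomeInfoDb::seqnames(cov$window))
  if (length(runs) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      mean_depth = numeric(0), max_depth = integer(0)))
  }
  mean_depth <- vapply(seq_along(runs), function(i) {
    mean(cov$depth[BiocGenerics::start(runs)[i]:BiocGenerics::end(runs)[i]])
  }, numeric(1))
  max_depth <- vapply(seq_along(runs), function(i) {
    max(cov$depth[BiocGenerics::start(runs)[i]:BiocGenerics::end(runs)[i]])
  }, numeric(1))
  data.frame(
    chrom = chrom,
    start = BiocGenerics::start(runs) + offset,
    end = BiocGenerics::end(runs) + offset,
    mean_depth = mean_depth,
    max_depth = as.integer(max_depth),
    stringsAsFactors = FALSE
  )
}

# Match junctions to an island edge on one genomic side: the island-side
# boundary must sit within tolerance of the island edge and the exon-side
# boundary within tolerance of an annotated exon boundary strictly beyond
# the island. Returns the matching junction rows with an exon_index column.
match_links <- function(jx, island_side, island_edge, exon_side, exon_bounds,
                        side, island_limit, tol) {
  empty <- cbind(jx[0, , drop = FALSE], exon_index = integer(0))
  if (nrow(jx) == 0L) return(empty)
  cand <- which(abs(island_side - island_edge) <= tol)
  if (length(cand) == 0L) return(empty)
  exon_index <- integer(0)
  keep <- logical(0)
  for (k in cand) {
    ok <- abs(exon_side[k] - exon_bounds) <= tol &
      (if (side == "right") exon_bounds > island_limit else exon_bounds < island_limit)
    keep <- c(keep, any(ok))
    exon_index <- c(exon_index, if (any(ok)) which(ok)[1L] else NA_integer_)
  }
  out <- jx[cand[keep], , drop = FALSE]
  out$exon_index <- exon_index[keep]
  rownames(out) <- NULL
  out
}

#' Call and classify novel exons from intronic islands
#'
#' Islands overlapping any annotated exon of the gene (the union over all
#' known isoforms) are discarded. For each surviving intronic island, a
#' junction is a link on the genomic-right side when its `donor_end` is
#' within `boundary_tolerance` of the island end and its `acceptor_start` is
#' within `boundary_tolerance` of an annotated exon start to the right of the
#' island; the genomic-left side is defined mirror-wise. Links are mapped to
#' transcriptional upstream/downstream via the gene strand, and the exon
#' class follows the link-presence truth table: downstream links only =>
#' `first_exon`; upstream only => `terminal`; both => `internal`; none =>
#' `unlinked`. When a linking junction exists, the island edge is snapped to
#' the junction coordinate (splice sites are base-precise; coverage edges are
#' not). Islands extending beyond the gene span are flagged but reported.
#'
#' @param islands data.frame from [call_islands()]
#' @param gene a [gene_model()]
#' @param junctions data.frame from [extract_junctions()]
#' @param boundary_tolerance bp slack for boundary matching (default 5)
#' @return list of `novel_exon_call` objects; see [novel_exon_table()] for a
#'   flat summary
#' @export
call_novel_exons <- function(islands, gene, junctions, boundary_tolerance = 5L) {
  stopifnot(boundary_tolerance >= 0L)
  calls <- list()
  if (nrow(islands) == 0L) return(calls)
  if (any(islands$chrom != gene$chrom)) {
    stop2("islands on a different chromosome than gene '", gene$gene_id, "'")
  }
  ex_start <- BiocGenerics::start(gene$exons)
  ex_end <- BiocGenerics::end(gene$exons)
  span <- gene_span(gene)
  isl_gr <- GenomicRanges::GRanges(islands$chrom,
                                   IRanges::IRanges(islands$start, islands$end))
  hits <- GenomicRanges::countOverlaps(isl_gr, gene$exons, ignore.strand = TRUE)
  for (i in which(hits == 0L)) {
    isl <- islands[i, , drop = FALSE]
    jx <- junctions[junctions$chrom == gene$chrom, , drop = FALSE]
    # genomic-right links: junction leaves the island end into an exon start
    right <- match_links(jx, jx$donor_end, isl$end, jx$acceptor_start,
                         ex_start, "right", isl$end, boundary_tolerance)
    # genomic-left links: junction arrives at the island start from an exon end
    left <- match_links(jx, jx$acceptor_start, isl$start, jx$donor_end,
                        ex_end, "left", isl$start, boundary_tolerance)
    raw <- isl
    # junction evidence outranks coverage decay: snap island edges
    if (nrow(right) > 0L) isl$end <- right$donor_end[which.max(right$support)]
    if (nrow(left) > 0L) isl$start <- left$acceptor_start[which.max(left$support)]
    if (gene$strand == "-") {
      upstream <- right; downstream <- left
    } else {
      upstream <- left; downstream <- right
    }
    exon_class <- if (nrow(upstream) == 0L && nrow(downstream) > 0L) "first_exon"
      else if (nrow(upstream) > 0L && nrow(downstream) == 0L) "terminal"
      else if (nrow(upstream) > 0L && nrow(downstream) > 0L) "internal"
      else "unlinked"
    flags <- character(0)
    if (isl$start < BiocGenerics::start(span) || isl$end > BiocGenerics::end(span)) {
      flags <- c(flags, "outside_gene_span")
    }
    calls[[length(calls) + 1L]] <- structure(
      list(island = isl, raw_island = raw,
           upstream_links = upstream, downstream_links = downstream,
           exon_class = exon_class, gene_id = gene$gene_id,
           strand = gene$strand, flags = flags),
      class = "novel_exon_call"
    )
  }
  calls
}

#' @export
print.novel_exon_call <- function(x, ...) {
  cat(sprintf("novel_exon_call [%s] %s (gene %s, strand %s)\n",
              x$exon_class,
              format_region(x$island$chrom, x$island$start, x$island$end),
              x$gene_id, x$strand))
  cat(sprintf("  links: %d upstream, %d downstream; mean depth %.1f%s\n",
              nrow(x$upstream_links), nrow(x$downstream_links),
              x$island$mean_depth,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Flat summary table of novel exon calls
#'
#' One row per call with 1-based inclusive printed coordinates, ready for
#' TSV export.
#'
#' @param calls list of `novel_exon_call` objects
#' @return data.frame
#' @export
novel_exon_table <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(gene_id = character(0), region = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      length = integer(0), exon_class = character(0),
                      mean_depth = numeric(0), n_upstream_links = integer(0),
                      n_downstream_links = integer(0), flags = character(0)))
  }
  do.call(rbind, lapply(calls, function(x) {
    data.frame(
      gene_id = x$gene_id,
      region = format_region(x$island$chrom, x$island$start, x$island$end),
      chrom = x$island$chrom, start = x$island$start, end = x$island$end,
      length = x$island$end - x$island$start + 1L,
      exon_class = x$exon_class,
      mean_depth = x$island$mean_depth,
      n_upstream_links = nrow(x$upstream_links),
      n_downstream_links = nrow(x$downstream_links),
      flags = paste(x$flags, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
}

#' Export islands or calls as BED
#'
#' @param x data.frame with chrom/start/end (e.g. from [call_islands()] or
#'   [novel_exon_table()])
#' @param path output BED path (0-based half-open on disk)
#' @return `path`, invisibly
#' @export
export_islands_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
  if (!is.null(x$mean_depth)) S4Vectors::mcols(gr)$score <- x$mean_depth
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
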