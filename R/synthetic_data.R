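# Synthetic-locus generator: a multi-exon gene with one unannotated exon
# planted in an intron, genotype-dependent spliced reads, qPCR tables, a
# multi-species alignment with planted conserved blocks, and tissue
# methylation tracks — all with known ground truth.

#' Specification of a synthetic gene locus
#'
#' The default locus mimics a multi-exon neural gene with two known isoforms
#' (a long one using all 7 exons and a short one starting at exon 3) and one
#' unannotated 386 bp exon planted inside the intron between exons 4 and 5.
#' The novel transcript starts at the planted exon and continues from exon 5
#' along the known structure.
#'
#' @param chrom chromosome name
#' @param locus_start 1-based start of exon 1
#' @param exon_lengths lengths of the known exons (bp)
#' @param intron_lengths lengths of the introns between consecutive exons
#'   (length = exons - 1)
#' @param novel_intron index of the intron carrying the novel exon (intron i
#'   lies between exons i and i+1)
#' @param novel_offset bp between the upstream exon end and the novel exon
#'   start
#' @param novel_length length of the planted novel exon (default 386 bp)
#' @param transcripts named list of exon-index vectors for the known guide
#'   transcripts
#' @param genotype_weights named list: per genotype, a named numeric vector
#'   of expression weights for the known transcripts plus `novel`. The
#'   defaults plant a novel-exon KO:WT ratio of 8 in the "e67" pair and 1.71
#'   in the "e7" pair, against equal-weight known isoforms.
#' @param seed integer seed controlling the genome sequence
#' @return a `locus_spec` object
#' @export
locus_spec <- function(chrom = "chrS",
                       locus_start = 1001L,
                       exon_lengths = c(200L, 150L, 180L, 120L, 250L, 140L, 300L),
                       intron_lengths = c(500L, 400L, 600L, 1500L, 700L, 450L),
                       novel_intron = 4L,
                       novel_offset = 400L,
                       novel_length = 386L,
                       transcripts = list(long_isoform = 1:7, short_isoform = 3:7),
                       genotype_weights = list(
                         e67_KO = c(long_isoform = 10, short_isoform = 10, novel = 8),
                         e67_WT = c(long_isoform = 10, short_isoform = 10, novel = 1),
                         e7_KO = c(long_isoform = 10, short_isoform = 10, novel = 1.71),
                         e7_WT = c(long_isoform = 10, short_isoform = 10, novel = 1)),
                       seed = 20200406L) {
  if (length(intron_lengths) != length(exon_lengths) - 1L) {
    stop2("need one intron length per exon pair")
  }
  if (any(exon_lengths <= 0L) || any(intron_lengths <= 0L)) {
    stop2("exon and intron lengths must be positive")
  }
  if (novel_length <= 0L) stop2("novel exon length must be positive")
  if (novel_intron < 1L || novel_intron > length(intron_lengths)) {
    stop2("novel_intron out of range")
  }
  if (novel_offset < 1L ||
      novel_offset + novel_length > intron_lengths[novel_intron]) {
    stop2("novel exon does not fit strictly inside intron ", novel_intron)
  }
  structure(
    list(chrom = chrom, locus_start = as.integer(locus_start),
         exon_lengths = as.integer(exon_lengths),
         intron_lengths = as.integer(intron_lengths),
         novel_intron = as.integer(novel_intron),
         novel_offset = as.integer(novel_offset),
         novel_length = as.integer(novel_length),
         transcripts = transcripts, genotype_weights = genotype_weights,
         seed = as.integer(seed)),
    class = "locus_spec"
  )
}

#' Simulate a gene locus with a planted unannotated exon
#'
#' Emits the annotation (known transcripts only; the planted exon is absent
#' from the GTF and present only in the ground truth), a random genome
#' sequence for the locus chromosome, and the full ground truth (planted
#' exon, true junction, genotype weights, true fold changes). Outputs are
#' byte-identical for the same spec/seed.
#'
#' @param spec a [locus_spec()]
#' @param dir optional output directory; when given, writes `annotation.gtf`,
#'   `genome.fa` and `truth.json`
#' @return a `synthetic_locus`: list(gene = [gene_model()], genome =
#'   DNAStringSet, truth = ground-truth list, spec, files)
#' @export
simulate_locus <- function(spec = locus_spec(), dir = NULL) {
  stopifnot(inherits(spec, "locus_spec"))
  k <- length(spec$exon_lengths)
  starts <- integer(k); ends <- integer(k)
  pos <- spec$locus_start
  for (i in seq_len(k)) {
    starts[i] <- pos
    ends[i] <- pos + spec$exon_lengths[i] - 1L
    if (i < k) pos <- ends[i] + spec$intron_lengths[i] + 1L
  }
  gene <- gene_model("geneS", spec$chrom, "+",
                     data.frame(start = starts, end = ends), spec$transcripts)
  nstart <- ends[spec$novel_intron] + spec$novel_offset + 1L
  nend <- nstart + spec$novel_length - 1L
  chrom_len <- ends[k] + 1000L
  set.seed(spec$seed)
  genome_seq <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                      collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, spec$chrom))
  downstream_exon <- spec$novel_intron + 1L
  truth <- list(
    chrom = spec$chrom, chrom_length = chrom_len,
    novel_exon = list(start = nstart, end = nend),
    junction = list(donor_end = nend, acceptor_start = starts[downstream_exon]),
    downstream_exon_index = downstream_exon,
    exon_class = "first_exon",
    novel_chain_exons = seq(downstream_exon, k),
    genotype_weights = spec$genotype_weights,
    true_folds = local({
      gw <- spec$genotype_weights
      folds <- list()
      for (ko in grep("_KO$", names(gw), value = TRUE)) {
        wt <- sub("_KO$", "_WT", ko)
        if (wt %in% names(gw) && gw[[wt]]["novel"] > 0) {
          folds[[sub("_KO$", "", ko)]] <-
            unname(gw[[ko]]["novel"] / gw[[wt]]["novel"])
        }
      }
      folds
    })
  )
  files <- list()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files$annotation <- file.path(dir, "annotation.gtf")
    write_gene_annotation(gene, files$annotation)
    files$genome <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, files$genome)
    files$truth <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  structure(list(gene = gene, genome = genome, truth = truth, spec = spec,
                 files = files),
            class = "synthetic_locus")
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf("synthetic_locus: gene '%s' with %d known exons; planted novel exon %s (%d bp)\n",
              x$gene$gene_id, length(x$gene$exons),
              format_region(x$truth$chrom, x$truth$novel_exon$start,
                            x$truth$novel_exon$end),
              x$truth$novel_exon$end - x$truth$novel_exon$start + 1L))
  invisible(x)
}

# exon chains (GRanges) per transcript, novel transcript included
locus_transcript_models <- function(locus) {
  gene <- locus$gene
  tx <- lapply(gene$transcripts, function(idx) gene$exons[idx])
  nov <- GenomicRanges::GRanges(
    locus$truth$chrom,
    IRanges::IRanges(c(locus$truth$novel_exon$start,
                       BiocGenerics::start(gene$exons)[locus$truth$novel_chain_exons]),
                     c(locus$truth$novel_exon$end,
                       BiocGenerics::end(gene$exons)[locus$truth$novel_chain_exons])))
  c(tx, list(novel = nov))
}

#' Simulate spliced reads for one genotype
#'
#' Reads are sampled along each transcript proportionally to the genotype's
#' expression weights; reads spanning splice sites get N-gapped CIGARs; all
#' reads are emitted as uniquely mapped (MAPQ 60, primary). The per-base
#' depth contributed by transcript t is `depth * w_t / sum(known weights)`,
#' so a constitutive exon (present in every known isoform) has expected
#' depth equal to `depth`.
#'
#' Two sampling modes: `noiseless = TRUE` tiles deterministic end-truncated
#' fragments so every transcript base has depth exactly d (idealized uniform
#' coverage; boundary recovery is then well-posed at unjunctioned exon
#' ends); the default stochastic mode draws a Poisson number of fragments
#' with uniform starts over the end-extended domain, giving unbiased
#' coverage up to the transcript boundaries.
#'
#' @param locus a `synthetic_locus` from [simulate_locus()]
#' @param genotype one of the names of `spec$genotype_weights`
#' @param depth target per-base depth over a constitutive exon (default 50)
#' @param read_length read length in bp (default 100)
#' @param seed integer seed
#' @param noiseless deterministic uniform tiling instead of Poisson sampling
#' @param path optional SAM output path (header records the library size in
#'   an `@CO` line)
#' @return a `spliced_reads` object with attribute `library_size`; written
#'   to `path` as SAM when given
#' @export
simulate_reads <- function(locus, genotype, depth = 50, read_length = 100L,
                           seed = 1L, noiseless = FALSE, path = NULL) {
  stopifnot(inherits(locus, "synthetic_locus"), depth > 0, read_length >= 20L)
  weights <- locus$spec$genotype_weights[[genotype]]
  if (is.null(weights)) {
    stop2("unknown genotype '", genotype, "'; known: ",
          paste(names(locus$spec$genotype_weights), collapse = ", "))
  }
  models <- locus_transcript_models(locus)
  known <- setdiff(names(models), "novel")
  w_ref <- sum(weights[known])
  set.seed(seed)
  all_pos <- integer(0); all_cigar <- character(0); all_tx <- character(0)
  for (tx in names(models)) {
    exs <- models[[tx]]
    L <- sum(BiocGenerics::width(exs))
    d_t <- depth * unname(weights[tx]) / w_ref
    if (d_t <= 0) next
    if (noiseless) {
      s <- read_length / d_t
      frag_starts <- round(seq(1 - read_length + 1, L, by = s))
    } else {
      domain <- L + read_length - 1
      n <- stats::rpois(1L, d_t * domain / read_length)
      frag_starts <- sort(sample.int(domain, n, replace = TRUE) - read_length + 1L)
    }
    frag_ends <- pmin(frag_starts + read_length - 1L, L)
    frag_starts <- pmax(frag_starts, 1L)
    ok <- frag_ends >= frag_starts
    frag_starts <- frag_starts[ok]; frag_ends <- frag_ends[ok]
    if (length(frag_starts) == 0L) next
    maps <- tx_to_genomic(frag_starts, frag_ends, exs)
    all_pos <- c(all_pos, maps$pos)
    all_cigar <- c(all_cigar, maps$cigar)
    all_tx <- c(all_tx, rep(tx, length(maps$pos)))
  }
  ord <- order(all_pos)
  all_pos <- all_pos[ord]; all_cigar <- all_cigar[ord]; all_tx <- all_tx[ord]
  qname <- sprintf("sim_%s_%06d", genotype, seq_along(all_pos))
  seqlen <- stats::setNames(locus$truth$chrom_length, locus$truth$chrom)
  reads <- spliced_reads(locus$truth$chrom, all_pos, all_cigar, qname,
                         seqlengths = seqlen)
  S4Vectors::mcols(reads$alignments)$transcript <- all_tx
  # The SAM emulates a single-locus extract of a whole-transcriptome
  # library: the library size records total sequencing effort (proportional
  # to depth, equal across genotypes), not the locus record count, exactly
  # as a genome-wide "total uniquely mapped reads" figure would.
  lib <- as.integer(round(depth * 2e4))
  attr(reads, "library_size") <- lib
  attr(reads, "genotype") <- genotype
  if (!is.null(path)) write_sam(reads, path, seqlen, lib)
  reads
}

# Map transcript-coordinate fragments onto genomic blocks and CIGARs.
tx_to_genomic <- function(fs, fe, exons) {
  ex_w <- BiocGenerics::width(exons)
  ex_start <- BiocGenerics::start(exons)
  tx_end <- cumsum(ex_w)
  tx_start <- tx_end - ex_w + 1L
  n <- length(fs)
  pos <- integer(n); cig <- character(n)
  for (r in seq_len(n)) {
    segs_m <- integer(0); segs_n <- integer(0); first <- NA_integer_
    for (e in seq_along(ex_w)) {
      a <- max(fs[r], tx_start[e]); b <- min(fe[r], tx_end[e])
      if (a > b) next
      gstart <- ex_start[e] + (a - tx_start[e])
      if (is.na(first)) {
        first <- gstart
      } else {
        prev_gend <- ex_start[e - 1L] + (tx_end[e - 1L] - tx_start[e - 1L])
        segs_n <- c(segs_n, gstart - prev_gend - 1L)
      }
      segs_m <- c(segs_m, b - a + 1L)
    }
    pos[r] <- first
    parts <- character(0)
    for (s in seq_along(segs_m)) {
      parts <- c(parts, paste0(segs_m[s], "M"))
      if (s <= length(segs_n)) parts <- c(parts, paste0(segs_n[s], "N"))
    }
    cig[r] <- paste(parts, collapse = "")
  }
  list(pos = pos, cigar = cig)
}

# Emit a spliced_reads object as a headered SAM file.
write_sam <- function(reads, path, seqlengths, library_size) {
  aln <- reads$alignments
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths),
           sprintf("@CO\tlibrary_size:%d", library_size))
  body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tNH:i:1",
                  S4Vectors::mcols(aln)$qname,
                  as.character(GenomeInfoDb::seqnames(aln)),
                  BiocGenerics::start(aln),
                  GenomicAlignments::cigar(aln))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Library size recorded in a SAM header comment
#'
#' Falls back to counting mapped records when no `@CO library_size` comment
#' is present.
#'
#' @param path SAM path
#' @return integer library size
#' @export
sam_library_size <- function(path) {
  hdr <- grep("^@", readLines(path, warn = FALSE), value = TRUE)
  co <- grep("^@CO\tlibrary_size:", hdr, value = TRUE)
  if (length(co) > 0L) {
    return(as.integer(sub("^@CO\tlibrary_size:", "", co[1L])))
  }
  length(grep("^[^@]", readLines(path, warn = FALSE)))
}

#' Simulate a qPCR Ct table with known fold change
#'
#' Control-group dCt (target minus reference Ct) is drawn about a baseline;
#' the case group is shifted by `-log2(true_fold)`. Gaussian noise with sd
#' `ct_sd` is applied per technical replicate to both target and reference
#' Ct, with `n_replicates` technical replicates per biological sample. With
#' `ct_sd = 0` the [ddct_fold_change()] estimate recovers `true_fold`
#' exactly.
#'
#' @param true_fold planted case/control fold change (> 0)
#' @param n_per_group biological samples per group (default 5)
#' @param ct_sd Gaussian Ct noise sd in cycles (default 0.3)
#' @param n_replicates technical replicates per sample (default 3)
#' @param seed integer seed
#' @param baseline_dct control-group dCt baseline in cycles (default 6)
#' @param reference_ct reference-gene Ct level (default 18)
#' @return data.frame (sample, group, replicate, target_ct, reference_ct)
#' @export
simulate_qpcr <- function(true_fold, n_per_group = 5L, ct_sd = 0.3,
                          n_replicates = 3L, seed = 1L,
                          baseline_dct = 6, reference_ct = 18) {
  stopifnot(true_fold > 0, n_per_group >= 1L, ct_sd >= 0, n_replicates >= 1L)
  set.seed(seed)
  rows <- list()
  for (grp in c("control", "case")) {
    shift <- if (grp == "case") -log2(true_fold) else 0
    for (i in seq_len(n_per_group)) {
      for (r in seq_len(n_replicates)) {
        ref <- reference_ct + stats::rnorm(1L, 0, ct_sd)
        tgt <- ref + baseline_dct + shift + stats::rnorm(1L, 0, ct_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_%d", grp, i), group = grp, replicate = r,
          target_ct = tgt, reference_ct = ref, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Per-site substitution rate q giving expected pairwise identity p between
# two sequences independently mutated from a common reference:
# (1-q)^2 + q^2/3 = p. For p below the random floor (0.25), q = 3/4.
identity_to_subrate <- function(p) {
  if (p >= 1) return(0)
  disc <- 1 - (4 / 3) * (1 - p)
  if (disc < 0) return(0.75)
  0.75 * (1 - sqrt(disc))
}

#' Simulate conservation and methylation tracks for the planted exon
#'
#' Builds an `n_species` alignment over the planted novel exon plus
#' `upstream_bp` of upstream context, with two planted high-identity blocks
#' (one upstream, promoter-like; one at the exon 3' end) against a divergent
#' background, plus per-tissue methylation tracks in which brain tissues are
#' hypomethylated (score 0.1) over the exon region and all tissues are
#' methylated (score 0.8) elsewhere. Planted block coordinates are aligned
#' to the default conservation window grid. The alignment is ungapped, so
#' alignment columns map 1:1 onto genomic positions of the extracted region.
#'
#' @param locus a `synthetic_locus`
#' @param n_species number of species (default 8)
#' @param conserved_identity target pairwise identity inside planted blocks
#'   (default 0.95)
#' @param background_identity target pairwise identity elsewhere
#'   (default 0.35)
#' @param upstream_bp upstream context included in the alignment
#'   (default 200)
#' @param tissues tissue names for methylation tracks; names containing
#'   "brain" are hypomethylated over the exon
#' @param seed integer seed
#' @param dir optional output directory (writes `alignment.fa` and
#'   `methylation_<tissue>.bed`)
#' @return an `evo_tracks`: list(msa, meth_tracks (named list of GRanges),
#'   truth = list(conserved_blocks (alignment columns), region,
#'   hypomethylated), files)
#' @export
simulate_evo_tracks <- function(locus, n_species = 8L,
                                conserved_identity = 0.95,
                                background_identity = 0.35,
                                upstream_bp = 200L,
                                tissues = c("brain_frontal", "brain_hippocampus",
                                            "liver", "heart"),
                                seed = 1L, dir = NULL) {
  stopifnot(inherits(locus, "synthetic_locus"), n_species >= 2L,
            background_identity >= 0, background_identity < conserved_identity,
            conserved_identity <= 1)
  species <- c("mouse", "human", "rhesus", "rat", "dog", "cow", "chicken",
               "frog", sprintf("species%d", seq_len(max(0L, n_species - 8L))))
  species <- species[seq_len(n_species)]
  nov <- locus$truth$novel_exon
  region_start <- nov$start - upstream_bp
  region_end <- nov$end
  L <- region_end - region_start + 1L
  ref <- strsplit(as.character(Biostrings::subseq(
    locus$genome[[locus$truth$chrom]], region_start, region_end)), "")[[1]]
  # planted blocks, aligned to the default window grid (width 20, step 10):
  # one in the upstream context, one at the exon 3' end
  exon_col <- upstream_bp + 1L                      # first exon column
  grid <- function(x) 10L * floor((x - 1L) / 10L) + 1L  # snap to 10k+1
  b1 <- c(grid(31L), grid(31L) + 119L)              # upstream, 120 cols
  b2_end <- 10L * floor(L / 10L) - 10L              # near the last grid row
  b2 <- c(b2_end - 119L, b2_end)                    # exon 3' end, 120 cols
  blocks <- data.frame(start = c(b1[1L], b2[1L]), end = c(b1[2L], b2[2L]))
  q_cons <- identity_to_subrate(conserved_identity)
  q_back <- identity_to_subrate(background_identity)
  qcol <- rep(q_back, L)
  for (b in seq_len(nrow(blocks))) {
    qcol[blocks$start[b]:blocks$end[b]] <- q_cons
  }
  set.seed(seed)
  seqs <- matrix("", n_species, L, dimnames = list(species, NULL))
  seqs["mouse", ] <- ref
  for (sp in setdiff(species, "mouse")) {
    mut <- stats::runif(L) < qcol
    row <- ref
    if (any(mut)) {
      row[mut] <- vapply(ref[mut], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
    seqs[sp, ] <- row
  }
  aln <- msa(apply(seqs, 1L, paste, collapse = ""))
  exon_gr <- GenomicRanges::GRanges(locus$truth$chrom,
                                    IRanges::IRanges(nov$start, nov$end))
  meth <- list()
  span_start <- max(1L, region_start - 2000L)
  span_end <- min(locus$truth$chrom_length, region_end + 2000L)
  for (t in tissues) {
    if (grepl("brain", t)) {
      hypo <- GenomicRanges::GRanges(locus$truth$chrom,
                                     IRanges::IRanges(nov$start - 50L, nov$end + 50L))
      rest <- GenomicRanges::setdiff(
        GenomicRanges::GRanges(locus$truth$chrom,
                               IRanges::IRanges(span_start, span_end)), hypo)
      gr <- c(hypo, rest)
      S4Vectors::mcols(gr)$score <- c(0.1, rep(0.8, length(rest)))
    } else {
      gr <- GenomicRanges::GRanges(locus$truth$chrom,
                                   IRanges::IRanges(span_start, span_end))
      S4Vectors::mcols(gr)$score <- 0.8
    }
    S4Vectors::mcols(gr)$score_missing <- FALSE
    meth[[t]] <- sort(gr, ignore.strand = TRUE)
  }
  truth <- list(conserved_blocks = blocks,
                region = list(start = region_start, end = region_end),
                exon_columns = c(exon_col, L),
                hypomethylated_tissues = grep("brain", tissues, value = TRUE))
  files <- list()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files$alignment <- file.path(dir, "alignment.fa")
    write_msa(aln, files$alignment)
    for (t in tissues) {
      f <- file.path(dir, sprintf("methylation_%s.bed", t))
      gr <- meth[[t]]
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(score = S4Vectors::mcols(gr)$score)
      write_scored_bed(gr, f)
      files[[paste0("methylation_", t)]] <- f
    }
  }
  structure(list(msa = aln, meth_tracks = meth, truth = truth,
                 exon = exon_gr, files = files),
            class = "evo_tracks")
}
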