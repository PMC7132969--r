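# End-to-end orchestration: a declarative YAML config drives discovery
# (coverage -> junctions -> islands -> calls -> variants -> fold changes)
# and characterization (conservation, phylogeny, methylation, ddCt), with
# TSV + JSON reports.

default_params <- function() {
  list(min_depth = 2L, min_length = 50L, merge_gap = 10L, min_support = 2L,
       boundary_tolerance = 5L, min_mapq = 30L, window_margin = 200L,
       pseudocount = 0)
}

#' Read and validate a pipeline run configuration
#'
#' A single declarative YAML file with nested sections; every stage
#' parameter has a documented default and is overridable. Referenced paths
#' are checked at validation time.
#'
#' @param path YAML config path, or an equivalent named list
#' @return a validated `run_config` list
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path)) {
    if (!file.exists(path)) stop2("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  config$params <- utils::modifyList(default_params(), config$params %||% list())
  p <- config$params
  if (p$min_depth < 1L || p$min_length < 1L || p$merge_gap < 0L ||
      p$min_support < 1L || p$boundary_tolerance < 0L) {
    stop2("stage parameter out of range")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  if (!is.null(config$annotation) && !file.exists(config$annotation)) {
    stop2("annotation file not found: ", config$annotation)
  }
  for (s in config$samples %||% list()) {
    if (is.null(s$id) || is.null(s$path) || is.null(s$genotype)) {
      stop2("each sample needs id, path and genotype")
    }
    if (!file.exists(s$path)) stop2("alignment file not found: ", s$path)
  }
  ch <- config$characterization %||% list()
  for (f in c(ch$msa, ch$qpcr, unlist(ch$methylation))) {
    if (!is.null(f) && !file.exists(f)) stop2("input file not found: ", f)
  }
  structure(config, class = "run_config")
}

parse_region <- function(txt) {
  m <- regmatches(txt, regexec("^([^:]+):([0-9]+)-([0-9]+)$", txt))[[1]]
  if (length(m) != 4L) stop2("cannot parse region '", txt,
                             "' (expected chrom:start-end, 1-based inclusive)")
  GenomicRanges::GRanges(m[2L], IRanges::IRanges(as.integer(m[3L]),
                                                 as.integer(m[4L])))
}

#' Run the discovery pipeline
#'
#' Per sample: coverage over each annotated gene's window, splice junctions,
#' transcribed islands, novel-exon calls (printed 1-based inclusive) and
#' guided transcript variants; across genotypes: a read-density fold change
#' per called novel region for every configured comparison. Reports are
#' written to `outdir` as TSV and JSON; every parameter used is logged.
#' Discovery is deterministic: rerunning the same config reproduces the
#' report.
#'
#' @param config a `run_config` (or YAML path / list accepted by
#'   [read_run_config()])
#' @return a `discovery_report` list (samples, calls, variants,
#'   fold_changes, params), invisibly written to `outdir` when configured
#' @export
run_discovery <- function(config) {
  config <- read_run_config(config)
  p <- config$params
  genes <- read_gene_annotation(config$annotation)
  if (length(genes) == 0L) stop2("no genes in annotation ", config$annotation)
  message("run_discovery: ", length(config$samples), " sample(s), ",
          length(genes), " gene(s); params: ",
          paste(names(p), unlist(p), sep = "=", collapse = ", "))
  samples <- list()
  all_calls <- list()
  for (s in config$samples) {
    reads <- read_alignments(s$path, unique_only = TRUE, min_mapq = p$min_mapq)
    lib <- sam_library_size(s$path)
    junctions <- extract_junctions(reads, min_support = p$min_support)
    per_gene <- list()
    for (g in names(genes)) {
      gene <- genes[[g]]
      span <- gene_span(gene)
      window <- GenomicRanges::GRanges(
        gene$chrom,
        IRanges::IRanges(max(1L, BiocGenerics::start(span) - p$window_margin),
                         BiocGenerics::end(span) + p$window_margin))
      cov <- compute_coverage(reads, window)
      islands <- call_islands(cov, p$min_depth, p$min_length, p$merge_gap)
      calls <- call_novel_exons(islands, gene, junctions, p$boundary_tolerance)
      graph <- build_splice_graph(gene, calls, junctions, p$boundary_tolerance)
      variants <- reconstruct_variants(graph)
      per_gene[[g]] <- list(gene = gene, coverage = cov, islands = islands,
                            calls = calls, graph = graph, variants = variants)
      for (cl in calls) {
        all_calls[[length(all_calls) + 1L]] <-
          cbind(sample = s$id, genotype = s$genotype, novel_exon_table(list(cl)))
      }
    }
    samples[[s$id]] <- list(id = s$id, genotype = s$genotype,
                            library_size = lib, reads = reads,
                            junctions = junctions, genes = per_gene)
  }
  call_tab <- if (length(all_calls) > 0L) do.call(rbind, all_calls) else
    cbind(sample = character(0), genotype = character(0), novel_exon_table(list()))
  # fold changes per comparison over the union of called novel regions
  folds <- list()
  if (nrow(call_tab) > 0L && length(config$comparisons %||% list()) > 0L) {
    regions <- GenomicRanges::reduce(
      GenomicRanges::GRanges(call_tab$chrom,
                             IRanges::IRanges(call_tab$start, call_tab$end)))
    for (cmp in config$comparisons) {
      case_ids <- names(Filter(function(x) x$genotype == cmp$case, samples))
      ctrl_ids <- names(Filter(function(x) x$genotype == cmp$control, samples))
      if (length(case_ids) == 0L || length(ctrl_ids) == 0L) next
      for (ri in seq_along(regions)) {
        region <- regions[ri]
        dens <- function(ids) lapply(ids, function(id) {
          region_density(samples[[id]]$reads, region,
                         samples[[id]]$library_size, sample_id = id)
        })
        fc <- density_fold_change(dens(case_ids), dens(ctrl_ids),
                                  pseudocount = p$pseudocount)
        folds[[length(folds) + 1L]] <- data.frame(
          comparison = cmp$name %||% paste0(cmp$case, "_vs_", cmp$control),
          region = format_region(as.character(GenomeInfoDb::seqnames(region)),
                                 BiocGenerics::start(region),
                                 BiocGenerics::end(region)),
          case = cmp$case, control = cmp$control,
          n_case = fc$n_case, n_control = fc$n_control,
          fold_change = fc$estimate, stringsAsFactors = FALSE)
      }
    }
  }
  fold_tab <- if (length(folds) > 0L) do.call(rbind, folds) else
    data.frame(comparison = character(0), region = character(0),
               case = character(0), control = character(0),
               n_case = integer(0), n_control = integer(0),
               fold_change = numeric(0))
  var_tab <- do.call(rbind, lapply(names(samples), function(id) {
    do.call(rbind, lapply(names(samples[[id]]$genes), function(g) {
      vt <- variant_table(samples[[id]]$genes[[g]]$variants)
      if (nrow(vt) == 0L) return(NULL)
      cbind(sample = id, gene_id = g, vt)
    }))
  }))
  if (nrow(call_tab) == 0L) {
    message("no novel transcribed regions detected at the configured thresholds")
  }
  report <- structure(
    list(samples = samples, calls = call_tab, variants = var_tab,
         fold_changes = fold_tab, params = p),
    class = "discovery_report"
  )
  if (!is.null(config$outdir)) write_discovery_report(report, config$outdir)
  invisible(report)
}

write_discovery_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(report$calls, "novel_exon_calls.tsv")
  tsv(report$fold_changes, "fold_changes.tsv")
  if (!is.null(report$variants)) tsv(report$variants, "variants.tsv")
  for (id in names(report$samples)) {
    for (g in names(report$samples[[id]]$genes)) {
      pg <- report$samples[[id]]$genes[[g]]
      cov <- pg$coverage
      tsv(data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(cov$window)),
        pos = seq(BiocGenerics::start(cov$window), BiocGenerics::end(cov$window)),
        depth = cov$depth), sprintf("coverage_%s_%s.tsv", id, g))
    }
  }
  jsonlite::write_json(
    list(calls = report$calls, fold_changes = report$fold_changes,
         variants = report$variants, params = report$params),
    file.path(outdir, "discovery_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(outdir)
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf("discovery_report: %d sample(s), %d novel exon call(s), %d fold change(s)\n",
              length(x$samples), nrow(x$calls), nrow(x$fold_changes)))
  if (nrow(x$calls) > 0L) {
    print(x$calls[, c("sample", "genotype", "region", "exon_class", "mean_depth")])
  }
  if (nrow(x$fold_changes) > 0L) {
    print(x$fold_changes[, c("comparison", "region", "fold_change")])
  }
  invisible(x)
}

#' Run the characterization pipeline
#'
#' Conservation profile and blocks, pairwise distances and NJ tree (Newick)
#' from a supplied alignment; hypomethylated-region overlaps per tissue for
#' a query region; ddCt folds from a Ct table. Each section is omitted
#' cleanly when its input is absent from the config's `characterization`
#' section.
#'
#' @param config a `run_config` (or YAML path / list)
#' @return a `characterization_report` list with sections `conservation`,
#'   `distances`, `tree`, `newick`, `methylation`, `qpcr`
#' @export
run_characterization <- function(config) {
  config <- read_run_config(config)
  ch <- config$characterization %||% list()
  out <- list()
  if (!is.null(ch$msa)) {
    aln <- read_msa(ch$msa)
    cp <- ch$conservation %||% list()
    out$conservation <- conserved_blocks(
      aln, window_size = cp$window_size %||% 20L, step = cp$step %||% 10L,
      threshold = cp$threshold %||% 0.8)
    out$distances <- pairwise_distances(aln, model = ch$distance_model %||% "jc69")
    out$tree <- build_nj_tree(out$distances)
    out$newick <- write_newick(out$tree)
  }
  if (!is.null(ch$methylation) && !is.null(ch$region)) {
    query <- parse_region(ch$region)
    out$methylation <- lapply(ch$methylation, function(f) {
      methylation_overlap(query, read_scored_bed(f),
                          hypo_threshold = ch$hypo_threshold %||% 0.3)
    })
  }
  if (!is.null(ch$qpcr)) {
    tab <- read_qpcr_table(ch$qpcr)
    out$qpcr <- ddct_fold_change(tab,
                                 case_group = ch$qpcr_case %||% "case",
                                 control_group = ch$qpcr_control %||% "control")
  }
  out <- structure(out, class = "characterization_report")
  if (!is.null(config$outdir)) write_characterization_report(out, config$outdir)
  invisible(out)
}

write_characterization_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list()
  if (!is.null(report$conservation)) {
    tsv(report$conservation$profile, "conservation_profile.tsv")
    tsv(report$conservation$blocks, "conserved_blocks.tsv")
    js$conserved_blocks <- report$conservation$blocks
  }
  if (!is.null(report$newick)) {
    writeLines(report$newick, file.path(outdir, "tree.nwk"))
    js$newick <- report$newick
  }
  if (!is.null(report$methylation)) {
    meth <- do.call(rbind, lapply(names(report$methylation), function(t) {
      m <- report$methylation[[t]]
      data.frame(tissue = t, overlapped_bp = m$overlapped_bp,
                 fraction = m$fraction, stringsAsFactors = FALSE)
    }))
    tsv(meth, "methylation_overlap.tsv")
    js$methylation <- meth
  }
  if (!is.null(report$qpcr)) {
    js$qpcr <- list(fold_change = report$qpcr$estimate,
                    ddct = report$qpcr$ddct)
  }
  jsonlite::write_json(js, file.path(outdir, "characterization_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(outdir)
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("characterization_report:\n")
  if (!is.null(x$conservation)) {
    cat(sprintf("  conservation: %d block(s)\n", nrow(x$conservation$blocks)))
  }
  if (!is.null(x$newick)) cat("  tree:", x$newick, "\n")
  if (!is.null(x$methylation)) {
    for (t in names(x$methylation)) {
      cat(sprintf("  methylation [%s]: fraction %.2f\n", t,
                  x$methylation[[t]]$fraction))
    }
  }
  if (!is.null(x$qpcr)) {
    cat(sprintf("  qPCR ddCt fold: %.4g\n", x$qpcr$estimate))
  }
  invisible(x)
}

#' Generate a complete synthetic dataset plus a ready-to-run config
#'
#' Writes annotation, genome, per-genotype SAM files, qPCR tables for both
#' planted fold changes, evolutionary tracks and a `config.yaml` wired to
#' them, so `run_discovery(file.path(dir, "config.yaml"))` works directly.
#'
#' @param dir output directory
#' @param spec a [locus_spec()]
#' @param depth sequencing depth for the read simulation (default 50)
#' @param read_length read length (default 100)
#' @param noiseless deterministic tiling (default FALSE)
#' @param ct_sd qPCR Ct noise sd (default 0.3)
#' @param seed master seed; per-file seeds are derived from it
#' @return invisibly, a list with the locus, file paths and config path
#' @export
simulate_dataset <- function(dir, spec = locus_spec(), depth = 50,
                             read_length = 100L, noiseless = FALSE,
                             ct_sd = 0.3, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  locus <- simulate_locus(spec, dir = dir)
  genotypes <- names(spec$genotype_weights)
  sam_paths <- character(0)
  for (i in seq_along(genotypes)) {
    gt <- genotypes[i]
    f <- file.path(dir, sprintf("%s.sam", gt))
    simulate_reads(locus, gt, depth = depth, read_length = read_length,
                   seed = seed * 1000L + i, noiseless = noiseless, path = f)
    sam_paths[gt] <- f
  }
  qpcr_paths <- character(0)
  cmps <- names(locus$truth$true_folds)
  for (cmp in cmps) {
    tf <- locus$truth$true_folds[[cmp]]
    tab <- simulate_qpcr(tf, ct_sd = ct_sd, seed = seed * 100L + match(cmp, cmps))
    f <- file.path(dir, sprintf("qpcr_%s.tsv", cmp))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    qpcr_paths[cmp] <- f
  }
  evo <- simulate_evo_tracks(locus, seed = seed * 10L + 7L, dir = dir)
  meth_files <- evo$files[grep("^methylation_", names(evo$files))]
  names(meth_files) <- sub("^methylation_", "", names(meth_files))
  config <- list(
    annotation = locus$files$annotation,
    samples = lapply(genotypes, function(gt) {
      list(id = gt, path = sam_paths[[gt]], genotype = gt)
    }),
    comparisons = lapply(cmps, function(cmp) {
      list(name = cmp, case = paste0(cmp, "_KO"), control = paste0(cmp, "_WT"))
    }),
    characterization = c(list(
      msa = evo$files$alignment,
      methylation = as.list(meth_files),
      region = format_region(locus$truth$chrom, locus$truth$novel_exon$start,
                             locus$truth$novel_exon$end)),
      if (length(cmps) > 0L) list(qpcr = qpcr_paths[[cmps[1L]]])),
    outdir = file.path(dir, "results"),
    seed = seed)
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  invisible(list(locus = locus, evo = evo, sam_paths = sam_paths,
                 qpcr_paths = qpcr_paths, config = config,
                 config_path = config_path))
}
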