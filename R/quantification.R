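# Expression of a called region per sample (RPKM-style densities), fold
# changes between genotype groups, and the Livak 2^-ddCt method for qPCR.

#' RPKM-style read density of a region
#'
#' Counts reads with at least one aligned block overlapping the region by at
#' least 1 bp (whole-read counting, not per-base integration; a spliced read
#' whose skip spans the region is not counted) and normalizes to reads per
#' kilobase per million mapped reads:
#' `density = read_count / (region_kb * library_size_millions)`.
#'
#' @param reads a `spliced_reads` object
#' @param region length-1 GRanges or data.frame with chrom/start/end
#'   (1-based inclusive)
#' @param library_size total uniquely mapped reads in the library (>= 1)
#' @param sample_id optional label carried into the result
#' @return a `region_expression`: list(region, sample_id, read_count,
#'   library_size, density)
#' @export
region_density <- function(reads, region, library_size, sample_id = NA_character_) {
  region <- as_window(region)
  if (library_size < 1L) stop2("library_size must be >= 1")
  blocks <- read_blocks(reads)
  hits <- GenomicRanges::countOverlaps(blocks, region, ignore.strand = TRUE)
  read_count <- sum(hits > 0L)
  kb <- BiocGenerics::width(region) / 1000
  millions <- library_size / 1e6
  structure(
    list(region = region, sample_id = sample_id,
         read_count = as.integer(read_count),
         library_size = as.integer(library_size),
         density = read_count / (kb * millions)),
    class = "region_expression"
  )
}

#' @export
print.region_expression <- function(x, ...) {
  cat(sprintf("region_expression %s%s: %d reads / %d mapped -> density %.3f\n",
              format_region(as.character(GenomeInfoDb::seqnames(x$region)),
                            BiocGenerics::start(x$region),
                            BiocGenerics::end(x$region)),
              if (!is.na(x$sample_id)) paste0(" [", x$sample_id, "]") else "",
              x$read_count, x$library_size, x$density))
  invisible(x)
}

#' Fold change of mean read densities between two groups
#'
#' `estimate = (mean(case densities) + pseudocount) /
#'             (mean(control densities) + pseudocount)`.
#' With the default pseudocount of 0, a control mean of exactly 0 is an
#' error (add a pseudocount to rescue an unexpressed control).
#'
#' @param case,control lists of `region_expression` objects (or numeric
#'   density vectors)
#' @param pseudocount non-negative value added to both means (default 0)
#' @return a `fold_change_result`: list(estimate, method, n_case, n_control,
#'   case_mean, control_mean, per_replicate)
#' @export
density_fold_change <- function(case, control, pseudocount = 0) {
  if (pseudocount < 0) stop2("pseudocount must be non-negative")
  dens <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(e) e$density, numeric(1))
  }
  cd <- dens(case); kd <- dens(control)
  if (length(cd) == 0L || length(kd) == 0L) stop2("both groups must be non-empty")
  cm <- mean(cd); km <- mean(kd)
  if (km + pseudocount == 0) {
    stop2("control mean density is 0 with pseudocount 0; supply a pseudocount")
  }
  per_rep <- (cd + pseudocount) / (km + pseudocount)
  structure(
    list(estimate = (cm + pseudocount) / (km + pseudocount),
         method = "density_ratio",
         n_case = length(cd), n_control = length(kd),
         case_mean = cm, control_mean = km,
         per_replicate = per_rep,
         dispersion = if (length(per_rep) > 1L) stats::sd(per_rep) else NA_real_),
    class = "fold_change_result"
  )
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("fold_change_result (%s): estimate %.4g (n=%d vs n=%d%s)\n",
              x$method, x$estimate, x$n_case, x$n_control,
              if (!is.na(x$dispersion)) sprintf(", per-replicate sd %.3g", x$dispersion) else ""))
  invisible(x)
}

#' Read a qPCR Ct table from TSV
#'
#' Expected columns: `sample`, `group`, `target_ct`, `reference_ct`, and
#' optionally `replicate` (technical replicate id).
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_qpcr_table <- function(path) {
  if (!file.exists(path)) stop2("qPCR table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "target_ct", "reference_ct")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop2("qPCR table missing column(s): ",
                               paste(miss, collapse = ", "))
  tab
}

#' Relative quantification by the 2^-ddCt (Livak) method
#'
#' Technical replicates are averaged per biological sample first; then
#' `dCt = target Ct - reference Ct` per sample,
#' `ddCt = mean dCt(case) - mean dCt(control)` and
#' `estimate = 2^(-ddCt)`. Per-sample folds
#' `2^-(dCt_i - mean dCt(control))` are reported as the dispersion summary.
#' Group aggregation is mean-of-dCt, not mean-of-folds.
#'
#' @param table data.frame with columns sample, group, target_ct,
#'   reference_ct (see [read_qpcr_table()])
#' @param case_group,control_group values of `group` defining the comparison
#'   (defaults "case"/"control")
#' @return a `fold_change_result` with method `"ddct"` and fields `ddct`,
#'   `per_replicate` (per-sample folds, both groups)
#' @export
ddct_fold_change <- function(table, case_group = "case", control_group = "control") {
  need <- c("sample", "group", "target_ct", "reference_ct")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L) stop2("qPCR table missing column(s): ",
                               paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(table[, c("target_ct", "reference_ct")])
  if (any(bad)) {
    stop2("missing Ct value(s) for sample(s): ",
          paste(unique(table$sample[bad]), collapse = ", "))
  }
  if (any(table$target_ct <= 0 | table$reference_ct <= 0)) {
    stop2("all Ct values must be positive")
  }
  # average technical replicates per biological sample
  agg <- stats::aggregate(cbind(target_ct, reference_ct) ~ sample + group,
                          data = table, FUN = mean)
  agg$dct <- agg$target_ct - agg$reference_ct
  case <- agg[agg$group == case_group, , drop = FALSE]
  ctrl <- agg[agg$group == control_group, , drop = FALSE]
  if (nrow(case) == 0L) stop2("no samples in case group '", case_group, "'")
  if (nrow(ctrl) == 0L) stop2("no samples in control group '", control_group, "'")
  ddct <- mean(case$dct) - mean(ctrl$dct)
  per_rep <- stats::setNames(2^(-(agg$dct - mean(ctrl$dct))), agg$sample)
  structure(
    list(estimate = 2^(-ddct), method = "ddct", ddct = ddct,
         n_case = nrow(case), n_control = nrow(ctrl),
         case_mean = mean(case$dct), control_mean = mean(ctrl$dct),
         per_replicate = per_rep,
         dispersion = stats::sd(2^(-(case$dct - mean(ctrl$dct))))),
    class = "fold_change_result"
  )
}
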