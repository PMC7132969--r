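# Guided transcript reconstruction over a splice graph of known + novel
# exons. Edges run from lower to higher genomic coordinates; transcription
# order is derived from the gene strand when chains are emitted.

#' Build a splice graph from known exons, novel calls and junctions
#'
#' One node per annotated exon (ids `E1..Ek`, genomic order) and per novel
#' call (ids `N1..Nm`); a read edge per junction whose two boundaries each
#' match exactly one node boundary within `boundary_tolerance`; guide edges
#' between consecutive exons of each known transcript are always present.
#' The graph is acyclic by construction (edges point from lower to higher
#' coordinates).
#'
#' @param gene a [gene_model()]
#' @param novel list of `novel_exon_call` objects (may be empty)
#' @param junctions data.frame from [extract_junctions()]
#' @param boundary_tolerance bp slack for matching junction boundaries to
#'   node boundaries (default 5)
#' @return a `splice_graph`: list with `nodes` (data.frame node_id, start,
#'   end, origin), `edges` (data.frame from, to, kind, support), `guides`
#'   (named list of node-id chains), `chrom`, `strand`
#' @export
build_splice_graph <- function(gene, novel = list(), junctions = NULL,
                               boundary_tolerance = 5L) {
  stopifnot(boundary_tolerance >= 0L)
  junctions <- junctions %||% data.frame(chrom = character(0),
                                         donor_end = integer(0),
                                         acceptor_start = integer(0),
                                         support = integer(0))
  nodes <- data.frame(
    node_id = sprintf("E%d", seq_along(gene$exons)),
    start = BiocGenerics::start(gene$exons),
    end = BiocGenerics::end(gene$exons),
    origin = "known",
    stringsAsFactors = FALSE
  )
  if (length(novel) > 0L) {
    nov <- do.call(rbind, lapply(seq_along(novel), function(i) {
      x <- novel[[i]]
      data.frame(node_id = sprintf("N%d", i),
                 start = x$island$start, end = x$island$end,
                 origin = "novel", stringsAsFactors = FALSE)
    }))
    nodes <- rbind(nodes, nov)
  }
  nodes <- nodes[order(nodes$start, nodes$end), , drop = FALSE]
  rownames(nodes) <- NULL
  guides <- lapply(gene$transcripts, function(idx) {
    exs <- gene$exons[idx]
    nodes$node_id[match(paste(BiocGenerics::start(exs), BiocGenerics::end(exs)),
                        paste(nodes$start, nodes$end))]
  })
  edges <- data.frame(from = character(0), to = character(0),
                      kind = character(0), support = integer(0),
                      stringsAsFactors = FALSE)
  jx <- junctions[junctions$chrom == gene$chrom, , drop = FALSE]
  for (k in seq_len(nrow(jx))) {
    from_hits <- which(abs(nodes$end - jx$donor_end[k]) <= boundary_tolerance)
    to_hits <- which(abs(nodes$start - jx$acceptor_start[k]) <= boundary_tolerance)
    if (length(from_hits) > 1L) {
      stop2("junction donor_end ", jx$donor_end[k], " matches multiple node ends: ",
            paste(nodes$node_id[from_hits], collapse = ", "))
    }
    if (length(to_hits) > 1L) {
      stop2("junction acceptor_start ", jx$acceptor_start[k],
            " matches multiple node starts: ",
            paste(nodes$node_id[to_hits], collapse = ", "))
    }
    if (length(from_hits) == 1L && length(to_hits) == 1L &&
        nodes$start[to_hits] > nodes$end[from_hits]) {
      edges <- rbind(edges, data.frame(from = nodes$node_id[from_hits],
                                       to = nodes$node_id[to_hits],
                                       kind = "read", support = jx$support[k],
                                       stringsAsFactors = FALSE))
    }
  }
  for (g in guides) {
    if (length(g) > 1L) {
      for (i in seq_len(length(g) - 1L)) {
        edges <- rbind(edges, data.frame(from = g[i], to = g[i + 1L],
                                         kind = "guide", support = NA_integer_,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  # collapse duplicate edges; a read-supported edge outranks its guide twin
  if (nrow(edges) > 0L) {
    key <- paste(edges$from, edges$to)
    ord <- order(key, edges$kind)  # "guide" < "read": keep read via rev dup
    edges <- edges[ord, , drop = FALSE]
    key <- key[ord]
    keep <- !duplicated(key, fromLast = TRUE)
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(nodes = nodes, edges = edges, guides = guides,
         chrom = gene$chrom, strand = gene$strand, gene_id = gene$gene_id),
    class = "splice_graph"
  )
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("splice_graph (%s, %s%s): %d nodes (%d novel), %d edges (%d read-supported), %d guides\n",
              x$gene_id, x$chrom, x$strand, nrow(x$nodes),
              sum(x$nodes$origin == "novel"), nrow(x$edges),
              sum(x$edges$kind == "read"), length(x$guides)))
  invisible(x)
}

#' Reconstruct transcript variants from a splice graph
#'
#' Returns (a) every guide transcript as a variant with `novelty = FALSE`,
#' and (b) for every novel node, the maximal chains obtained by extending
#' from the novel node along its read-supported junction links and then
#' following the guide transcript containing the linked exon to its end
#' (one variant per distinct compatible guide continuation); upstream links
#' are extended mirror-wise through guide prefixes. Variants are
#' deduplicated and chains that are contiguous sub-chains of another
#' returned chain are suppressed. A novel node with no edges yields no
#' variant and is listed in the `unlinked` attribute.
#'
#' Chains are stored in transcription order (5' to 3': ascending genomic
#' coordinates on "+", descending on "-").
#'
#' @param graph a `splice_graph` from [build_splice_graph()]
#' @return list of `transcript_variant` objects (fields `chain`, `novelty`,
#'   `support`, `variant_id`); unlinked novel node ids in
#'   `attr(,"unlinked")`
#' @export
reconstruct_variants <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  redges <- edges[edges$kind == "read", , drop = FALSE]
  novel_ids <- nodes$node_id[nodes$origin == "novel"]
  chains <- list()
  for (g in names(graph$guides)) {
    chains[[length(chains) + 1L]] <- list(chain = graph$guides[[g]],
                                          novelty = FALSE, guide = g)
  }
  unlinked <- character(0)
  for (nv in novel_ids) {
    down <- continuation_chains(nv, redges, graph$guides, direction = "down")
    up <- continuation_chains(nv, redges, graph$guides, direction = "up")
    if (length(down) == 0L && length(up) == 0L) {
      unlinked <- c(unlinked, nv)
      next
    }
    if (length(down) == 0L) down <- list(character(0))
    if (length(up) == 0L) up <- list(character(0))
    for (u in up) for (d in down) {
      chains[[length(chains) + 1L]] <- list(chain = c(u, nv, d),
                                            novelty = TRUE, guide = NA_character_)
    }
  }
  # deduplicate and suppress contiguous sub-chains of other novel chains
  keys <- vapply(chains, function(x) paste(x$chain, collapse = ">"), character(1))
  chains <- chains[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  padded <- paste0(">", keys, ">")
  is_sub <- vapply(seq_along(chains), function(i) {
    if (!chains[[i]]$novelty) return(FALSE)  # guides always preserved
    any(vapply(seq_along(chains), function(j) {
      j != i && grepl(padded[i], padded[j], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  chains <- chains[!is_sub]
  out <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]$chain
    supp <- chain_support(ch, redges)
    chain_tx <- if (graph$strand == "-") rev(ch) else ch
    structure(
      list(variant_id = if (chains[[i]]$novelty)
             sprintf("%s_novel_%d", graph$gene_id, i)
           else chains[[i]]$guide,
           chain = chain_tx, novelty = chains[[i]]$novelty,
           support = supp, gene_id = graph$gene_id, strand = graph$strand),
      class = "transcript_variant"
    )
  })
  attr(out, "unlinked") <- unlinked
  out
}

# Chains continuing from `node` through read edges in the given genomic
# direction, then following each guide containing the linked exon to its
# end (down) or from its start (up). Novel-to-novel links recurse.
continuation_chains <- function(node, redges, guides, direction) {
  if (direction == "down") {
    nexts <- redges$to[redges$from == node]
  } else {
    nexts <- redges$from[redges$to == node]
  }
  res <- list()
  for (nx in nexts) {
    in_guides <- Filter(function(g) nx %in% g, guides)
    if (length(in_guides) > 0L) {
      for (g in in_guides) {
        pos <- match(nx, g)
        tail_chain <- if (direction == "down") g[pos:length(g)] else g[1:pos]
        res[[length(res) + 1L]] <- tail_chain
      }
    } else {
      # linked node outside any guide (e.g. another novel node): recurse
      deeper <- continuation_chains(nx, redges, guides, direction)
      if (length(deeper) == 0L) deeper <- list(character(0))
      for (d in deeper) {
        res[[length(res) + 1L]] <- if (direction == "down") c(nx, d) else c(d, nx)
      }
    }
  }
  res[!duplicated(vapply(res, paste, character(1), collapse = ">"))]
}

chain_support <- function(chain, redges) {
  if (length(chain) < 2L) return(NA_integer_)
  supp <- vapply(seq_len(length(chain) - 1L), function(i) {
    hit <- which(redges$from == chain[i] & redges$to == chain[i + 1L])
    if (length(hit) == 0L) NA_integer_ else as.integer(max(redges$support[hit]))
  }, integer(1))
  if (all(is.na(supp))) NA_integer_ else min(supp, na.rm = TRUE)
}

#' @export
print.transcript_variant <- function(x, ...) {
  cat(sprintf("transcript_variant %s (%s): %s%s\n", x$variant_id,
              if (x$novelty) "novel" else "guide",
              paste(x$chain, collapse = " -> "),
              if (!is.na(x$support)) sprintf(" [min read support %d]", x$support) else ""))
  invisible(x)
}

#' Summary table of transcript variants
#' @param variants list from [reconstruct_variants()]
#' @return data.frame (variant_id, chain, n_exons, novelty, support)
#' @export
variant_table <- function(variants) {
  if (length(variants) == 0L) {
    return(data.frame(variant_id = character(0), chain = character(0),
                      n_exons = integer(0), novelty = logical(0),
                      support = integer(0)))
  }
  do.call(rbind, lapply(variants, function(x) {
    data.frame(variant_id = x$variant_id,
               chain = paste(x$chain, collapse = ","),
               n_exons = length(x$chain), novelty = x$novelty,
               support = x$support, stringsAsFactors = FALSE)
  }))
}

#' Export transcript variants as GTF
#'
#' Novel variants carry generated transcript_ids and the source tag
#' `exonscout_novel`; guide variants re-emit their transcript ids with
#' source `exonscout_guide`.
#'
#' @param variants list from [reconstruct_variants()]
#' @param graph the `splice_graph` the variants came from
#' @param path output GTF path
#' @return `path`, invisibly
#' @export
export_variants_gtf <- function(variants, graph, path) {
  recs <- lapply(variants, function(v) {
    idx <- match(v$chain, graph$nodes$node_id)
    idx <- idx[order(graph$nodes$start[idx])]  # genomic order in the file
    gr <- GenomicRanges::GRanges(graph$chrom,
                                 IRanges::IRanges(graph$nodes$start[idx],
                                                  graph$nodes$end[idx]),
                                 strand = graph$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = if (v$novelty) "exonscout_novel" else "exonscout_guide",
      type = "exon", gene_id = v$gene_id, transcript_id = v$variant_id
    )
    gr
  })
  gr <- unlist(methods::as(recs, "GRangesList"), use.names = FALSE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
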