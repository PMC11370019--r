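# Number of child bins produced by one zoom step; a range narrower than this
# collapses to single-position bins (terminal zoom).
ZOOM_BINS <- 20L

new_histogram <- function(bins, level, zoom_stack, filter, vcf_path, bundle,
                          clinvar = NULL, gene = NULL) {
  structure(list(bins = bins, level = as.integer(level),
                 zoom_stack = zoom_stack, filter = filter,
                 vcf_path = vcf_path, bundle = bundle, clinvar = clinvar,
                 gene = gene),
            class = "vgc_histogram")
}

#' Level-0 per-chromosome variant histogram
#'
#' The default whole-file view: one bin per chromosome, counts taken straight
#' from the sidecar index (no file scan). Filters map to the index columns:
#' ALL to the line-span size, PASS to `pass_count`, PATHOGENIC to
#' `pathogenic_count` (an error when the index was built without a
#' pathogenicity source).
#'
#' @param bundle A `vgc_index`.
#' @param vcf_path The indexed VCF (used by later zooms).
#' @param filter `"ALL"`, `"PASS"` or `"PATHOGENIC"`.
#' @param clinvar Optional `vgc_clinvar`, carried for zoom/hover annotation.
#' @return A `vgc_histogram` at level 0 with an empty zoom stack.
#' @export
vgc_histogram <- function(bundle, vcf_path, filter = "ALL", clinvar = NULL) {
  stopifnot(inherits(bundle, "vgc_index"))
  filter <- check_filter(filter)
  if (filter == "PATHOGENIC" && bundle$no_pathogenicity_source) {
    vgc_abort(paste("index was built without a pathogenicity source;",
                    "rebuild with a clinvar table to use the PATHOGENIC filter"),
              "vgc_annotation_required")
  }
  e <- bundle$entries
  count <- switch(filter,
                  ALL = e$end_line - e$start_line + 1L,
                  PASS = e$pass_count,
                  PATHOGENIC = e$pathogenic_count)
  bins <- data.frame(chrom = e$chrom, start = e$start_pos, end = e$end_pos,
                     count = as.integer(count), stringsAsFactors = FALSE)
  new_histogram(bins, level = 0L, zoom_stack = list(), filter = filter,
                vcf_path = vcf_path, bundle = bundle, clinvar = clinvar)
}

#' Gene-level histogram view
#'
#' Builds a zoomable view over one gene's span, with per-bin exonic counts
#' for the exonic/intronic colouring of gene browsing.
#'
#' @inheritParams vgc_histogram
#' @param catalog A `vgc_catalog`.
#' @param symbol Gene symbol.
#' @export
vgc_gene_histogram <- function(bundle, vcf_path, catalog, symbol,
                               filter = "ALL", clinvar = NULL) {
  gene <- vgc_lookup_gene(catalog, symbol)
  view <- new_histogram(bins = NULL, level = 0L, zoom_stack = list(),
                        filter = check_filter(filter), vcf_path = vcf_path,
                        bundle = bundle, clinvar = clinvar, gene = gene)
  view$bins <- bin_range(view, gene$chrom, gene$start, gene$end)
  view
}

# split [start, end] on chrom into ZOOM_BINS equal-width bins (last bin
# absorbs the remainder); widths <= ZOOM_BINS collapse to width-1 bins
bin_edges <- function(start, end) {
  width <- end - start + 1L
  if (width <= ZOOM_BINS) {
    s <- start:end
    return(cbind(s, s, deparse.level = 0))
  }
  w <- width %/% ZOOM_BINS
  s <- start + w * (0:(ZOOM_BINS - 1L))
  e <- c(s[-1] - 1L, end)
  cbind(s, e, deparse.level = 0)
}

bin_range <- function(view, chrom, start, end) {
  res <- vgc_query_range(view$bundle, view$vcf_path,
                         vgc_range(chrom, start, end), filter = view$filter,
                         clinvar = view$clinvar)
  edges <- bin_edges(start, end)
  pos <- res$variants$pos
  idx <- findInterval(pos, edges[, 1])
  bins <- data.frame(chrom = rep(chrom, nrow(edges)),
                     start = edges[, 1], end = edges[, 2],
                     count = as.integer(tabulate(idx, nbins = nrow(edges))),
                     stringsAsFactors = FALSE)
  if (!is.null(view$clinvar)) {
    bins$pathogenic_count <- as.integer(
      tabulate(idx[res$variants$is_pathogenic], nbins = nrow(edges)))
  }
  if (!is.null(view$gene)) {
    exonic <- vgc_classify_position(view$gene, pos) == "EXONIC"
    bins$exonic_count <- as.integer(tabulate(idx[exonic], nbins = nrow(edges)))
  }
  bins
}

#' Zoom into one histogram bin
#'
#' Produces a new view over the selected bin's genomic range, split into 20
#' equal-width child bins (the last absorbs the remainder); ranges of width
#' 20 or less become single-position bins. The previous view is pushed onto
#' the zoom stack for back-navigation. Child counts are recomputed with the
#' view's filter via an index-backed range query, so they sum to the parent
#' bin's count.
#'
#' @param view A `vgc_histogram`.
#' @param bin_index 1-based bin index into `view$bins`.
#' @return The zoomed `vgc_histogram` (level + 1).
#' @export
vgc_zoom <- function(view, bin_index) {
  stopifnot(inherits(view, "vgc_histogram"))
  if (bin_index < 1L || bin_index > nrow(view$bins)) {
    vgc_abort(sprintf("bin_index %d out of range", bin_index), "vgc_parameter")
  }
  b <- view$bins[bin_index, ]
  bins <- bin_range(view, b$chrom, b$start, b$end)
  snapshot <- view
  snapshot$zoom_stack <- list()   # history lives on the child's stack
  new_histogram(bins, level = view$level + 1L,
                zoom_stack = c(view$zoom_stack, list(snapshot)),
                filter = view$filter, vcf_path = view$vcf_path,
                bundle = view$bundle, clinvar = view$clinvar, gene = view$gene)
}

#' Navigate back to the previous zoom level
#' @param view A zoomed `vgc_histogram`.
#' @return The view as it was before the last [vgc_zoom()].
#' @export
vgc_zoom_back <- function(view) {
  stopifnot(inherits(view, "vgc_histogram"))
  n <- length(view$zoom_stack)
  if (n == 0L) {
    vgc_abort("already at the top-level view", "vgc_parameter")
  }
  prev <- view$zoom_stack[[n]]
  prev$zoom_stack <- view$zoom_stack[-n]
  prev
}

#' Hover payload for one histogram bin
#'
#' Returns the bin's genomic range and variant count; for single-position
#' bins (the terminal zoom level) it additionally lists the variants at that
#' position with their ref/alt alleles and ClinVar significance, the
#' tooltip detail shown at single-position magnification.
#'
#' @param view A `vgc_histogram`.
#' @param bin_index 1-based bin index.
#' @return List with `range` (a `vgc_range`), `variant_count`, and
#'   `variants_at_position` (data.frame of ref, alt, significance; only for
#'   width-1 bins, otherwise absent).
#' @export
vgc_hover <- function(view, bin_index) {
  stopifnot(inherits(view, "vgc_histogram"))
  if (bin_index < 1L || bin_index > nrow(view$bins)) {
    vgc_abort(sprintf("bin_index %d out of range", bin_index), "vgc_parameter")
  }
  b <- view$bins[bin_index, ]
  payload <- list(range = vgc_range(b$chrom, b$start, b$end),
                  variant_count = b$count)
  if (b$end == b$start) {
    res <- vgc_query_range(view$bundle, view$vcf_path,
                           vgc_range(b$chrom, b$start, b$end),
                           filter = view$filter, clinvar = view$clinvar)
    payload$variants_at_position <- data.frame(
      ref = res$variants$ref, alt = res$variants$alt,
      significance = if (!is.null(view$clinvar)) res$variants$significance
                     else rep(NA_character_, nrow(res$variants)),
      stringsAsFactors = FALSE)
  }
  payload
}

#' Bipartite variant-sample node graph
#'
#' One node per queried variant (flagged pathogenic via the pathogenicity
#' table) and one node per group-assigned sample (labelled with its group);
#' an edge connects a variant to every sample carrying it, labelled `HET` or
#' `HOM_ALT`. Reference and missing genotypes produce no edge.
#'
#' @param result A `vgc_query_result`.
#' @param groups A `vgc_phenotypes`.
#' @param clinvar Optional `vgc_clinvar` for the pathogenicity flags.
#' @return A `vgc_node_graph`: list of data.frames `variant_nodes` (key,
#'   pathogenic), `sample_nodes` (sample_id, group) and `edges` (variant_key,
#'   sample_id, genotype).
#' @export
vgc_node_graph <- function(result, groups, clinvar = NULL) {
  stopifnot(inherits(result, "vgc_query_result"),
            inherits(groups, "vgc_phenotypes"))
  v <- result$variants
  keys <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  pathogenic <- if (!is.null(clinvar)) {
    annotate_block(v$chrom, v$pos, v$ref, v$alt, clinvar)$is_pathogenic
  } else if (!is.null(v$is_pathogenic)) {
    v$is_pathogenic
  } else {
    rep(FALSE, nrow(v))
  }
  assigned <- names(groups$assignment)
  assigned <- assigned[assigned %in% result$sample_ids]
  sample_nodes <- data.frame(sample_id = assigned,
                             group = unname(groups$assignment[assigned]),
                             stringsAsFactors = FALSE)
  cols <- match(assigned, result$sample_ids)
  gt <- result$gt[, cols, drop = FALSE]
  carrier <- which(gt == GT_HET | gt == GT_HOM_ALT, arr.ind = TRUE)
  edges <- data.frame(
    variant_key = keys[carrier[, 1]],
    sample_id = assigned[carrier[, 2]],
    genotype = ifelse(gt[carrier] == GT_HET, "HET", "HOM_ALT"),
    stringsAsFactors = FALSE)
  edges <- edges[order(carrier[, 1], carrier[, 2]), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(variant_nodes = data.frame(key = keys, pathogenic = pathogenic,
                                            stringsAsFactors = FALSE),
                 sample_nodes = sample_nodes,
                 edges = edges),
            class = "vgc_node_graph")
}

#' Genotype heat-map matrix
#'
#' @param result A `vgc_query_result`.
#' @return Integer matrix of genotype-class codes (0 = HOM_REF, 1 = HET,
#'   2 = HOM_ALT, -1 = MISSING); rows follow the query's variant order
#'   (named by variant key), columns the VCF sample order.
#' @export
vgc_genotype_matrix <- function(result) {
  stopifnot(inherits(result, "vgc_query_result"))
  m <- result$gt
  v <- result$variants
  dimnames(m) <- list(variant_key(v$chrom, v$pos, v$ref, v$alt),
                      result$sample_ids)
  m
}

#' Serialize a histogram view to JSON
#' @param view A `vgc_histogram`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
vgc_histogram_json <- function(view, path = NULL) {
  obj <- list(level = view$level, filter = view$filter, bins = view$bins)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a node graph to JSON
#' @param graph A `vgc_node_graph`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
vgc_node_graph_json <- function(graph, path = NULL) {
  obj <- list(variant_nodes = graph$variant_nodes,
              sample_nodes = graph$sample_nodes,
              edges = graph$edges)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.vgc_histogram <- function(x, ...) {
  cat(sprintf("Histogram view (level %d, filter %s): %d bins, %d variants\n",
              x$level, x$filter, nrow(x$bins), sum(x$bins$count)))
  invisible(x)
}

#' @export
print.vgc_node_graph <- function(x, ...) {
  cat(sprintf("Node graph: %d variant nodes, %d sample nodes, %d edges\n",
              nrow(x$variant_nodes), nrow(x$sample_nodes), nrow(x$edges)))
  invisible(x)
}
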