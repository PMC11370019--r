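FILTERS <- c("ALL", "PASS", "PATHOGENIC")

check_filter <- function(filter) {
  f <- FILTERS[match(toupper(filter), FILTERS)]
  if (is.na(f)) {
    vgc_abort(sprintf("unknown filter '%s' (use ALL, PASS or PATHOGENIC)", filter),
              "vgc_validation")
  }
  f
}

#' Construct a 1-based inclusive genomic range
#'
#' @param chrom Chromosome name (with or without a `chr` prefix).
#' @param start,end 1-based inclusive endpoints, `start <= end`.
#' @export
vgc_range <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    vgc_abort(sprintf("invalid range %s:%s-%s", chrom, start, end), "vgc_validation")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "vgc_range")
}

#' Construct a query specification
#'
#' A query spec records what was asked — gene, range or batch mode, the
#' ALL/PASS/PATHOGENIC filter and the assembly — and is what analysis plans
#' persist.
#'
#' @param mode `"GENE"`, `"RANGE"` or `"BATCH"`.
#' @param gene_symbol Gene symbol (GENE mode).
#' @param range A `vgc_range` (RANGE mode).
#' @param batch_items Character vector of batch lines (BATCH mode).
#' @param filter `"ALL"`, `"PASS"` or `"PATHOGENIC"`.
#' @param assembly `"GRCh37"` or `"GRCh38"`.
#' @export
vgc_query_spec <- function(mode = c("GENE", "RANGE", "BATCH"),
                           gene_symbol = NULL, range = NULL, batch_items = NULL,
                           filter = "ALL", assembly = "GRCh38") {
  mode <- match.arg(mode)
  filter <- check_filter(filter)
  assembly <- check_assembly(assembly)
  populated <- c(GENE = !is.null(gene_symbol), RANGE = !is.null(range),
                 BATCH = !is.null(batch_items))
  if (!populated[[mode]] || sum(populated) != 1L) {
    vgc_abort(sprintf("mode %s requires exactly its own field to be set", mode),
              "vgc_validation")
  }
  structure(list(mode = mode, gene_symbol = gene_symbol, range = range,
                 batch_items = batch_items, filter = filter, assembly = assembly),
            class = "vgc_query_spec")
}

empty_result <- function(spec, sample_ids) {
  blk <- parse_variant_block(character(0), integer(0), length(sample_ids))
  new_query_result(spec, blk, sample_ids, lines_scanned = 0L)
}

new_query_result <- function(spec, block, sample_ids, lines_scanned,
                             per_item_counts = NULL) {
  structure(list(spec = spec,
                 variants = block$fields,
                 gt = block$gt,
                 phased = block$phased,
                 gt_raw = block$gt_raw,
                 sample_ids = sample_ids,
                 per_item_counts = per_item_counts,
                 lines_scanned = lines_scanned),
            class = "vgc_query_result")
}

# Core retrieval: data lines of one chromosome whose positions fall in
# [start, end], then the filter predicate. Only lines inside the
# chromosome's index span are parsed (lines_scanned counts parsed lines).
query_range_impl <- function(bundle, vcf_path, range, filter, clinvar) {
  filter <- check_filter(filter)
  if (filter == "PATHOGENIC" && is.null(clinvar)) {
    vgc_abort("filter PATHOGENIC requires a pathogenicity table (clinvar)",
              "vgc_annotation_required")
  }
  n_samples <- length(bundle$sample_ids)
  hit <- which(norm_chrom(bundle$entries$chrom) == norm_chrom(range$chrom))
  if (length(hit) == 0L) {
    return(list(block = parse_variant_block(character(0), integer(0), n_samples),
                annot = NULL, lines_scanned = 0L))
  }
  e <- bundle$entries[hit[1], ]
  lines <- read_line_window(vcf_path, e$start_line, e$end_line)
  line_numbers <- seq.int(e$start_line, e$end_line)
  # binary search over the sorted position column of this chromosome block
  pos <- as.integer(sub("\t.*$", "", sub("^[^\t]*\t", "", lines)))
  i1 <- findInterval(range$start - 1L, pos) + 1L
  i2 <- findInterval(range$end, pos)
  if (i2 < i1) {
    sel <- integer(0)
  } else {
    sel <- i1:i2
  }
  block <- parse_variant_block(lines[sel], line_numbers[sel], n_samples)
  annot <- NULL
  if (!is.null(clinvar)) {
    annot <- annotate_block(block$fields$chrom, block$fields$pos,
                            block$fields$ref, block$fields$alt, clinvar)
  }
  keep <- switch(filter,
                 ALL = rep(TRUE, nrow(block$fields)),
                 PASS = block$fields$filter == "PASS",
                 PATHOGENIC = annot$is_pathogenic)
  block$fields <- block$fields[keep, , drop = FALSE]
  block$gt <- block$gt[keep, , drop = FALSE]
  block$phased <- block$phased[keep, , drop = FALSE]
  block$gt_raw <- block$gt_raw[keep, , drop = FALSE]
  if (!is.null(annot)) {
    annot <- lapply(annot, `[`, keep)
  }
  list(block = block, annot = annot, lines_scanned = length(sel))
}

attach_annot <- function(result, annot) {
  if (!is.null(annot)) {
    result$variants$significance <- annot$significance
    result$variants$is_pathogenic <- annot$is_pathogenic
  }
  result
}

#' Query variants within a genomic range
#'
#' Uses the sidecar index to restrict reading to the chromosome's line span,
#' then a binary search over the (sorted) positions. Endpoints are inclusive
#' on both sides. A chromosome absent from the index yields an empty result,
#' not an error.
#'
#' @param bundle A `vgc_index` for `vcf_path` (see [vgc_build_index()] /
#'   [vgc_load_index()]); passing `NULL` raises a `vgc_index_required` error.
#' @param vcf_path The indexed VCF.
#' @param range A `vgc_range`.
#' @param filter `"ALL"`, `"PASS"` or `"PATHOGENIC"`. The PATHOGENIC filter
#'   requires `clinvar`.
#' @param clinvar Optional `vgc_clinvar` lookup; when supplied, results carry
#'   `significance` and `is_pathogenic` columns.
#' @param assembly Assembly recorded in the result's spec.
#' @return A `vgc_query_result` with `variants` (data.frame, position
#'   sorted), genotype class matrix `gt`, raw per-sample fields `gt_raw`,
#'   `sample_ids` and the `lines_scanned` counter.
#' @export
vgc_query_range <- function(bundle, vcf_path, range, filter = "ALL",
                            clinvar = NULL, assembly = "GRCh38") {
  if (is.null(bundle)) {
    vgc_abort("no index available; build one with vgc_build_index()",
              "vgc_index_required")
  }
  stopifnot(inherits(range, "vgc_range"))
  spec <- vgc_query_spec("RANGE", range = range, filter = filter,
                         assembly = assembly)
  out <- query_range_impl(bundle, vcf_path, range, filter, clinvar)
  res <- new_query_result(spec, out$block, bundle$sample_ids, out$lines_scanned)
  attach_annot(res, out$annot)
}

#' Query all variants of a gene
#'
#' Equivalent to [vgc_query_range()] over the gene's span; each returned
#' variant additionally carries an `EXONIC`/`INTRONIC` region label from the
#' gene's exon layout.
#'
#' @inheritParams vgc_query_range
#' @param catalog A `vgc_catalog` for the chosen assembly.
#' @param symbol Gene symbol, matched case-insensitively.
#' @export
vgc_query_gene <- function(bundle, vcf_path, catalog, symbol, filter = "ALL",
                           clinvar = NULL) {
  if (is.null(bundle)) {
    vgc_abort("no index available; build one with vgc_build_index()",
              "vgc_index_required")
  }
  gene <- vgc_lookup_gene(catalog, symbol)
  range <- vgc_range(gene$chrom, gene$start, gene$end)
  spec <- vgc_query_spec("GENE", gene_symbol = gene$symbol, filter = filter,
                         assembly = catalog$assembly)
  out <- query_range_impl(bundle, vcf_path, range, filter, clinvar)
  res <- new_query_result(spec, out$block, bundle$sample_ids, out$lines_scanned)
  res <- attach_annot(res, out$annot)
  res$variants$region <- vgc_classify_position(gene, res$variants$pos)
  res$gene <- gene
  res
}

#' Query a batch of genes and ranges from a file
#'
#' One item per line: a gene symbol or `chrom:start-end`; `#` comments and
#' blank lines are skipped. The result is the deduplicated union of the
#' per-item results in file order of the VCF; `per_item_counts` records the
#' variant count each input line contributed. Unknown genes are recorded
#' with count 0 and a warning, not an error.
#'
#' @inheritParams vgc_query_gene
#' @param batch_path Path to the batch file.
#' @export
vgc_query_batch <- function(bundle, vcf_path, catalog, batch_path,
                            filter = "ALL", clinvar = NULL) {
  if (is.null(bundle)) {
    vgc_abort("no index available; build one with vgc_build_index()",
              "vgc_index_required")
  }
  raw <- readLines(batch_path, warn = FALSE)
  items <- trimws(raw)
  keep <- nzchar(items) & !startsWith(items, "#")
  items <- items[keep]
  item_lines <- which(keep)
  if (length(items) == 0L) {
    vgc_abort(sprintf("batch file %s contains no items", batch_path), "vgc_parse")
  }

  counts <- setNames(integer(length(items)), items)
  line_sets <- vector("list", length(items))
  blocks <- vector("list", length(items))
  annots <- vector("list", length(items))
  scanned <- 0L
  for (i in seq_along(items)) {
    it <- items[i]
    if (looks_like_range(it)) {
      rng <- tryCatch(parse_range_string(it), vgc_error = function(e)
        vgc_abort(sprintf("batch file line %d: %s", item_lines[i],
                          conditionMessage(e)), "vgc_parse"))
      out <- query_range_impl(bundle, vcf_path, rng, filter, clinvar)
    } else if (grepl("^[A-Za-z][A-Za-z0-9._-]*$", it)) {
      gene <- tryCatch(vgc_lookup_gene(catalog, it),
                       vgc_unknown_gene = function(e) NULL)
      if (is.null(gene)) {
        warning(sprintf("batch file line %d: unknown gene '%s' (count 0)",
                        item_lines[i], it))
        counts[i] <- 0L
        next
      }
      rng <- vgc_range(gene$chrom, gene$start, gene$end)
      out <- query_range_impl(bundle, vcf_path, rng, filter, clinvar)
    } else {
      vgc_abort(sprintf("batch file line %d: cannot parse item '%s'",
                        item_lines[i], it), "vgc_parse")
    }
    counts[i] <- nrow(out$block$fields)
    line_sets[i] <- list(out$block$fields$line)
    blocks[i] <- list(out$block)
    annots[i] <- list(out$annot)
    scanned <- scanned + out$lines_scanned
  }

  # union, deduplicated by source line, ordered as in the file
  all_lines <- sort(unique(unlist(line_sets)))
  n_samples <- length(bundle$sample_ids)
  fields <- NULL; gt <- NULL; phased <- NULL; gt_raw <- NULL
  sig <- character(0); isp <- logical(0)
  seen <- integer(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (is.null(b) || nrow(b$fields) == 0L) next
    new <- !(b$fields$line %in% seen)
    seen <- c(seen, b$fields$line[new])
    fields <- rbind(fields, b$fields[new, , drop = FALSE])
    gt <- rbind(gt, b$gt[new, , drop = FALSE])
    phased <- rbind(phased, b$phased[new, , drop = FALSE])
    gt_raw <- rbind(gt_raw, b$gt_raw[new, , drop = FALSE])
    if (!is.null(annots[[i]])) {
      sig <- c(sig, annots[[i]]$significance[new])
      isp <- c(isp, annots[[i]]$is_pathogenic[new])
    }
  }
  if (is.null(fields)) {
    blk <- parse_variant_block(character(0), integer(0), n_samples)
  } else {
    o <- order(fields$line)
    blk <- list(fields = fields[o, , drop = FALSE], gt = gt[o, , drop = FALSE],
                phased = phased[o, , drop = FALSE],
                gt_raw = gt_raw[o, , drop = FALSE])
  }
  spec <- vgc_query_spec("BATCH", batch_items = items, filter = filter,
                         assembly = catalog$assembly)
  res <- new_query_result(spec, blk, bundle$sample_ids, scanned,
                          per_item_counts = counts)
  if (!is.null(clinvar) && !is.null(fields)) {
    res$variants$significance <- sig[order(fields$line)]
    res$variants$is_pathogenic <- isp[order(fields$line)]
  }
  res
}

# ---- analysis plans: canonical flat key=value serialization ----

PLAN_KEYS <- c("mode", "gene_symbol", "range", "batch_items", "filter", "assembly")

#' Save an analysis plan
#'
#' Plans are flat `key=value` text documents with a canonical key order, so
#' equal specs serialize byte-identically and can be reused for reproducible
#' re-analysis.
#'
#' @param spec A `vgc_query_spec`.
#' @param path Output path.
#' @export
vgc_save_plan <- function(spec, path) {
  stopifnot(inherits(spec, "vgc_query_spec"))
  kv <- list(
    mode = spec$mode,
    gene_symbol = spec$gene_symbol %||% "",
    range = if (is.null(spec$range)) "" else
      sprintf("%s:%d-%d", spec$range$chrom, spec$range$start, spec$range$end),
    batch_items = paste(spec$batch_items %||% character(0), collapse = ";"),
    filter = spec$filter,
    assembly = spec$assembly)
  write_kv(kv[PLAN_KEYS], path)
}

#' Load an analysis plan
#' @param path Plan file written by [vgc_save_plan()].
#' @return The reconstructed `vgc_query_spec`.
#' @export
vgc_load_plan <- function(path) {
  kv <- read_kv(path)
  missing <- setdiff(PLAN_KEYS, names(kv))
  if (length(missing)) {
    vgc_abort(sprintf("plan %s is missing key '%s'", path, missing[1]), "vgc_parse")
  }
  if (!toupper(kv$filter) %in% FILTERS) {
    vgc_abort(sprintf("plan %s: unknown filter value '%s'", path, kv$filter),
              "vgc_parse")
  }
  if (!toupper(kv$mode) %in% c("GENE", "RANGE", "BATCH")) {
    vgc_abort(sprintf("plan %s: unknown mode value '%s'", path, kv$mode),
              "vgc_parse")
  }
  vgc_query_spec(
    mode = toupper(kv$mode),
    gene_symbol = if (nzchar(kv$gene_symbol)) kv$gene_symbol else NULL,
    range = if (nzchar(kv$range)) parse_range_string(kv$range) else NULL,
    batch_items = if (nzchar(kv$batch_items))
      strsplit(kv$batch_items, ";", fixed = TRUE)[[1]] else NULL,
    filter = kv$filter,
    assembly = kv$assembly)
}

#' @export
print.vgc_query_result <- function(x, ...) {
  cat(sprintf("Query result (%s, filter %s): %d variants x %d samples\n",
              x$spec$mode, x$spec$filter, nrow(x$variants),
              length(x$sample_ids)))
  invisible(x)
}
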