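ASSEMBLIES <- c("GRCh37", "GRCh38")

check_assembly <- function(assembly) {
  a <- ASSEMBLIES[match(tolower(assembly), tolower(ASSEMBLIES))]
  if (is.na(a)) {
    vgc_abort(sprintf("unknown assembly '%s' (use GRCh37 or GRCh38)", assembly),
              "vgc_validation")
  }
  a
}

# merge overlapping/adjacent-or-overlapping intervals; input/output 1-based inclusive
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) return(matrix(integer(0), ncol = 2))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {           # overlap (boundary positions are inside)
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

#' Load a gene catalog for one assembly
#'
#' The catalog maps gene symbols to genomic spans and exon layouts and is the
#' source of gene-query coordinates and exonic/intronic classification. Two
#' file layouts are accepted:
#' \itemize{
#'   \item TSV with columns `symbol, chrom, start, end, exons` where `exons`
#'     is a semicolon-joined list of `start-end` pairs (1-based inclusive,
#'     possibly empty);
#'   \item 6-column BED (`format = "bed"`): 0-based half-open, converted on
#'     load; column 4 is the symbol, no exon information.
#' }
#' Exon lists are normalised on load: sorted and overlapping intervals merged.
#'
#' @param path Catalog file path.
#' @param assembly `"GRCh37"` or `"GRCh38"`.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return A `vgc_catalog`: list with `assembly` and `genes` (named list of
#'   `vgc_gene` models; names are upper-cased symbols).
#' @export
vgc_load_catalog <- function(path, assembly, format = c("tsv", "bed")) {
  assembly <- check_assembly(assembly)
  format <- match.arg(format)
  dt <- data.table::fread(path, sep = "\t", header = (format == "tsv"),
                          colClasses = "character", data.table = FALSE)
  if (format == "bed") {
    if (ncol(dt) < 4L) vgc_abort("BED catalog needs at least 4 columns", "vgc_validation")
    dt <- data.frame(symbol = dt[[4]], chrom = dt[[1]],
                     start = as.integer(dt[[2]]) + 1L,  # 0-based half-open -> 1-based incl.
                     end = as.integer(dt[[3]]),
                     exons = "", stringsAsFactors = FALSE)
  } else {
    need <- c("symbol", "chrom", "start", "end", "exons")
    if (!all(need %in% names(dt))) {
      vgc_abort(sprintf("catalog %s lacks columns: %s", path,
                        paste(setdiff(need, names(dt)), collapse = ", ")),
                "vgc_validation")
    }
    dt$start <- as.integer(dt$start)
    dt$end <- as.integer(dt$end)
  }
  keys <- toupper(dt$symbol)
  if (anyDuplicated(keys)) {
    vgc_abort(sprintf("duplicate gene symbol in catalog: %s",
                      dt$symbol[duplicated(keys)][1]), "vgc_duplicate_gene")
  }
  genes <- vector("list", nrow(dt))
  names(genes) <- keys
  for (i in seq_len(nrow(dt))) {
    if (is.na(dt$start[i]) || is.na(dt$end[i]) || dt$start[i] > dt$end[i]) {
      vgc_abort(sprintf("gene %s: invalid span", dt$symbol[i]), "vgc_validation")
    }
    ex <- matrix(integer(0), ncol = 2)
    exons_str <- if ("exons" %in% names(dt)) dt$exons[i] else ""
    if (!is.na(exons_str) && nzchar(exons_str)) {
      pairs <- strsplit(strsplit(exons_str, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
      if (any(lengths(pairs) != 2L)) {
        vgc_abort(sprintf("gene %s: malformed exons field '%s'",
                          dt$symbol[i], exons_str), "vgc_validation")
      }
      es <- as.integer(vapply(pairs, `[`, character(1), 1))
      ee <- as.integer(vapply(pairs, `[`, character(1), 2))
      if (anyNA(es) || anyNA(ee) || any(es > ee)) {
        vgc_abort(sprintf("gene %s: malformed exon interval", dt$symbol[i]),
                  "vgc_validation")
      }
      if (any(es < dt$start[i]) || any(ee > dt$end[i])) {
        vgc_abort(sprintf("gene %s: exon outside the gene span", dt$symbol[i]),
                  "vgc_validation")
      }
      ex <- merge_intervals(es, ee)
    }
    genes[[i]] <- structure(list(symbol = dt$symbol[i], assembly = assembly,
                                 chrom = dt$chrom[i], start = dt$start[i],
                                 end = dt$end[i], exons = ex),
                            class = "vgc_gene")
  }
  structure(list(assembly = assembly, genes = genes), class = "vgc_catalog")
}

#' Look up a gene by symbol (case-insensitive)
#'
#' @param catalog A `vgc_catalog`.
#' @param symbol Gene symbol.
#' @return The `vgc_gene` model. Unknown symbols raise a `vgc_unknown_gene`
#'   error listing the nearest matches.
#' @export
vgc_lookup_gene <- function(catalog, symbol) {
  stopifnot(inherits(catalog, "vgc_catalog"))
  g <- catalog$genes[[toupper(symbol)]]
  if (is.null(g)) {
    d <- adist(toupper(symbol), names(catalog$genes))
    near <- names(catalog$genes)[order(d)][seq_len(min(3L, length(catalog$genes)))]
    vgc_abort(sprintf("unknown gene '%s'; nearest matches: %s",
                      symbol, paste(near, collapse = ", ")), "vgc_unknown_gene")
  }
  g
}

#' Classify a position relative to a gene model
#'
#' @param gene A `vgc_gene`.
#' @param pos Integer vector of 1-based positions.
#' @return Character vector over `{"EXONIC", "INTRONIC", "OUTSIDE"}`:
#'   `EXONIC` inside any exon interval (boundaries inclusive), `INTRONIC`
#'   inside the gene span but no exon, `OUTSIDE` otherwise.
#' @export
vgc_classify_position <- function(gene, pos) {
  stopifnot(inherits(gene, "vgc_gene"))
  out <- rep("OUTSIDE", length(pos))
  inside <- pos >= gene$start & pos <= gene$end
  out[inside] <- "INTRONIC"
  if (nrow(gene$exons) > 0L && any(inside)) {
    for (k in seq_len(nrow(gene$exons))) {
      hit <- pos >= gene$exons[k, 1] & pos <= gene$exons[k, 2]
      out[hit] <- "EXONIC"
    }
  }
  out
}

#' @export
print.vgc_catalog <- function(x, ...) {
  cat(sprintf("Gene catalog (%s): %d genes\n", x$assembly, length(x$genes)))
  invisible(x)
}
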