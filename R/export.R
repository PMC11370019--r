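#' Flatten a query result into a spreadsheet-style table
#'
#' Columns are the eight fixed VCF columns (CHROM, POS, ID, REF, ALT, QUAL,
#' FILTER, INFO) exactly as they appear in the source file, one column per
#' sample with the full per-sample field, then annotation columns
#' (`significance`, `region` when the query was gene-based, `gnomad_url`) and
#' optionally the association columns (cell counts, p-values, seed). All
#' values are kept as text so exports round-trip losslessly.
#'
#' @param result A `vgc_query_result`.
#' @param assoc Optional `vgc_association` for the same result.
#' @param assembly Assembly for the gnomAD URLs (defaults to the query
#'   spec's assembly).
#' @return A `vgc_result_table` (a character data.frame with `provenance`
#'   attributes).
#' @export
vgc_result_table <- function(result, assoc = NULL, assembly = NULL) {
  stopifnot(inherits(result, "vgc_query_result"))
  assembly <- check_assembly(assembly %||% result$spec$assembly)
  v <- result$variants
  tab <- data.frame(CHROM = v$chrom, POS = as.character(v$pos), ID = v$id,
                    REF = v$ref, ALT = v$alt, QUAL = v$qual, FILTER = v$filter,
                    INFO = v$info, stringsAsFactors = FALSE,
                    check.names = FALSE)
  gt <- as.data.frame(result$gt_raw, stringsAsFactors = FALSE)
  names(gt) <- result$sample_ids
  if (nrow(gt) == nrow(tab)) tab <- cbind(tab, gt, stringsAsFactors = FALSE)
  if (!is.null(v$significance)) tab$significance <- ifelse(
    is.na(v$significance), "", v$significance)
  if (!is.null(v$region)) tab$region <- v$region
  tab$gnomad_url <- vapply(seq_len(nrow(v)), function(i) {
    alt1 <- strsplit(v$alt[i], ",", fixed = TRUE)[[1]][1]
    tryCatch(vgc_gnomad_url(list(chrom = v$chrom[i], pos = v$pos[i],
                                 ref = v$ref[i], alt_alleles = alt1),
                            assembly = assembly),
             vgc_error = function(e) "")
  }, character(1))
  if (!is.null(assoc)) {
    stopifnot(nrow(assoc) == nrow(tab))
    acols <- setdiff(names(assoc), c("chrom", "pos", "ref", "alt"))
    for (cn in acols) {
      val <- assoc[[cn]]
      tab[[cn]] <- ifelse(is.na(val), "", as.character(val))
    }
  }
  rownames(tab) <- NULL
  structure(tab,
            provenance = list(spec = result$spec,
                              stem = vcf_stem(result$spec$source %||% ""),
                              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = c("vgc_result_table", "data.frame"))
}

SUPPORTED_FORMATS <- c("csv", "tsv")

infer_format <- function(path) tolower(tools::file_ext(path))

#' Write a result table to disk
#'
#' CSV output follows RFC 4180 (all fields quoted, quotes doubled, UTF-8);
#' TSV is tab-separated with the same quoting. The legacy `.xls` and layout
#' `.pdf` dialects are deliberately unsupported, and `.xlsx` additionally
#' requires a spreadsheet writer that this package does not depend on — all
#' three raise an explicit not-supported error.
#'
#' @param table A `vgc_result_table` (or plain data.frame of characters).
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
vgc_write_table <- function(table, path, format = infer_format(path)) {
  if (!format %in% SUPPORTED_FORMATS) {
    vgc_abort(sprintf(
      "format '%s' is not supported (this tool exports csv and tsv only; xlsx/xls/pdf were dropped by design)",
      format), "vgc_not_supported")
  }
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  } else {
    write.table(df, path, row.names = FALSE, quote = TRUE, sep = "\t",
                qmethod = "double", fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read back an exported table
#'
#' All columns are read as character, so `vgc_read_table(vgc_write_table(x))`
#' reproduces `x` exactly at the text level.
#'
#' @param path File written by [vgc_write_table()].
#' @param format `"csv"` or `"tsv"`; inferred from the extension by default.
#' @export
vgc_read_table <- function(path, format = infer_format(path)) {
  if (!format %in% SUPPORTED_FORMATS) {
    vgc_abort(sprintf("format '%s' is not supported", format), "vgc_not_supported")
  }
  read.csv(path, colClasses = "character", check.names = FALSE,
           sep = if (format == "csv") "," else "\t",
           fileEncoding = "UTF-8")
}
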