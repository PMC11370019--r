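#' Build the sidecar index for a coordinate-sorted VCF
#'
#' Scans the file once and summarises, per chromosome, the physical line span
#' (1-based over all lines including meta/header lines), the position span,
#' the number of data lines whose FILTER is literally `"PASS"`, and the
#' number of lines whose (chrom, pos, ref, alt) matches a pathogenic entry in
#' the supplied ClinVar-style lookup. Without a pathogenicity source the
#' pathogenic counts are recorded as 0 and the bundle carries the
#' `no_pathogenicity_source` flag.
#'
#' @param vcf_path Path to a coordinate-sorted VCF (plain or gzipped).
#' @param clinvar Optional lookup from [vgc_load_clinvar()].
#' @return An object of class `vgc_index`: list with `info` (file-level
#'   summary), `entries` (one data.frame row per chromosome), `source_path`,
#'   `source_size`, `source_mtime` and `no_pathogenicity_source`.
#' @export
vgc_build_index <- function(vcf_path, clinvar = NULL) {
  hdr <- vgc_read_header(vcf_path)
  lines <- read_all_lines(vcf_path)
  is_data <- !startsWith(lines, "#") & nzchar(lines)
  dl <- which(is_data)
  if (length(dl) == 0L) {
    vgc_abort(sprintf("VCF %s contains no data lines", vcf_path), "vgc_empty_file")
  }
  srt <- vgc_validate_sorted(vcf_path)
  if (!srt$chrom_contiguous || !srt$positions_sorted) {
    vgc_abort(sprintf(
      "VCF is not coordinate-sorted (first offending line %d); sort it before indexing",
      srt$first_offending_line), "vgc_sort_required")
  }

  sc <- light_scan(lines[dl])
  path_flags <- rep(FALSE, length(dl))
  if (!is.null(clinvar)) {
    path_flags <- vapply(seq_along(dl), function(i) {
      alts <- strsplit(sc$alt[i], ",", fixed = TRUE)[[1]]
      any(vapply(alts, function(a) {
        rec <- clinvar_get(clinvar, sc$chrom[i], sc$pos[i], sc$ref[i], a)
        !is.null(rec) && rec$is_pathogenic
      }, logical(1)))
    }, logical(1))
  }

  r <- rle(sc$chrom)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  entries <- data.frame(
    chrom = r$values,
    start_line = dl[starts],
    end_line = dl[ends],
    start_pos = sc$pos[starts],
    end_pos = sc$pos[ends],
    pass_count = vapply(seq_along(starts), function(i)
      sum(sc$filter[starts[i]:ends[i]] == "PASS"), integer(1)),
    pathogenic_count = vapply(seq_along(starts), function(i)
      sum(path_flags[starts[i]:ends[i]]), integer(1)),
    stringsAsFactors = FALSE)

  fi <- file.info(vcf_path)
  info <- list(vcf_version = hdr$vcf_version,
               sample_count = length(hdr$sample_ids),
               chromosome_count = nrow(entries),
               variant_count = length(dl),
               header_line = hdr$column_header_line,
               chromosome_list = entries$chrom)
  structure(list(info = info,
                 entries = entries,
                 sample_ids = hdr$sample_ids,
                 source_path = normalizePath(vcf_path),
                 source_size = as.numeric(fi$size),
                 source_mtime = sprintf("%.6f", as.numeric(fi$mtime)),
                 no_pathogenicity_source = is.null(clinvar)),
            class = "vgc_index")
}

vcf_stem <- function(vcf_path) {
  stem <- basename(vcf_path)
  stem <- sub("\\.gz$", "", stem)
  sub("\\.vcf$", "", stem)
}

sidecar_paths <- function(vcf_path, root) {
  stem <- vcf_stem(vcf_path)
  dir <- file.path(root, "VGCGeneratedFiles", paste0("VGC_", stem))
  list(dir = dir,
       info = file.path(dir, paste0("info_", stem, ".txt")),
       index = file.path(dir, paste0("index_", stem, ".txt")))
}

INDEX_COLS <- c("chrom", "start_line", "end_line", "start_pos", "end_pos",
                "pass_count", "pathogenic_count")

#' Persist a sidecar index to disk
#'
#' Creates `<root>/VGCGeneratedFiles/VGC_<stem>/` containing
#' `info_<stem>.txt` (flat `key=value` lines) and `index_<stem>.txt`
#' (a TSV with one row per chromosome). Writes are atomic (temp file then
#' rename) and idempotent.
#'
#' @param bundle A `vgc_index` from [vgc_build_index()].
#' @param root Directory under which the `VGCGeneratedFiles` tree is created;
#'   defaults to the user home directory.
#' @return Named list with the `info` and `index` file paths, invisibly.
#' @export
vgc_write_index <- function(bundle, root = path.expand("~")) {
  stopifnot(inherits(bundle, "vgc_index"))
  p <- sidecar_paths(bundle$source_path, root)
  ok <- dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(p$dir)) {
    vgc_abort(sprintf("cannot create directory %s", p$dir), "vgc_io")
  }
  info <- bundle$info
  kv <- list(vcf_version = info$vcf_version,
             sample_count = info$sample_count,
             chromosome_count = info$chromosome_count,
             variant_count = info$variant_count,
             header_line = info$header_line,
             chromosomes = paste(info$chromosome_list, collapse = ","),
             source_size = sprintf("%.0f", bundle$source_size),
             source_mtime = bundle$source_mtime,
             no_pathogenicity_source = tolower(bundle$no_pathogenicity_source))
  write_kv(kv, p$info)

  tmp <- tempfile(tmpdir = p$dir)
  e <- bundle$entries
  lines <- c(paste(INDEX_COLS, collapse = "\t"),
             paste(e$chrom, e$start_line, e$end_line, e$start_pos, e$end_pos,
                   e$pass_count, e$pathogenic_count, sep = "\t"))
  writeLines(lines, tmp, sep = "\n")
  if (!file.rename(tmp, p$index)) {
    unlink(tmp)
    vgc_abort(sprintf("cannot write %s", p$index), "vgc_io")
  }
  invisible(list(info = p$info, index = p$index))
}

#' Load a previously written sidecar index
#'
#' Returns `NULL` when no sidecar exists or when the source VCF changed since
#' indexing (size or mtime mismatch — the index is stale and should be
#' rebuilt). Corrupt sidecar files raise a `vgc_corrupt_index` error.
#'
#' @param vcf_path The VCF the index was built for.
#' @param root Directory given to [vgc_write_index()].
#' @return A `vgc_index` or `NULL`.
#' @export
vgc_load_index <- function(vcf_path, root = path.expand("~")) {
  p <- sidecar_paths(vcf_path, root)
  if (!file.exists(p$info) || !file.exists(p$index)) return(NULL)
  kv <- tryCatch(read_kv(p$info), vgc_error = function(e)
    vgc_abort(sprintf("corrupt info file %s: %s; rebuild the index",
                      p$info, conditionMessage(e)), "vgc_corrupt_index"))
  need <- c("vcf_version", "sample_count", "chromosome_count", "variant_count",
            "header_line", "chromosomes", "source_size", "source_mtime")
  if (!all(need %in% names(kv))) {
    vgc_abort(sprintf("info file %s is missing keys (%s); rebuild the index",
                      p$info, paste(setdiff(need, names(kv)), collapse = ", ")),
              "vgc_corrupt_index")
  }
  fi <- file.info(vcf_path)
  if (sprintf("%.0f", as.numeric(fi$size)) != kv$source_size ||
      sprintf("%.6f", as.numeric(fi$mtime)) != kv$source_mtime) {
    return(NULL)  # stale
  }
  idx_lines <- readLines(p$index, warn = FALSE)
  if (length(idx_lines) < 2L ||
      !identical(strsplit(idx_lines[1], "\t", fixed = TRUE)[[1]], INDEX_COLS)) {
    vgc_abort(sprintf("corrupt index file %s; rebuild the index", p$index),
              "vgc_corrupt_index")
  }
  parts <- strsplit(idx_lines[-1], "\t", fixed = TRUE)
  if (any(lengths(parts) != length(INDEX_COLS))) {
    vgc_abort(sprintf("corrupt index file %s (truncated row); rebuild the index",
                      p$index), "vgc_corrupt_index")
  }
  m <- matrix(unlist(parts), ncol = length(INDEX_COLS), byrow = TRUE)
  entries <- data.frame(chrom = m[, 1],
                        start_line = as.integer(m[, 2]),
                        end_line = as.integer(m[, 3]),
                        start_pos = as.integer(m[, 4]),
                        end_pos = as.integer(m[, 5]),
                        pass_count = as.integer(m[, 6]),
                        pathogenic_count = as.integer(m[, 7]),
                        stringsAsFactors = FALSE)
  if (anyNA(entries[-1])) {
    vgc_abort(sprintf("corrupt index file %s (non-numeric fields); rebuild the index",
                      p$index), "vgc_corrupt_index")
  }
  chromosome_list <- if (nzchar(kv$chromosomes))
    strsplit(kv$chromosomes, ",", fixed = TRUE)[[1]] else character(0)
  if (!identical(chromosome_list, entries$chrom) ||
      sum(entries$end_line - entries$start_line + 1L) != as.integer(kv$variant_count)) {
    vgc_abort(sprintf("info and index files disagree under %s; rebuild the index",
                      p$dir), "vgc_corrupt_index")
  }
  hdr <- vgc_read_header(vcf_path)
  info <- list(vcf_version = kv$vcf_version,
               sample_count = as.integer(kv$sample_count),
               chromosome_count = as.integer(kv$chromosome_count),
               variant_count = as.integer(kv$variant_count),
               header_line = kv$header_line,
               chromosome_list = chromosome_list)
  structure(list(info = info,
                 entries = entries,
                 sample_ids = hdr$sample_ids,
                 source_path = normalizePath(vcf_path),
                 source_size = as.numeric(kv$source_size),
                 source_mtime = kv$source_mtime,
                 no_pathogenicity_source =
                   identical(tolower(kv$no_pathogenicity_source %||% "true"), "true")),
            class = "vgc_index")
}

#' Load an existing index or build (and persist) a fresh one
#' @inheritParams vgc_build_index
#' @param root Sidecar root directory.
#' @param write Persist a freshly built index.
#' @export
vgc_open_index <- function(vcf_path, root = path.expand("~"), clinvar = NULL,
                           write = TRUE) {
  bundle <- vgc_load_index(vcf_path, root)
  if (is.null(bundle) ||
      (bundle$no_pathogenicity_source && !is.null(clinvar))) {
    bundle <- vgc_build_index(vcf_path, clinvar)
    if (write) vgc_write_index(bundle, root)
  }
  bundle
}

#' @export
print.vgc_index <- function(x, ...) {
  cat(sprintf("VCF index for %s: %d variants, %d chromosomes, %d samples\n",
              basename(x$source_path), x$info$variant_count,
              x$info$chromosome_count, x$info$sample_count))
  print(x$entries)
  invisible(x)
}
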