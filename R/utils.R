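#' @importFrom stats rhyper runif setNames
#' @importFrom utils read.csv write.csv write.table head adist str
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed vgccraft error
#'
#' All package errors carry a machine-readable condition class under the
#' `vgc_error` umbrella so callers (and tests) can discriminate failure modes.
#' @noRd
vgc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vgc_error")))
}

#' Strip an optional "chr" prefix so "chr1" and "1" compare equal
#' @noRd
norm_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

#' Canonical variant key used for joins and node identifiers
#' @noRd
variant_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), pos, ref, alt, sep = ":")
}

#' Open a VCF path for line reading; gzfile() transparently handles plain
#' text, gzip and bgzip streams.
#' @noRd
open_vcf <- function(path) {
  if (!file.exists(path)) {
    vgc_abort(sprintf("file not found: %s", path), "vgc_io")
  }
  gzfile(path, "rt")
}

read_all_lines <- function(path) {
  con <- open_vcf(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read physical lines `from`..`to` (1-based, inclusive) of a possibly
#' compressed text file. Lines before `from` are skipped without parsing.
#' @noRd
read_line_window <- function(path, from, to) {
  con <- open_vcf(path)
  on.exit(close(con))
  lines <- readLines(con, n = to, warn = FALSE)
  if (length(lines) < to) {
    vgc_abort(sprintf("file %s has fewer than %d lines", path, to), "vgc_io")
  }
  lines[from:to]
}

# ---- flat key=value documents (sidecar info files, analysis plans) ----

write_kv <- function(x, path) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  lines <- paste0(names(x), "=", vapply(x, as.character, character(1)))
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(lines, tmp, sep = "\n")
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    vgc_abort(sprintf("cannot write %s", path), "vgc_io")
  }
  invisible(path)
}

read_kv <- function(path) {
  if (!file.exists(path)) vgc_abort(sprintf("file not found: %s", path), "vgc_io")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) {
    vgc_abort(sprintf("malformed key=value line in %s: %s",
                      path, lines[which(eq < 0)[1]]), "vgc_parse")
  }
  keys <- substr(lines, 1L, eq - 1L)
  vals <- substr(lines, eq + 1L, nchar(lines))
  setNames(as.list(vals), keys)
}

#' Parse "chrom:start-end" range syntax
#' @noRd
parse_range_string <- function(s) {
  m <- regmatches(s, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4L) {
    vgc_abort(sprintf("cannot parse genomic range '%s' (expected chrom:start-end)", s),
              "vgc_parse")
  }
  vgc_range(m[2], as.integer(m[3]), as.integer(m[4]))
}

looks_like_range <- function(s) grepl("^[^:[:space:]]+:[0-9]+-[0-9]+$", s)

#' Restore the caller's RNG state after a seeded computation
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    vgc_abort("seed must be a single integer", "vgc_parameter")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
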