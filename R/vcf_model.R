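# Genotype class codes shared across the package:
#   0 = HOM_REF, 1 = HET, 2 = HOM_ALT, -1 = MISSING
GT_HOM_REF <- 0L
GT_HET     <- 1L
GT_HOM_ALT <- 2L
GT_MISSING <- -1L

GT_LABELS <- c("HOM_REF", "HET", "HOM_ALT")

gt_code_to_label <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code == GT_MISSING] <- "MISSING"
  out[code == GT_HOM_REF] <- "HOM_REF"
  out[code == GT_HET]     <- "HET"
  out[code == GT_HOM_ALT] <- "HOM_ALT"
  out
}

#' Read the header of a VCF file
#'
#' Reads meta lines (`##...`) and the `#CHROM` column header of a plain or
#' gzip/bgzip compressed VCF, stopping before the first data line.
#'
#' @param vcf_path Path to a VCF text file (optionally gzipped).
#' @return An object of class `vgc_header`: a list with `vcf_version`
#'   (e.g. `"VCFv4.2"`), `sample_ids` (ordered character vector),
#'   `column_header_line` (the literal `#CHROM...` line) and
#'   `meta_line_count` (number of lines preceding the first data line,
#'   including the column header itself).
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
#'                    "INFO", "FORMAT", "S1", sep = "\t"),
#'              paste("1", "100", ".", "A", "T", "50", "PASS", ".", "GT", "0/1",
#'                    sep = "\t")), vcf)
#' h <- vgc_read_header(vcf)
#' h$vcf_version
#' h$sample_ids
#' @export
vgc_read_header <- function(vcf_path) {
  con <- open_vcf(vcf_path)
  on.exit(close(con))
  version <- NA_character_
  n_meta <- 0L
  header_line <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) {
      vgc_abort("no '#CHROM' column header line found before end of file",
                "vgc_malformed_file")
    }
    n_meta <- n_meta + 1L
    if (startsWith(line, "##")) {
      if (startsWith(line, "##fileformat=")) {
        version <- sub("^##fileformat=", "", line)
      }
      next
    }
    if (startsWith(line, "#CHROM")) {
      header_line <- line
      break
    }
    vgc_abort(sprintf(
      "line %d: first non-meta line does not start with '#CHROM'", n_meta),
      "vgc_malformed_file")
  }
  cols <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) {
    vgc_abort("VCF declares no sample columns", "vgc_no_samples")
  }
  samples <- cols[-(1:9)]
  if (anyDuplicated(samples)) {
    vgc_abort("duplicate sample IDs in the #CHROM header line",
              "vgc_malformed_file")
  }
  structure(list(vcf_version = version,
                 sample_ids = samples,
                 column_header_line = header_line,
                 meta_line_count = n_meta),
            class = "vgc_header")
}

#' Classify GT strings into genotype classes
#'
#' Vectorised over `gt`. The class collapses multi-allelic calls by
#' alternate-allele count: 0 alt alleles is HOM_REF, exactly 1 is HET and 2
#' (equal or not, e.g. `1/2`) is HOM_ALT. Any `.` allele yields MISSING.
#' Haploid calls are treated as homozygous for their single allele; calls
#' with more than two alleles are rejected.
#'
#' @param gt Character vector of GT subfields, e.g. `c("0/1", "1|1", "./.")`.
#' @return A list with integer `class` codes (0/1/2/-1), logical `phased`,
#'   and integer allele indices `a1`, `a2` (-1 for missing).
#' @export
vgc_classify_gt <- function(gt) {
  phased <- grepl("|", gt, fixed = TRUE)
  toks <- strsplit(gt, "[/|]")
  n <- length(gt)
  cls <- integer(n)
  a1 <- integer(n)
  a2 <- integer(n)
  for (i in seq_len(n)) {
    a <- toks[[i]]
    if (length(a) > 2L) {
      vgc_abort(sprintf(
        "genotype '%s' has more than two alleles; only haploid or diploid calls are supported",
        gt[i]), "vgc_ploidy")
    }
    if (length(a) == 1L) a <- c(a, a)  # haploid: homozygous for its allele
    ai <- suppressWarnings(as.integer(ifelse(a == ".", -1L, a)))
    if (anyNA(ai) || any(ai < -1L)) {
      vgc_abort(sprintf("cannot parse genotype '%s'", gt[i]), "vgc_malformed_line")
    }
    a1[i] <- ai[1]; a2[i] <- ai[2]
    if (any(ai == -1L)) {
      cls[i] <- GT_MISSING
    } else {
      n_alt <- sum(ai > 0L)
      cls[i] <- if (n_alt == 0L) GT_HOM_REF else if (n_alt == 1L) GT_HET else GT_HOM_ALT
    }
  }
  list(class = cls, phased = phased, a1 = a1, a2 = a2)
}

#' Parse one VCF data line into a variant record
#'
#' @param line A tab-separated VCF data line whose FORMAT contains `GT`.
#' @param n_samples Number of sample columns the owning file declares.
#' @param source_line_number 1-based physical line number of `line` in its file.
#' @return An object of class `vgc_variant`: chrom, pos (1-based), id, ref,
#'   `alt_alleles` (character vector), qual (numeric or NA), filter, info,
#'   a `genotypes` list (one `vgc_genotype` per sample, with `allele_indices`,
#'   `phased` and `class`), raw column strings in `fields_raw` and
#'   `sample_fields`, and `source_line_number`.
#' @export
vgc_parse_data_line <- function(line, n_samples, source_line_number = 1L) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 9L + n_samples) {
    vgc_abort(sprintf(
      "line %d: expected at least %d tab-separated columns, found %d",
      source_line_number, 9L + n_samples, length(f)), "vgc_malformed_line")
  }
  fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1]]
  gt_idx <- match("GT", fmt)
  if (is.na(gt_idx)) {
    vgc_abort(sprintf("line %d: FORMAT column lacks GT", source_line_number),
              "vgc_malformed_line")
  }
  sample_fields <- f[10L:(9L + n_samples)]
  gt <- vapply(strsplit(sample_fields, ":", fixed = TRUE),
               function(x) x[[gt_idx]], character(1))
  g <- vgc_classify_gt(gt)
  genotypes <- lapply(seq_len(n_samples), function(i) {
    structure(list(allele_indices = c(g$a1[i], g$a2[i]),
                   phased = g$phased[i],
                   class = gt_code_to_label(g$class[i])),
              class = "vgc_genotype")
  })
  alt <- if (f[5L] == ".") character(0) else strsplit(f[5L], ",", fixed = TRUE)[[1]]
  structure(list(chrom = f[1L],
                 pos = as.integer(f[2L]),
                 id = f[3L],
                 ref = f[4L],
                 alt_alleles = alt,
                 qual = if (f[6L] == ".") NA_real_ else as.numeric(f[6L]),
                 filter = f[7L],
                 info = f[8L],
                 format = f[9L],
                 genotypes = genotypes,
                 gt_codes = g$class,
                 fields_raw = f[1:9],
                 sample_fields = sample_fields,
                 source_line_number = as.integer(source_line_number)),
            class = "vgc_variant")
}

#' Re-serialize the fixed columns of a parsed variant
#'
#' Returns the CHROM..FORMAT columns byte-for-byte as they appeared in the
#' source file (raw strings are retained at parse time).
#' @param variant A `vgc_variant`.
#' @param with_samples Also append the per-sample columns.
#' @export
vgc_serialize_variant <- function(variant, with_samples = FALSE) {
  cols <- variant$fields_raw
  if (with_samples) cols <- c(cols, variant$sample_fields)
  paste(cols, collapse = "\t")
}

# Internal single-pass extraction of the light columns (chrom, pos, filter)
# from raw data lines, without touching sample columns.
light_scan <- function(lines) {
  chrom <- sub("\t.*$", "", lines)
  rest <- sub("^[^\t]*\t", "", lines)
  pos <- as.integer(sub("\t.*$", "", rest))
  # FILTER is column 7; split only what is needed
  parts <- strsplit(lines, "\t", fixed = TRUE)
  filt <- vapply(parts, function(p) p[7L], character(1))
  ref <- vapply(parts, function(p) p[4L], character(1))
  alt <- vapply(parts, function(p) p[5L], character(1))
  list(chrom = chrom, pos = pos, filter = filt, ref = ref, alt = alt)
}

#' Check the sortedness assumptions the sidecar index relies on
#'
#' A diagnostic pass over the whole file: chromosome blocks must be
#' contiguous (a chromosome never reappears after another one started) and
#' positions must be nondecreasing within each chromosome.
#'
#' @param vcf_path Path to a VCF file.
#' @return A list with logicals `chrom_contiguous` and `positions_sorted`,
#'   and `first_offending_line` (1-based physical line number, `NA` if clean).
#' @export
vgc_validate_sorted <- function(vcf_path) {
  lines <- read_all_lines(vcf_path)
  is_data <- !startsWith(lines, "#") & nzchar(lines)
  dl <- which(is_data)
  if (length(dl) == 0L) {
    return(list(chrom_contiguous = TRUE, positions_sorted = TRUE,
                first_offending_line = NA_integer_))
  }
  chrom <- sub("\t.*$", "", lines[dl])
  rest <- sub("^[^\t]*\t", "", lines[dl])
  pos <- as.integer(sub("\t.*$", "", rest))

  contiguous <- TRUE
  sorted <- TRUE
  offending <- NA_integer_

  r <- rle(chrom)
  if (anyDuplicated(r$values)) {
    contiguous <- FALSE
    # first data line where an already-seen chromosome restarts
    block_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    bad_block <- which(duplicated(r$values))[1]
    offending <- dl[block_start[bad_block]]
  }
  new_chrom <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  backstep <- c(FALSE, diff(pos) < 0) & !new_chrom
  if (any(backstep)) {
    sorted <- FALSE
    off2 <- dl[which(backstep)[1]]
    offending <- if (is.na(offending)) off2 else min(offending, off2)
  }
  list(chrom_contiguous = contiguous, positions_sorted = sorted,
       first_offending_line = offending)
}

# Parse a block of data lines into the package's bulk representation:
#   $fields  data.frame of raw column strings (chrom, pos [int], id, ref, alt,
#            qual, filter, info, format, line)
#   $gt      integer genotype-class matrix (variants x samples)
#   $phased  logical matrix
#   $gt_raw  character matrix of full per-sample fields
parse_variant_block <- function(lines, line_numbers, n_samples) {
  nv <- length(lines)
  if (nv == 0L) {
    return(list(
      fields = data.frame(chrom = character(0), pos = integer(0),
                          id = character(0), ref = character(0),
                          alt = character(0), qual = character(0),
                          filter = character(0), info = character(0),
                          format = character(0), line = integer(0),
                          stringsAsFactors = FALSE),
      gt = matrix(integer(0), nrow = 0, ncol = n_samples),
      phased = matrix(logical(0), nrow = 0, ncol = n_samples),
      gt_raw = matrix(character(0), nrow = 0, ncol = n_samples)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(ncols < 9L + n_samples)
  if (length(bad)) {
    vgc_abort(sprintf(
      "line %d: expected at least %d columns, found %d",
      line_numbers[bad[1]], 9L + n_samples, ncols[bad[1]]), "vgc_malformed_line")
  }
  m <- matrix(unlist(lapply(parts, `[`, seq_len(9L + n_samples))),
              nrow = nv, byrow = TRUE)
  fields <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), id = m[, 3],
                       ref = m[, 4], alt = m[, 5], qual = m[, 6],
                       filter = m[, 7], info = m[, 8], format = m[, 9],
                       line = as.integer(line_numbers),
                       stringsAsFactors = FALSE)
  gt_raw <- m[, 9L + seq_len(n_samples), drop = FALSE]
  gt_pos <- vapply(strsplit(m[, 9], ":", fixed = TRUE),
                   function(x) match("GT", x), integer(1))
  if (anyNA(gt_pos)) {
    vgc_abort(sprintf("line %d: FORMAT column lacks GT",
                      line_numbers[which(is.na(gt_pos))[1]]), "vgc_malformed_line")
  }
  gt_strings <- gt_raw
  # extract the GT subfield row-wise (FORMAT can differ per line)
  for (i in seq_len(nv)) {
    if (gt_pos[i] == 1L) {
      gt_strings[i, ] <- sub(":.*$", "", gt_raw[i, ])
    } else {
      gt_strings[i, ] <- vapply(strsplit(gt_raw[i, ], ":", fixed = TRUE),
                                function(x) x[[gt_pos[i]]], character(1))
    }
  }
  g <- vgc_classify_gt(as.vector(gt_strings))
  list(fields = fields,
       gt = matrix(g$class, nrow = nv, ncol = n_samples),
       phased = matrix(g$phased, nrow = nv, ncol = n_samples),
       gt_raw = gt_raw)
}

#' @export
print.vgc_header <- function(x, ...) {
  cat(sprintf("VCF header: version %s, %d samples, %d header lines\n",
              x$vcf_version, length(x$sample_ids), x$meta_line_count))
  invisible(x)
}

#' @export
print.vgc_variant <- function(x, ...) {
  cat(sprintf("%s:%d %s>%s FILTER=%s (%d genotypes)\n",
              x$chrom, x$pos, x$ref, paste(x$alt_alleles, collapse = ","),
              x$filter, length(x$genotypes)))
  invisible(x)
}
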