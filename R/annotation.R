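# ClinVar aggregate labels counted as pathogenic (case-insensitive);
# "conflicting interpretations" is deliberately not in this set.
PATHOGENIC_LABELS <- c("pathogenic", "likely pathogenic",
                       "pathogenic/likely pathogenic")

clinvar_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), pos, ref, alt, sep = ":")
}

clinvar_get <- function(table, chrom, pos, ref, alt) {
  stopifnot(inherits(table, "vgc_clinvar"))
  table$env[[clinvar_key(chrom, pos, ref, alt)]]
}

#' Load a local ClinVar-style pathogenicity table
#'
#' The table is a TSV extract with columns `chrom, pos, ref, alt,
#' clinical_significance` and optionally `condition` and `review_status`.
#' Records are keyed by (chrom, pos, ref, alt) with `chr`-prefix
#' normalisation, so `"chr1"` in the table matches `"1"` in a VCF. Duplicate
#' keys keep the last record, with a warning.
#'
#' @param path TSV file path. An empty file yields a valid empty lookup.
#' @return A `vgc_clinvar` lookup object.
#' @export
vgc_load_clinvar <- function(path) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  n <- 0L
  if (file.exists(path) && file.size(path) > 0L) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", data.table = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "clinical_significance")
    if (!all(need %in% names(dt))) {
      vgc_abort(sprintf("pathogenicity table %s lacks columns: %s", path,
                        paste(setdiff(need, names(dt)), collapse = ", ")),
                "vgc_validation")
    }
    keys <- clinvar_key(dt$chrom, dt$pos, dt$ref, dt$alt)
    if (anyDuplicated(keys)) {
      warning(sprintf("pathogenicity table %s: %d duplicate keys; keeping the last record",
                      path, sum(duplicated(keys))))
    }
    for (i in seq_len(nrow(dt))) {
      sig <- dt$clinical_significance[i]
      env[[keys[i]]] <- list(
        chrom = dt$chrom[i], pos = as.integer(dt$pos[i]),
        ref = dt$ref[i], alt = dt$alt[i],
        clinical_significance = sig,
        condition = if ("condition" %in% names(dt)) dt$condition[i] else NA_character_,
        review_status = if ("review_status" %in% names(dt)) dt$review_status[i] else NA_character_,
        is_pathogenic = tolower(sig) %in% PATHOGENIC_LABELS)
    }
    n <- nrow(dt)
  }
  structure(list(env = env, n = n, path = path), class = "vgc_clinvar")
}

#' Annotate one variant against the pathogenicity table
#'
#' A variant matches when any of its alternate alleles keys into the table by
#' (chrom, pos, ref, alt). It is called pathogenic when matched and the
#' record's clinical significance is (case-insensitively) one of
#' `Pathogenic`, `Likely pathogenic` or `Pathogenic/Likely pathogenic`.
#'
#' @param variant A `vgc_variant` (or a list with chrom, pos, ref,
#'   alt_alleles).
#' @param table A `vgc_clinvar` lookup.
#' @return List with `is_pathogenic`, `significance` (`NA` when unmatched)
#'   and `matched`.
#' @export
vgc_annotate_pathogenicity <- function(variant, table) {
  res <- annotate_block(variant$chrom, variant$pos, variant$ref,
                        paste(variant$alt_alleles, collapse = ","), table)
  list(is_pathogenic = res$is_pathogenic[1],
       significance = res$significance[1],
       matched = res$matched[1])
}

# vectorised annotation over parallel vectors; alt may be comma-joined
annotate_block <- function(chrom, pos, ref, alt, table) {
  n <- length(pos)
  is_path <- logical(n)
  matched <- logical(n)
  sig <- rep(NA_character_, n)
  if (!is.null(table)) {
    for (i in seq_len(n)) {
      for (a in strsplit(alt[i], ",", fixed = TRUE)[[1]]) {
        rec <- clinvar_get(table, chrom[i], pos[i], ref[i], a)
        if (!is.null(rec)) {
          matched[i] <- TRUE
          # first matching alt allele wins unless a later one is pathogenic
          if (is.na(sig[i]) || rec$is_pathogenic) sig[i] <- rec$clinical_significance
          if (rec$is_pathogenic) {
            is_path[i] <- TRUE
            break
          }
        }
      }
    }
  }
  list(is_pathogenic = is_path, significance = sig, matched = matched)
}

GNOMAD_DEFAULT_TAGS <- c(GRCh37 = "gnomad_r2_1", GRCh38 = "gnomad_r4")

#' Construct a gnomAD variant URL
#'
#' Pure string construction — no network access is performed. The chromosome
#' is stripped of any `chr` prefix and the dataset tag defaults to
#' `gnomad_r2_1` for GRCh37 and `gnomad_r4` for GRCh38 (overridable, since
#' gnomAD dataset versions drift).
#'
#' @param variant A `vgc_variant`, or a list with `chrom`, `pos`, `ref`,
#'   `alt_alleles`.
#' @param alt_index Which alternate allele to link (default first).
#' @param assembly `"GRCh37"` or `"GRCh38"`.
#' @param dataset_tags Named character vector mapping assembly to dataset tag.
#' @return The URL string.
#' @export
vgc_gnomad_url <- function(variant, alt_index = 1L, assembly = "GRCh38",
                           dataset_tags = GNOMAD_DEFAULT_TAGS) {
  assembly <- check_assembly(assembly)
  if (alt_index < 1L || alt_index > length(variant$alt_alleles)) {
    vgc_abort(sprintf("alt_index %d out of range", alt_index), "vgc_parameter")
  }
  alt <- variant$alt_alleles[alt_index]
  if (grepl("[][<>]", alt) || grepl("[][<>]", variant$ref)) {
    vgc_abort(sprintf("symbolic or breakend allele '%s' has no gnomAD variant page", alt),
              "vgc_unsupported_allele")
  }
  sprintf("https://gnomad.broadinstitute.org/variant/%s-%d-%s-%s?dataset=%s",
          norm_chrom(variant$chrom), as.integer(variant$pos), variant$ref, alt,
          dataset_tags[[assembly]])
}

#' Load an MSigDB-style GMT gene-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB member TAB ...`.
#' Duplicate members within one set are stored once; member symbols are kept
#' as written but matched case-insensitively by
#' [vgc_gene_set_membership()].
#'
#' @param gmt_path GMT file path.
#' @param name Collection label (defaults to the file stem).
#' @return A `vgc_gene_sets` collection.
#' @export
vgc_load_gene_sets <- function(gmt_path, name = NULL) {
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      vgc_abort(sprintf("%s line %d: GMT line needs name, description and at least one member",
                        gmt_path, i), "vgc_parse")
    }
    if (!is.null(sets[[f[1]]])) {
      vgc_abort(sprintf("%s line %d: duplicate set name '%s'", gmt_path, i, f[1]),
                "vgc_parse")
    }
    sets[[f[1]]] <- list(description = f[2], members = unique(f[-(1:2)]))
  }
  structure(list(name = name %||% sub("\\.gmt$", "", basename(gmt_path)),
                 sets = sets),
            class = "vgc_gene_sets")
}

#' Write a gene-set collection back to GMT
#' @param collection A `vgc_gene_sets`.
#' @param path Output path.
#' @export
vgc_write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "vgc_gene_sets"))
  lines <- vapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Gene-set membership of a symbol
#'
#' @param collection A `vgc_gene_sets`.
#' @param symbol Gene symbol (matched case-insensitively).
#' @return Character vector of set names containing the symbol (possibly
#'   empty).
#' @export
vgc_gene_set_membership <- function(collection, symbol) {
  stopifnot(inherits(collection, "vgc_gene_sets"))
  hit <- vapply(collection$sets, function(s)
    toupper(symbol) %in% toupper(s$members), logical(1))
  names(collection$sets)[hit]
}

#' @export
print.vgc_clinvar <- function(x, ...) {
  cat(sprintf("Pathogenicity table: %d records (%s)\n", x$n, x$path))
  invisible(x)
}
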