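#' Configuration for the synthetic case-control cohort simulator
#'
#' The generator emulates the shape of a case-control exome cohort: two (or
#' more) phenotype groups, chromosome blocks of coordinate-sorted variants,
#' Hardy-Weinberg genotypes at a per-locus alternate-allele frequency, a
#' PASS/non-PASS FILTER mix, planted group-differentiated association
#' signals and planted ClinVar-pathogenic loci.
#'
#' @param seed Integer seed; the same config yields byte-identical files.
#' @param n_cases,n_controls Group sizes (defaults 61 and 82, the shape of a
#'   preeclampsia case-control exome cohort).
#' @param chromosomes Named integer vector of chromosome lengths.
#' @param n_variants Total background variants, allocated to chromosomes
#'   proportionally to length.
#' @param pass_fraction Probability a variant's FILTER is `"PASS"` (else
#'   `"q10"`).
#' @param genes List of gene definitions: each a list with `symbol`, `chrom`,
#'   `start`, `end`, optional `exons` (2-column matrix) and optional
#'   `n_variants` placed inside the span (default 0).
#' @param planted_signals List of association signals: each a list with
#'   `chrom`, `pos`, `case_freq`, `control_freq` (group alt-allele
#'   frequencies).
#' @param planted_pathogenic List of loci (`chrom`, `pos`) to mark Pathogenic
#'   in the generated ClinVar-style table.
#' @param missing_rate Per-genotype missingness probability.
#' @param null_freq_range Range the per-locus null alternate-allele frequency
#'   is drawn from (uniform).
#' @return A validated `vgc_sim_config`.
#' @export
vgc_sim_config <- function(seed,
                           n_cases = 61L,
                           n_controls = 82L,
                           chromosomes = c(`1` = 1000000L, `2` = 1000000L),
                           n_variants = 200L,
                           pass_fraction = 0.9,
                           genes = list(),
                           planted_signals = list(),
                           planted_pathogenic = list(),
                           missing_rate = 0.02,
                           null_freq_range = c(0.05, 0.5)) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes)))) {
    vgc_abort("chromosomes must be a named vector of lengths", "vgc_config")
  }
  if (pass_fraction < 0 || pass_fraction > 1 || missing_rate < 0 || missing_rate >= 1) {
    vgc_abort("pass_fraction must be in [0,1] and missing_rate in [0,1)", "vgc_config")
  }
  in_chrom <- function(chrom, pos) {
    L <- chromosomes[[as.character(chrom)]]
    !is.null(L) && pos >= 1 && pos <= L
  }
  for (s in planted_signals) {
    if (!in_chrom(s$chrom, s$pos)) {
      vgc_abort(sprintf("planted signal at %s:%d lies outside the declared chromosomes",
                        s$chrom, s$pos), "vgc_config")
    }
    if (s$case_freq < 0 || s$case_freq > 1 || s$control_freq < 0 || s$control_freq > 1) {
      vgc_abort("planted frequencies must be in [0,1]", "vgc_config")
    }
  }
  for (p in planted_pathogenic) {
    if (!in_chrom(p$chrom, p$pos)) {
      vgc_abort(sprintf("planted pathogenic locus %s:%d lies outside the declared chromosomes",
                        p$chrom, p$pos), "vgc_config")
    }
  }
  for (g in genes) {
    if (!in_chrom(g$chrom, g$start) || !in_chrom(g$chrom, g$end)) {
      vgc_abort(sprintf("gene %s lies outside the declared chromosomes", g$symbol),
                "vgc_config")
    }
  }
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 chromosomes = chromosomes, n_variants = as.integer(n_variants),
                 pass_fraction = pass_fraction, genes = genes,
                 planted_signals = planted_signals,
                 planted_pathogenic = planted_pathogenic,
                 missing_rate = missing_rate,
                 null_freq_range = null_freq_range),
            class = "vgc_sim_config")
}

BASES <- c("A", "C", "G", "T")

# Hardy-Weinberg genotype codes (0/1/2) for n samples at alt frequency p
hwe_codes <- function(n, p) {
  sample(c(GT_HOM_REF, GT_HET, GT_HOM_ALT), n, replace = TRUE,
         prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
}

#' Simulate a fully self-contained case-control cohort
#'
#' Writes, under `out_dir`: `cohort.vcf` (coordinate-sorted, contiguous
#' chromosome blocks), `phenotype.tsv`, `catalog.tsv` (gene models with exon
#' layouts), `clinvar.tsv` (pathogenic rows for the planted loci plus benign
#' decoys), `sets.gmt` (gene sets over the catalog symbols) and `truth.json`
#' (the manifest of every planted fact, so tests never re-derive ground truth
#' from the VCF). Genotypes are drawn per group under Hardy-Weinberg at the
#' locus's group alternate-allele frequency; non-planted loci share one
#' frequency across groups (the null).
#'
#' @param config A `vgc_sim_config`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of file paths (`vcf`, `phenotype`, `catalog`, `clinvar`,
#'   `gmt`, `truth`).
#' @export
vgc_simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "vgc_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                phenotype = file.path(out_dir, "phenotype.tsv"),
                catalog = file.path(out_dir, "catalog.tsv"),
                clinvar = file.path(out_dir, "clinvar.tsv"),
                gmt = file.path(out_dir, "sets.gmt"),
                truth = file.path(out_dir, "truth.json"))
  with_seed(config$seed, simulate_impl(config, paths))
  paths
}

simulate_impl <- function(config, paths) {
  n_cases <- config$n_cases
  n_controls <- config$n_controls
  samples <- c(sprintf("CASE%03d", seq_len(n_cases)),
               sprintf("CTRL%03d", seq_len(n_controls)))
  is_case <- c(rep(TRUE, n_cases), rep(FALSE, n_controls))
  n <- length(samples)

  chroms <- names(config$chromosomes)
  lens <- as.numeric(config$chromosomes)

  # background loci proportional to chromosome length, at least 1 per chrom
  alloc <- pmax(1L, round(config$n_variants * lens / sum(lens)))
  loci <- list()
  for (ci in seq_along(chroms)) {
    pos <- sort(sample.int(lens[ci], alloc[ci]))
    loci[[chroms[ci]]] <- data.frame(chrom = chroms[ci], pos = pos,
                                     stringsAsFactors = FALSE)
  }
  # in-gene loci
  for (g in config$genes) {
    ng <- as.integer(g$n_variants %||% 0L)
    if (ng > 0L) {
      pos <- sort(sample(seq.int(g$start, g$end), ng))
      loci[[g$chrom]] <- rbind(loci[[g$chrom]],
                               data.frame(chrom = g$chrom, pos = pos,
                                          stringsAsFactors = FALSE))
    }
  }
  # planted loci are forced into the locus set
  for (s in config$planted_signals) {
    loci[[as.character(s$chrom)]] <- rbind(
      loci[[as.character(s$chrom)]],
      data.frame(chrom = as.character(s$chrom), pos = s$pos,
                 stringsAsFactors = FALSE))
  }
  for (p in config$planted_pathogenic) {
    loci[[as.character(p$chrom)]] <- rbind(
      loci[[as.character(p$chrom)]],
      data.frame(chrom = as.character(p$chrom), pos = p$pos,
                 stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, loci[chroms])
  df <- df[!duplicated(paste(df$chrom, df$pos)), ]
  df <- df[order(match(df$chrom, chroms), df$pos), ]
  rownames(df) <- NULL
  nv <- nrow(df)

  # alleles and per-group frequencies
  df$ref <- sample(BASES, nv, replace = TRUE)
  df$alt <- vapply(df$ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  fr <- config$null_freq_range
  df$case_freq <- df$control_freq <- runif(nv, fr[1], fr[2])
  sig_keys <- vapply(config$planted_signals,
                     function(s) paste(s$chrom, s$pos), character(1))
  idx <- match(sig_keys, paste(df$chrom, df$pos))
  for (k in seq_along(idx)) {
    df$case_freq[idx[k]] <- config$planted_signals[[k]]$case_freq
    df$control_freq[idx[k]] <- config$planted_signals[[k]]$control_freq
  }
  df$filter <- ifelse(runif(nv) < config$pass_fraction, "PASS", "q10")
  df$qual <- sprintf("%.1f", runif(nv, 30, 90))

  # genotype matrix
  gt <- matrix("", nrow = nv, ncol = n)
  gt_txt <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nv)) {
    codes <- integer(n)
    codes[is_case] <- hwe_codes(n_cases, df$case_freq[i])
    codes[!is_case] <- hwe_codes(n_controls, df$control_freq[i])
    row <- gt_txt[codes + 1L]
    if (config$missing_rate > 0) {
      row[runif(n) < config$missing_rate] <- "./."
    }
    gt[i, ] <- row
  }

  # ---- VCF ----
  header <- c("##fileformat=VCFv4.2",
              "##source=vgccraft_simulate",
              sprintf("##contig=<ID=%s,length=%.0f>", chroms, lens),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(df$chrom, df$pos, ".", df$ref, df$alt, df$qual, df$filter,
                sprintf("NS=%d", n), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths$vcf, sep = "\n")

  # ---- phenotype ----
  writeLines(c("sample_id\tgroup",
               paste(samples, ifelse(is_case, "case", "control"), sep = "\t")),
             paths$phenotype, sep = "\n")

  # ---- catalog ----
  cat_lines <- "symbol\tchrom\tstart\tend\texons"
  for (g in config$genes) {
    ex <- ""
    if (!is.null(g$exons) && nrow(g$exons) > 0L) {
      ex <- paste(sprintf("%d-%d", g$exons[, 1], g$exons[, 2]), collapse = ";")
    }
    cat_lines <- c(cat_lines, sprintf("%s\t%s\t%d\t%d\t%s", g$symbol, g$chrom,
                                      as.integer(g$start), as.integer(g$end), ex))
  }
  writeLines(cat_lines, paths$catalog, sep = "\n")

  # ---- clinvar: pathogenic rows for planted loci, benign decoys elsewhere ----
  cv <- "chrom\tpos\tref\talt\tclinical_significance\tcondition\treview_status"
  path_keys <- vapply(config$planted_pathogenic,
                      function(p) paste(p$chrom, p$pos), character(1))
  pidx <- match(path_keys, paste(df$chrom, df$pos))
  for (i in pidx) {
    cv <- c(cv, sprintf("%s\t%d\t%s\t%s\tPathogenic\tsimulated condition\tcriteria provided",
                        df$chrom[i], df$pos[i], df$ref[i], df$alt[i]))
  }
  decoys <- setdiff(seq_len(min(nv, 3L)), pidx)
  for (i in decoys) {
    cv <- c(cv, sprintf("%s\t%d\t%s\t%s\tBenign\t\t",
                        df$chrom[i], df$pos[i], df$ref[i], df$alt[i]))
  }
  writeLines(cv, paths$clinvar, sep = "\n")

  # ---- gene sets ----
  symbols <- vapply(config$genes, `[[`, character(1), "symbol")
  if (length(symbols) == 0L) symbols <- "PLACEHOLDER"
  gmt <- c(paste(c("SIM_SET_ALL", "all simulated genes", symbols), collapse = "\t"),
           paste(c("SIM_SET_FIRST", "first simulated gene", symbols[1]), collapse = "\t"))
  writeLines(gmt, paths$gmt, sep = "\n")

  # ---- truth manifest ----
  truth <- list(
    seed = config$seed,
    n_cases = n_cases, n_controls = n_controls,
    samples = samples,
    chromosomes = as.list(config$chromosomes),
    n_variants = nv,
    per_chrom_variant_counts = as.list(table(factor(df$chrom, levels = chroms))),
    per_chrom_pass_counts = as.list(tapply(df$filter == "PASS",
                                           factor(df$chrom, levels = chroms), sum)),
    pass_fraction = config$pass_fraction,
    missing_rate = config$missing_rate,
    planted_signals = lapply(seq_along(config$planted_signals), function(k) {
      s <- config$planted_signals[[k]]
      i <- idx[k]
      list(chrom = as.character(s$chrom), pos = s$pos, ref = df$ref[i],
           alt = df$alt[i], case_freq = s$case_freq,
           control_freq = s$control_freq)
    }),
    planted_pathogenic = lapply(seq_along(config$planted_pathogenic), function(k) {
      i <- pidx[k]
      list(chrom = df$chrom[i], pos = df$pos[i], ref = df$ref[i],
           alt = df$alt[i], filter = df$filter[i])
    }))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}

#' The preeclampsia-shaped cohort preset
#'
#' A ready-made [vgc_sim_config()] matching the shape of the cohort the
#' package's views are designed around: 143 samples (61 cases, 82 term
#' controls), two chromosomes with exome-like clustering of variants inside
#' three muscle-gene-like models (including a TTN-sized gene on chromosome
#' 2), one planted association signal inside a TTN exon (case alt frequency
#' 0.8 vs control 0.05) and three planted pathogenic loci.
#'
#' @param seed Integer seed.
#' @return A `vgc_sim_config`.
#' @export
vgc_preset_preeclampsia_shape <- function(seed) {
  ttn <- list(symbol = "TTN", chrom = "2", start = 179390716L, end = 179695529L,
              exons = cbind(c(179392000L, 179420000L, 179500000L, 179600000L),
                            c(179398000L, 179460000L, 179560000L, 179650000L)),
              n_variants = 80L)
  actn2 <- list(symbol = "ACTN2", chrom = "1", start = 236849754L, end = 236927931L,
                exons = cbind(c(236850000L, 236880000L), c(236860000L, 236900000L)),
                n_variants = 40L)
  obscn <- list(symbol = "OBSCN", chrom = "1", start = 228395830L, end = 228566577L,
                exons = cbind(228400000L, 228500000L),
                n_variants = 40L)
  vgc_sim_config(
    seed = seed,
    n_cases = 61L, n_controls = 82L,
    chromosomes = c(`1` = 249250621L, `2` = 243199373L),
    n_variants = 240L,
    pass_fraction = 0.85,
    genes = list(ttn, actn2, obscn),
    planted_signals = list(list(chrom = "2", pos = 179425000L,
                                case_freq = 0.8, control_freq = 0.05)),
    planted_pathogenic = list(list(chrom = "2", pos = 179430000L),
                              list(chrom = "1", pos = 236855000L),
                              list(chrom = "1", pos = 100000L)),
    missing_rate = 0.02)
}
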