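# Fixture builders and independent oracles. Everything here is generated in
# code at test time; the oracles deliberately avoid the package's own code
# paths.

VCF_HEADER_COLS <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT")

# Write a small VCF from a data.frame of fixed columns plus a character
# matrix of per-sample GT fields. Returns the path.
write_mini_vcf <- function(df, gt, samples, path = tempfile(fileext = ".vcf"),
                           meta = "##fileformat=VCFv4.2") {
  stopifnot(nrow(df) == nrow(gt), ncol(gt) == length(samples))
  header <- c(meta, paste(c(VCF_HEADER_COLS, samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste(c(df$chrom[i], df$pos[i], df$id[i] %||% ".", df$ref[i], df$alt[i],
            df$qual[i] %||% "50", df$filter[i], df$info[i] %||% ".",
            df$format[i] %||% "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, sep = "\n")
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The standard 10-variant, 2-chromosome fixture from the module contracts:
# 6 variants on chr1, 4 on chr2, 7 PASS overall, 3 clinvar-pathogenic on chr1.
std_fixture <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  df <- data.frame(
    chrom = c(rep("1", 6), rep("2", 4)),
    pos = c(100L, 150L, 200L, 250L, 300L, 350L, 80L, 120L, 160L, 200L),
    ref = c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C"),
    alt = c("T", "G", "A", "C", "G", "T,A", "C", "A", "G", "T"),
    filter = c("PASS", "PASS", "q10", "PASS", "PASS", "q10", "PASS", "PASS",
               "q10", "PASS"),
    stringsAsFactors = FALSE)
  samples <- c("S1", "S2", "S3", "S4")
  gt <- matrix(c("0/0", "0/1", "1/1", "./.",
                 "0/1", "0/1", "0/0", "0/0",
                 "1/1", "0/0", "0/1", "0/1",
                 "0/0", "0/0", "0/0", "0/1",
                 "0|1", "1|1", "0|0", "0/1",
                 "1/2", "0/1", "0/0", "0/2",
                 "0/1", "0/0", "0/0", "0/0",
                 "0/0", "1/1", "0/1", "./.",
                 "0/1", "0/1", "0/1", "0/1",
                 "0/0", "0/0", "1/1", "0/1"),
               nrow = 10, byrow = TRUE)
  vcf <- write_mini_vcf(df, gt, samples, file.path(dir, "cohort.vcf"))
  clinvar <- file.path(dir, "clinvar.tsv")
  writeLines(c("chrom\tpos\tref\talt\tclinical_significance",
               "1\t100\tA\tT\tPathogenic",
               "chr1\t200\tG\tA\tLikely pathogenic",
               "1\t300\tA\tG\tPathogenic/Likely pathogenic",
               "1\t250\tT\tC\tBenign",
               "2\t120\tT\tA\tPathogenic"),
             clinvar, sep = "\n")
  pheno <- file.path(dir, "pheno.tsv")
  writeLines(c("sample_id\tgroup", "S1\tA", "S2\tA", "S3\tB", "S4\tB"),
             pheno, sep = "\n")
  catalog <- file.path(dir, "catalog.tsv")
  writeLines(c("symbol\tchrom\tstart\tend\texons",
               "GENEA\t1\t100\t300\t150-160;240-260",
               "GENEB\t2\t100\t180\t",
               "TTN\t2\t179390716\t179695529\t179392000-179398000"),
             catalog, sep = "\n")
  list(vcf = vcf, clinvar = clinvar, pheno = pheno, catalog = catalog,
       samples = samples, df = df, gt = gt)
}

# Random sorted VCF generator for property tests. Returns path plus the
# ground-truth data frame used by the full-scan oracle.
random_vcf <- function(seed, n_chroms = NULL, n_samples = NULL) {
  set.seed(seed)
  n_chroms <- n_chroms %||% sample(2:4, 1)
  n_samples <- n_samples %||% sample(3:8, 1)
  chroms <- as.character(seq_len(n_chroms))
  rows <- lapply(chroms, function(ch) {
    nv <- sample(3:15, 1)
    data.frame(chrom = ch, pos = sort(sample.int(10000L, nv)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  nv <- nrow(df)
  bases <- c("A", "C", "G", "T")
  df$ref <- sample(bases, nv, replace = TRUE)
  df$alt <- vapply(df$ref, function(r) sample(setdiff(bases, r), 1), character(1))
  df$filter <- sample(c("PASS", "q10", "lowQ"), nv, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1))
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), nv * n_samples,
                      replace = TRUE, prob = c(0.5, 0.3, 0.15, 0.05)),
               nrow = nv)
  samples <- sprintf("S%02d", seq_len(n_samples))
  # mark a random subset pathogenic in a side table
  n_path <- sample(0:min(4, nv), 1)
  path_idx <- sort(sample.int(nv, n_path))
  clinvar <- tempfile(fileext = ".tsv")
  cv_lines <- "chrom\tpos\tref\talt\tclinical_significance"
  if (n_path > 0) {
    cv_lines <- c(cv_lines, sprintf("%s\t%d\t%s\t%s\tPathogenic",
                                    df$chrom[path_idx], df$pos[path_idx],
                                    df$ref[path_idx], df$alt[path_idx]))
  }
  writeLines(cv_lines, clinvar, sep = "\n")
  list(vcf = write_mini_vcf(df, gt, samples), clinvar = clinvar, df = df,
       gt = gt, samples = samples, pathogenic_idx = path_idx)
}

# ---- independent full-scan oracle -----------------------------------------
# Recomputes per-chromosome index fields and range-query hits from a plain
# line scan, sharing no code with the package internals.
full_scan_oracle <- function(vcf_path, pathogenic_keys = character(0)) {
  lines <- readLines(vcf_path)
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  f <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  tab <- data.frame(
    line = data_idx,
    chrom = vapply(f, `[`, character(1), 1),
    pos = as.integer(vapply(f, `[`, character(1), 2)),
    ref = vapply(f, `[`, character(1), 4),
    alt = vapply(f, `[`, character(1), 5),
    filter = vapply(f, `[`, character(1), 7),
    stringsAsFactors = FALSE)
  tab$pathogenic <- vapply(seq_len(nrow(tab)), function(i) {
    alts <- strsplit(tab$alt[i], ",", fixed = TRUE)[[1]]
    any(paste(sub("^chr", "", tab$chrom[i]), tab$pos[i], tab$ref[i], alts,
              sep = ":") %in% pathogenic_keys)
  }, logical(1))
  tab
}

oracle_chrom_summary <- function(tab) {
  out <- do.call(rbind, lapply(unique(tab$chrom), function(ch) {
    s <- tab[tab$chrom == ch, ]
    data.frame(chrom = ch, start_line = min(s$line), end_line = max(s$line),
               start_pos = min(s$pos), end_pos = max(s$pos),
               pass_count = sum(s$filter == "PASS"),
               pathogenic_count = sum(s$pathogenic),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

oracle_range_query <- function(tab, chrom, start, end, filter = "ALL") {
  s <- tab[sub("^chr", "", tab$chrom) == sub("^chr", "", chrom) &
             tab$pos >= start & tab$pos <= end, ]
  if (filter == "PASS") s <- s[s$filter == "PASS", ]
  if (filter == "PATHOGENIC") s <- s[s$pathogenic, ]
  s
}

pathogenic_keys_from_tsv <- function(path) {
  d <- read.delim(path, colClasses = "character")
  lab <- tolower(d$clinical_significance)
  keep <- lab %in% c("pathogenic", "likely pathogenic",
                     "pathogenic/likely pathogenic")
  paste(sub("^chr", "", d$chrom[keep]), d$pos[keep], d$ref[keep], d$alt[keep],
        sep = ":")
}

# ---- independent Fisher oracles -------------------------------------------
# Brute force over ALL nonnegative integer tables (every cell enumerated via
# expand.grid, then filtered on the margins). Only viable for tiny N, which
# is the point: it shares no structure with the package's row-recursive
# enumeration.
brute_fisher_p <- function(m, tol = 1e-12) {
  R <- rowSums(m); C <- colSums(m)
  stopifnot(nrow(m) == 2)
  grid <- expand.grid(a = 0:min(R[1], C[1]), b = 0:min(R[1], C[2]),
                      c = 0:min(R[1], C[3]))
  grid <- grid[grid$a + grid$b + grid$c == R[1], ]
  # second row forced by the column margins
  d <- C[1] - grid$a; e <- C[2] - grid$b; f <- C[3] - grid$c
  ok <- d >= 0 & e >= 0 & f >= 0
  grid <- grid[ok, ]; d <- d[ok]; e <- e[ok]; f <- f[ok]
  logp <- function(a, b, c, d, e, f) {
    sum(lfactorial(R)) + sum(lfactorial(C)) - lfactorial(sum(m)) -
      (lfactorial(a) + lfactorial(b) + lfactorial(c) +
         lfactorial(d) + lfactorial(e) + lfactorial(f))
  }
  lps <- mapply(logp, grid$a, grid$b, grid$c, d, e, f)
  pobs <- exp(logp(m[1, 1], m[1, 2], m[1, 3], m[2, 1], m[2, 2], m[2, 3]))
  sum(exp(lps)[exp(lps) <= pobs + tol])
}

random_table <- function(seed, max_n = 60, g = 2) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(g * 3, lambda = sample(2:8, 1)), nrow = g)
    if (sum(m) <= max_n &&
        sum(rowSums(m) > 0) >= 2 && sum(colSums(m) > 0) >= 2) return(m)
  }
}
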