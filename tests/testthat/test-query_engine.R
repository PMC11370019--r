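test_that("range queries agree with the index and honour inclusive endpoints", {
  fx <- std_fixture()
  cv <- vgc_load_clinvar(fx$clinvar)
  idx <- vgc_build_index(fx$vcf, cv)

  all1 <- vgc_query_range(idx, fx$vcf, vgc_range("1", 1, 1e9))
  expect_equal(nrow(all1$variants),
               idx$entries$end_line[1] - idx$entries$start_line[1] + 1L)
  pass1 <- vgc_query_range(idx, fx$vcf, vgc_range("1", 1, 1e9), filter = "PASS")
  expect_equal(nrow(pass1$variants), idx$entries$pass_count[1])

  # inclusive on both sides
  r <- vgc_query_range(idx, fx$vcf, vgc_range("1", 150, 300))
  expect_equal(r$variants$pos, c(150L, 200L, 250L, 300L))

  # chromosome absent from the index: empty result, not an error
  none <- vgc_query_range(idx, fx$vcf, vgc_range("99", 1, 100))
  expect_equal(nrow(none$variants), 0L)
  expect_equal(ncol(none$gt), 4L)

  # chr dialect mismatch still matches
  chr <- vgc_query_range(idx, fx$vcf, vgc_range("chr1", 150, 300))
  expect_equal(chr$variants$pos, r$variants$pos)

  expect_error(vgc_query_range(NULL, fx$vcf, vgc_range("1", 1, 10)),
               class = "vgc_index_required")
  expect_error(vgc_query_range(idx, fx$vcf, vgc_range("1", 1, 10),
                               filter = "PATHOGENIC"),
               class = "vgc_annotation_required")
})

test_that("index-backed queries equal full scans and never leave the span", {
  for (seed in 11:20) {
    rv <- random_vcf(seed)
    cv <- vgc_load_clinvar(rv$clinvar)
    idx <- vgc_build_index(rv$vcf, cv)
    oracle_tab <- full_scan_oracle(rv$vcf, pathogenic_keys_from_tsv(rv$clinvar))
    set.seed(seed + 1000)
    for (k in 1:5) {
      chrom <- sample(unique(rv$df$chrom), 1)
      a <- sample.int(10000L, 1); b <- sample.int(10000L, 1)
      rng <- vgc_range(chrom, min(a, b), max(a, b))
      for (filt in c("ALL", "PASS", "PATHOGENIC")) {
        got <- vgc_query_range(idx, rv$vcf, rng, filter = filt, clinvar = cv)
        want <- oracle_range_query(oracle_tab, chrom, rng$start, rng$end, filt)
        expect_equal(got$variants$line, want$line,
                     info = sprintf("seed %d filter %s", seed, filt))
        # only lines inside this chromosome's span were parsed
        span <- idx$entries[idx$entries$chrom == chrom, ]
        expect_lte(got$lines_scanned, span$end_line - span$start_line + 1L)
        expect_lt(got$lines_scanned, idx$info$variant_count + 1L)
      }
      # filter containment
      va <- vgc_query_range(idx, rv$vcf, rng, "ALL", cv)$variants$line
      expect_true(all(vgc_query_range(idx, rv$vcf, rng, "PASS", cv)$variants$line
                      %in% va))
      expect_true(all(vgc_query_range(idx, rv$vcf, rng, "PATHOGENIC",
                                      cv)$variants$line %in% va))
    }
  }
})

test_that("gene queries add exon labels and handle unknown symbols", {
  fx <- std_fixture()
  idx <- vgc_build_index(fx$vcf)
  catalog <- vgc_load_catalog(fx$catalog, "GRCh37")

  res <- vgc_query_gene(idx, fx$vcf, catalog, "GENEA")
  expect_equal(res$variants$pos, c(100L, 150L, 200L, 250L, 300L))
  expect_equal(res$variants$region,
               c("INTRONIC", "EXONIC", "INTRONIC", "EXONIC", "INTRONIC"))
  expect_equal(res$spec$mode, "GENE")

  low <- vgc_query_gene(idx, fx$vcf, catalog, "genea")
  expect_equal(low$variants, res$variants)

  # gene span with no variants: empty, no error
  empty <- vgc_query_gene(idx, fx$vcf, catalog, "TTN")
  expect_equal(nrow(empty$variants), 0L)

  err <- expect_error(vgc_query_gene(idx, fx$vcf, catalog, "GENEZ"),
                      class = "vgc_unknown_gene")
  expect_match(conditionMessage(err), "GENEA|GENEB")
})

test_that("batch queries union, deduplicate and count per item", {
  fx <- std_fixture()
  cv <- vgc_load_clinvar(fx$clinvar)
  idx <- vgc_build_index(fx$vcf, cv)
  catalog <- vgc_load_catalog(fx$catalog, "GRCh37")

  batch <- tempfile()
  writeLines(c("# comment line", "GENEA", "1:100-200", "", "2:100-130"), batch)
  res <- vgc_query_batch(idx, fx$vcf, catalog, batch)
  expect_equal(unname(res$per_item_counts), c(5L, 3L, 1L))
  # union of GENEA (100..300) and the two ranges, deduplicated
  expect_equal(res$variants$pos, c(100L, 150L, 200L, 250L, 300L, 120L))
  expect_equal(anyDuplicated(res$variants$line), 0L)

  # batch equals the union of individual queries
  genea <- vgc_query_gene(idx, fx$vcf, catalog, "GENEA")$variants$line
  r1 <- vgc_query_range(idx, fx$vcf, vgc_range("1", 100, 200))$variants$line
  r2 <- vgc_query_range(idx, fx$vcf, vgc_range("2", 100, 130))$variants$line
  expect_equal(sort(res$variants$line), sort(unique(c(genea, r1, r2))))

  # duplicate items change nothing
  batch2 <- tempfile()
  writeLines(c("GENEA", "GENEA", "1:100-200", "1:100-200", "2:100-130"), batch2)
  res2 <- vgc_query_batch(idx, fx$vcf, catalog, batch2)
  expect_equal(res2$variants$line, res$variants$line)

  # unknown gene: warning + zero count, not fatal
  batch3 <- tempfile()
  writeLines(c("GENEA", "NOSUCHGENE"), batch3)
  expect_warning(res3 <- vgc_query_batch(idx, fx$vcf, catalog, batch3),
                 "NOSUCHGENE")
  expect_equal(unname(res3$per_item_counts["NOSUCHGENE"]), 0L)

  # unparseable line is fatal and names the line
  batch4 <- tempfile()
  writeLines(c("GENEA", "1:abc-200"), batch4)
  expect_error(vgc_query_batch(idx, fx$vcf, catalog, batch4),
               class = "vgc_parse")
})

test_that("analysis plans round-trip canonically", {
  spec <- vgc_query_spec("GENE", gene_symbol = "TTN", filter = "PASS",
                         assembly = "GRCh37")
  p1 <- tempfile(); p2 <- tempfile()
  vgc_save_plan(spec, p1)
  expect_equal(vgc_load_plan(p1), spec)

  vgc_save_plan(vgc_query_spec("GENE", gene_symbol = "TTN", filter = "PASS",
                               assembly = "GRCh37"), p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical

  spec2 <- vgc_query_spec("RANGE", range = vgc_range("chr2", 10, 20))
  vgc_save_plan(spec2, p1)
  expect_equal(vgc_load_plan(p1), spec2)
  spec3 <- vgc_query_spec("BATCH", batch_items = c("TTN", "1:1-10"))
  vgc_save_plan(spec3, p1)
  expect_equal(vgc_load_plan(p1), spec3)

  bad <- tempfile()
  writeLines(c("mode=GENE", "gene_symbol=TTN", "range=", "batch_items=",
               "filter=SOMETIMES", "assembly=GRCh38"), bad)
  expect_error(vgc_load_plan(bad), class = "vgc_parse")
  writeLines(c("mode=GENE", "gene_symbol=TTN"), bad)
  err <- expect_error(vgc_load_plan(bad), class = "vgc_parse")
  expect_match(conditionMessage(err), "range|batch_items|filter|assembly")
})
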