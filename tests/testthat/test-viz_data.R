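test_that("level-0 histogram mirrors the index without scanning", {
  fx <- std_fixture()
  cv <- vgc_load_clinvar(fx$clinvar)
  idx <- vgc_build_index(fx$vcf, cv)
  v <- vgc_histogram(idx, fx$vcf)
  expect_equal(v$bins$count, c(6L, 4L))
  expect_equal(v$level, 0L)
  expect_equal(vgc_histogram(idx, fx$vcf, "PASS")$bins$count,
               idx$entries$pass_count)
  expect_equal(vgc_histogram(idx, fx$vcf, "PATHOGENIC", cv)$bins$count,
               idx$entries$pathogenic_count)

  idx0 <- vgc_build_index(fx$vcf)
  expect_error(vgc_histogram(idx0, fx$vcf, "PATHOGENIC"),
               class = "vgc_annotation_required")
})

test_that("zoom splits ranges into 20 bins with a remainder-absorbing last bin", {
  edges <- vgccraft:::bin_edges(1001L, 3000L)    # width 2000
  expect_equal(nrow(edges), 20L)
  expect_true(all(edges[, 2] - edges[, 1] + 1L == 100L))
  expect_equal(edges[1, 1], 1001L)
  expect_equal(edges[20, 2], 3000L)

  ragged <- vgccraft:::bin_edges(1L, 2007L)      # width 2007: last bin wider
  expect_equal(nrow(ragged), 20L)
  expect_equal(ragged[20, 2] - ragged[20, 1] + 1L, 107L)
  expect_true(all(diff(ragged[, 1]) == 100L))

  tiny <- vgccraft:::bin_edges(10L, 16L)         # width 7: single positions
  expect_equal(nrow(tiny), 7L)
  expect_true(all(tiny[, 1] == tiny[, 2]))
  expect_equal(tiny[, 1], 10:16)
})

test_that("zoom conserves counts down to single positions and pops back", {
  fx <- std_fixture()
  cv <- vgc_load_clinvar(fx$clinvar)
  idx <- vgc_build_index(fx$vcf, cv)
  for (filt in c("ALL", "PASS")) {
    view <- vgc_histogram(idx, fx$vcf, filt, cv)
    level <- view
    repeat {
      bi <- which.max(level$bins$count)
      child <- vgc_zoom(level, bi)
      expect_equal(sum(child$bins$count), level$bins$count[bi],
                   info = sprintf("filter %s level %d", filt, level$level))
      expect_equal(child$level, level$level + 1L)
      # back-navigation restores the pre-zoom view
      expect_equal(vgc_zoom_back(child), level)
      if (all(child$bins$end == child$bins$start)) break
      level <- child
    }
  }
  v0 <- vgc_histogram(idx, fx$vcf)
  expect_error(vgc_zoom_back(v0), class = "vgc_parameter")
  expect_error(vgc_zoom(v0, 99L), class = "vgc_parameter")
  # zoom on an empty bin yields empty bins, no error
  deep <- vgc_zoom(v0, 1L)
  empty_bin <- which(deep$bins$count == 0L)[1]
  expect_equal(sum(vgc_zoom(deep, empty_bin)$bins$count), 0L)
})

test_that("hover reports range, count and single-position ClinVar detail", {
  fx <- std_fixture()
  cv <- vgc_load_clinvar(fx$clinvar)
  idx <- vgc_build_index(fx$vcf, cv)
  view <- vgc_histogram(idx, fx$vcf, "ALL", cv)
  h0 <- vgc_hover(view, 1L)
  expect_equal(h0$variant_count, 6L)
  expect_equal(h0$range, vgc_range("1", 100, 350))
  expect_null(h0$variants_at_position)  # width > 1

  # zoom to the planted pathogenic position 1:100
  single <- view
  repeat {
    bi <- which(single$bins$start <= 100 & single$bins$end >= 100)[1]
    if (single$bins$start[bi] == single$bins$end[bi]) break
    single <- vgc_zoom(single, bi)
  }
  h1 <- vgc_hover(single, bi)
  expect_equal(h1$range$start, 100L)
  expect_equal(h1$variant_count, 1L)
  expect_equal(h1$variants_at_position$significance, "Pathogenic")
  expect_equal(h1$variants_at_position$ref, "A")
})

test_that("node graph links carriers only and matches contingency tallies", {
  ids <- c("s1", "s2", "s3", "s4")
  df <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "T",
                   filter = "PASS", stringsAsFactors = FALSE)
  gt <- rbind(c("0/0", "0/1", "1/1", "./."),
              c("0/0", "0/0", "0/0", "0/0"))
  vcf <- write_mini_vcf(df, gt, ids)
  p <- tempfile(); writeLines(c("s1\tA", "s2\tA", "s3\tB", "s4\tB"), p)
  idx <- vgc_build_index(vcf)
  res <- vgc_query_range(idx, vcf, vgc_range("1", 1, 100))
  g <- vgc_load_phenotypes(p, ids)
  graph <- vgc_node_graph(res, g)
  expect_equal(nrow(graph$variant_nodes), 2L)
  expect_equal(nrow(graph$sample_nodes), 4L)
  expect_equal(nrow(graph$edges), 2L)
  expect_equal(graph$edges$genotype, c("HET", "HOM_ALT"))
  expect_equal(graph$edges$sample_id, c("s2", "s3"))
  # second variant is isolated (degree 0)
  expect_false(graph$variant_nodes$key[2] %in% graph$edges$variant_key)

  # edge count equals HET+HOM_ALT cells across contingency tables
  for (seed in 41:45) {
    rv <- random_vcf(seed, n_chroms = 2, n_samples = 6)
    ph <- tempfile()
    writeLines(paste(rv$samples, rep(c("case", "control"), length.out = 6),
                     sep = "\t"), ph)
    ridx <- vgc_build_index(rv$vcf)
    rres <- vgc_query_range(ridx, rv$vcf, vgc_range("1", 1, 1e9))
    rg <- vgc_load_phenotypes(ph, rv$samples)
    rgraph <- vgc_node_graph(rres, rg)
    tally <- sum(vapply(seq_len(nrow(rres$variants)), function(i) {
      tab <- vgccraft:::contingency_from_codes(rres$gt[i, ], rg, rv$samples)
      sum(tab$counts[, c("HET", "HOM_ALT")])
    }, numeric(1)))
    expect_equal(nrow(rgraph$edges), tally, info = sprintf("seed %d", seed))
    # sample-node degree = its non-reference genotype count
    deg <- table(factor(rgraph$edges$sample_id, levels = rv$samples))
    gmat <- vgc_genotype_matrix(rres)
    expect_equal(as.integer(deg),
                 as.integer(colSums(gmat == 1L | gmat == 2L)))
  }
})

test_that("genotype matrix projects codes in variant and sample order", {
  fx <- std_fixture()
  idx <- vgc_build_index(fx$vcf)
  res <- vgc_query_range(idx, fx$vcf, vgc_range("1", 100, 150))
  m <- vgc_genotype_matrix(res)
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(unname(m[1, ]), c(0L, 1L, 2L, -1L))  # 0/0 0/1 1/1 ./.
  expect_equal(colnames(m), fx$samples)
  expect_equal(rownames(m)[1], "1:100:A:T")

  none <- vgc_query_range(idx, fx$vcf, vgc_range("1", 1, 2))
  m0 <- vgc_genotype_matrix(none)
  expect_equal(dim(m0), c(0L, 4L))
})

test_that("histogram and node-graph JSON round-trip through jsonlite", {
  fx <- std_fixture()
  idx <- vgc_build_index(fx$vcf)
  view <- vgc_histogram(idx, fx$vcf)
  path <- tempfile(fileext = ".json")
  vgc_histogram_json(view, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$bins$count, view$bins$count)
  expect_equal(parsed$level, 0L)

  res <- vgc_query_range(idx, fx$vcf, vgc_range("1", 1, 1e9))
  g <- vgc_load_phenotypes(fx$pheno, res$sample_ids)
  gr <- vgc_node_graph(res, g)
  j <- jsonlite::parse_json(vgc_node_graph_json(gr), simplifyVector = TRUE)
  expect_equal(nrow(j$edges), nrow(gr$edges))
})
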