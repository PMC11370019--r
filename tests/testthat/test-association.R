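test_that("phenotype loading restricts to VCF samples and validates", {
  fx <- std_fixture()
  ids <- c("S1", "S2", "S3", "S4")
  g <- vgc_load_phenotypes(fx$pheno, ids)
  expect_equal(g$group_order, c("A", "B"))
  expect_equal(unname(g$assignment[ids]), c("A", "A", "B", "B"))
  expect_equal(g$unassigned, character(0))

  p <- tempfile()
  writeLines(c("S1\tcase", "S2\tcase", "S9\tcontrol"), p)  # headerless + unknown
  expect_warning(g2 <- vgc_load_phenotypes(p, ids), "not present")
  expect_equal(g2$n_unknown, 1L)
  expect_equal(sort(g2$unassigned), c("S3", "S4"))

  writeLines(c("S1\tcase", "S1\tcase", "S2\tcontrol"), p)  # dup, same group
  expect_equal(length(vgc_load_phenotypes(p, ids)$assignment), 2L)

  writeLines(c("S1\tcase", "S1\tcontrol"), p)
  expect_error(vgc_load_phenotypes(p, ids), class = "vgc_conflict")

  writeLines(c("X1\tcase", "X2\tcontrol"), p)
  expect_warning(expect_error(vgc_load_phenotypes(p, ids),
                              class = "vgc_no_overlap"))
})

test_that("contingency tables tally genotype classes and exclude missing", {
  ids <- c("s1", "s2", "s3", "s4")
  p <- tempfile()
  writeLines(c("s1\tA", "s2\tA", "s3\tB", "s4\tB"), p)
  g <- vgc_load_phenotypes(p, ids)
  line <- paste(c("1", "100", ".", "A", "T", "50", "PASS", ".", "GT",
                  "0/0", "0/1", "1/1", "./."), collapse = "\t")
  v <- vgc_parse_data_line(line, 4)
  tab <- vgc_build_contingency(v, g, ids)
  expect_equal(unname(tab$counts), rbind(c(1L, 1L, 0L), c(0L, 0L, 1L)))
  expect_equal(tab$n_missing_excluded, 1L)
  expect_equal(tab$n_total, 3L)

  # all-missing variant: zero table, test is degenerate downstream
  allmiss <- vgc_parse_data_line(
    paste(c("1", "100", ".", "A", "T", "50", "PASS", ".", "GT",
            "./.", "./.", "./.", "./."), collapse = "\t"), 4)
  tab0 <- vgc_build_contingency(allmiss, g, ids)
  expect_equal(sum(tab0$counts), 0L)
  expect_equal(tab0$n_missing_excluded, 4L)
  expect_error(vgc_fisher_mc(tab0, seed = 1), class = "vgc_degenerate")

  one <- tempfile(); writeLines(c("s1\tA", "s2\tA"), one)
  expect_error(vgc_build_contingency(v, vgc_load_phenotypes(one, ids), ids),
               class = "vgc_insufficient_groups")

  # recount oracle on random genotype vectors
  set.seed(99)
  for (k in 1:20) {
    codes <- sample(c(-1L, 0L, 1L, 2L), 4, replace = TRUE)
    t2 <- vgccraft:::contingency_from_codes(codes, g, ids)
    expect_equal(t2$n_total + t2$n_missing_excluded, 4L)
    expect_equal(sum(t2$counts), sum(codes != -1L))
  }
})

test_that("exact enumeration matches closed forms and independent oracles", {
  # two-table margin case: both tables have probability 1/2
  f <- vgc_fisher_exact(rbind(c(1L, 0L, 0L), c(0L, 1L, 0L)))
  expect_equal(f$p_exact, 1.0)
  expect_equal(f$observed_table_probability, 0.5)

  # one row all zeros: unique table given margins
  expect_equal(vgc_fisher_exact(rbind(c(3L, 2L, 1L), c(0L, 0L, 0L)))$p_exact, 1.0)
  expect_equal(vgc_fisher_exact(rbind(c(5L, 0L, 0L), c(2L, 0L, 0L)))$p_exact, 1.0)

  # brute-force oracle over every nonnegative table with the same margins
  m <- rbind(c(8L, 2L, 0L), c(1L, 5L, 4L))
  expect_equal(vgc_fisher_exact(m)$p_exact, brute_fisher_p(m), tolerance = 1e-12)
  for (seed in 1:15) {
    m2 <- random_table(seed, max_n = 14)
    expect_equal(vgc_fisher_exact(m2)$p_exact, brute_fisher_p(m2),
                 tolerance = 1e-10, info = sprintf("seed %d", seed))
  }
  # second independent oracle: stats::fisher.test
  for (seed in 16:30) {
    m3 <- random_table(seed, max_n = 40)
    expect_equal(vgc_fisher_exact(m3)$p_exact,
                 stats::fisher.test(m3)$p.value,
                 tolerance = 1e-6, info = sprintf("seed %d", seed))
  }
})

test_that("enumeration probabilities are a distribution and p is permutation-invariant", {
  for (seed in 31:40) {
    m <- random_table(seed, max_n = 30)
    lp <- vgccraft:::enumerate_logp(rowSums(m), colSums(m))
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-9)
    p <- vgc_fisher_exact(m)$p_exact
    expect_equal(vgc_fisher_exact(m[2:1, ])$p_exact, p, tolerance = 1e-12)
    expect_equal(vgc_fisher_exact(m[, 3:1])$p_exact, p, tolerance = 1e-12)
  }
  # budget gate
  big <- rbind(c(300L, 200L, 100L), c(100L, 200L, 300L))
  expect_error(vgc_fisher_exact(big, budget = 500L),
               class = "vgc_budget_exceeded")
})

test_that("Monte Carlo p-values are deterministic, floored and null-symmetric", {
  m <- rbind(c(5L, 5L, 5L), c(5L, 5L, 5L))
  f1 <- vgc_fisher_mc(m, iterations = 2000, seed = 7)
  f2 <- vgc_fisher_mc(m, iterations = 2000, seed = 7)
  expect_identical(f1$p_mc, f2$p_mc)
  expect_gte(f1$p_mc, 0.9)  # identical rows: nothing is more extreme
  expect_gte(vgc_fisher_mc(rbind(c(9L, 0L, 0L), c(0L, 9L, 0L)),
                           iterations = 200, seed = 1)$p_mc, 1 / 201)
  expect_error(vgc_fisher_mc(m, iterations = 0, seed = 1),
               class = "vgc_parameter")
})

test_that("sampled tables follow the enumerated fixed-margin distribution", {
  # chi-square goodness of fit of 1e5 sampled table probabilities against the
  # exact enumeration, collapsed by probability value
  m <- rbind(c(4L, 3L, 1L), c(2L, 2L, 4L))
  lp_all <- vgccraft:::enumerate_logp(rowSums(m), colSums(m))
  lp_draw <- vgccraft:::with_seed(123, vgccraft:::sample_tables_logp(m, 1e5))
  br <- sort(unique(round(lp_all, 9)))
  obs <- table(factor(round(lp_draw, 9), levels = br))
  prob <- vapply(br, function(v) sum(exp(lp_all)[round(lp_all, 9) == v]),
                 numeric(1))
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs), p = prob,
                                            rescale.p = TRUE))
  expect_gt(gof$p.value, 0.001)
})

test_that("per-variant association is reproducible and flags degenerates", {
  fx <- std_fixture()
  idx <- vgc_build_index(fx$vcf)
  res <- vgc_query_range(idx, fx$vcf, vgc_range("1", 1, 1e9))
  g <- vgc_load_phenotypes(fx$pheno, res$sample_ids)
  a1 <- vgc_association(res, g, iterations = 500, seed = 3, exact = TRUE)
  a2 <- vgc_association(res, g, iterations = 500, seed = 3, exact = TRUE)
  expect_identical(a1$p_mc, a2$p_mc)
  expect_equal(nrow(a1), nrow(res$variants))
  expect_equal(a1$seed, 3L + seq_len(nrow(a1)))
  # variant 4 is nearly monomorphic (one HET in group B): still a valid table;
  # check p ranges and agreement between MC and exact where both exist
  both <- !is.na(a1$p_mc) & !is.na(a1$p_exact)
  expect_true(any(both))
  expect_true(all(abs(a1$p_mc[both] - a1$p_exact[both]) <
                    3 * sqrt(a1$p_exact[both] * (1 - a1$p_exact[both]) / 500) + 0.01))

  # monomorphic variant: p absent with reason "degenerate"
  df <- data.frame(chrom = "1", pos = 10L, ref = "A", alt = "T",
                   filter = "PASS", stringsAsFactors = FALSE)
  mono <- write_mini_vcf(df, matrix("0/0", 1, 4), c("s1", "s2", "s3", "s4"))
  p <- tempfile(); writeLines(c("s1\tA", "s2\tA", "s3\tB", "s4\tB"), p)
  midx <- vgc_build_index(mono)
  mres <- vgc_query_range(midx, mono, vgc_range("1", 1, 100))
  ma <- vgc_association(mres, vgc_load_phenotypes(p, mres$sample_ids), seed = 1)
  expect_true(is.na(ma$p_mc[1]))
  expect_equal(ma$reason[1], "degenerate")
})
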