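# Tie tolerance on table probabilities: a sampled/enumerated table counts as
# "at least as extreme" as the observed one when P(T) <= P(obs) + TIE_TOL.
TIE_TOL <- 1e-12

#' Load sample group assignments from a phenotype file
#'
#' The phenotype file is a two-column TSV (`sample_id`, `group`); a header
#' row is optional and detected by name. Assignments are restricted to the
#' samples present in the VCF: samples in the VCF but absent from the file
#' are collected as `unassigned` (excluded from contingency tables), samples
#' in the file but not in the VCF are ignored with a warning.
#'
#' @param path Phenotype TSV path.
#' @param sample_ids Sample IDs of the owning VCF, in VCF column order.
#' @return A `vgc_phenotypes`: list with `assignment` (named character
#'   vector, names are sample IDs), `group_order` (labels in order of first
#'   appearance), `unassigned` and `n_unknown` (file rows not in the VCF).
#' @export
vgc_load_phenotypes <- function(path, sample_ids) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 2L) {
    vgc_abort(sprintf("phenotype file %s needs two tab-separated columns", path),
              "vgc_parse")
  }
  sid <- dt[[1]]; grp <- dt[[2]]
  if (tolower(sid[1]) %in% c("sample", "sample_id", "id", "iid") &&
      tolower(grp[1]) %in% c("group", "phenotype", "status", "label")) {
    sid <- sid[-1]; grp <- grp[-1]
  }
  # same sample listed twice: identical group is deduplicated, different is fatal
  for (s in unique(sid[duplicated(sid)])) {
    gs <- unique(grp[sid == s])
    if (length(gs) > 1L) {
      vgc_abort(sprintf("sample '%s' assigned to conflicting groups: %s",
                        s, paste(gs, collapse = ", ")), "vgc_conflict")
    }
  }
  first <- !duplicated(sid)
  sid <- sid[first]; grp <- grp[first]
  unknown <- !(sid %in% sample_ids)
  if (any(unknown)) {
    warning(sprintf("phenotype file lists %d sample(s) not present in the VCF; ignored",
                    sum(unknown)))
  }
  sid2 <- sid[!unknown]; grp2 <- grp[!unknown]
  if (length(sid2) == 0L) {
    vgc_abort("phenotype file has no overlap with the VCF samples", "vgc_no_overlap")
  }
  structure(list(assignment = setNames(grp2, sid2),
                 group_order = unique(grp2),
                 unassigned = setdiff(sample_ids, sid2),
                 n_unknown = sum(unknown)),
            class = "vgc_phenotypes")
}

new_contingency <- function(counts, n_missing_excluded) {
  structure(list(counts = counts,
                 n_total = sum(counts),
                 n_missing_excluded = as.integer(n_missing_excluded)),
            class = "vgc_contingency")
}

# internal: g x 3 table from a vector of genotype class codes
contingency_from_codes <- function(codes, groups, sample_ids) {
  if (length(groups$group_order) < 2L) {
    vgc_abort("at least two phenotype groups are required for association testing",
              "vgc_insufficient_groups")
  }
  stopifnot(length(codes) == length(sample_ids))
  counts <- matrix(0L, nrow = length(groups$group_order), ncol = 3L,
                   dimnames = list(groups$group_order, GT_LABELS))
  grp <- groups$assignment[sample_ids]       # NA for unassigned samples
  assigned <- !is.na(grp)
  missing <- assigned & codes == GT_MISSING
  use <- assigned & !missing
  if (any(use)) {
    tab <- table(factor(grp[use], levels = groups$group_order),
                 factor(codes[use], levels = c(GT_HOM_REF, GT_HET, GT_HOM_ALT)))
    counts[] <- as.integer(tab)
  }
  new_contingency(counts, sum(missing))
}

#' Build the group-by-genotype contingency table for one variant
#'
#' Rows are the phenotype groups (in `group_order`), columns the genotype
#' classes HOM_REF / HET / HOM_ALT. Samples with a MISSING genotype or
#' without a group assignment are excluded; missing exclusions are tallied in
#' `n_missing_excluded`.
#'
#' @param variant A `vgc_variant` (from [vgc_parse_data_line()]).
#' @param groups A `vgc_phenotypes`.
#' @param sample_ids Sample IDs aligned with the variant's genotypes.
#' @return A `vgc_contingency`.
#' @export
vgc_build_contingency <- function(variant, groups, sample_ids) {
  stopifnot(inherits(variant, "vgc_variant"))
  contingency_from_codes(variant$gt_codes, groups, sample_ids)
}

as_counts_matrix <- function(table) {
  if (inherits(table, "vgc_contingency")) return(table$counts)
  if (is.matrix(table)) return(table)
  vgc_abort("expected a vgc_contingency or a count matrix", "vgc_parameter")
}

# drop all-zero rows and columns; they carry no probability mass
reduce_table <- function(m) {
  m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
}

# log probability of a fixed-margin table under the hypergeometric null:
# P(T) = (prod_i R_i!)(prod_j C_j!) / (N! prod_ij n_ij!)
logp_table <- function(m) {
  sum(lfactorial(rowSums(m))) + sum(lfactorial(colSums(m))) -
    lfactorial(sum(m)) - sum(lfactorial(m))
}

tie_threshold <- function(lobs) {
  pobs <- exp(lobs)
  if (pobs > 0) log(pobs + TIE_TOL) else log(TIE_TOL)
}

# all compositions of `total` into length(bounds) parts with 0 <= x_j <= bounds_j
compositions <- function(total, bounds) {
  k <- length(bounds)
  if (k == 1L) {
    if (total <= bounds[1]) return(matrix(total, 1, 1))
    return(matrix(integer(0), 0, 1))
  }
  lo <- max(0L, total - sum(bounds[-1]))
  hi <- min(bounds[1], total)
  if (lo > hi) return(matrix(integer(0), 0, k))
  do.call(rbind, lapply(lo:hi, function(x) {
    rest <- compositions(total - x, bounds[-1])
    if (nrow(rest) == 0L) return(matrix(integer(0), 0, k))
    cbind(x, rest, deparse.level = 0)
  }))
}

# log probabilities of every table with row margins R and column margins C
enumerate_logp <- function(R, C) {
  K <- sum(lfactorial(R)) + sum(lfactorial(C)) - lfactorial(sum(R))
  rec <- function(i, rem) {
    if (i == length(R)) {
      return(sum(lfactorial(rem)))  # last row is fully determined
    }
    rows <- compositions(R[i], rem)
    unlist(lapply(seq_len(nrow(rows)), function(r) {
      sum(lfactorial(rows[r, ])) + rec(i + 1L, rem - rows[r, ])
    }))
  }
  K - rec(1L, C)
}

new_fisher <- function(p_exact = NULL, p_mc = NULL, mc_iterations = 0L,
                       mc_seed = NA_integer_, obs_prob = 1) {
  structure(list(p_exact = p_exact, p_mc = p_mc,
                 mc_iterations = as.integer(mc_iterations),
                 mc_seed = mc_seed,
                 observed_table_probability = obs_prob),
            class = "vgc_fisher")
}

#' Fisher's exact test by complete enumeration
#'
#' Enumerates every g x 3 (more generally g x k) table sharing the observed
#' row and column margins and sums the null probabilities of all tables no
#' more probable than the observed one (two-sided, probability ordering;
#' ties within an additive `1e-12` tolerance on probabilities count as
#' extreme). All factorials are handled in log space. Zero rows/columns are
#' removed first; a table whose margins admit a single configuration has
#' `p_exact = 1`.
#'
#' @param table A `vgc_contingency` or a plain count matrix.
#' @param budget Maximum table total N for enumeration (default 500); larger
#'   tables raise `vgc_budget_exceeded` and should use [vgc_fisher_mc()].
#' @return A `vgc_fisher` with `p_exact` and `observed_table_probability`
#'   filled.
#' @export
vgc_fisher_exact <- function(table, budget = 500L) {
  m <- reduce_table(as_counts_matrix(table))
  if (sum(m) == 0L) {
    vgc_abort("contingency table is empty (all genotypes missing?)",
              "vgc_degenerate")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    # margins admit exactly one table
    return(new_fisher(p_exact = 1, obs_prob = 1))
  }
  if (sum(m) > budget) {
    vgc_abort(sprintf(
      "table total %d exceeds the enumeration budget (%d); use vgc_fisher_mc()",
      sum(m), budget), "vgc_budget_exceeded")
  }
  lobs <- logp_table(m)
  lp <- enumerate_logp(rowSums(m), colSums(m))
  thr <- tie_threshold(lobs)
  p <- sum(exp(lp[lp <= thr]))
  new_fisher(p_exact = min(1, p), obs_prob = exp(lobs))
}

#' Fisher's exact test by Monte Carlo simulation
#'
#' Draws `iterations` tables uniformly from the fixed-margin hypergeometric
#' null (sequential multivariate hypergeometric fill, row by row, vectorised
#' over iterations) and estimates the two-sided p as `(1 + k) / (B + 1)`
#' where `k` counts sampled tables no more probable than the observed one.
#' The estimator never returns 0 and is deterministic for a fixed seed.
#'
#' @param table A `vgc_contingency` or a plain count matrix with at least two
#'   non-zero rows and columns after reduction.
#' @param iterations Number of simulated tables (default 2000).
#' @param seed Integer seed (required, recorded in the result).
#' @return A `vgc_fisher` with `p_mc`, `mc_iterations`, `mc_seed` and
#'   `observed_table_probability` filled.
#' @export
vgc_fisher_mc <- function(table, iterations = 2000L, seed) {
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1) {
    vgc_abort("iterations must be a positive integer", "vgc_parameter")
  }
  iterations <- as.integer(iterations)
  m <- reduce_table(as_counts_matrix(table))
  if (nrow(m) < 2L || ncol(m) < 2L) {
    vgc_abort(
      "table is degenerate after removing zero margins; the test is undefined",
      "vgc_degenerate")
  }
  lobs <- logp_table(m)
  thr <- tie_threshold(lobs)
  lp <- with_seed(seed, sample_tables_logp(m, iterations))
  kcount <- sum(lp <= thr)
  new_fisher(p_mc = (1 + kcount) / (iterations + 1), mc_iterations = iterations,
             mc_seed = as.integer(seed), obs_prob = exp(lobs))
}

# Draw B tables from the fixed-margin hypergeometric null by sequential
# multivariate hypergeometric fill (row by row, vectorised over draws) and
# return their log probabilities. Uses the current RNG state.
sample_tables_logp <- function(m, B) {
  R <- rowSums(m); C <- colSums(m)
  g <- nrow(m); k <- ncol(m)
  K <- sum(lfactorial(R)) + sum(lfactorial(C)) - lfactorial(sum(m))
  rem <- matrix(rep(as.integer(C), each = B), nrow = B)
  lfsum <- numeric(B)
  for (i in seq_len(g - 1L)) {
    left <- rep(R[i], B)
    for (j in seq_len(k - 1L)) {
      restcols <- rowSums(rem[, (j + 1L):k, drop = FALSE])
      x <- rhyper(B, m = rem[, j], n = restcols, k = left)
      lfsum <- lfsum + lfactorial(x)
      rem[, j] <- rem[, j] - x
      left <- left - x
    }
    lfsum <- lfsum + lfactorial(left)     # last column takes the remainder
    rem[, k] <- rem[, k] - left
  }
  lfsum <- lfsum + rowSums(lfactorial(rem))  # last row is the remainder
  K - lfsum
}

#' Per-variant genotype-phenotype association over a query result
#'
#' For each variant in the result, builds the group-by-genotype contingency
#' table and computes the Monte Carlo Fisher p-value (and optionally the
#' exact enumeration p when the table total is within `budget`). Each variant
#' uses the derived seed `seed + ordinal` so the full table is reproducible
#' from one seed. Degenerate tables (monomorphic variants, all-missing
#' genotypes) yield `NA` p-values with `reason = "degenerate"` rather than an
#' error.
#'
#' @param result A `vgc_query_result`.
#' @param groups A `vgc_phenotypes` with at least two groups.
#' @param iterations Monte Carlo iterations per variant (default 2000).
#' @param seed Base integer seed.
#' @param exact Also compute `p_exact` where the budget allows.
#' @param budget Enumeration budget for `exact`.
#' @return A data.frame of class `vgc_association`: chrom, pos, ref, alt, one
#'   count column per (group x genotype class), `n_missing`, `p_mc`,
#'   `p_exact` (NA unless `exact`), `seed` and `reason`.
#' @export
vgc_association <- function(result, groups, iterations = 2000L, seed = 1L,
                            exact = FALSE, budget = 500L) {
  stopifnot(inherits(result, "vgc_query_result"),
            inherits(groups, "vgc_phenotypes"))
  if (length(groups$group_order) < 2L) {
    vgc_abort("at least two phenotype groups are required", "vgc_insufficient_groups")
  }
  nv <- nrow(result$variants)
  gl <- groups$group_order
  count_cols <- as.vector(t(outer(gl, GT_LABELS, paste, sep = ".")))
  counts <- matrix(NA_integer_, nrow = nv, ncol = length(count_cols),
                   dimnames = list(NULL, count_cols))
  n_missing <- integer(nv)
  p_mc <- rep(NA_real_, nv)
  p_exact <- rep(NA_real_, nv)
  seeds <- as.integer(seed) + seq_len(nv)
  reason <- rep(NA_character_, nv)
  tables <- vector("list", nv)
  for (i in seq_len(nv)) {
    tab <- contingency_from_codes(result$gt[i, ], groups, result$sample_ids)
    tables[[i]] <- tab
    counts[i, ] <- as.vector(t(tab$counts))
    n_missing[i] <- tab$n_missing_excluded
    red <- reduce_table(tab$counts)
    if (nrow(red) < 2L || ncol(red) < 2L) {
      reason[i] <- "degenerate"
      next
    }
    p_mc[i] <- vgc_fisher_mc(tab, iterations = iterations, seed = seeds[i])$p_mc
    if (exact && tab$n_total <= budget) {
      p_exact[i] <- vgc_fisher_exact(tab, budget = budget)$p_exact
    }
  }
  out <- data.frame(chrom = result$variants$chrom, pos = result$variants$pos,
                    ref = result$variants$ref, alt = result$variants$alt,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts))
  out$n_missing <- n_missing
  out$p_mc <- p_mc
  out$p_exact <- p_exact
  out$seed <- seeds
  out$reason <- reason
  attr(out, "tables") <- tables
  attr(out, "iterations") <- as.integer(iterations)
  class(out) <- c("vgc_association", "data.frame")
  out
}

#' @export
print.vgc_contingency <- function(x, ...) {
  print(x$counts)
  cat(sprintf("n = %d, missing excluded = %d\n", x$n_total, x$n_missing_excluded))
  invisible(x)
}

#' @export
print.vgc_fisher <- function(x, ...) {
  if (!is.null(x$p_exact)) cat(sprintf("p_exact = %.6g\n", x$p_exact))
  if (!is.null(x$p_mc)) cat(sprintf("p_mc = %.6g (%d iterations, seed %d)\n",
                                    x$p_mc, x$mc_iterations, x$mc_seed))
  invisible(x)
}
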