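test_that("promoter binding needs a same-strand cross-link in the TSS window", {
  g <- toy_genes(1000, 2500, "+")[1, ]
  at_tss10 <- tibble::tibble(chrom = "chrI", start = 1010L, end = 1011L,
                             strand = "+")
  expect_true(assign_promoter_binding(g, at_tss10)$bound)
  expect_false(assign_promoter_binding(g, dplyr::mutate(at_tss10,
                                                        strand = "-"))$bound)
  # window edges: [-250, +300) around the TSS
  edge_in <- dplyr::mutate(at_tss10, start = 1000L - 250L, end = 1000L - 249L)
  edge_out <- dplyr::mutate(at_tss10, start = 1000L + 300L, end = 1000L + 301L)
  expect_true(assign_promoter_binding(g, edge_in)$bound)
  expect_false(assign_promoter_binding(g, edge_out)$bound)
  expect_error(assign_promoter_binding(g, at_tss10, window_up = -1), ">= 0")
})

test_that("promoter binding matches a brute-force overlap oracle", {
  for (seed in 1:50) {
    set.seed(seed)
    genes <- random_genes(20, chrom_len = 20000L)
    xl_pos <- sample.int(20000L, 100, replace = TRUE) - 1L
    xl <- tibble::tibble(chrom = "chrI", start = xl_pos, end = xl_pos + 1L,
                         strand = sample(c("+", "-"), 100, replace = TRUE))
    got <- assign_promoter_binding(genes, xl)

    want <- vapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      lo <- if (g$strand == "+") g$tss - 250 else g$tss - 299
      hi <- if (g$strand == "+") g$tss + 300 else g$tss + 251
      any(xl$strand == g$strand & xl$start < hi & xl$end > max(lo, 0))
    }, logical(1))
    expect_equal(got$bound, want, info = paste("seed", seed))
  }
})

test_that("expression normalization divides rows and drops zero-expression genes", {
  m <- matrix(c(2, 4, 6, 1, 1, 1, 5, 5, 5), nrow = 3, byrow = TRUE)
  rownames(m) <- c("a", "b", "c")
  expr <- tibble::tibble(gene_id = c("a", "b", "c"),
                         expression = c(2, 0, 10))
  expect_message(out <- normalize_by_expression(m, expr), "zero expression")
  expect_equal(rownames(out), c("a", "c"))
  expect_equal(out["a", ], c(1, 2, 3))
  expect_equal(out["c", ], c(0.5, 0.5, 0.5))

  expect_error(normalize_by_expression(m, expr[1:2, ]), "missing")

  # random matrix equals the elementwise oracle
  set.seed(17)
  r <- matrix(runif(50 * 20), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  e <- tibble::tibble(gene_id = rownames(r),
                      expression = runif(50, 0.5, 4))
  got <- normalize_by_expression(r, e)
  want <- r / e$expression[match(rownames(r), e$gene_id)]
  expect_equal(unclass(got)[1:50, ], want, ignore_attr = TRUE)
})

test_that("expression matching finds exact twins and never reuses controls", {
  expr <- tibble::tibble(
    gene_id = c(sprintf("b%d", 1:5), sprintf("c%d", 1:5), sprintf("x%d", 1:5)),
    expression = c(1:5, 1:5, 100 + 1:5)
  )
  m <- match_expression_controls(sprintf("b%d", 1:5),
                                 c(sprintf("c%d", 1:5), sprintf("x%d", 1:5)),
                                 expr)
  expect_setequal(m$controls, sprintf("c%d", 1:5))
  expect_equal(m$ks_post, 0)
  expect_false(any(duplicated(m$controls)))
  expect_length(intersect(m$controls, sprintf("b%d", 1:5)), 0)

  # |bound| = 1: nearest log-expression neighbour wins
  one <- match_expression_controls("b3", c("c1", "c2", "c4", "c5", "x1"), expr)
  expect_true(one$controls %in% c("c2", "c4"))

  expect_error(match_expression_controls(c("b1", "b2"), "c1", expr),
               "smaller")
  expect_error(match_expression_controls("b1", c("b1", "c1"), expr),
               "disjoint")
})

test_that("matching shrinks the KS distance on log-normal expressions", {
  set.seed(31)
  n_bound <- 200; n_pool <- 2000
  expr <- tibble::tibble(
    gene_id = c(sprintf("b%03d", 1:n_bound), sprintf("p%04d", 1:n_pool)),
    expression = c(rlnorm(n_bound, meanlog = 1, sdlog = 0.6),
                   rlnorm(n_pool, meanlog = 0, sdlog = 0.8))
  )
  m <- match_expression_controls(sprintf("b%03d", 1:n_bound),
                                 sprintf("p%04d", 1:n_pool), expr)
  # oracle recomputation of both KS distances
  lb <- log10(expr$expression[1:n_bound] + 1e-3)
  lp <- log10(expr$expression[-(1:n_bound)] + 1e-3)
  lc <- log10(expr$expression[match(m$controls, expr$gene_id)] + 1e-3)
  expect_equal(m$ks_pre, unname(stats::ks.test(lb, lp)$statistic))
  expect_equal(m$ks_post, unname(stats::ks.test(lb, lc)$statistic))
  expect_lte(m$ks_post, m$ks_pre)
})

test_that("breadth comparison measures width at a fraction of the maximum", {
  # noiseless rectangles: widths 100 vs 300
  rect <- function(width, n = 12) {
    m <- matrix(0, nrow = n, ncol = 500)
    m[, 50 + seq_len(width)] <- 2
    rownames(m) <- sprintf("g%02d_%d", seq_len(n), width)
    m
  }
  bt <- compare_pausing_breadth(rect(100), rect(300), window = 500,
                                level = 0.25)
  expect_equal(unique(bt$breadth_a), 100)
  expect_equal(unique(bt$breadth_b), 300)
  expect_false(bt$degenerate)

  # identical constant groups are degenerate with p = 1
  same <- compare_pausing_breadth(rect(100), rect(100))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  # identical heterogeneous groups: p ~ 1 by symmetry
  set.seed(41)
  het <- matrix(rpois(40 * 500, 1), nrow = 40) +
    rect(200, 40)[, 1:500] * rep(runif(40, 0.5, 2), 500)
  rownames(het) <- sprintf("h%02d", 1:40)
  sym <- compare_pausing_breadth(het, het)
  expect_gt(sym$p_value, 0.9)

  # all-zero rows are excluded; an empty group errors
  zero <- matrix(0, nrow = 3, ncol = 500,
                 dimnames = list(c("z1", "z2", "z3"), NULL))
  expect_error(compare_pausing_breadth(zero, rect(100)), "empty")
})

test_that("breadth comparison detects planted 100 vs 200 base widths", {
  set.seed(55)
  planted <- function(width, n = 200) {
    base <- matrix(rpois(n * 500, 1), nrow = n)
    peak <- matrix(0, nrow = n, ncol = 500)
    peak[, seq_len(width)] <- 6
    m <- base + matrix(rpois(n * 500, peak), nrow = n)
    rownames(m) <- sprintf("g%03d_%d", seq_len(n), width)
    m
  }
  a <- planted(100)
  b <- planted(200)
  bt <- compare_pausing_breadth(a, b)
  expect_lt(bt$p_value, 0.01)

  # symmetry: swapping groups keeps the p-value
  sw <- compare_pausing_breadth(b, a)
  expect_equal(sw$p_value, bt$p_value)
  expect_equal(sort(c(sw$breadth_a, sw$breadth_b)),
               sort(c(bt$breadth_a, bt$breadth_b)))
  g <- glance(bt)
  expect_lt(g$median_a, g$median_b)
})

test_that("cross-link BED round-trip preserves intervals and strands", {
  xl <- tibble::tibble(chrom = "chrI", start = c(10L, 99L), end = c(11L, 120L),
                       strand = c("+", "-"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_crosslinks(xl, bed)
  back <- read_crosslinks(bed)
  expect_equal(back, xl)
})
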