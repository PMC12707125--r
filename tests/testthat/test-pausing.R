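# Independent oracle: slice the raw per-base array directly and divide means.
oracle_pi <- function(vec, promoter_len, mode) {
  len <- length(vec)
  body_to <- if (mode == "netseq") len - promoter_len else len
  prom <- mean(vec[1:promoter_len])
  body <- mean(vec[(promoter_len + 1):body_to])
  list(prom = prom, body = body,
       pi = if (body > 0) prom / body else NA_real_)
}

test_that("pausing index is a density ratio: uniform coverage gives exactly 1", {
  g <- toy_genes(1000, 3000, "+")[1, ]
  pair <- toy_pair(rep(4.2, 5000))
  rec <- pausing_index(g, pair, "netseq")
  expect_identical(rec$pausing_index, 1)
  expect_identical(pausing_index(g, pair, "proseq")$pausing_index, 1)

  # promoter mean 4, body mean 2 -> PI = 2
  vals <- numeric(5000)
  vals[1001:1300] <- 4
  vals[1301:3000] <- 2
  expect_equal(pausing_index(g, toy_pair(vals), "proseq")$pausing_index, 2)
})

test_that("pausing index matches the slice-and-mean oracle on random coverage", {
  set.seed(13)
  for (strand in c("+", "-")) {
    g <- toy_genes(500, 2500, strand)[1, ]
    raw <- as.numeric(rpois(2000, 1.3))
    genome <- numeric(4000)
    genome[501:2500] <- if (strand == "+") raw else rev(raw)
    pair <- if (strand == "+") toy_pair(genome) else
      toy_pair(numeric(4000), genome)
    for (mode in c("netseq", "proseq")) {
      want <- oracle_pi(raw, 300, mode)
      rec <- pausing_index(g, pair, mode)
      expect_equal(rec$pausing_index, want$pi, tolerance = 1e-12)
      expect_equal(rec$promoter_density, want$prom, tolerance = 1e-12)
      expect_equal(rec$body_density, want$body, tolerance = 1e-12)
    }
  }
})

test_that("pausing index is invariant to global scaling; body_sum is not", {
  set.seed(3)
  g <- toy_genes(0, 2000, "+")[1, ]
  raw <- as.numeric(rpois(2000, 0.8))
  rec1 <- pausing_index(g, toy_pair(raw), "netseq")
  rec7 <- pausing_index(g, toy_pair(7 * raw), "netseq")
  expect_equal(rec7$pausing_index, rec1$pausing_index)
  expect_equal(rec7$body_sum, 7 * rec1$body_sum)
})

test_that("undefined PI (zero body) is NA, and short genes are a distinct error", {
  g <- toy_genes(0, 1000, "+")[1, ]
  vals <- numeric(1500)
  vals[1:300] <- 5   # promoter signal only
  rec <- pausing_index(g, toy_pair(vals), "proseq")
  expect_true(is.na(rec$pausing_index))
  expect_equal(rec$promoter_density, 5)

  short <- toy_genes(0, 550, "+")[1, ]
  expect_error(pausing_index(short, toy_pair(vals), "netseq"), "too short")
  expect_error(pausing_index(short, toy_pair(vals), "proseq", promoter_len = 600),
               "too short")
})

test_that("eligibility applies strict length and signal thresholds per sample", {
  mk_records <- function(body_sums, ids = "g1") {
    tidyr::crossing(gene_id = ids, sample_id = paste0("s", 1:4)) |>
      dplyr::mutate(body_sum = body_sums, pausing_index = 1)
  }
  genes901 <- toy_genes(0, 901, "+", ids = "g1")
  expect_true(eligible_genes(mk_records(rep(10.5, 4)), genes901,
                             "netseq")$eligible)
  expect_false(eligible_genes(mk_records(c(10.5, 10.5, 10, 10.5)), genes901,
                              "netseq")$eligible)
  genes900 <- toy_genes(0, 900, "+", ids = "g1")
  expect_false(eligible_genes(mk_records(rep(100, 4)), genes900,
                              "netseq")$eligible)
  genes601 <- toy_genes(0, 601, "+", ids = "g1")
  expect_true(eligible_genes(mk_records(rep(0.1, 4)), genes601,
                             "proseq")$eligible)
  expect_false(eligible_genes(mk_records(rep(0, 4)), genes601,
                              "proseq")$eligible)
  # a missing sample record is an error, not a silent FALSE
  rec <- mk_records(rep(20, 4))[-1, ]
  expect_error(eligible_genes(rec, genes901, "netseq",
                              sample_ids = paste0("s", 1:4)),
               "missing sample")
})

ptab <- function(ref_pis, mut_pis) {
  n <- length(ref_pis)
  tibble::tibble(
    gene_id = "g1",
    condition = rep(c("wt", "mut"), each = n),
    replicate = rep(seq_len(n), 2),
    pausing_index = c(ref_pis, mut_pis)
  )
}

test_that("differential calls follow the consistency-plus-threshold rule", {
  d <- classify_differential(ptab(c(1.0, 1.2), c(1.8, 1.9)), "wt", "mut")
  expect_equal(d$delta_rep1, 0.8)
  expect_equal(d$delta_rep2, 0.7)
  expect_equal(d$mean_delta, 0.75)
  expect_equal(as.character(d$label), "increased")

  expect_equal(as.character(
    classify_differential(ptab(c(1, 2), c(1, 2)), "wt", "mut")$label),
    "unchanged")
  # inconsistent trend is unchanged regardless of the mean
  expect_equal(as.character(
    classify_differential(ptab(c(1, 2), c(1.9, 1.9)), "wt", "mut")$label),
    "unchanged")
  # consistent trend but mean below 0.5 is unchanged
  expect_equal(as.character(
    classify_differential(ptab(c(1, 1), c(1.3, 1.4)), "wt", "mut")$label),
    "unchanged")
  # undefined PI anywhere excludes the gene
  expect_equal(as.character(
    classify_differential(ptab(c(1, NA), c(2, 2)), "wt", "mut")$label),
    "excluded")

  # per-replicate variant demands the threshold in every replicate
  tb <- ptab(c(1, 1), c(1.4, 2.0))
  expect_equal(as.character(
    classify_differential(tb, "wt", "mut")$label), "increased")
  expect_equal(as.character(
    classify_differential(tb, "wt", "mut", per_replicate = TRUE)$label),
    "unchanged")

  bad <- dplyr::filter(ptab(c(1, 1), c(2, 2)),
                       !(condition == "mut" & replicate == 2))
  expect_error(classify_differential(bad, "wt", "mut"), "replicate sets")
})

test_that("classification is antisymmetric under condition swap", {
  set.seed(21)
  n <- 200
  tb <- tibble::tibble(
    gene_id = rep(sprintf("g%03d", 1:n), times = 4),
    condition = rep(c("wt", "wt", "mut", "mut"), each = n),
    replicate = rep(c(1L, 2L, 1L, 2L), each = n),
    pausing_index = c(runif(2 * n, 0, 3), runif(2 * n, 0, 3))
  )
  fwd <- classify_differential(tb, "wt", "mut")
  rev <- classify_differential(tb, "mut", "wt")
  map <- c(increased = "decreased", decreased = "increased",
           unchanged = "unchanged", excluded = "excluded")
  expect_equal(as.character(rev$label),
               unname(map[as.character(fwd$label)]))
  expect_equal(rev$mean_delta, -fwd$mean_delta)
})

test_that("quantile split gives near-equal ordered groups with id tie-breaks", {
  tb8 <- tibble::tibble(gene_id = sprintf("g%d", 1:8), condition = "wt",
                        replicate = 1L, pausing_index = 1:8)
  q <- pausing_quantiles(tb8, k = 4)
  expect_equal(as.character(q$quantile[match(sprintf("g%d", 1:8), q$gene_id)]),
               rep(paste0("Q", 1:4), each = 2))

  ties <- dplyr::mutate(tb8, pausing_index = 5)
  qt <- pausing_quantiles(ties, k = 4)
  expect_true(all(table(qt$quantile) == 2))
  # ties broken lexicographically: g1 sorts before g2
  expect_equal(as.character(qt$quantile[qt$gene_id == "g1"]), "Q1")

  set.seed(9)
  big <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000), condition = "wt",
                        replicate = 1L, pausing_index = runif(1000, 0, 10))
  qb <- pausing_quantiles(big, k = 4)
  expect_true(all(table(qb$quantile) == 250))
  rng <- dplyr::summarise(dplyr::group_by(
    dplyr::left_join(qb, big, by = "gene_id"), quantile),
    lo = min(pausing_index), hi = max(pausing_index))
  expect_true(all(diff(rng$lo) > 0) && all(rng$hi[-4] <= rng$lo[-1]))

  expect_error(pausing_quantiles(tb8[1:3, ], k = 4), "fewer genes")
  expect_error(pausing_quantiles(dplyr::mutate(tb8, pausing_index = NA_real_),
                                 k = 4), "defined")
})

test_that("tidy and glance summarise differential calls", {
  d <- classify_differential(ptab(c(1, 1), c(2, 2)), "wt", "mut")
  expect_s3_class(tidy(d), "tbl_df")
  g <- glance(d)
  expect_equal(g$n_increased, 1)
  expect_equal(g$min_delta, 0.5)
})
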