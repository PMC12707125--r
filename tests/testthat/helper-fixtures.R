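# Shared in-code fixtures: tiny gene tables, dense toy tracks, and random
# worlds used across the module tests.

toy_genes <- function(starts, ends, strands, chrom = "chrI",
                      ids = sprintf("t%02d", seq_along(starts)),
                      biotype = "protein_coding") {
  add_gene_anchors(tibble::tibble(
    gene_id = ids, chrom = chrom,
    start = as.integer(starts), end = as.integer(ends),
    strand = strands, biotype = biotype
  ))
}

# A track pair whose two strands hold the given dense vectors.
toy_pair <- function(plus_vals, minus_vals = NULL, chrom = "chrI",
                     sample_id = "s1", condition = "wt", replicate = 1L) {
  if (is.null(minus_vals)) minus_vals <- numeric(length(plus_vals))
  track_pair(
    coverage_track(stats::setNames(list(plus_vals), chrom), "+"),
    coverage_track(stats::setNames(list(minus_vals), chrom), "-"),
    sample_id, condition, replicate
  )
}

# Random genes scattered on a chromosome, allowed to overlap (for
# brute-force filter comparisons).
random_genes <- function(n, chrom_len = 50000L, len_range = c(200L, 1500L)) {
  starts <- sample.int(chrom_len - len_range[2], n, replace = TRUE)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  toy_genes(starts, starts + lens,
            sample(c("+", "-"), n, replace = TRUE),
            ids = sprintf("r%03d", seq_len(n)))
}

# Independent brute-force oracle for the isolation filter: O(n^2) loop over
# all pairs, testing overlap of the two flank windows with any other
# same-strand unit.
brute_isolated <- function(genes, all_units, flank) {
  ok <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    wins <- list(c(max(g$start - flank, 0), g$start),
                 c(g$end, g$end + flank))
    clash <- FALSE
    for (j in seq_len(nrow(all_units))) {
      u <- all_units[j, ]
      same_record <- u$gene_id == g$gene_id && u$start == g$start &&
        u$end == g$end && u$chrom == g$chrom
      if (same_record || u$strand != g$strand || u$chrom != g$chrom) next
      for (w in wins) {
        if (w[1] < w[2] && u$start < w[2] && u$end > w[1]) clash <- TRUE
      }
    }
    ok[i] <- !clash
  }
  genes[ok, , drop = FALSE]
}
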