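#' Pausing index of one gene in one sample
#'
#' The pausing index (PI) is the ratio of the mean per-base signal in the
#' promoter window (first `promoter_len` bases downstream of the TSS, in
#' transcription direction) to the mean per-base signal in the gene body. The
#' body depends on the assay mode: for NET-seq-style data it runs from
#' `TSS + promoter_len` to `PAS - promoter_len`; for PRO-seq-style data it
#' runs from `TSS + promoter_len` to the PAS. Both terms are densities, so PI
#' is unitless, equals 1 on uniform coverage, and is invariant to global
#' scaling and gene length. When the body density is zero the PI is undefined
#' (`NA`), never 0 or infinity.
#'
#' @param gene One-row gene tibble (see [load_gene_models()]).
#' @param pair A [track_pair()].
#' @param mode `"netseq"` (body `[promoter_len, length - promoter_len)`) or
#'   `"proseq"` (body `[promoter_len, length)`).
#' @param promoter_len Promoter window width in bases (default 300).
#' @param numerator `"density"` (default; mean per-base promoter signal) or
#'   `"sum"` (total promoter signal, the literal signal/density reading).
#' @return One-row tibble: `gene_id`, `sample_id`, `promoter_density`,
#'   `body_density`, `body_sum`, `pausing_index` (`NA` when undefined).
#' @export
pausing_index <- function(gene, pair, mode = c("netseq", "proseq"),
                          promoter_len = 300L,
                          numerator = c("density", "sum")) {
  mode <- match.arg(mode)
  numerator <- match.arg(numerator)
  len <- gene$end - gene$start
  min_len <- if (mode == "netseq") 2L * promoter_len else promoter_len
  if (len <= min_len) {
    stop(sprintf("gene %s (length %d) too short for mode %s with promoter_len %d",
                 gene$gene_id, len, mode, promoter_len), call. = FALSE)
  }
  body_to <- if (mode == "netseq") len - promoter_len else len
  prof <- oriented_profile(pair, gene, upstream = 0L, downstream = len)
  prom <- prof[seq_len(promoter_len)]
  body <- prof[(promoter_len + 1):body_to]
  promoter_density <- mean(prom)
  body_density <- mean(body)
  body_sum <- sum(body)
  num <- if (numerator == "density") promoter_density else sum(prom)
  tibble::tibble(
    gene_id = gene$gene_id,
    sample_id = pair$sample_id,
    promoter_density = promoter_density,
    body_density = body_density,
    body_sum = body_sum,
    pausing_index = if (body_density > 0) num / body_density else NA_real_
  )
}

#' Pausing indices for all genes across all samples
#'
#' Applies [pausing_index()] to every gene x sample combination and attaches
#' the sample's condition and replicate.
#'
#' @param genes Gene tibble; every gene must satisfy the mode's length
#'   precondition.
#' @param pairs List of [track_pair()] objects.
#' @inheritParams pausing_index
#' @return Tibble with one row per gene x sample: `gene_id`, `sample_id`,
#'   `condition`, `replicate`, `promoter_density`, `body_density`,
#'   `body_sum`, `pausing_index`.
#' @export
pausing_table <- function(genes, pairs, mode = c("netseq", "proseq"),
                          promoter_len = 300L,
                          numerator = c("density", "sum")) {
  mode <- match.arg(mode)
  numerator <- match.arg(numerator)
  purrr::map_dfr(pairs, function(pair) {
    recs <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      pausing_index(genes[i, ], pair, mode, promoter_len, numerator)
    })
    recs$condition <- pair$condition
    recs$replicate <- pair$replicate
    recs
  })
}

#' Per-gene eligibility under the mode's length and signal rules
#'
#' NET-seq mode keeps genes longer than `min_len` (default 900 bp) with body
#' signal strictly greater than `min_body_signal` (default 10) in *every*
#' sample; PRO-seq mode keeps genes longer than 600 bp with any body signal
#' (> 0) in every sample. All thresholds are strict inequalities.
#'
#' @param records Pausing table from [pausing_table()], covering every sample
#'   entering the analysis.
#' @param genes Gene tibble (for lengths).
#' @param mode `"netseq"` or `"proseq"`.
#' @param min_len,min_body_signal Override the mode defaults.
#' @param sample_ids The samples every gene must have a record for; defaults
#'   to the sample ids present in `records`.
#' @return Tibble `gene_id`, `eligible`.
#' @export
eligible_genes <- function(records, genes, mode = c("netseq", "proseq"),
                           min_len = NULL, min_body_signal = NULL,
                           sample_ids = unique(records$sample_id)) {
  mode <- match.arg(mode)
  if (is.null(min_len)) min_len <- if (mode == "netseq") 900 else 600
  if (is.null(min_body_signal)) {
    min_body_signal <- if (mode == "netseq") 10 else 0
  }
  if (!all(records$sample_id %in% sample_ids)) {
    stop("records contain sample ids outside `sample_ids`", call. = FALSE)
  }
  n_samples <- length(sample_ids)
  per_gene <- dplyr::summarise(
    dplyr::group_by(records, .data$gene_id),
    n_rec = dplyr::n(),
    min_body_sum = min(.data$body_sum),
    .groups = "drop"
  )
  if (any(per_gene$n_rec != n_samples)) {
    stop("missing sample record(s) for gene(s): ",
         paste(per_gene$gene_id[per_gene$n_rec != n_samples], collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::left_join(
    dplyr::select(genes, "gene_id", "length"), per_gene, by = "gene_id"
  )
  if (anyNA(out$min_body_sum)) {
    stop("missing sample record(s) for gene(s): ",
         paste(out$gene_id[is.na(out$min_body_sum)], collapse = ", "),
         call. = FALSE)
  }
  dplyr::transmute(
    out, .data$gene_id,
    eligible = .data$length > min_len & .data$min_body_sum > min_body_signal
  )
}

#' Classify differential pausing between two conditions
#'
#' For each gene, replicate `i` of the mutant condition is paired with
#' replicate `i` of the reference and the per-replicate difference
#' `dPI_i = PI_mut,i - PI_ref,i` is computed. A gene is labelled
#' `increased` when every `dPI_i > 0` and the mean difference is at least
#' `min_delta`; `decreased` symmetrically; otherwise `unchanged`. Genes with
#' any undefined PI are labelled `excluded`. With `per_replicate = TRUE` the
#' `min_delta` threshold must instead hold in every replicate individually.
#'
#' @param records Pausing table with columns `gene_id`, `condition`,
#'   `replicate`, `pausing_index`.
#' @param ref,mut Condition labels for reference and mutant.
#' @param min_delta Minimum pausing-index difference (default 0.5).
#' @param per_replicate Apply `min_delta` per replicate instead of to the
#'   mean.
#' @return Tibble of class `pausing_diff`: `gene_id`, `delta_rep<i>` columns,
#'   `mean_delta` (`NA` for excluded genes), `label` (factor with levels
#'   increased, decreased, unchanged, excluded).
#' @export
classify_differential <- function(records, ref, mut, min_delta = 0.5,
                                  per_replicate = FALSE) {
  stopifnot(all(c(ref, mut) %in% records$condition))
  sub <- dplyr::filter(records, .data$condition %in% c(ref, mut))
  reps_ref <- sort(unique(sub$replicate[sub$condition == ref]))
  reps_mut <- sort(unique(sub$replicate[sub$condition == mut]))
  if (!identical(reps_ref, reps_mut)) {
    stop("replicate sets differ between conditions (",
         paste(reps_ref, collapse = ","), " vs ",
         paste(reps_mut, collapse = ","), ")", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(sub, "gene_id", "condition", "replicate", "pausing_index"),
    names_from = c("condition", "replicate"), values_from = "pausing_index"
  )
  delta <- purrr::map(reps_ref, function(r) {
    wide[[paste(mut, r, sep = "_")]] - wide[[paste(ref, r, sep = "_")]]
  })
  dmat <- do.call(cbind, delta)
  n_ok <- rowSums(!is.na(dmat))
  mean_delta <- rowMeans(dmat)
  all_pos <- rowSums(dmat > 0, na.rm = TRUE) == ncol(dmat)
  all_neg <- rowSums(dmat < 0, na.rm = TRUE) == ncol(dmat)
  inc <- all_pos & if (per_replicate) {
    rowSums(dmat >= min_delta, na.rm = TRUE) == ncol(dmat)
  } else {
    mean_delta >= min_delta
  }
  dec <- all_neg & if (per_replicate) {
    rowSums(dmat <= -min_delta, na.rm = TRUE) == ncol(dmat)
  } else {
    mean_delta <= -min_delta
  }
  label <- dplyr::case_when(
    n_ok < ncol(dmat) ~ "excluded",
    inc ~ "increased",
    dec ~ "decreased",
    .default = "unchanged"
  )
  out <- tibble::tibble(gene_id = wide$gene_id)
  for (j in seq_along(reps_ref)) {
    out[[paste0("delta_rep", reps_ref[j])]] <- dmat[, j]
  }
  out$mean_delta <- ifelse(label == "excluded", NA_real_, mean_delta)
  out$label <- factor(label,
                      levels = c("increased", "decreased", "unchanged",
                                 "excluded"))
  class(out) <- c("pausing_diff", class(out))
  attr(out, "ref") <- ref
  attr(out, "mut") <- mut
  attr(out, "min_delta") <- min_delta
  out
}

#' Split genes into pausing-index quantile groups
#'
#' Genes are ranked by their mean pausing index across replicates of one
#' condition (the reference, by convention) and split into `k` groups of
#' near-equal size (sizes differ by at most 1). Ties are broken by
#' lexicographic `gene_id`. `Q1` holds the lowest pausing indices.
#'
#' @param records Pausing table restricted to the ranking condition (rows for
#'   other conditions may be removed with the `condition` argument).
#' @param k Number of groups (default 4).
#' @param condition Optional condition label to subset `records` first.
#' @return Tibble `gene_id`, `mean_pi`, `quantile` (factor `Q1`..`Qk`).
#' @export
pausing_quantiles <- function(records, k = 4L, condition = NULL) {
  if (!is.null(condition)) {
    records <- dplyr::filter(records, .data$condition == !!condition)
  }
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  per_gene <- dplyr::summarise(
    dplyr::group_by(records, .data$gene_id),
    mean_pi = mean(.data$pausing_index), .groups = "drop"
  )
  if (anyNA(per_gene$mean_pi)) {
    stop("all genes must have a defined pausing index", call. = FALSE)
  }
  n <- nrow(per_gene)
  if (n < k) stop("fewer genes (", n, ") than quantile groups (", k, ")",
                  call. = FALSE)
  ord <- order(per_gene$mean_pi, per_gene$gene_id)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  grp <- ceiling(rank * k / n)
  dplyr::mutate(per_gene,
                quantile = factor(paste0("Q", grp),
                                  levels = paste0("Q", seq_len(k))))
}
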