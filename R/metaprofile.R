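new_meta_profile_matrix <- function(values, gene_ids, mode, bin_size,
                                    upstream, downstream, body_bins = NULL,
                                    anchor = "tss", dropped = character()) {
  rownames(values) <- gene_ids
  structure(values,
            gene_ids = gene_ids, mode = mode, bin_size = bin_size,
            upstream = upstream, downstream = downstream,
            body_bins = body_bins, anchor = anchor, dropped = dropped,
            class = c("meta_profile_matrix", "matrix", "array"))
}

#' @export
print.meta_profile_matrix <- function(x, ...) {
  cat("<meta_profile_matrix>", attr(x, "mode"), "| genes:", nrow(x),
      "| bins:", ncol(x), "| anchor:", attr(x, "anchor"),
      sprintf("| flanks -%d/+%d @ %d bp", attr(x, "upstream"),
              attr(x, "downstream"), attr(x, "bin_size")))
  if (!is.null(attr(x, "body_bins"))) {
    cat(" | body bins:", attr(x, "body_bins"))
  }
  cat("\n")
  invisible(x)
}

bin_means <- function(v, bin_size) {
  colMeans(matrix(v, nrow = bin_size))
}

#' Reference-point metaprofile matrix
#'
#' One row per gene: the oriented per-base signal in the window
#' `[-upstream, downstream)` around the anchor, averaged within consecutive
#' non-overlapping bins of `bin_size` bases. Genes whose window leaves the
#' chromosome are dropped (their ids are kept in the `dropped` attribute and
#' reported with a message).
#'
#' @param genes Gene tibble.
#' @param pair A [track_pair()].
#' @param anchor `"tss"` or `"pas"`.
#' @param upstream,downstream Window extents in bases (defaults 250/750).
#' @param bin_size Bin width in bases; must divide `upstream + downstream`.
#' @return A `meta_profile_matrix` (genes x bins).
#' @export
reference_point_matrix <- function(genes, pair, anchor = c("tss", "pas"),
                                   upstream = 250L, downstream = 750L,
                                   bin_size = 10L) {
  anchor <- match.arg(anchor)
  if ((upstream + downstream) %% bin_size != 0) {
    stop("bin_size must divide upstream + downstream", call. = FALSE)
  }
  rows <- vector("list", nrow(genes))
  ok <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    prof <- tryCatch(
      oriented_profile(pair, genes[i, ], upstream, downstream, anchor),
      error = function(e) NULL
    )
    if (!is.null(prof)) {
      rows[[i]] <- bin_means(prof, bin_size)
      ok[i] <- TRUE
    }
  }
  dropped <- genes$gene_id[!ok]
  if (length(dropped) > 0) {
    message(length(dropped), " gene(s) dropped (window outside chromosome)")
  }
  new_meta_profile_matrix(
    do.call(rbind, rows[ok]), genes$gene_id[ok], "reference_point",
    bin_size, upstream, downstream, anchor = anchor, dropped = dropped
  )
}

#' Scaled-gene-body metaprofile matrix
#'
#' Flanks upstream of the TSS and downstream of the PAS are binned as in
#' [reference_point_matrix()]; the gene body (TSS to PAS, i.e. the whole
#' annotated unit) is partitioned into `body_bins` equal-length fractional
#' segments, each bin's value being the overlap-weighted mean of the per-base
#' signal it covers. A constant signal therefore stays constant under
#' scaling, and bin value times genomic bin width (`length / body_bins`)
#' sums exactly to the raw body signal. Genes shorter than `body_bins` bases
#' or whose flanks leave the chromosome are dropped (logged).
#'
#' @param genes Gene tibble.
#' @param pair A [track_pair()].
#' @param upstream,downstream Flank widths in bases (defaults 250/250).
#' @param body_bins Number of body segments (default 100).
#' @param bin_size Flank bin width; must divide both flanks.
#' @return A `meta_profile_matrix` with `upstream/bin_size + body_bins +
#'   downstream/bin_size` columns.
#' @export
scale_regions_matrix <- function(genes, pair, upstream = 250L,
                                 downstream = 250L, body_bins = 100L,
                                 bin_size = 10L) {
  if (upstream %% bin_size != 0 || downstream %% bin_size != 0) {
    stop("bin_size must divide both flank widths", call. = FALSE)
  }
  rows <- vector("list", nrow(genes))
  ok <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$end - g$start
    if (len < body_bins) next
    prof <- tryCatch(
      oriented_profile(pair, g, upstream, len + downstream, anchor = "tss"),
      error = function(e) NULL
    )
    if (is.null(prof)) next
    up_part <- if (upstream > 0) {
      bin_means(prof[seq_len(upstream)], bin_size)
    } else numeric(0)
    body <- prof[(upstream + 1):(upstream + len)]
    down_part <- if (downstream > 0) {
      bin_means(prof[(upstream + len + 1):(upstream + len + downstream)],
                bin_size)
    } else numeric(0)
    rows[[i]] <- c(up_part, scale_body(body, body_bins), down_part)
    ok[i] <- TRUE
  }
  dropped <- genes$gene_id[!ok]
  if (length(dropped) > 0) {
    message(length(dropped),
            " gene(s) dropped (too short or window outside chromosome)")
  }
  new_meta_profile_matrix(
    do.call(rbind, rows[ok]), genes$gene_id[ok], "scale_regions",
    bin_size, upstream, downstream, body_bins = body_bins,
    anchor = "tss", dropped = dropped
  )
}

# Overlap-weighted mean of x over body_bins equal fractional segments.
# Uses the continuous cumulative signal S(t) = integral of the step function,
# so fractional bases contribute proportionally to the overlap.
scale_body <- function(x, body_bins) {
  len <- length(x)
  cs <- c(0, cumsum(x))
  S <- function(t) {
    f <- floor(t)
    frac <- t - f
    cs[f + 1] + ifelse(f < len, frac * x[pmin(f, len - 1) + 1], 0)
  }
  edges <- len * (0:body_bins) / body_bins
  binsum <- S(edges[-1]) - S(edges[-(body_bins + 1)])
  binsum / (len / body_bins)
}

#' Average metaprofile across genes, then across replicates
#'
#' For each replicate matrix the column-wise mean over genes is taken; the
#' replicate mean profiles are then averaged element-wise (unweighted). All
#' matrices must share shape, mode and gene set.
#'
#' @param matrices List of `meta_profile_matrix` objects, one per replicate.
#' @return Tibble `bin`, `position`, `value`, where `position` is the bin
#'   midpoint relative to the anchor (reference-point mode) or `NA` for body
#'   bins (scale-regions mode).
#' @export
mean_profile <- function(matrices) {
  if (inherits(matrices, "meta_profile_matrix")) matrices <- list(matrices)
  m1 <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(dim(m), dim(m1)) ||
        !identical(attr(m, "mode"), attr(m1, "mode")) ||
        !identical(attr(m, "gene_ids"), attr(m1, "gene_ids"))) {
      stop("replicate matrices must share shape, mode and gene set",
           call. = FALSE)
    }
  }
  per_rep <- vapply(matrices, colMeans, numeric(ncol(m1)))
  value <- rowMeans(per_rep)
  tibble::tibble(bin = seq_along(value),
                 position = profile_positions(m1),
                 value = value)
}

# Bin-midpoint coordinates relative to the anchor; NA for scaled body bins.
profile_positions <- function(mat) {
  bs <- attr(mat, "bin_size")
  up <- attr(mat, "upstream")
  down <- attr(mat, "downstream")
  if (attr(mat, "mode") == "reference_point") {
    -up + (seq_len((up + down) / bs) - 0.5) * bs
  } else {
    bb <- attr(mat, "body_bins")
    c(-up + (seq_len(up / bs) - 0.5) * bs,
      rep(NA_real_, bb),
      (seq_len(down / bs) - 0.5) * bs)
  }
}

#' Write a metaprofile matrix as TSV with a JSON metadata header
#'
#' The first line is a `#`-prefixed JSON object carrying mode, windows, bin
#' size and gene count; the rest is a plain TSV (gene_id + one column per
#' bin).
#'
#' @param mat A `meta_profile_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_matrix <- function(mat, path) {
  meta <- list(mode = attr(mat, "mode"), bin_size = attr(mat, "bin_size"),
               upstream = attr(mat, "upstream"),
               downstream = attr(mat, "downstream"),
               body_bins = attr(mat, "body_bins"),
               anchor = attr(mat, "anchor"), n_genes = nrow(mat))
  header <- paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"))
  df <- tibble::as_tibble(as.data.frame(unclass(mat)[seq_len(nrow(mat)), ,
                                                     drop = FALSE]),
                          .name_repair = ~ paste0("bin", seq_len(ncol(mat))))
  df <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(mat)), df)
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
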