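#' Read cross-link sites from BED6
#'
#' @param path BED file; the strand column is required (cross-links are
#'   strand-specific).
#' @return Tibble `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @export
read_crosslinks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strand_chr <- as.character(BiocGenerics::strand(gr))
  if (any(!strand_chr %in% c("+", "-"))) {
    stop("cross-link BED must carry +/- strand for every interval",
         call. = FALSE)
  }
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand_chr
  )
}

#' Write cross-link sites as BED6
#' @param xlinks Tibble `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_crosslinks <- function(xlinks, path) {
  bed <- dplyr::transmute(
    xlinks, .data$chrom, .data$start, .data$end,
    name = paste0("xl_", dplyr::row_number()), score = 0L, .data$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Flag genes with a cross-link in their promoter
#'
#' A gene is "bound" when at least one same-strand cross-link interval
#' overlaps the transcription-oriented window `[-window_up, window_down)`
#' around its TSS. Windows extending past the chromosome start are clipped
#' (this is a presence/absence call, so clipping cannot bias a density).
#'
#' @param genes Gene tibble.
#' @param xlinks Cross-link tibble (see [read_crosslinks()]).
#' @param window_up Bases upstream of the TSS (default 250).
#' @param window_down Bases downstream of the TSS (default 300).
#' @return Tibble `gene_id`, `bound` (logical).
#' @export
assign_promoter_binding <- function(genes, xlinks, window_up = 250L,
                                    window_down = 300L) {
  if (window_up < 0 || window_down < 0) {
    stop("windows must be >= 0", call. = FALSE)
  }
  win <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    w <- gene_window(genes[i, ], -window_up, window_down)
    tibble::tibble(gene_id = genes$gene_id[i], chrom = w$chrom,
                   wstart = max(w$start, 0), wend = w$end,
                   strand = w$strand)
  })
  hit <- dplyr::inner_join(win, xlinks, by = c("chrom", "strand"),
                           relationship = "many-to-many")
  hit <- dplyr::filter(hit, .data$start < .data$wend,
                       .data$end > .data$wstart)
  tibble::tibble(
    gene_id = genes$gene_id,
    bound = genes$gene_id %in% hit$gene_id
  )
}

#' Read a two-column expression TSV
#' @param path TSV with header columns `gene_id`, `expression`.
#' @return Tibble `gene_id`, `expression`.
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  stopifnot(all(c("gene_id", "expression") %in% names(expr)))
  if (any(expr$expression < 0)) stop("expression must be >= 0", call. = FALSE)
  if (anyDuplicated(expr$gene_id)) {
    stop("duplicate gene_id in expression table", call. = FALSE)
  }
  expr
}

#' Divide each metaprofile row by the gene's expression level
#'
#' Genes with zero expression are dropped (their count is reported with a
#' message) rather than divided; genes absent from the expression table are
#' an error.
#'
#' @param mat A [meta_profile_matrix] (or plain matrix with `gene_id`
#'   rownames).
#' @param expr Expression tibble (`gene_id`, `expression`).
#' @return The matrix with rows rescaled, zero-expression genes removed.
#' @export
normalize_by_expression <- function(mat, expr) {
  ids <- rownames(mat)
  missing <- setdiff(ids, expr$gene_id)
  if (length(missing) > 0) {
    stop("genes missing from expression table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  e <- expr$expression[match(ids, expr$gene_id)]
  zero <- e == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with zero expression dropped")
  }
  out <- mat[!zero, , drop = FALSE] / e[!zero]
  extra <- attributes(mat)
  extra <- extra[setdiff(names(extra), c("dim", "dimnames"))]
  extra$gene_ids <- rownames(out)
  for (a in names(extra)) attr(out, a) <- extra[[a]]
  out
}

#' Select an expression-matched control gene set
#'
#' Greedy nearest-neighbour matching without replacement on
#' `log10(expression + pseudocount)`: bound genes are visited in descending
#' expression order and each takes the still-unused pool gene with the
#' closest log-expression (ties broken by `gene_id`). The report includes the
#' Kolmogorov-Smirnov distance between the bound and pool/control expression
#' distributions before and after matching.
#'
#' @param bound Character vector of bound gene ids.
#' @param pool Character vector of candidate control ids (disjoint from
#'   `bound`, at least as many).
#' @param expr Expression tibble covering both sets.
#' @param pseudocount Added before the log (default 1e-3).
#' @return Object of class `expression_match`: list with `controls`
#'   (character), `pairs` (tibble `bound_id`, `control_id`, `log_expr_bound`,
#'   `log_expr_control`), `ks_pre`, `ks_post`.
#' @export
match_expression_controls <- function(bound, pool, expr,
                                      pseudocount = 1e-3) {
  if (length(intersect(bound, pool)) > 0) {
    stop("pool must be disjoint from bound", call. = FALSE)
  }
  if (length(pool) < length(bound)) {
    stop("pool (", length(pool), ") smaller than bound set (", length(bound),
         ")", call. = FALSE)
  }
  le <- function(ids) {
    e <- expr$expression[match(ids, expr$gene_id)]
    if (anyNA(e)) {
      stop("genes missing from expression table: ",
           paste(ids[is.na(e)], collapse = ", "), call. = FALSE)
    }
    log10(e + pseudocount)
  }
  lb <- le(bound)
  lp <- le(pool)
  ks_pre <- unname(suppressWarnings(stats::ks.test(lb, lp))$statistic)

  ord <- order(-lb, bound)
  pool_ord <- order(lp, pool)   # deterministic tie-break by id
  pool_sorted <- pool[pool_ord]
  lp_sorted <- lp[pool_ord]
  used <- rep(FALSE, length(pool_sorted))
  control_id <- character(length(bound))
  control_le <- numeric(length(bound))
  for (i in ord) {
    free <- which(!used)
    j <- free[which.min(abs(lp_sorted[free] - lb[i]))]
    used[j] <- TRUE
    control_id[i] <- pool_sorted[j]
    control_le[i] <- lp_sorted[j]
  }
  ks_post <- unname(suppressWarnings(stats::ks.test(lb, control_le))$statistic)
  structure(
    list(
      controls = control_id,
      pairs = tibble::tibble(bound_id = bound, control_id = control_id,
                             log_expr_bound = lb,
                             log_expr_control = control_le),
      ks_pre = ks_pre, ks_post = ks_post
    ),
    class = "expression_match"
  )
}

#' @export
print.expression_match <- function(x, ...) {
  cat("<expression_match>", length(x$controls), "controls | KS",
      sprintf("%.4f -> %.4f\n", x$ks_pre, x$ks_post))
  invisible(x)
}

#' Compare promoter pausing breadth between two gene groups
#'
#' The per-gene pausing breadth is the number of positions in the first
#' `window` bases downstream of the TSS whose signal is at least
#' `level` times that gene's maximum within the window; genes with an
#' all-zero window are excluded. The two breadth distributions are compared
#' with a two-sided Wilcoxon rank-sum test. This width-at-fraction-of-max
#' statistic is this package's operationalization of "pausing breadth"; it is
#' labelled as such in outputs.
#'
#' @param profiles_a,profiles_b Matrices of TSS-anchored oriented per-base
#'   profiles (genes x positions); column `upstream + 1` is the TSS. The
#'   `upstream` attribute of a [meta_profile_matrix] is honoured, else 0.
#' @param window Breadth window in bases downstream of the TSS (default 500).
#' @param level Fraction of the per-gene maximum (default 0.25).
#' @return Object of class `breadth_test`: `statistic` (rank-sum U), `p_value`,
#'   `breadth_a`, `breadth_b`, `n_excluded`, `degenerate` (TRUE when every
#'   breadth in both groups is identical).
#' @export
compare_pausing_breadth <- function(profiles_a, profiles_b, window = 500L,
                                    level = 0.25) {
  breadth <- function(mat) {
    up <- attr(mat, "upstream") %||% 0L
    if (ncol(mat) < up + window) {
      stop("profiles shorter than upstream + window", call. = FALSE)
    }
    sub <- mat[, (up + 1):(up + window), drop = FALSE]
    mx <- apply(sub, 1, max)
    keep <- mx > 0
    b <- vapply(which(keep), function(i) {
      sum(sub[i, ] >= level * mx[i])
    }, numeric(1))
    list(b = b, excluded = sum(!keep))
  }
  a <- breadth(profiles_a)
  b <- breadth(profiles_b)
  if (length(a$b) == 0 || length(b$b) == 0) {
    stop("a group is empty after excluding all-zero windows", call. = FALSE)
  }
  degenerate <- length(unique(c(a$b, b$b))) == 1
  wt <- suppressWarnings(
    stats::wilcox.test(a$b, b$b, alternative = "two.sided", exact = FALSE)
  )
  structure(
    list(statistic = unname(wt$statistic),
         p_value = if (degenerate) 1 else wt$p.value,
         breadth_a = a$b, breadth_b = b$b,
         n_excluded = a$excluded + b$excluded,
         degenerate = degenerate,
         window = window, level = level),
    class = "breadth_test"
  )
}

#' @export
print.breadth_test <- function(x, ...) {
  cat("<breadth_test> width-at-", x$level, "-of-max in ", x$window,
      " bp after TSS\n", sep = "")
  cat(sprintf("  medians %.1f vs %.1f | U = %.1f, p = %.3g%s\n",
              stats::median(x$breadth_a), stats::median(x$breadth_b),
              x$statistic, x$p_value,
              if (x$degenerate) " (degenerate: constant breadths)" else ""))
  invisible(x)
}
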