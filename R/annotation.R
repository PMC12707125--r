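#' Read gene models from a GFF3 file
#'
#' Imports features of type `gene` and returns one row per gene as a tibble of
#' gene models. Coordinates are converted from the 1-based inclusive GFF
#' convention to the package-internal 0-based half-open convention, and the
#' transcription anchors are derived from the annotated extremities: on the
#' `+` strand the TSS is `start` and the PAS is `end - 1`; on the `-` strand
#' the TSS is `end - 1` and the PAS is `start` (both anchors are positions of
#' transcribed bases, so they always lie inside `[start, end)`).
#'
#' @param gff_path Path to a GFF3 file.
#' @param biotype_filter Optional biotype to retain (e.g. `"protein_coding"`);
#'   matched against the `biotype` or `gene_biotype` attribute. `NULL` keeps
#'   every gene regardless of biotype.
#' @param feature_type GFF3 feature type to read (default `"gene"`).
#'
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`, `tss`, `pas`, `length`. Records on a strand other than
#'   `+`/`-` are dropped with a warning.
#' @export
load_gene_models <- function(gff_path, biotype_filter = NULL,
                             feature_type = "gene") {
  if (!file.exists(gff_path)) {
    stop("GFF3 file not found: ", gff_path, call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(gff_path, format = "gff3"),
    error = function(e) {
      stop("failed to parse GFF3 '", gff_path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  md <- S4Vectors::mcols(gr)
  keep <- !is.na(md$type) & as.character(md$type) == feature_type
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)

  strand_chr <- as.character(BiocGenerics::strand(gr))
  bad_strand <- !strand_chr %in% c("+", "-")
  if (any(bad_strand)) {
    warning(sum(bad_strand), " record(s) rejected: strand must be '+' or '-'",
            call. = FALSE)
    gr <- gr[!bad_strand]
    md <- S4Vectors::mcols(gr)
    strand_chr <- strand_chr[!bad_strand]
  }

  biotype <- if ("biotype" %in% names(md)) {
    as.character(md$biotype)
  } else if ("gene_biotype" %in% names(md)) {
    as.character(md$gene_biotype)
  } else {
    rep(NA_character_, length(gr))
  }
  gene_id <- if ("ID" %in% names(md) && !all(is.na(md$ID))) {
    as.character(md$ID)
  } else if ("Name" %in% names(md)) {
    as.character(md$Name)
  } else {
    paste0("gene_", seq_along(gr))
  }

  genes <- tibble::tibble(
    gene_id = gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    # GFF is 1-based inclusive; internal representation 0-based half-open
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand_chr,
    biotype = biotype
  )
  if (!is.null(biotype_filter)) {
    genes <- dplyr::filter(genes, !is.na(.data$biotype),
                           .data$biotype %in% biotype_filter)
  }
  add_gene_anchors(genes)
}

#' Derive TSS/PAS anchors and length for a gene table
#'
#' @param genes Tibble with `start`, `end`, `strand` (0-based half-open).
#' @return The input with `tss`, `pas` and `length` columns (re)computed.
#' @export
add_gene_anchors <- function(genes) {
  stopifnot(all(genes$start < genes$end))
  dplyr::mutate(
    genes,
    tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
    pas = ifelse(.data$strand == "+", .data$end - 1L, .data$start),
    length = .data$end - .data$start
  )
}

#' Keep genes with no same-strand neighbor near their TSS or PAS
#'
#' A gene survives when no *other* transcription unit on the same strand
#' overlaps either the window extending `flank` bases upstream of its TSS or
#' the window extending `flank` bases downstream of its PAS (windows oriented
#' by transcription direction). For both strands these are the genomic
#' intervals `[start - flank, start)` and `[end, end + flank)`. The focal
#' gene never disqualifies itself; `all_units` should contain every annotated
#' transcription unit, not only the focal (biotype-filtered) list.
#'
#' @param genes Focal gene tibble (as from [load_gene_models()]).
#' @param all_units Tibble of all transcription units; defaults to `genes`.
#' @param flank Flank width in bases (default 250).
#' @return The surviving subset of `genes`.
#' @export
filter_isolated <- function(genes, all_units = genes, flank = 250L) {
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  if (nrow(genes) == 0) return(genes)

  win <- dplyr::bind_rows(
    dplyr::transmute(genes, .row = dplyr::row_number(),
                     chrom = .data$chrom, strand = .data$strand,
                     wstart = pmax(.data$start - flank, 0L),
                     wend = .data$start),
    dplyr::transmute(genes, .row = dplyr::row_number(),
                     chrom = .data$chrom, strand = .data$strand,
                     wstart = .data$end, wend = .data$end + flank)
  )
  win <- dplyr::filter(win, .data$wstart < .data$wend)
  gene_key <- paste(genes$gene_id, genes$chrom, genes$start, genes$end)
  unit_key <- paste(all_units$gene_id, all_units$chrom, all_units$start,
                    all_units$end)

  win_gr <- GenomicRanges::GRanges(
    win$chrom,
    IRanges::IRanges(start = win$wstart + 1L, end = win$wend),
    strand = win$strand
  )
  unit_gr <- GenomicRanges::GRanges(
    all_units$chrom,
    IRanges::IRanges(start = all_units$start + 1L, end = all_units$end),
    strand = all_units$strand
  )
  hits <- GenomicRanges::findOverlaps(win_gr, unit_gr, ignore.strand = FALSE)
  # drop self-hits: the focal gene's own record in all_units
  self <- gene_key[win$.row[S4Vectors::queryHits(hits)]] ==
    unit_key[S4Vectors::subjectHits(hits)]
  bad_rows <- unique(win$.row[S4Vectors::queryHits(hits)[!self]])
  genes[setdiff(seq_len(nrow(genes)), bad_rows), , drop = FALSE]
}

#' Keep genes strictly longer than a minimum length
#'
#' @param genes Gene tibble with a `length` column.
#' @param min_len Minimum length in bases; genes with `length > min_len` are
#'   retained (strict inequality, matching the "longer than" eligibility
#'   wording used for nascent-transcription data).
#' @return Filtered tibble.
#' @export
filter_length <- function(genes, min_len) {
  stopifnot(min_len >= 0)
  dplyr::filter(genes, .data$length > min_len)
}

#' Write a gene table as BED6 and TSV
#'
#' BED is written 0-based half-open with `name = gene_id`, `score = 0`.
#'
#' @param genes Gene tibble.
#' @param bed_path,tsv_path Output paths (`NULL` to skip either).
#' @return Invisibly, the input.
#' @export
write_gene_set <- function(genes, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- dplyr::transmute(genes, .data$chrom, .data$start, .data$end,
                            name = .data$gene_id, score = 0L, .data$strand)
    readr::write_tsv(bed, bed_path, col_names = FALSE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(
      dplyr::select(genes, "gene_id", "chrom", "start", "end", "strand",
                    "length"),
      tsv_path
    )
  }
  invisible(genes)
}

#' Write gene models as GFF3
#'
#' Inverse of [load_gene_models()]: internal 0-based half-open coordinates are
#' written 1-based inclusive, with `ID` and `biotype` attributes.
#'
#' @param genes Gene tibble.
#' @param path Output GFF3 path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$biotype <- genes$biotype
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
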