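#' Construct a per-base coverage track
#'
#' A coverage track stores dense non-negative per-base signal, one numeric
#' vector per chromosome, plus a strand label. Position `i` (0-based) of
#' chromosome `chrom` is `values[[chrom]][i + 1]`.
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param strand_label One of `"+"`, `"-"`, `"*"` (unstranded).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, strand_label = "*") {
  stopifnot(is.list(values), !is.null(names(values)))
  strand_label <- match.arg(strand_label, c("+", "-", "*"))
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (!is.numeric(v)) stop("coverage values must be numeric", call. = FALSE)
    if (anyNA(v) || any(v < 0)) {
      stop("negative or missing coverage on ", chrom, call. = FALSE)
    }
  }
  structure(
    list(values = values,
         chrom_sizes = vapply(values, length, integer(1)),
         strand_label = strand_label),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> strand", x$strand_label, "|",
      length(x$values), "chromosome(s),",
      format(sum(as.numeric(x$chrom_sizes)), big.mark = ","), "bases, total signal",
      format(sum(vapply(x$values, sum, numeric(1)))), "\n")
  invisible(x)
}

#' Load a coverage track from bedGraph or bigWig
#'
#' Positions not covered by any interval get value 0. Overlapping bedGraph
#' intervals, intervals exceeding the declared chromosome size, and negative
#' values are errors (no silent clipping or summing).
#'
#' @param path Input file.
#' @param format `"bedgraph"` or `"bigwig"`.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param strand_label Strand this track represents.
#' @return A [coverage_track()].
#' @export
load_track <- function(path, format = c("bedgraph", "bigwig"), chrom_sizes,
                       strand_label = "*") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(
    path, format = if (format == "bedgraph") "bedGraph" else "BigWig"
  )
  vals <- lapply(names(chrom_sizes), function(chrom) numeric(chrom_sizes[[chrom]]))
  names(vals) <- names(chrom_sizes)
  if (length(gr) > 0) {
    chrom <- as.character(GenomeInfoDb::seqnames(gr))
    unknown <- setdiff(unique(chrom), names(chrom_sizes))
    if (length(unknown) > 0) {
      stop("track chromosome(s) not in chrom_sizes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    start0 <- BiocGenerics::start(gr) - 1L
    end0 <- BiocGenerics::end(gr)
    score <- S4Vectors::mcols(gr)$score
    if (any(score < 0)) stop("negative coverage value in ", path, call. = FALSE)
    for (cm in unique(chrom)) {
      i <- which(chrom == cm)
      i <- i[order(start0[i])]
      if (any(end0[i] > chrom_sizes[[cm]])) {
        stop("interval exceeds size of chromosome ", cm, call. = FALSE)
      }
      if (length(i) > 1 && any(start0[i][-1] < end0[i][-length(i)])) {
        stop("overlapping bedGraph intervals on ", cm, call. = FALSE)
      }
      w <- end0[i] - start0[i]
      vals[[cm]][sequence(w, from = start0[i] + 1L)] <- rep(score[i], w)
    }
  }
  coverage_track(vals, strand_label)
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted; adjacent equal values are merged into one interval.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  pieces <- lapply(names(track$values), function(chrom) {
    r <- rle(track$values[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep],
                   score = r$values[keep])
  })
  bg <- dplyr::bind_rows(pieces)
  gr <- GenomicRanges::GRanges(
    bg$chrom, IRanges::IRanges(start = bg$start + 1L, end = bg$end),
    score = bg$score,
    seqinfo = GenomeInfoDb::Seqinfo(names(track$chrom_sizes),
                                    unname(track$chrom_sizes))
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Bundle plus- and minus-strand tracks for one sample
#'
#' @param plus,minus `coverage_track`s for the two strands; must share
#'   chromosome sizes.
#' @param sample_id,condition Sample identifiers.
#' @param replicate Replicate index (integer >= 1).
#' @return An object of class `track_pair`.
#' @export
track_pair <- function(plus, minus, sample_id, condition, replicate = 1L) {
  stopifnot(inherits(plus, "coverage_track"), inherits(minus, "coverage_track"))
  if (!identical(plus$chrom_sizes, minus$chrom_sizes)) {
    stop("plus and minus tracks must share chrom_sizes", call. = FALSE)
  }
  if (replicate < 1) stop("replicate must be >= 1", call. = FALSE)
  structure(
    list(plus = plus, minus = minus, sample_id = sample_id,
         condition = condition, replicate = as.integer(replicate)),
    class = "track_pair"
  )
}

#' @export
print.track_pair <- function(x, ...) {
  cat("<track_pair>", x$sample_id, sprintf("(%s, rep %d)\n", x$condition,
                                           x$replicate))
  invisible(x)
}

#' Sum and mean of a coverage window
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window; must lie inside the chromosome
#'   (out-of-bounds windows are errors, never clipped).
#' @return List with `sum` and `mean`.
#' @export
window_stats <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom, call. = FALSE)
  if (start < 0 || end > length(v) || start >= end) {
    stop(sprintf("window [%d,%d) out of bounds for %s (size %d)",
                 start, end, chrom, length(v)), call. = FALSE)
  }
  s <- sum(v[(start + 1):end])
  list(sum = s, mean = s / (end - start))
}

#' Genomic interval of a transcription-oriented window
#'
#' Offsets are measured in transcription direction relative to an anchor base
#' (TSS by default): offset 0 is the anchor itself, negative offsets are
#' upstream. The genomic interval covering offsets `[from_tss, to_tss)` is
#' `[tss + from_tss, tss + to_tss)` on the `+` strand and its mirror
#' `[tss - to_tss + 1, tss - from_tss + 1)` on the `-` strand.
#'
#' @param gene One-row gene tibble (or list) with `chrom`, `strand` and the
#'   anchor position.
#' @param from_tss,to_tss Signed offsets, `from_tss < to_tss`.
#' @param anchor Column holding the anchor position (`"tss"` or `"pas"`).
#' @return List with `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @export
gene_window <- function(gene, from_tss, to_tss, anchor = "tss") {
  if (from_tss >= to_tss) stop("from_tss must be < to_tss", call. = FALSE)
  a <- gene[[anchor]]
  if (gene$strand == "+") {
    list(chrom = gene$chrom, start = a + from_tss, end = a + to_tss,
         strand = "+")
  } else {
    list(chrom = gene$chrom, start = a - to_tss + 1, end = a - from_tss + 1,
         strand = "-")
  }
}

#' Oriented per-base signal around a gene anchor
#'
#' Extracts signal from the track matching the gene's strand and returns it
#' reading 5'->3' in transcription direction (minus-strand windows are
#' reversed). The window covers transcription offsets
#' `[-upstream, downstream)` around the anchor.
#'
#' @param pair A [track_pair()].
#' @param gene One-row gene tibble.
#' @param upstream,downstream Window extents in bases.
#' @param anchor `"tss"` or `"pas"`.
#' @return Numeric vector of length `upstream + downstream`.
#' @export
oriented_profile <- function(pair, gene, upstream, downstream,
                             anchor = "tss") {
  w <- gene_window(gene, -upstream, downstream, anchor = anchor)
  track <- if (gene$strand == "+") pair$plus else pair$minus
  v <- track$values[[w$chrom]]
  if (is.null(v)) stop("unknown chromosome: ", w$chrom, call. = FALSE)
  if (w$start < 0 || w$end > length(v)) {
    stop(sprintf("window [%d,%d) out of bounds for %s", w$start, w$end,
                 w$chrom), call. = FALSE)
  }
  out <- v[(w$start + 1):w$end]
  if (gene$strand == "-") rev(out) else out
}

#' Read a 2-column chromosome-sizes TSV
#'
#' @param path TSV with columns chromosome name and length, no header.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  cs <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = "ci", progress = FALSE)
  stats::setNames(cs$size, cs$chrom)
}

#' Write chromosome sizes as TSV
#' @param chrom_sizes Named integer vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  readr::write_tsv(
    tibble::tibble(chrom = names(chrom_sizes), size = unname(chrom_sizes)),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Load all samples listed in a sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `condition`,
#' `replicate`, `plus_path`, `minus_path`. Relative paths are resolved
#' against the sheet's directory. `swap_strands = TRUE` exchanges the two
#' tracks on loading, for library protocols that record nascent signal on the
#' opposite strand.
#'
#' @param sheet_path Sample-sheet TSV.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param format Track format, `"bedgraph"` or `"bigwig"`.
#' @param swap_strands Swap plus/minus tracks on load.
#' @return Named list of [track_pair()] objects (by `sample_id`).
#' @export
read_sample_sheet <- function(sheet_path, chrom_sizes,
                              format = c("bedgraph", "bigwig"),
                              swap_strands = FALSE) {
  format <- match.arg(format)
  sheet <- readr::read_tsv(sheet_path, col_types = "ccicc", progress = FALSE)
  needed <- c("sample_id", "condition", "replicate", "plus_path", "minus_path")
  if (!all(needed %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(sheet_path)
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  pairs <- purrr::pmap(sheet, function(sample_id, condition, replicate,
                                       plus_path, minus_path) {
    plus <- load_track(resolve(plus_path), format, chrom_sizes, "+")
    minus <- load_track(resolve(minus_path), format, chrom_sizes, "-")
    if (swap_strands) {
      tmp <- plus$values
      plus$values <- minus$values
      minus$values <- tmp
    }
    track_pair(plus, minus, sample_id, condition, replicate)
  })
  stats::setNames(pairs, sheet$sample_id)
}
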