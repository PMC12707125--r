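#' Configuration for the synthetic nascent-transcription world
#'
#' The generator plants a known pausing structure: every gene gets a
#' rectangular promoter-proximal elevation over the first 300 bases after the
#' TSS (factor `pi_ref` in the reference condition) and a peak of
#' `pas_peak_amp` times the body density over the `pas_peak_len` bases
#' immediately upstream of the PAS. In the mutant condition the promoter
#' factor of genes planted as `increased`/`decreased` is shifted by
#' `+/- pi_mut_shift`. Because the elevation is rectangular and the PAS peak
#' (150 bp by default) stays outside the NET-seq body (which ends 300 bp
#' before the PAS), the planted pausing index is exact in expectation under
#' the density/density convention. Per-base counts are independent Poisson
#' draws. Defaults describe a compact fungal-like genome: 1000 genes of
#' 1200-4000 bp on alternating strands, 300-800 bp intergenic gaps with a 5%
#' fraction of deliberately close (< 250 bp) same-strand neighbours, 10%
#' of genes with increased and 10% with decreased mutant pausing
#' (`pi_mut_shift = 2`), 30% of genes cross-link-bound at the promoter,
#' base body density 0.5 counts/base with log-normal (sdlog 0.5)
#' gene-to-gene expression variation, 2 replicates per condition.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range,intergap_range Min/max gene length and gap (bp).
#' @param frac_close Fraction of gaps forced below 250 bp (exercises the
#'   isolation filter).
#' @param frac_increased,frac_decreased Fractions of genes whose pausing
#'   rises/falls in the mutant.
#' @param frac_bound Fraction of genes with promoter cross-links.
#' @param base_body_density Expected body counts per base before the
#'   expression factor.
#' @param expr_sdlog Log-normal sdlog of the per-gene expression factor.
#' @param pi_ref Planted reference pausing index.
#' @param pi_mut_shift Magnitude of the mutant pausing-index shift.
#' @param promoter_len Width of the planted promoter elevation (bp).
#' @param pas_peak_amp,pas_peak_len PAS-proximal peak amplitude (times body
#'   density) and width (bp).
#' @param n_replicates Replicates per condition.
#' @param conditions Length-2 character vector: reference then mutant label.
#' @param crosslink_background Expected number of background cross-links per
#'   kilobase outside promoters (default 0).
#' @param chrom_len Chromosome length; `NULL` sizes it to fit with a 2 kb
#'   margin.
#' @param margin Bases kept gene-free at both chromosome ends.
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       gene_length_range = c(1200L, 4000L),
                       intergap_range = c(300L, 800L),
                       frac_close = 0.05,
                       frac_increased = 0.1,
                       frac_decreased = 0.1,
                       frac_bound = 0.3,
                       base_body_density = 0.5,
                       expr_sdlog = 0.5,
                       pi_ref = 2,
                       pi_mut_shift = 2,
                       promoter_len = 300L,
                       pas_peak_amp = 3,
                       pas_peak_len = 150L,
                       n_replicates = 2L,
                       conditions = c("wt", "mut"),
                       crosslink_background = 0,
                       chrom_len = NULL,
                       margin = 2000L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_genes >= 1,
    frac_increased >= 0, frac_decreased >= 0,
    frac_increased + frac_decreased <= 1,
    frac_bound >= 0, frac_bound <= 1,
    base_body_density > 0, pi_ref >= 0, pi_mut_shift >= 0,
    gene_length_range[1] <= gene_length_range[2],
    gene_length_range[1] > 2 * promoter_len,
    n_replicates >= 1, length(conditions) == 2
  )
  structure(cfg, class = "sim_config")
}

#' Simulate the annotation and per-gene ground truth
#'
#' Genes are placed left to right on one chromosome, alternating strands,
#' with gaps drawn uniformly from `intergap_range` except a `frac_close`
#' minority forced under 250 bp. Planted classes, binding flags and
#' expression factors are assigned by seeded draws; class counts equal
#' `round(frac * n_genes)` exactly.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_world`: `genes` (gene tibble), `chrom_sizes`,
#'   `truth` (tibble `gene_id`, `planted_class`, `bound`, `pi_wt`, `pi_mut`,
#'   `expression_true`), `cfg`.
#' @export
simulate_world <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  lens <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], n,
                 replace = TRUE)
  gaps <- sample(cfg$intergap_range[1]:cfg$intergap_range[2], n,
                 replace = TRUE)
  strand <- rep_len(c("+", "-"), n)
  n_close <- round(cfg$frac_close * n)
  if (n_close > 0 && n > 1) {
    close_idx <- sample(n - 1, min(n_close, n - 1))
    gaps[close_idx] <- sample(50:200, length(close_idx), replace = TRUE)
    # close pairs share a strand so the isolation filter has work to do
    strand[close_idx + 1] <- strand[close_idx]
  }
  starts <- cfg$margin + cumsum(c(0L, lens[-n] + gaps[-n]))
  ends <- starts + lens
  chrom_len <- cfg$chrom_len %||% (max(ends) + cfg$margin)
  if (max(ends) + cfg$margin > chrom_len) {
    stop("genes do not fit in chrom_len ", chrom_len,
         "; need at least ", max(ends) + cfg$margin, call. = FALSE)
  }
  genes <- add_gene_anchors(tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = "chrS",
    start = as.integer(starts),
    end = as.integer(ends),
    strand = strand,
    biotype = "protein_coding"
  ))

  n_inc <- round(cfg$frac_increased * n)
  n_dec <- round(cfg$frac_decreased * n)
  cls <- rep("unchanged", n)
  pick <- sample(n, n_inc + n_dec)
  cls[pick[seq_len(n_inc)]] <- "increased"
  if (n_dec > 0) cls[pick[n_inc + seq_len(n_dec)]] <- "decreased"
  bound <- rep(FALSE, n)
  bound[sample(n, round(cfg$frac_bound * n))] <- TRUE
  expr_factor <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$expr_sdlog)

  truth <- tibble::tibble(
    gene_id = genes$gene_id,
    planted_class = cls,
    bound = bound,
    pi_wt = cfg$pi_ref,
    pi_mut = cfg$pi_ref +
      cfg$pi_mut_shift * (cls == "increased") -
      cfg$pi_mut_shift * (cls == "decreased"),
    expression_true = cfg$base_body_density * expr_factor
  )
  structure(list(genes = genes,
                 chrom_sizes = c(chrS = as.integer(chrom_len)),
                 truth = truth, cfg = cfg),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat("<sim_world>", nrow(x$genes), "genes on",
      format(unname(x$chrom_sizes), big.mark = ","), "bp |",
      sum(x$truth$planted_class == "increased"), "increased,",
      sum(x$truth$planted_class == "decreased"), "decreased,",
      sum(x$truth$bound), "bound\n")
  invisible(x)
}

#' Expected per-base Poisson rate for one gene
#'
#' Transcription-oriented rate vector: body density `d_g =
#' expression_true[gene]`, multiplied by the condition's planted pausing
#' factor over the promoter window, plus `pas_peak_amp * d_g` over the
#' `pas_peak_len` bases immediately upstream of the PAS.
#'
#' @param world A `sim_world`.
#' @param gene_id Gene identifier.
#' @param condition Condition label (one of `cfg$conditions`).
#' @return Numeric rate vector of the gene's length, 5'->3'.
#' @export
expected_rate <- function(world, gene_id, condition) {
  cfg <- world$cfg
  i <- match(gene_id, world$genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id, call. = FALSE)
  len <- world$genes$length[i]
  d <- world$truth$expression_true[i]
  pi_val <- if (condition == cfg$conditions[1]) {
    world$truth$pi_wt[i]
  } else if (condition == cfg$conditions[2]) {
    world$truth$pi_mut[i]
  } else {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  lam <- rep(d, len)
  lam[seq_len(cfg$promoter_len)] <- d * pi_val
  if (cfg$pas_peak_len > 0 && cfg$pas_peak_amp > 0) {
    peak <- (len - cfg$pas_peak_len + 1):len
    lam[peak] <- lam[peak] + cfg$pas_peak_amp * d
  }
  lam
}

#' Simulate the strand-specific coverage tracks for every sample
#'
#' Per-base counts are independent Poisson draws from [expected_rate()],
#' written onto the gene's own strand at the mirrored genomic positions for
#' minus-strand genes. Randomness is governed by `cfg$seed` (offset per
#' sample), independent of the annotation draw.
#'
#' @param world A `sim_world`.
#' @return Named list of [track_pair()] objects
#'   (`<condition>_rep<r>`), one per condition x replicate.
#' @export
simulate_tracks <- function(world) {
  cfg <- world$cfg
  genes <- world$genes
  chrom_len <- unname(world$chrom_sizes[1])
  chrom <- names(world$chrom_sizes)[1]
  pairs <- list()
  sidx <- 0L
  for (cond in cfg$conditions) {
    lam_list <- lapply(genes$gene_id, function(g)
      expected_rate(world, g, cond))
    for (r in seq_len(cfg$n_replicates)) {
      sidx <- sidx + 1L
      set.seed(cfg$seed + 1000L * sidx)
      plus <- numeric(chrom_len)
      minus <- numeric(chrom_len)
      for (i in seq_len(nrow(genes))) {
        counts <- stats::rpois(genes$length[i], lam_list[[i]])
        if (genes$strand[i] == "+") {
          plus[(genes$start[i] + 1):genes$end[i]] <- counts
        } else {
          minus[(genes$start[i] + 1):genes$end[i]] <- rev(counts)
        }
      }
      sample_id <- paste0(cond, "_rep", r)
      pairs[[sample_id]] <- track_pair(
        coverage_track(stats::setNames(list(plus), chrom), "+"),
        coverage_track(stats::setNames(list(minus), chrom), "-"),
        sample_id, cond, r
      )
    }
  }
  pairs
}

#' Simulate promoter cross-link sites
#'
#' Each bound gene receives 1-3 single-base cross-links placed uniformly at
#' transcription offsets `[-100, 200)` around its TSS, on its own strand.
#' With `crosslink_background > 0`, background single-base sites are
#' scattered uniformly over the chromosome on random strands at that rate
#' (expected sites per kilobase).
#'
#' @param world A `sim_world`.
#' @return Cross-link tibble (`chrom`, `start`, `end`, `strand`).
#' @export
simulate_crosslinks <- function(world) {
  cfg <- world$cfg
  set.seed(cfg$seed + 77L)
  genes <- world$genes
  bound <- which(world$truth$bound)
  rows <- purrr::map_dfr(bound, function(i) {
    k <- sample(1:3, 1)
    offs <- sample(-100:199, k, replace = TRUE)
    g <- genes[i, ]
    pos <- if (g$strand == "+") g$tss + offs else g$tss - offs
    tibble::tibble(chrom = g$chrom, start = pos, end = pos + 1L,
                   strand = g$strand)
  })
  if (cfg$crosslink_background > 0) {
    chrom_len <- unname(world$chrom_sizes[1])
    n_bg <- stats::rpois(1, cfg$crosslink_background * chrom_len / 1000)
    if (n_bg > 0) {
      pos <- sample.int(chrom_len, n_bg, replace = TRUE) - 1L
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        chrom = names(world$chrom_sizes)[1], start = pos, end = pos + 1L,
        strand = sample(c("+", "-"), n_bg, replace = TRUE)
      ))
    }
  }
  if (nrow(rows) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  dplyr::arrange(rows, .data$chrom, .data$start, .data$strand)
}

#' Per-gene expression table of the synthetic world
#'
#' Expression is the planted body density (counts/base), the quantity the
#' promoter/body densities are proportional to; empirical body density is an
#' estimator of it.
#'
#' @param world A `sim_world`.
#' @return Tibble `gene_id`, `expression`.
#' @export
simulate_expression <- function(world) {
  tibble::tibble(gene_id = world$truth$gene_id,
                 expression = world$truth$expression_true)
}

#' Write a complete synthetic study to disk
#'
#' Emits everything [run_all()] consumes: `annotation.gff3`, `chrom.sizes`,
#' one bedGraph per strand per sample, `samples.tsv`, `crosslinks.bed`,
#' `expression.tsv`, and `truth.tsv`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `sim_world`, the track pairs, the
#'   cross-links and the written paths.
#' @export
simulate_study <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  world <- simulate_world(cfg)
  pairs <- simulate_tracks(world)
  xlinks <- simulate_crosslinks(world)

  paths <- list(
    annotation = file.path(out_dir, "annotation.gff3"),
    chrom_sizes = file.path(out_dir, "chrom.sizes"),
    sample_sheet = file.path(out_dir, "samples.tsv"),
    crosslinks = file.path(out_dir, "crosslinks.bed"),
    expression = file.path(out_dir, "expression.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_gene_models(world$genes, paths$annotation)
  write_chrom_sizes(world$chrom_sizes, paths$chrom_sizes)
  sheet <- purrr::map_dfr(pairs, function(p) {
    plus_file <- paste0(p$sample_id, "_plus.bedgraph")
    minus_file <- paste0(p$sample_id, "_minus.bedgraph")
    write_bedgraph(p$plus, file.path(out_dir, plus_file))
    write_bedgraph(p$minus, file.path(out_dir, minus_file))
    tibble::tibble(sample_id = p$sample_id, condition = p$condition,
                   replicate = p$replicate, plus_path = plus_file,
                   minus_path = minus_file)
  })
  readr::write_tsv(sheet, paths$sample_sheet)
  write_crosslinks(xlinks, paths$crosslinks)
  readr::write_tsv(simulate_expression(world), paths$expression)
  readr::write_tsv(world$truth, paths$truth)
  invisible(list(world = world, pairs = pairs, xlinks = xlinks,
                 paths = paths))
}
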