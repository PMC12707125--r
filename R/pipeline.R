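#' Assemble a pipeline run configuration
#'
#' Collects input paths and every analysis threshold. Thresholds not given
#' fall back to mode-dependent defaults: minimum gene length 900 bp and body
#' signal > 10 for `netseq`, 600 bp and body signal > 0 for `proseq`; the
#' isolation flank is 250 bp, the promoter window 300 bp and the differential
#' threshold 0.5 in either mode. Thresholds carrying a literature default are
#' flagged in the run manifest; all others are marked `artifact-default`.
#'
#' @param annotation GFF3 path.
#' @param sample_sheet Sample-sheet TSV path (see [read_sample_sheet()]).
#' @param chrom_sizes Chromosome-sizes TSV path.
#' @param out_dir Output directory.
#' @param mode `"netseq"` or `"proseq"`.
#' @param crosslinks,expression Optional BED/TSV paths (`NULL` skips the
#'   stratification stage).
#' @param ref,mut Condition labels; defaults are taken from the sample sheet
#'   order.
#' @param biotype_filter Gene biotype analysed (default `protein_coding`).
#' @param flank,promoter_len,min_len,min_body_signal,min_delta,quantiles
#'   Analysis thresholds (see module functions).
#' @param match_pseudocount,breadth_window,breadth_level Matching/breadth
#'   parameters.
#' @param track_format `"bedgraph"` or `"bigwig"`.
#' @param swap_strands Swap plus/minus tracks on load.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed governs nothing unless future stochastic stages
#'   are added).
#' @return List of class `run_config`.
#' @export
run_config <- function(annotation, sample_sheet, chrom_sizes, out_dir,
                       mode = c("netseq", "proseq"),
                       crosslinks = NULL, expression = NULL,
                       ref = NULL, mut = NULL,
                       biotype_filter = "protein_coding",
                       flank = 250L, promoter_len = 300L,
                       min_len = NULL, min_body_signal = NULL,
                       min_delta = 0.5, quantiles = 4L,
                       match_pseudocount = 1e-3,
                       breadth_window = 500L, breadth_level = 0.25,
                       track_format = "bedgraph",
                       swap_strands = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  if (is.null(cfg$min_len)) cfg$min_len <- if (mode == "netseq") 900L else 600L
  if (is.null(cfg$min_body_signal)) {
    cfg$min_body_signal <- if (mode == "netseq") 10 else 0
  }
  stopifnot(cfg$flank >= 0, cfg$promoter_len > 0, cfg$min_delta >= 0,
            cfg$quantiles >= 2)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; relative input paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  for (key in c("annotation", "sample_sheet", "chrom_sizes", "crosslinks",
                "expression")) {
    if (!is.null(y[[key]]) && !grepl("^/", y[[key]])) {
      y[[key]] <- file.path(base, y[[key]])
    }
  }
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(run_config, y)
}

#' Run the full pausing analysis
#'
#' Executes annotation filtering, coverage loading, pausing-index
#' computation, eligibility, differential classification, quantile split,
#' cross-link stratification with expression-matched controls and breadth
#' comparison (when cross-links and expression are configured), and
#' TSS-anchored plus scaled-gene-body metaprofiles. All tables are written
#' under `out_dir` together with `manifest.json` recording parameters, input
#' checksums and per-filter survivor counts. With a single condition the
#' differential stage is skipped with an explicit notice and pausing tables
#' are still produced. Reruns with identical config and inputs are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of in-memory results (`genes`, `pausing`,
#'   `differential`, `quantiles`, `binding`, `match`, `breadth`, `profiles`,
#'   `manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  note <- function(stage, n) {
    counts[[stage]] <<- n
    message(sprintf("[%s] %d genes", stage, n))
  }

  # --- annotation ---
  all_units <- load_gene_models(config$annotation, biotype_filter = NULL)
  genes <- if (is.null(config$biotype_filter)) all_units else
    dplyr::filter(all_units, .data$biotype %in% config$biotype_filter)
  note("coding", nrow(genes))
  genes <- filter_isolated(genes, all_units, flank = config$flank)
  note("isolated", nrow(genes))
  genes <- filter_length(genes, config$min_len)
  note("length", nrow(genes))
  if (nrow(genes) == 0) stop("stage annotation: no genes survive filtering",
                             call. = FALSE)
  write_gene_set(genes, bed_path = file.path(out, "genes_filtered.bed"),
                 tsv_path = file.path(out, "genes_filtered.tsv"))

  # --- coverage ---
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  pairs <- read_sample_sheet(config$sample_sheet, chrom_sizes,
                             format = config$track_format,
                             swap_strands = config$swap_strands)
  conditions <- unique(vapply(pairs, function(p) p$condition, character(1)))
  ref <- config$ref %||% conditions[1]
  mut <- config$mut %||% (if (length(conditions) > 1) conditions[2] else NULL)

  # --- pausing ---
  ptab <- pausing_table(genes, pairs, mode = config$mode,
                        promoter_len = config$promoter_len)
  elig <- eligible_genes(ptab, genes, mode = config$mode,
                         min_len = config$min_len,
                         min_body_signal = config$min_body_signal,
                         sample_ids = names(pairs))
  keep_ids <- elig$gene_id[elig$eligible]
  note("eligible", length(keep_ids))
  genes_el <- dplyr::filter(genes, .data$gene_id %in% keep_ids)
  ptab_el <- dplyr::filter(ptab, .data$gene_id %in% keep_ids)
  readr::write_tsv(
    dplyr::select(ptab_el, "gene_id", "sample_id", "promoter_density",
                  "body_density", "body_sum", "pausing_index"),
    file.path(out, "pausing_index.tsv")
  )

  # --- differential ---
  diff <- NULL
  if (!is.null(mut)) {
    diff <- classify_differential(ptab_el, ref = ref, mut = mut,
                                  min_delta = config$min_delta)
    readr::write_tsv(tibble::as_tibble(diff),
                     file.path(out, "differential.tsv"))
    for (lab in c("increased", "decreased")) {
      ids <- diff$gene_id[diff$label == lab]
      write_gene_set(dplyr::filter(genes_el, .data$gene_id %in% ids),
                     bed_path = file.path(out, paste0(lab, ".bed")))
      note(lab, length(ids))
    }
  } else {
    message("[differential] skipped: single condition in sample sheet")
  }

  # --- quantiles (reference condition, defined PIs only) ---
  ref_tab <- dplyr::filter(ptab_el, .data$condition == ref,
                           !is.na(.data$pausing_index))
  defined <- dplyr::group_by(ref_tab, .data$gene_id)
  defined <- dplyr::filter(defined, dplyr::n() ==
                             length(unique(ref_tab$replicate)))
  defined <- dplyr::ungroup(defined)
  quant <- NULL
  if (length(unique(defined$gene_id)) >= config$quantiles) {
    quant <- pausing_quantiles(defined, k = config$quantiles)
    readr::write_tsv(quant, file.path(out, "quantiles.tsv"))
  }

  # --- stratification ---
  binding <- match_res <- breadth <- NULL
  if (!is.null(config$crosslinks)) {
    xlinks <- read_crosslinks(config$crosslinks)
    binding <- assign_promoter_binding(genes_el, xlinks)
    readr::write_tsv(binding, file.path(out, "promoter_binding.tsv"))
    note("bound", sum(binding$bound))
    if (!is.null(config$expression)) {
      expr <- read_expression(config$expression)
      bound_ids <- binding$gene_id[binding$bound]
      pool_ids <- binding$gene_id[!binding$bound]
      if (length(bound_ids) > 0 && length(pool_ids) >= length(bound_ids)) {
        match_res <- match_expression_controls(
          bound_ids, pool_ids, expr, pseudocount = config$match_pseudocount
        )
        readr::write_tsv(match_res$pairs, file.path(out, "matching.tsv"))
        ref_pair <- pairs[[which(vapply(pairs, function(p)
          p$condition == ref, logical(1)))[1]]]
        up <- 0L
        prof_b <- profile_rows(genes_el, bound_ids, ref_pair, up,
                               config$breadth_window)
        prof_c <- profile_rows(genes_el, match_res$controls, ref_pair, up,
                               config$breadth_window)
        breadth <- compare_pausing_breadth(prof_b, prof_c,
                                           window = config$breadth_window,
                                           level = config$breadth_level)
        readr::write_tsv(tidy(breadth), file.path(out, "breadth.tsv"))
      } else {
        message("[stratify] matching skipped: bound/pool sizes unsuitable")
      }
    }
  }

  # --- metaprofiles ---
  profiles <- list()
  for (p in pairs) {
    m <- reference_point_matrix(genes_el, p, anchor = "tss")
    profiles[[p$sample_id]] <- m
    write_profile_matrix(m, file.path(out, paste0("profile_tss_",
                                                  p$sample_id, ".tsv")))
  }
  mean_profiles <- purrr::map_dfr(conditions, function(cond) {
    reps <- profiles[vapply(pairs, function(p) p$condition == cond,
                            logical(1))]
    dplyr::mutate(mean_profile(unname(reps)), condition = cond)
  })
  readr::write_tsv(mean_profiles, file.path(out, "mean_profile_tss.tsv"))

  # --- manifest ---
  inputs <- purrr::compact(config[c("annotation", "sample_sheet",
                                    "chrom_sizes", "crosslinks",
                                    "expression")])
  literature <- c("flank", "promoter_len", "min_len", "min_body_signal",
                  "min_delta", "quantiles")
  params <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    package_version = as.character(utils::packageVersion("polpause")),
    parameters = params,
    parameter_provenance = stats::setNames(
      as.list(ifelse(names(params) %in% literature, "literature",
                     "artifact-default")),
      names(params)
    ),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    filter_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(genes = genes_el, pausing = ptab_el, differential = diff,
                 quantiles = quant, binding = binding, match = match_res,
                 breadth = breadth, profiles = profiles,
                 mean_profiles = mean_profiles, manifest = manifest))
}

# Per-base TSS-anchored profiles for a set of gene ids, as a plain matrix
# with rownames and an `upstream` attribute (consumed by
# compare_pausing_breadth).
profile_rows <- function(genes, ids, pair, upstream, downstream) {
  sub <- genes[match(ids, genes$gene_id), , drop = FALSE]
  m <- t(vapply(seq_len(nrow(sub)), function(i) {
    oriented_profile(pair, sub[i, ], upstream, downstream)
  }, numeric(upstream + downstream)))
  rownames(m) <- ids
  attr(m, "upstream") <- upstream
  m
}
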