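#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-pausing classification
#'
#' @param x A `pausing_diff` from [classify_differential()].
#' @param ... Unused.
#' @return The underlying tibble (one row per gene).
#' @method tidy pausing_diff
#' @export
tidy.pausing_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pausing_diff")
  out
}

#' Summarise a differential-pausing classification
#'
#' @param x A `pausing_diff`.
#' @param ... Unused.
#' @return One-row tibble with the class counts, the conditions compared and
#'   the threshold used.
#' @method glance pausing_diff
#' @export
glance.pausing_diff <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_increased = sum(x$label == "increased"),
    n_decreased = sum(x$label == "decreased"),
    n_unchanged = sum(x$label == "unchanged"),
    n_excluded = sum(x$label == "excluded"),
    ref = attr(x, "ref"), mut = attr(x, "mut"),
    min_delta = attr(x, "min_delta")
  )
}

#' Tidy a pausing-breadth comparison
#'
#' @param x A `breadth_test` from [compare_pausing_breadth()].
#' @param ... Unused.
#' @return Tibble with one row per gene: `group` (`A`/`B`) and `breadth_bp`.
#' @method tidy breadth_test
#' @export
tidy.breadth_test <- function(x, ...) {
  tibble::tibble(
    group = rep(c("A", "B"), c(length(x$breadth_a), length(x$breadth_b))),
    breadth_bp = c(x$breadth_a, x$breadth_b)
  )
}

#' Summarise a pausing-breadth comparison
#'
#' @param x A `breadth_test`.
#' @param ... Unused.
#' @return One-row tibble with the rank-sum statistic, p-value, group
#'   medians and the width-at-fraction parameters.
#' @method glance breadth_test
#' @export
glance.breadth_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value,
    median_a = stats::median(x$breadth_a),
    median_b = stats::median(x$breadth_b),
    n_a = length(x$breadth_a), n_b = length(x$breadth_b),
    n_excluded = x$n_excluded, degenerate = x$degenerate,
    window = x$window, level = x$level
  )
}

#' Tidy a metaprofile matrix into long format
#'
#' @param x A `meta_profile_matrix`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `bin`, `position`, `value` (`position` is `NA`
#'   for scaled body bins).
#' @method tidy meta_profile_matrix
#' @export
tidy.meta_profile_matrix <- function(x, ...) {
  pos <- profile_positions(x)
  tibble::tibble(
    gene_id = rep(rownames(x), each = ncol(x)),
    bin = rep(seq_len(ncol(x)), nrow(x)),
    position = rep(pos, nrow(x)),
    value = as.vector(t(unclass(x)[seq_len(nrow(x)), , drop = FALSE]))
  )
}

#' Plot the mean metaprofile of a matrix
#'
#' @param object A `meta_profile_matrix`.
#' @param ... Unused.
#' @return A ggplot: mean signal per bin with a vertical guide at the anchor
#'   (reference-point mode) or body-boundary guides (scale-regions mode).
#' @method autoplot meta_profile_matrix
#' @export
autoplot.meta_profile_matrix <- function(object, ...) {
  prof <- mean_profile(list(object))
  if (attr(object, "mode") == "reference_point") {
    p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$position,
                                            y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                          colour = "grey50") +
      ggplot2::labs(x = sprintf("distance from %s (bp)",
                                toupper(attr(object, "anchor"))),
                    y = "mean signal")
  } else {
    bs <- attr(object, "bin_size")
    n_up <- attr(object, "upstream") / bs
    bb <- attr(object, "body_bins")
    p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$bin,
                                            y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = c(n_up + 0.5, n_up + bb + 0.5),
                          linetype = "dashed", colour = "grey50") +
      ggplot2::labs(x = "bin (flank | scaled body | flank)",
                    y = "mean signal")
  }
  p + ggplot2::theme_minimal()
}

#' Plot breadth distributions of a pausing-breadth comparison
#'
#' @param object A `breadth_test`.
#' @param ... Unused.
#' @return A ggplot boxplot of per-gene breadths by group.
#' @method autoplot breadth_test
#' @export
autoplot.breadth_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$group, y = .data$breadth_bp)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("pausing breadth (bp at %.0f%% of max, %d bp window)",
                  100 * object$level, object$window)
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean profiles per condition
#'
#' @param profiles Tibble as produced by the `mean_profiles` element of
#'   [run_all()] (columns `position`, `value`, `condition`).
#' @return A ggplot line plot, one line per condition.
#' @export
plot_mean_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$position, y = .data$value,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "distance from TSS (bp)", y = "mean signal",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
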