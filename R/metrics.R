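# Per-sample diversity and clonal-expansion metrics, and the
# reference-cohort-derived threshold separating normal from
# pathological expansion.

#' Inverse Simpson Index
#'
#' \eqn{ISI = 1 / \sum_i p_i^2} with \eqn{p_i} the template-space
#' frequency of clonotype i — the effective number of equally abundant
#' clonotypes. Bounded by 1 (monoclonal) and the richness (perfectly
#' even repertoire).
#'
#' @param table A [clonotype_table] with at least one template.
#' @return The ISI (numeric scalar).
#' @examples
#' inverse_simpson(clonotype_table(c(A = 2L, B = 2L, C = 1L), "S1")) # 25/9
#' @export
inverse_simpson <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  if (table$total_templates < 1) {
    stop("ISI is undefined for an empty clonotype table", call. = FALSE)
  }
  p <- table$data$templates / table$total_templates
  1 / sum(p^2)
}

#' Derive the pathological-expansion threshold from a reference cohort
#'
#' For each reference sample (typically donors plus healthy controls at
#' a common normalized depth) the mean size of its expanded clonotypes
#' (size > 1 template) is computed. The threshold is the upper limit of
#' the t-based confidence interval of the across-sample mean of those
#' means: `upper_ci = mean + t(1-(1-ci_level)/2, n-1) * SE`, and
#' `tau = floor(upper_ci)`. Clonotypes of size strictly greater than
#' `tau` are called pathologically expanded.
#'
#' Reference samples with no expanded clonotype carry no information
#' about expansion size and are excluded with a warning.
#'
#' @param reference List of [clonotype_table] objects at a common depth.
#' @param ci_level Confidence level (default 0.95).
#' @return An object of class `expansion_threshold` with fields
#'   `upper_ci`, `tau`, `reference_n`, `mean_of_means`, `ci_level`.
#' @examples
#' ref <- list(
#'   clonotype_table(c(A = 4L, B = 4L, C = 1L), "r1"),
#'   clonotype_table(c(A = 5L, B = 5L, C = 1L), "r2"),
#'   clonotype_table(c(A = 6L, B = 6L, C = 1L), "r3"))
#' derive_threshold(ref) # per-sample means 4, 5, 6 -> tau = 7
#' @export
derive_threshold <- function(reference, ci_level = 0.95) {
  stopifnot(is.list(reference), ci_level > 0, ci_level < 1)
  means <- vapply(reference, function(t) {
    sizes <- t$data$templates
    expanded <- sizes[sizes > 1L]
    if (length(expanded) == 0) NA_real_ else mean(expanded)
  }, numeric(1))
  unusable <- is.na(means)
  if (any(unusable)) {
    ids <- vapply(reference[unusable], function(t) t$sample_id, character(1))
    warning("excluding ", sum(unusable), " reference sample(s) with no ",
            "expanded clonotype: ", paste(ids, collapse = ", "),
            call. = FALSE)
    means <- means[!unusable]
  }
  n <- length(means)
  if (n < 2) {
    stop("need at least 2 usable reference samples to derive the ",
         "expansion threshold (got ", n, ")", call. = FALSE)
  }
  m <- mean(means)
  se <- stats::sd(means) / sqrt(n)
  upper <- m + stats::qt(1 - (1 - ci_level) / 2, df = n - 1) * se
  tau <- max(1L, as.integer(floor(upper)))
  structure(
    list(upper_ci = upper, tau = tau, reference_n = n,
         mean_of_means = m, ci_level = ci_level),
    class = "expansion_threshold"
  )
}

#' @export
print.expansion_threshold <- function(x, ...) {
  cat(sprintf(
    paste0("<expansion_threshold> tau = %d (upper %.0f%% CI of mean ",
           "expanded-clone size: %.3f; reference mean %.3f over %d ",
           "samples)\n"),
    x$tau, 100 * x$ci_level, x$upper_ci, x$mean_of_means, x$reference_n))
  invisible(x)
}

#' Fix a pathological-expansion threshold by hand
#'
#' Wraps a known cutoff `tau` (e.g. a previously derived cohort value)
#' in an `expansion_threshold` object, for runs that reuse a published
#' threshold instead of deriving one.
#'
#' @param tau Positive integer cutoff; clonotypes with size > `tau` are
#'   pathologically expanded.
#' @return An `expansion_threshold` object.
#' @export
fixed_threshold <- function(tau) {
  stopifnot(is_count(tau))
  structure(
    list(upper_ci = as.numeric(tau), tau = as.integer(tau),
         reference_n = NA_integer_, mean_of_means = NA_real_,
         ci_level = NA_real_),
    class = "expansion_threshold"
  )
}

#' Compute per-sample repertoire metrics
#'
#' Classifies each clonotype of a sample as nonexpanded (1 template),
#' normally expanded (2..tau templates) or pathologically expanded
#' (> tau templates), and summarizes the repertoire: richness, expanded
#' / pathologically expanded / hyperexpanded counts, mean and median
#' expansion sizes, Inverse Simpson Index, and the clonal space
#' occupancy of the three classes (template-space fractions summing
#' to 1).
#'
#' @param table A [clonotype_table].
#' @param threshold An [expansion_threshold] (see [derive_threshold()]).
#' @param hyper_cutoff Hyperexpansion cutoff in templates (default 100):
#'   clonotypes strictly larger are counted as hyperexpanded.
#' @return A one-row data frame with columns `sample_id`, `group`,
#'   `depth`, `richness`, `n_expanded`, `n_path_expanded`,
#'   `n_hyperexpanded`, `mean_expansion_size`,
#'   `mean_path_expansion_size`, `median_path_expansion_size`, `isi`,
#'   `occ_nonexpanded`, `occ_normal`, `occ_pathological`.
#' @export
compute_metrics <- function(table, threshold, hyper_cutoff = 100L) {
  stopifnot(inherits(table, "clonotype_table"),
            inherits(threshold, "expansion_threshold"),
            is_count(hyper_cutoff))
  sizes <- table$data$templates
  if (length(sizes) == 0) {
    stop("cannot compute metrics on an empty clonotype table (sample ",
         table$sample_id, ")", call. = FALSE)
  }
  tau <- threshold$tau
  depth <- table$total_templates
  expanded <- sizes[sizes > 1L]
  path <- sizes[sizes > tau]
  data.frame(
    sample_id = table$sample_id,
    group = table$group,
    depth = depth,
    richness = length(sizes),
    n_expanded = length(expanded),
    n_path_expanded = length(path),
    n_hyperexpanded = sum(sizes > hyper_cutoff),
    mean_expansion_size = if (length(expanded)) mean(expanded) else NA_real_,
    mean_path_expansion_size = if (length(path)) mean(path) else NA_real_,
    median_path_expansion_size =
      if (length(path)) stats::median(path) else NA_real_,
    isi = inverse_simpson(table),
    occ_nonexpanded = sum(sizes[sizes == 1L]) / depth,
    occ_normal = sum(sizes[sizes > 1L & sizes <= tau]) / depth,
    occ_pathological = sum(path) / depth,
    stringsAsFactors = FALSE
  )
}

#' Metrics table for a whole cohort
#'
#' @param cohort List of [clonotype_table] objects.
#' @inheritParams compute_metrics
#' @return A data frame with one row per sample (see [compute_metrics()]).
#' @export
cohort_metrics <- function(cohort, threshold, hyper_cutoff = 100L) {
  stopifnot(length(cohort) > 0)
  do.call(rbind, lapply(cohort, compute_metrics, threshold = threshold,
                        hyper_cutoff = hyper_cutoff))
}

#' Template-space fractions by clonotype rank bin
#'
#' Sorts clonotypes by decreasing size (ties broken by key, so the
#' ranking is reproducible) and reports the fraction of template space
#' held by the rank bins 1-10, 11-100, 101-1000, 1001-10000 and beyond:
#' the footprint of the most expanded versus the rarer clonotypes.
#'
#' @param table A [clonotype_table].
#' @param bins Increasing rank boundaries (default
#'   `c(10, 100, 1000, 10000)`).
#' @return Named numeric vector of per-bin fractions summing to 1.
#' @export
rank_distribution <- function(table, bins = c(10L, 100L, 1000L, 10000L)) {
  stopifnot(inherits(table, "clonotype_table"),
            length(bins) >= 1, all(diff(bins) > 0), all(bins >= 1))
  sizes <- table$data$templates # constructor already sorted by -size, key
  if (length(sizes) == 0) {
    stop("rank distribution is undefined for an empty table", call. = FALSE)
  }
  rank_bin <- findInterval(seq_along(sizes) - 1L, bins) + 1L
  labels <- c(paste0("top", bins[1]),
              if (length(bins) > 1) {
                paste0("top", utils::head(bins, -1) + 1, "_",
                       utils::tail(bins, -1))
              },
              paste0("beyond", bins[length(bins)]))
  out <- stats::setNames(numeric(length(labels)), labels)
  got <- tapply(sizes, rank_bin, sum) / table$total_templates
  out[as.integer(names(got))] <- got
  out
}

#' Fold change of per-category counts against a reference group
#'
#' Element-wise ratio of group means to reference means (e.g. counts of
#' nonexpanded / expanded / pathologically expanded clonotypes in
#' recipients relative to donors). Categories with a zero reference
#' mean have no defined fold change and are returned as `NA` with a
#' warning.
#'
#' @param group_counts Named numeric vector of per-category means for
#'   the group of interest.
#' @param reference_counts Same-named vector for the reference group.
#' @return Named numeric vector of ratios.
#' @export
group_fold_change <- function(group_counts, reference_counts) {
  stopifnot(is.numeric(group_counts), is.numeric(reference_counts),
            length(group_counts) == length(reference_counts))
  if (!is.null(names(group_counts)) && !is.null(names(reference_counts))) {
    stopifnot(identical(names(group_counts), names(reference_counts)))
  }
  undefined <- reference_counts == 0
  if (any(undefined)) {
    warning("fold change undefined for categories with zero reference ",
            "count: ",
            paste(names(group_counts)[undefined] %||%
                    which(undefined), collapse = ", "),
            call. = FALSE)
  }
  out <- group_counts / reference_counts
  out[undefined] <- NA_real_
  out
}
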