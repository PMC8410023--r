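# Pairwise clonotype sharing, the public-clonotype background estimated
# from unrelated pairs, and donor -> recipient origin of shared clones.

size_class_filter <- function(table, size_class, threshold = NULL) {
  switch(size_class,
    all = table$data$clonotype_key,
    expanded = table$data$clonotype_key[table$data$templates > 1L],
    pathological = {
      if (is.null(threshold)) {
        stop("size_class = 'pathological' requires an expansion threshold",
             call. = FALSE)
      }
      table$data$clonotype_key[table$data$templates > threshold$tau]
    },
    stop("unknown size class: ", size_class, call. = FALSE)
  )
}

#' Clonotypes shared between two samples
#'
#' Intersection of clonotype keys after restricting both samples to a
#' size class (`all`, `expanded` = size > 1, `pathological` = size >
#' tau). Symmetric in its two arguments. Size-class comparisons are only
#' meaningful between samples normalized to the same depth, so a depth
#' mismatch is an error for `size_class != "all"`.
#'
#' @param a,b [clonotype_table] objects.
#' @param size_class `"all"` (default), `"expanded"` or `"pathological"`.
#' @param threshold An [expansion_threshold]; required for
#'   `"pathological"`.
#' @return Character vector of shared clonotype keys (sorted).
#' @export
shared_clonotypes <- function(a, b, size_class = c("all", "expanded",
                                                   "pathological"),
                              threshold = NULL) {
  size_class <- match.arg(size_class)
  stopifnot(inherits(a, "clonotype_table"), inherits(b, "clonotype_table"))
  if (size_class != "all" && a$total_templates != b$total_templates) {
    stop("size-class-restricted sharing requires both samples at a ",
         "common depth (", a$total_templates, " vs ", b$total_templates,
         "); normalize first", call. = FALSE)
  }
  sort(intersect(size_class_filter(a, size_class, threshold),
                 size_class_filter(b, size_class, threshold)))
}

#' Pairwise repertoire overlap coefficient
#'
#' Two forms. `count`: the classical overlap coefficient
#' \eqn{|A \cap B| / \min(|A|, |B|)} over clonotype keys. `weighted`:
#' \eqn{\sum_{k \in A \cap B} \min(p_A(k), p_B(k))} over template-space
#' frequencies, which additionally weighs the relative abundance of
#' each shared clonotype. Both are symmetric and lie in [0, 1], with 1
#' attained for identical repertoires.
#'
#' @param a,b Non-empty [clonotype_table] objects.
#' @param method `"count"` (default) or `"weighted"`.
#' @return Numeric scalar in [0, 1].
#' @export
overlap_coefficient <- function(a, b, method = c("count", "weighted")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "clonotype_table"), inherits(b, "clonotype_table"))
  if (nrow(a$data) == 0 || nrow(b$data) == 0) {
    stop("overlap coefficient is undefined for an empty repertoire",
         call. = FALSE)
  }
  shared <- intersect(a$data$clonotype_key, b$data$clonotype_key)
  if (method == "count") {
    length(shared) / min(nrow(a$data), nrow(b$data))
  } else {
    if (length(shared) == 0) return(0)
    pa <- clone_sizes(a)[shared] / a$total_templates
    pb <- clone_sizes(b)[shared] / b$total_templates
    sum(pmin(pa, pb))
  }
}

#' Public-clonotype background from unrelated sample pairs
#'
#' Estimates how much sharing two unrelated individuals show by chance:
#' for every unordered pair of unrelated reference samples at a common
#' depth, the number of shared clonotypes is computed (for all
#' clonotypes, expanded only, and pathologically expanded only); the
#' background fraction per size class is the mean pairwise shared count
#' divided by the mean per-sample richness in that class. An identical
#' cohort therefore yields a background of 1, a pairwise-disjoint one 0.
#'
#' @param reference List of [clonotype_table] objects at a common depth
#'   (at least 2).
#' @param threshold An [expansion_threshold] for the pathological class.
#' @param exclude_pairs Optional two-column data frame (or matrix) of
#'   sample-id pairs to skip, e.g. related donor-recipient pairs.
#' @return An object of class `public_background` with fields
#'   `fraction_all`, `fraction_expanded`, `fraction_path_expanded`,
#'   `n_pairs`.
#' @export
public_background <- function(reference, threshold, exclude_pairs = NULL) {
  stopifnot(is.list(reference), length(reference) >= 2,
            inherits(threshold, "expansion_threshold"))
  depths <- vapply(reference, function(t) t$total_templates, integer(1))
  if (length(unique(depths)) > 1) {
    stop("public background requires all reference samples at a common ",
         "depth; normalize first", call. = FALSE)
  }
  ids <- vapply(reference, function(t) t$sample_id, character(1))
  excluded <- character(0)
  if (!is.null(exclude_pairs)) {
    exclude_pairs <- as.data.frame(exclude_pairs, stringsAsFactors = FALSE)
    stopifnot(ncol(exclude_pairs) >= 2)
    excluded <- c(paste(exclude_pairs[[1]], exclude_pairs[[2]]),
                  paste(exclude_pairs[[2]], exclude_pairs[[1]]))
  }

  classes <- c("all", "expanded", "pathological")
  keysets <- lapply(classes, function(cl) {
    lapply(reference, size_class_filter, size_class = cl,
           threshold = threshold)
  })
  names(keysets) <- classes

  n_pairs <- 0L
  shared_sums <- stats::setNames(numeric(3), classes)
  n <- length(reference)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (paste(ids[i], ids[j]) %in% excluded) next
      n_pairs <- n_pairs + 1L
      for (cl in classes) {
        shared_sums[[cl]] <- shared_sums[[cl]] +
          length(intersect(keysets[[cl]][[i]], keysets[[cl]][[j]]))
      }
    }
  }
  if (n_pairs < 1) {
    stop("no eligible unrelated pair among the reference samples",
         call. = FALSE)
  }
  mean_rich <- vapply(classes, function(cl) {
    mean(lengths(keysets[[cl]]))
  }, numeric(1))
  frac <- ifelse(mean_rich > 0, (shared_sums / n_pairs) / mean_rich, 0)
  structure(
    list(fraction_all = unname(frac[["all"]]),
         fraction_expanded = unname(frac[["expanded"]]),
         fraction_path_expanded = unname(frac[["pathological"]]),
         n_pairs = n_pairs),
    class = "public_background"
  )
}

#' @export
print.public_background <- function(x, ...) {
  cat(sprintf(
    paste0("<public_background> over %d unrelated pairs: all %.4f, ",
           "expanded %.4f, pathological %.4f\n"),
    x$n_pairs, x$fraction_all, x$fraction_expanded,
    x$fraction_path_expanded))
  invisible(x)
}

#' Donor-recipient clonotype overlap, corrected for the public background
#'
#' Quantifies how much of a recipient's post-transplant repertoire is
#' shared with the graft donor at a common depth. The raw
#' `recipient_shared_fraction` (shared clonotypes / recipient richness)
#' still contains sharing expected between any two unrelated
#' individuals; subtracting the public background (see
#' [public_background()]) and flooring at zero gives the
#' `adjusted_fraction` attributable to the graft. The remainder of the
#' recipient repertoire is de novo at the analyzed depth.
#'
#' @param recipient,donor [clonotype_table] objects at a common depth.
#' @param background A `public_background` object, or `NULL` to skip the
#'   correction (background treated as 0).
#' @param threshold Optional [expansion_threshold]; when given,
#'   class-restricted shared fractions and their adjusted versions are
#'   included.
#' @return An object of class `overlap_result` with fields `n_shared`,
#'   `shared_keys`, `oc_count`, `oc_weighted`,
#'   `recipient_shared_fraction`, `adjusted_fraction` (and, with a
#'   threshold, `shared_fraction_expanded` / `_path_expanded` plus
#'   adjusted versions).
#' @export
donor_recipient_overlap <- function(recipient, donor, background = NULL,
                                    threshold = NULL) {
  stopifnot(inherits(recipient, "clonotype_table"),
            inherits(donor, "clonotype_table"))
  if (recipient$total_templates != donor$total_templates) {
    stop("recipient and donor must be normalized to a common depth (",
         recipient$total_templates, " vs ", donor$total_templates, ")",
         call. = FALSE)
  }
  if (!is.null(background)) stopifnot(inherits(background, "public_background"))
  shared <- shared_clonotypes(recipient, donor, "all")
  rsf <- length(shared) / nrow(recipient$data)
  bg_all <- if (is.null(background)) 0 else background$fraction_all
  out <- list(
    recipient_id = recipient$sample_id,
    donor_id = donor$sample_id,
    n_shared = length(shared),
    shared_keys = shared,
    oc_count = overlap_coefficient(recipient, donor, "count"),
    oc_weighted = overlap_coefficient(recipient, donor, "weighted"),
    recipient_shared_fraction = rsf,
    adjusted_fraction = max(0, rsf - bg_all),
    adjusted_fraction_raw = rsf - bg_all # unfloored, kept for inspection
  )
  if (!is.null(threshold)) {
    for (cl in c("expanded", "pathological")) {
      keys_r <- size_class_filter(recipient, cl, threshold)
      keys_d <- size_class_filter(donor, cl, threshold)
      frac <- if (length(keys_r) == 0) {
        0
      } else {
        length(intersect(keys_r, keys_d)) / length(keys_r)
      }
      bg <- if (is.null(background)) {
        0
      } else if (cl == "expanded") {
        background$fraction_expanded
      } else {
        background$fraction_path_expanded
      }
      suffix <- if (cl == "expanded") "expanded" else "path_expanded"
      out[[paste0("shared_fraction_", suffix)]] <- frac
      out[[paste0("adjusted_fraction_", suffix)]] <- max(0, frac - bg)
    }
  }
  structure(out, class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    paste0("<overlap_result> %s vs donor %s: %d shared clonotypes, ",
           "OC(count) %.4f, OC(weighted) %.4f,\n  recipient shared ",
           "fraction %.4f (adjusted for public background: %.4f)\n"),
    x$recipient_id, x$donor_id, x$n_shared, x$oc_count, x$oc_weighted,
    x$recipient_shared_fraction, x$adjusted_fraction))
  invisible(x)
}

#' Origin of recipient clonotypes by expansion class
#'
#' Cross-tabulates every recipient clonotype by its expansion class in
#' the recipient (nonexpanded / normal / pathological) against its
#' status in the paired donor (absent / nonexpanded / normal /
#' pathological), at a common depth. Row sums equal the recipient's
#' class sizes; the "absent" column is the de novo fraction.
#'
#' @param recipient,donor [clonotype_table] objects at a common depth.
#' @param threshold An [expansion_threshold].
#' @return A 3 x 4 integer matrix (rows: recipient class, columns:
#'   donor class).
#' @export
origin_composition <- function(recipient, donor, threshold) {
  stopifnot(inherits(recipient, "clonotype_table"),
            inherits(donor, "clonotype_table"),
            inherits(threshold, "expansion_threshold"))
  if (recipient$total_templates != donor$total_templates) {
    stop("origin composition requires a common depth", call. = FALSE)
  }
  tau <- threshold$tau
  classify <- function(sizes) {
    ifelse(sizes == 1L, "nonexpanded",
           ifelse(sizes <= tau, "normal", "pathological"))
  }
  r_class <- factor(classify(recipient$data$templates),
                    levels = c("nonexpanded", "normal", "pathological"))
  d_sizes <- clone_sizes(donor)[recipient$data$clonotype_key]
  d_class <- factor(
    ifelse(is.na(d_sizes), "absent", classify(d_sizes)),
    levels = c("absent", "nonexpanded", "normal", "pathological"))
  table(recipient = r_class, donor = d_class)
}

#' Rank correlation of shared-clonotype sizes between recipient and donor
#'
#' Spearman rank correlation of clone sizes over clonotypes shared by a
#' recipient-donor pair, testing whether clones expanded in the donor
#' remain expanded in the recipient.
#'
#' @param pairs Two-column matrix or data frame of (recipient size,
#'   donor size) for shared clonotypes, or a list of such pairs; at
#'   least 3 rows.
#' @return Spearman's rho, or `NA` (with a warning) when either margin
#'   is fully tied.
#' @export
expansion_size_correlation <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(pairs) >= 2)
  x <- as.numeric(pairs[[1]])
  y <- as.numeric(pairs[[2]])
  if (length(x) < 3) {
    stop("need at least 3 shared clonotypes for a size correlation",
         call. = FALSE)
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("expansion size correlation undefined: all sizes tied on one ",
            "side", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}
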