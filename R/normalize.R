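# Depth normalization: choose a cohort-wide common depth and subsample
# each sample's templates to it without replacement.

#' Determine the common downsampling depth for a cohort
#'
#' Samples shallower than `min_acceptable` templates are excluded (their
#' ids are reported in a message); the common depth is the minimum total
#' template count among the remaining samples — the "lowest acceptable
#' depth" to which every retained sample can be subsampled without
#' replacement.
#'
#' @param cohort List of [clonotype_table] objects.
#' @param min_acceptable Minimum tolerated sample depth in templates.
#' @return The common depth (positive integer).
#' @export
determine_common_depth <- function(cohort, min_acceptable) {
  stopifnot(length(cohort) > 0, is_count(min_acceptable))
  depths <- vapply(cohort, function(t) t$total_templates, integer(1))
  ids <- vapply(cohort, function(t) t$sample_id, character(1))
  keep <- depths >= min_acceptable
  if (!any(keep)) {
    stop("all ", length(cohort), " samples are below the minimum ",
         "acceptable depth of ", min_acceptable, " templates", call. = FALSE)
  }
  if (any(!keep)) {
    message("excluding ", sum(!keep), " sample(s) below depth ",
            min_acceptable, ": ", paste(ids[!keep], collapse = ", "))
  }
  min(depths[keep])
}

#' Downsample a clonotype table to a fixed template depth
#'
#' Draws `depth` individual templates uniformly at random without
#' replacement from the sample's template pool (multivariate
#' hypergeometric law), so each clonotype's sampled count never exceeds
#' its original count and the output depth is exactly `depth`.
#' Clonotypes reduced to zero templates are dropped. The draw is a
#' deterministic function of `(table, depth, seed)`.
#'
#' Subsampling without replacement mirrors the physical process of
#' sequencing fewer genomic molecules, which is why it is preferred over
#' multinomial resampling here.
#'
#' @param table A [clonotype_table].
#' @param depth Target depth in templates; must not exceed the sample
#'   depth (no upsampling).
#' @param seed Integer seed for this draw.
#' @return A [clonotype_table] at exactly `depth` templates.
#' @examples
#' tab <- clonotype_table(c(CASSLGF = 90L, CASSQEF = 10L), "S1")
#' downsample(tab, 10, seed = 1)
#' @export
downsample <- function(table, depth, seed) {
  stopifnot(inherits(table, "clonotype_table"), is_count(depth))
  n_total <- table$total_templates
  if (depth > n_total) {
    stop("cannot downsample sample ", table$sample_id, " to depth ", depth,
         ": only ", n_total, " templates available (no upsampling)",
         call. = FALSE)
  }
  if (depth == n_total) {
    return(table)
  }
  sizes <- table$data$templates
  # pick `depth` template indices out of 1..N; map each back to its
  # clonotype via the cumulative size boundaries
  picked <- with_seed(seed, sample.int(n_total, depth))
  clone_of <- findInterval(picked, cumsum(sizes), left.open = TRUE) + 1L
  new_sizes <- tabulate(clone_of, nbins = length(sizes))
  keep <- new_sizes > 0L
  clonotype_table(
    stats::setNames(new_sizes[keep], table$data$clonotype_key[keep]),
    sample_id = table$sample_id, group = table$group
  )
}

#' Downsample every sample of a cohort to a common depth
#'
#' Applies [downsample()] to each table using a per-sample seed derived
#' from `master_seed` and the sample id (see [derive_seed()]), so the
#' draw for one sample is unaffected by the presence of others. Samples
#' shallower than `depth` are excluded.
#'
#' @param cohort List of [clonotype_table] objects.
#' @param depth Common target depth.
#' @param master_seed Master seed for the run.
#' @return A list with `tables` (the downsampled cohort) and `manifest`
#'   (data frame: sample_id, group, original_depth, sampled_depth, seed,
#'   included).
#' @export
downsample_cohort <- function(cohort, depth, master_seed) {
  stopifnot(length(cohort) > 0, is_count(depth))
  ids <- vapply(cohort, function(t) t$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  depths <- vapply(cohort, function(t) t$total_templates, integer(1))
  seeds <- vapply(ids, derive_seed, integer(1), master_seed = master_seed)
  included <- depths >= depth
  tables <- vector("list", sum(included))
  names(tables) <- ids[included]
  j <- 0L
  for (i in which(included)) {
    j <- j + 1L
    tables[[j]] <- downsample(cohort[[i]], depth, seeds[[i]])
  }
  manifest <- data.frame(
    sample_id = ids,
    group = vapply(cohort, function(t) t$group, character(1)),
    original_depth = depths,
    sampled_depth = ifelse(included, depth, NA_integer_),
    seed = unname(seeds),
    included = included,
    stringsAsFactors = FALSE
  )
  list(tables = tables, manifest = manifest)
}
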