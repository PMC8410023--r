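# CDR3 specificity annotation: aggregate VDJdb/McPAS-style reference
# tables, match clonotypes by exact amino-acid CDR3, and summarize the
# annotated repertoire per disease category.

SPECIFICITY_CATEGORIES <- c("pathogen", "cancer", "autoimmune", "allergy",
                            "other")

DEFAULT_REFERENCE_COLUMNS <- c(cdr3 = "cdr3", epitope = "antigen_epitope",
                               antigen_source = "antigen_species",
                               category = "category", disease = "disease",
                               provenance = "source")

#' Build an aggregated CDR3-specificity reference
#'
#' Unions one or more annotation tables (TSV paths or data frames) into
#' a single reference mapping CDR3 amino-acid sequences to known
#' specificities. Each source may declare a `column_map` translating its
#' column names onto the canonical schema (`cdr3`, `antigen_epitope`,
#' `antigen_species`, `category`, `disease`, `source`) and a
#' `category_map` translating its disease-category labels onto the
#' canonical categories (pathogen, cancer, autoimmune, allergy, other).
#' Exact duplicate (cdr3, epitope, provenance) triples are collapsed;
#' per-source entry counts are reported.
#'
#' @param sources List of sources; each either a path / data frame, or a
#'   list with fields `data` (path or data frame), `column_map` (named
#'   character vector, canonical name -> source column) and
#'   `category_map` (named character vector, source label -> canonical
#'   category).
#' @return An object of class `specificity_reference`: a data frame of
#'   entries with columns `cdr3_aa`, `epitope`, `antigen_source`,
#'   `category`, `disease`, `provenance`.
#' @export
build_reference <- function(sources) {
  stopifnot(is.list(sources))
  if (length(sources) == 0) {
    warning("no specificity sources given; reference is empty",
            call. = FALSE)
    return(empty_reference())
  }
  parts <- lapply(seq_along(sources), function(i) {
    src <- sources[[i]]
    if (!is.list(src) || is.data.frame(src)) src <- list(data = src)
    df <- src$data
    if (is.character(df)) {
      df <- utils::read.delim(df, sep = "\t", header = TRUE,
                              colClasses = "character", quote = "",
                              stringsAsFactors = FALSE)
    }
    cols <- DEFAULT_REFERENCE_COLUMNS
    if (!is.null(src$column_map)) cols[names(src$column_map)] <- src$column_map
    missing_cols <- setdiff(unname(cols), names(df))
    if (length(missing_cols) > 0) {
      stop("specificity source ", i, " lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    category_raw <- df[[cols[["category"]]]]
    category <- category_raw
    if (!is.null(src$category_map)) {
      mapped <- src$category_map[category]
      mapped[is.na(mapped)] <- category[is.na(mapped)]
      category <- unname(mapped)
    }
    category <- tolower(category)
    bad <- unique(category_raw[!(category %in% SPECIFICITY_CATEGORIES)])
    if (length(bad) > 0) {
      stop("specificity source ", i, " contains unmapped category ",
           "label(s): ", paste(bad, collapse = ", "),
           "; provide a category_map onto ",
           paste(SPECIFICITY_CATEGORIES, collapse = "/"), call. = FALSE)
    }
    out <- data.frame(
      cdr3_aa = toupper(df[[cols[["cdr3"]]]]),
      epitope = df[[cols[["epitope"]]]],
      antigen_source = df[[cols[["antigen_source"]]]],
      category = category,
      disease = df[[cols[["disease"]]]],
      provenance = df[[cols[["provenance"]]]],
      stringsAsFactors = FALSE
    )
    message(sprintf("specificity source %d: %d entries", i, nrow(out)))
    out
  })
  entries <- do.call(rbind, parts)
  dup <- duplicated(entries[, c("cdr3_aa", "epitope", "provenance")])
  entries <- entries[!dup, , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, class = c("specificity_reference", "data.frame"))
}

empty_reference <- function() {
  structure(
    data.frame(cdr3_aa = character(), epitope = character(),
               antigen_source = character(), category = character(),
               disease = character(), provenance = character(),
               stringsAsFactors = FALSE),
    class = c("specificity_reference", "data.frame")
  )
}

#' Restrict a specificity reference to entries matching a pattern
#'
#' Convenience filter, e.g. `filter_reference(ref, "CMV")` for the
#' cytomegalovirus subset used in anti-CMV clonotype tracking.
#'
#' @param ref A `specificity_reference`.
#' @param pattern Regular expression matched (case-insensitively)
#'   against `antigen_source` and `disease`.
#' @return The restricted `specificity_reference`.
#' @export
filter_reference <- function(ref, pattern) {
  stopifnot(inherits(ref, "specificity_reference"))
  keep <- grepl(pattern, ref$antigen_source, ignore.case = TRUE) |
    grepl(pattern, ref$disease, ignore.case = TRUE)
  structure(ref[keep, , drop = FALSE],
            class = c("specificity_reference", "data.frame"))
}

#' Annotate a clonotype table against a specificity reference
#'
#' Matches clonotypes to reference entries by exact CDR3 amino-acid
#' identity (no fuzzy matching). A clonotype may match several entries
#' and so carry several categories; clonotypes with no match get a
#' single row with category `"unknown"`. Annotation is a pure function
#' of its inputs.
#'
#' @param table A [clonotype_table] keyed by amino-acid CDR3.
#' @param ref A `specificity_reference` (see [build_reference()]).
#' @return A long-format data frame with one row per (clonotype,
#'   annotation): columns `sample_id`, `clonotype_key`, `templates`,
#'   `category`, `epitope`, `antigen_source`, `disease`, `provenance`.
#' @export
annotate <- function(table, ref) {
  stopifnot(inherits(table, "clonotype_table"),
            inherits(ref, "specificity_reference"))
  hits <- merge(
    data.frame(clonotype_key = table$data$clonotype_key,
               templates = table$data$templates, stringsAsFactors = FALSE),
    as.data.frame(ref),
    by.x = "clonotype_key", by.y = "cdr3_aa", all.x = TRUE, sort = FALSE
  )
  hits$category[is.na(hits$category)] <- "unknown"
  out <- data.frame(
    sample_id = table$sample_id,
    clonotype_key = hits$clonotype_key,
    templates = hits$templates,
    category = hits$category,
    epitope = hits$epitope,
    antigen_source = hits$antigen_source,
    disease = hits$disease,
    provenance = hits$provenance,
    stringsAsFactors = FALSE
  )
  out[order(-out$templates, out$clonotype_key, out$category,
            method = "radix"), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Summarize annotated clonotypes per disease category
#'
#' For each canonical category: the number of distinct annotated
#' clonotypes, their mean clone size (templates), and their share of
#' template space. Clonotypes carrying k categories contribute to each
#' of the k categories, so category rows may double-count clonotypes
#' (the per-category view, not a partition). The overall annotated
#' fraction is reported both as a fraction of clonotypes and of
#' template space.
#'
#' @param annotated Long-format annotation table from [annotate()].
#' @param threshold Optional [expansion_threshold]; when given, the
#'   per-category count of pathologically expanded clonotypes is added.
#' @return A list with `by_category` (data frame: category,
#'   n_clonotypes, mean_size, template_fraction, and optionally
#'   n_path_expanded) and scalars `annotated_fraction_clonotypes`,
#'   `annotated_fraction_templates`.
#' @export
category_summary <- function(annotated, threshold = NULL) {
  stopifnot(is.data.frame(annotated),
            all(c("clonotype_key", "templates", "category") %in%
                  names(annotated)))
  per_clone <- annotated[!duplicated(annotated$clonotype_key),
                         c("clonotype_key", "templates")]
  depth <- sum(per_clone$templates)
  richness <- nrow(per_clone)

  rows <- lapply(SPECIFICITY_CATEGORIES, function(cat) {
    sub <- annotated[annotated$category == cat, , drop = FALSE]
    sub <- sub[!duplicated(sub$clonotype_key), , drop = FALSE]
    data.frame(
      category = cat,
      n_clonotypes = nrow(sub),
      mean_size = if (nrow(sub)) mean(sub$templates) else NA_real_,
      template_fraction = if (depth > 0) sum(sub$templates) / depth else 0,
      n_path_expanded = if (is.null(threshold)) {
        NA_integer_
      } else {
        sum(sub$templates > threshold$tau)
      },
      stringsAsFactors = FALSE
    )
  })
  by_category <- do.call(rbind, rows)
  if (is.null(threshold)) by_category$n_path_expanded <- NULL

  known <- annotated[annotated$category != "unknown", , drop = FALSE]
  known <- known[!duplicated(known$clonotype_key), , drop = FALSE]
  list(
    by_category = by_category,
    annotated_fraction_clonotypes =
      if (richness > 0) nrow(known) / richness else 0,
    annotated_fraction_templates =
      if (depth > 0) sum(known$templates) / depth else 0
  )
}

#' Track a specificity category across timepoints
#'
#' Longitudinal view of one category (e.g. pathogen-associated
#' clonotypes) over an ordered series of samples from one individual:
#' the number of distinct matching clonotypes and their mean clone size
#' at each timepoint. Anti-CMV tracking is conventionally run on
#' non-normalized tables so that no clonotype is lost to downsampling;
#' pass the raw tables for that use.
#'
#' @param samples Ordered named list of [clonotype_table] objects (names
#'   are timepoint labels; unnamed lists get the sample ids).
#' @param ref A `specificity_reference` applied to every sample.
#' @param category Canonical category to track.
#' @return Data frame with columns `timepoint`, `n_clonotypes`,
#'   `mean_size` (`NA` when the category is absent, with n = 0).
#' @export
track_category_over_time <- function(samples, ref, category) {
  stopifnot(is.list(samples), length(samples) > 0,
            inherits(ref, "specificity_reference"),
            category %in% SPECIFICITY_CATEGORIES)
  labels <- names(samples) %||%
    vapply(samples, function(t) t$sample_id, character(1))
  rows <- lapply(seq_along(samples), function(i) {
    ann <- annotate(samples[[i]], ref)
    sub <- ann[ann$category == category, , drop = FALSE]
    sub <- sub[!duplicated(sub$clonotype_key), , drop = FALSE]
    data.frame(timepoint = labels[[i]],
               n_clonotypes = nrow(sub),
               mean_size = if (nrow(sub)) mean(sub$templates) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count distinct CMV-associated clonotypes in a sample
#'
#' Number of distinct clonotypes of the sample carrying at least one
#' annotation in a CMV-restricted reference. Run on the non-normalized
#' table by default so that rare anti-CMV clonotypes are not lost to
#' downsampling; duplicate annotations of one clonotype count once.
#'
#' @param table A [clonotype_table] (typically non-normalized).
#' @param cmv_ref A `specificity_reference` restricted to CMV entries
#'   (see [filter_reference()]).
#' @return Integer count of distinct CMV-associated clonotypes.
#' @export
cmv_clonotype_count <- function(table, cmv_ref) {
  stopifnot(inherits(table, "clonotype_table"),
            inherits(cmv_ref, "specificity_reference"))
  length(intersect(table$data$clonotype_key, unique(cmv_ref$cdr3_aa)))
}
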