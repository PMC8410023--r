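# Ingestion of rearrangement tables (ImmunoSEQ export and AIRR
# Rearrangement TSV dialects) into canonical per-sample clonotype tables.

IMMUNOSEQ_COLUMNS <- c(cdr3_nt = "rearrangement", cdr3_aa = "amino_acid",
                       v_gene = "v_resolved", j_gene = "j_resolved",
                       templates = "templates", frame = "frame_type")
AIRR_COLUMNS <- c(cdr3_nt = "junction", cdr3_aa = "junction_aa",
                  v_gene = "v_call", j_gene = "j_call",
                  templates = "duplicate_count", frame = "productive")

#' Read a rearrangement table
#'
#' Parses an ImmunoSEQ-style export or an AIRR Rearrangement TSV into a
#' data frame of rearrangement records, one row per rearrangement. The
#' abundance unit is the genomic template: `templates` counts sequenced
#' DNA molecules carrying the rearrangement.
#'
#' Frame status is taken from `frame_type` (`In`/`Out`/`Stop`) for the
#' ImmunoSEQ dialect. For AIRR input, `productive == TRUE` maps to
#' `in_frame`; non-productive rows map to `has_stop` when a truthy
#' `stop_codon` column is present and to `out_of_frame` otherwise.
#'
#' @param path Path to a tab-separated rearrangement file with one header
#'   row.
#' @param dialect `"immunoseq_v2"`, `"airr"`, or `"auto"` (default), in
#'   which case the dialect is detected from the header.
#' @return A data frame with columns `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `templates` (positive integer) and `frame_status`
#'   (`in_frame`, `out_of_frame`, `has_stop`).
#' @seealso [filter_productive()], [aggregate_clonotypes()]
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste("rearrangement", "amino_acid", "v_resolved", "j_resolved",
#'         "templates", "frame_type", sep = "\t"),
#'   paste("TGTGCCAGC", "CASSLGF", "TCRBV05-01", "TCRBJ02-01", "10", "In",
#'         sep = "\t")), tsv)
#' read_rearrangements(tsv)
#' @export
read_rearrangements <- function(path,
                                dialect = c("auto", "immunoseq_v2", "airr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("rearrangement file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  header <- names(raw)
  if (dialect == "auto") {
    dialect <- detect_dialect(header, path)
  }
  cols <- switch(dialect, immunoseq_v2 = IMMUNOSEQ_COLUMNS,
                 airr = AIRR_COLUMNS)
  missing_cols <- setdiff(unname(cols), header)
  if (length(missing_cols) > 0) {
    stop("file ", path, " is not a valid '", dialect,
         "' table: missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("rearrangement file has a header but zero rows: ", path,
            call. = FALSE)
    return(empty_rearrangements())
  }

  templates_chr <- raw[[cols[["templates"]]]]
  templates <- suppressWarnings(as.numeric(templates_chr))
  bad_parse <- is.na(templates) | templates != floor(templates)
  if (any(bad_parse)) {
    stop("non-integer template count ", sQuote(templates_chr[bad_parse][1]),
         " at line ", which(bad_parse)[1] + 1L, " of ", path, call. = FALSE)
  }
  nonpositive <- templates < 1
  if (any(nonpositive)) {
    stop("rejected row with template count < 1 at line ",
         which(nonpositive)[1] + 1L, " of ", path,
         " (template counts are molecule counts and must be >= 1)",
         call. = FALSE)
  }

  frame_status <- if (dialect == "immunoseq_v2") {
    frame_from_immunoseq(raw[[cols[["frame"]]]])
  } else {
    frame_from_airr(raw[[cols[["frame"]]]],
                    if ("stop_codon" %in% header) raw[["stop_codon"]])
  }

  out <- data.frame(
    cdr3_nt = toupper(raw[[cols[["cdr3_nt"]]]]),
    cdr3_aa = toupper(raw[[cols[["cdr3_aa"]]]]),
    v_gene = raw[[cols[["v_gene"]]]],
    j_gene = raw[[cols[["j_gene"]]]],
    templates = as.integer(templates),
    frame_status = frame_status,
    stringsAsFactors = FALSE
  )
  message(sprintf("read %d rearrangement rows from %s (%s dialect)",
                  nrow(out), basename(path), dialect))
  out
}

empty_rearrangements <- function() {
  data.frame(cdr3_nt = character(), cdr3_aa = character(),
             v_gene = character(), j_gene = character(),
             templates = integer(), frame_status = character(),
             stringsAsFactors = FALSE)
}

detect_dialect <- function(header, path) {
  if (all(unname(IMMUNOSEQ_COLUMNS) %in% header)) return("immunoseq_v2")
  if (all(unname(AIRR_COLUMNS) %in% header)) return("airr")
  stop("cannot auto-detect dialect of ", path,
       ": header matches neither the ImmunoSEQ export nor the AIRR ",
       "Rearrangement schema", call. = FALSE)
}

frame_from_immunoseq <- function(x) {
  idx <- match(tolower(trimws(x)), c("in", "out", "stop"))
  if (anyNA(idx)) {
    stop("unknown frame_type value ", sQuote(x[is.na(idx)][1]),
         " (expected In/Out/Stop)", call. = FALSE)
  }
  c("in_frame", "out_of_frame", "has_stop")[idx]
}

frame_from_airr <- function(productive, stop_codon = NULL) {
  prod <- tolower(trimws(productive)) %in% c("t", "true", "1", "yes")
  out <- ifelse(prod, "in_frame", "out_of_frame")
  if (!is.null(stop_codon)) {
    has_stop <- tolower(trimws(stop_codon)) %in% c("t", "true", "1", "yes")
    out[!prod & has_stop] <- "has_stop"
  }
  out
}

#' Keep only productive rearrangements
#'
#' A rearrangement is productive when it is in frame and its CDR3
#' translation contains no stop codon; only these contribute to
#' clonotype tables. Input order is preserved and the operation is
#' idempotent.
#'
#' @param records Data frame of rearrangement records as returned by
#'   [read_rearrangements()].
#' @return The subset of productive records.
#' @export
filter_productive <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("cdr3_aa", "templates", "frame_status") %in% names(records)))
  keep <- records$frame_status == "in_frame" &
    nzchar(records$cdr3_aa) &
    !grepl("*", records$cdr3_aa, fixed = TRUE)
  records[keep, , drop = FALSE]
}

#' Aggregate productive rearrangements into a clonotype table
#'
#' Collapses rearrangements to clonotypes. By default the clonotype key
#' is the CDR3 amino-acid sequence alone, so nucleotide rearrangements
#' converging on the same amino-acid CDR3 are merged by summing their
#' template counts; `key = "aa_vgene"` appends the V-gene call for
#' sensitivity analyses.
#'
#' @param records Data frame of productive rearrangement records.
#' @param sample_id Sample identifier stored on the table.
#' @param group Sample group, one of `healthy_control`, `donor`,
#'   `recipient_pre`, `recipient_d30`, `recipient_d100`,
#'   `recipient_d180`, `other`.
#' @param key `"aa"` (default) or `"aa_vgene"`.
#' @return A [clonotype_table] object.
#' @export
aggregate_clonotypes <- function(records, sample_id, group = "other",
                                 key = c("aa", "aa_vgene")) {
  key <- match.arg(key)
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0 && any(records$frame_status != "in_frame")) {
    stop("aggregate_clonotypes() expects productive records; ",
         "run filter_productive() first", call. = FALSE)
  }
  keys <- if (key == "aa") {
    records$cdr3_aa
  } else {
    paste(records$cdr3_aa, records$v_gene, sep = "|")
  }
  sizes <- if (length(keys) == 0) {
    integer(0)
  } else {
    tapply(records$templates, keys, sum)
  }
  clonotype_table(stats::setNames(as.integer(sizes), names(sizes)),
                  sample_id = sample_id, group = group)
}

SAMPLE_GROUPS <- c("healthy_control", "donor", "recipient_pre",
                   "recipient_d30", "recipient_d100", "recipient_d180",
                   "other")

#' Construct a clonotype table
#'
#' The canonical per-sample container: unique CDR3 clonotype keys with
#' their template counts (clone sizes). Rows are stored sorted by
#' decreasing size, ties broken by key, so tables are deterministic and
#' two tables with the same content are identical.
#'
#' @param sizes Named integer vector: names are clonotype keys (CDR3
#'   amino-acid strings), values are template counts (all >= 1).
#' @param sample_id Sample identifier.
#' @param group Sample group label; see [aggregate_clonotypes()].
#' @return An object of class `clonotype_table` with fields `sample_id`,
#'   `group`, `data` (data frame `clonotype_key`, `templates`) and
#'   `total_templates`.
#' @examples
#' clonotype_table(c(CASSLGF = 5L, CASSQEF = 1L), "S1", "donor")
#' @export
clonotype_table <- function(sizes, sample_id, group = "other") {
  group <- match.arg(group, SAMPLE_GROUPS)
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  if (length(sizes) > 0) {
    if (is.null(names(sizes)) || anyNA(names(sizes)) ||
        any(!nzchar(names(sizes)))) {
      stop("clonotype sizes must be named by clonotype key", call. = FALSE)
    }
    sizes <- sizes[order(-sizes, names(sizes), method = "radix")]
  }
  keys <- names(sizes)
  if (length(sizes) > 0) {
    if (anyDuplicated(keys)) {
      stop("duplicate clonotype keys in table for sample ", sample_id,
           call. = FALSE)
    }
    if (any(sizes < 1)) {
      stop("all clonotype template counts must be >= 1", call. = FALSE)
    }
  }
  structure(
    list(sample_id = sample_id, group = group,
         data = data.frame(clonotype_key = as.character(keys %||% character()),
                           templates = as.integer(sizes),
                           row.names = NULL, stringsAsFactors = FALSE),
         total_templates = as.integer(sum(sizes))),
    class = "clonotype_table"
  )
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf(
    "<clonotype_table> sample %s (%s): %d clonotypes, %d templates\n",
    x$sample_id, x$group, nrow(x$data), x$total_templates))
  if (nrow(x$data) > 0) {
    utils::head(x$data, 5) |> print(row.names = FALSE)
    if (nrow(x$data) > 5) cat("  ...\n")
  }
  invisible(x)
}

clone_sizes <- function(table) {
  stats::setNames(table$data$templates, table$data$clonotype_key)
}

#' Write / read the canonical clonotype TSV
#'
#' The on-disk interchange format: UTF-8, tab-separated, one header row,
#' columns `sample_id`, `clonotype_key`, `templates`. Writing then
#' re-reading a table reproduces it exactly.
#'
#' @param table A [clonotype_table].
#' @param path Output (or input) file path.
#' @return `write_clonotype_table()` returns `path` invisibly;
#'   `read_clonotype_table()` returns a [clonotype_table].
#' @export
write_clonotype_table <- function(table, path) {
  stopifnot(inherits(table, "clonotype_table"))
  df <- data.frame(sample_id = table$sample_id,
                   clonotype_key = table$data$clonotype_key,
                   templates = table$data$templates,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_clonotype_table
#' @param group Group label to attach on read (the canonical TSV does
#'   not carry it).
#' @export
read_clonotype_table <- function(path, group = "other") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"),
                          quote = "", stringsAsFactors = FALSE)
  required <- c("sample_id", "clonotype_key", "templates")
  if (!all(required %in% names(df))) {
    stop("not a canonical clonotype TSV (need columns ",
         paste(required, collapse = ", "), "): ", path, call. = FALSE)
  }
  sample_id <- unique(df$sample_id)
  if (length(sample_id) > 1) {
    stop("canonical clonotype TSV must contain a single sample: ", path,
         call. = FALSE)
  }
  if (length(sample_id) == 0) sample_id <- tools::file_path_sans_ext(basename(path))
  clonotype_table(stats::setNames(df$templates, df$clonotype_key),
                  sample_id = sample_id, group = group)
}
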