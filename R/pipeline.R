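# End-to-end orchestration: ingest (or simulate) -> normalize ->
# threshold -> metrics -> overlap -> annotate -> HED -> export, with a
# deterministic run manifest and a JSON-lines stage log.

#' Assemble a pipeline run configuration
#'
#' Two input modes. `synthetic`: the cohort is generated by
#' [generate_cohort()] from `cohort` (a [cohort_config]). `tsv`: canonical
#' clonotype TSVs are read from `input_dir`, with a `samples` manifest
#' (TSV or data frame: `sample_id`, `group`, `file`) and a `pairing`
#' manifest (`recipient_id`, `donor_id`, `timepoint`). A fixed `tau` and
#' a derived threshold are mutually exclusive: when `tau` is `NULL` the
#' threshold is derived from the healthy-control plus donor samples.
#'
#' @param out_dir Output directory for all stage TSVs and the manifest.
#' @param mode `"synthetic"` or `"tsv"`.
#' @param cohort A [cohort_config] (synthetic mode).
#' @param input_dir,samples,pairing TSV-mode inputs.
#' @param reference A `specificity_reference`, a list of sources for
#'   [build_reference()], or `NULL` (synthetic mode supplies its own).
#' @param min_acceptable Minimum acceptable sample depth (default 5420
#'   templates, a conventional lower bound for repertoire comparisons).
#' @param tau Optional fixed pathological-expansion cutoff.
#' @param hyper_cutoff Hyperexpansion cutoff (templates).
#' @param seed Master seed for downsampling draws.
#' @param hla Optional list with `allele_fasta` and `genotypes` (TSV
#'   path or data frame) for the HED stage.
#' @param cmv_on_raw Track CMV-associated clonotypes on non-normalized
#'   tables (default `TRUE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       mode = c("synthetic", "tsv"),
                       cohort = cohort_config(),
                       input_dir = NULL, samples = NULL, pairing = NULL,
                       reference = NULL,
                       min_acceptable = 5420L,
                       tau = NULL,
                       hyper_cutoff = 100L,
                       seed = 1L,
                       hla = NULL,
                       cmv_on_raw = TRUE) {
  mode <- match.arg(mode)
  if (mode == "tsv") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("tsv mode requires an existing input_dir", call. = FALSE)
    }
    if (is.null(samples)) {
      stop("tsv mode requires a samples manifest", call. = FALSE)
    }
  }
  if (!is.null(tau)) stopifnot(is_count(tau))
  if (!is.null(hla)) {
    stopifnot(is.list(hla), !is.null(hla$allele_fasta),
              !is.null(hla$genotypes))
    if (!file.exists(hla$allele_fasta)) {
      stop("HLA allele FASTA not found: ", hla$allele_fasta, call. = FALSE)
    }
  }
  structure(
    list(out_dir = out_dir, mode = mode, cohort = cohort,
         input_dir = input_dir, samples = samples, pairing = pairing,
         reference = reference, min_acceptable = as.integer(min_acceptable),
         tau = tau, hyper_cutoff = as.integer(hyper_cutoff),
         seed = as.integer(seed), hla = hla,
         cmv_on_raw = isTRUE(cmv_on_raw)),
    class = "run_config"
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full repertoire pipeline
#'
#' Executes all stages in dependency order, writes one plain TSV (or
#' JSON) per stage into `config$out_dir`, and finishes with a
#' deterministic `run_manifest.json` recording seeds, record counts and
#' the MD5 of every output, so an unchanged configuration reproduces
#' byte-identical outputs and an identical manifest. Per-stage timings
#' go to `log.jsonl` (not part of the manifest).
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort_raw`, `normalized`, `threshold`, `metrics`, `background`,
#'   `overlap`, `annotation`, `cmv`, `hed`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  outputs <- character(0)
  t_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    cat(jsonlite::toJSON(list(stage = stage,
                              elapsed_s = round(proc.time()[["elapsed"]] -
                                                  t0, 3)),
                         auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
    res
  }

  # -- ingest ---------------------------------------------------------
  ing <- t_stage("ingest", ingest_stage(config))
  raw <- ing$tables
  pairing <- ing$pairing
  reference <- ing$reference

  if (!is.null(pairing) && nrow(pairing) > 0) {
    missing_ids <- setdiff(c(pairing$recipient_id, pairing$donor_id),
                           names(raw))
    if (length(missing_ids) > 0) {
      stop("pairing manifest names samples absent from the cohort: ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           call. = FALSE)
    }
  }

  # -- normalize ------------------------------------------------------
  norm <- t_stage("normalize", {
    depth <- determine_common_depth(raw, config$min_acceptable)
    ds <- downsample_cohort(raw, depth, config$seed)
    ds$depth <- depth
    ds
  })
  outputs <- c(outputs,
               write_tsv(norm$manifest,
                         file.path(config$out_dir,
                                   "normalization_manifest.tsv")))

  groups <- vapply(norm$tables, function(t) t$group, character(1))
  reference_set <- norm$tables[groups %in% c("healthy_control", "donor")]

  # -- threshold ------------------------------------------------------
  threshold <- t_stage("threshold", {
    if (!is.null(config$tau)) {
      fixed_threshold(config$tau)
    } else {
      if (length(reference_set) < 2) {
        stop("threshold derivation needs >= 2 healthy-control/donor ",
             "samples; supply a fixed tau instead", call. = FALSE)
      }
      derive_threshold(reference_set)
    }
  })
  jsonlite::write_json(
    list(tau = threshold$tau, upper_ci = threshold$upper_ci,
         mean_of_means = threshold$mean_of_means,
         reference_n = threshold$reference_n,
         ci_level = threshold$ci_level),
    file.path(config$out_dir, "threshold.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  outputs <- c(outputs, file.path(config$out_dir, "threshold.json"))

  # -- metrics --------------------------------------------------------
  metrics <- t_stage("metrics",
                     cohort_metrics(norm$tables, threshold,
                                    config$hyper_cutoff))
  outputs <- c(outputs,
               write_tsv(metrics, file.path(config$out_dir, "metrics.tsv")))

  # -- overlap --------------------------------------------------------
  background <- NULL
  overlap_tab <- NULL
  if (!is.null(pairing) && nrow(pairing) > 0) {
    res <- t_stage("overlap", {
      bg <- public_background(reference_set, threshold)
      rows <- lapply(seq_len(nrow(pairing)), function(i) {
        rid <- pairing$recipient_id[i]
        did <- pairing$donor_id[i]
        if (!(rid %in% names(norm$tables)) ||
            !(did %in% names(norm$tables))) {
          return(NULL) # excluded at normalization
        }
        ov <- donor_recipient_overlap(norm$tables[[rid]],
                                      norm$tables[[did]],
                                      background = bg,
                                      threshold = threshold)
        data.frame(recipient_id = rid, donor_id = did,
                   timepoint = pairing$timepoint[i],
                   n_shared = ov$n_shared,
                   oc_count = ov$oc_count,
                   oc_weighted = ov$oc_weighted,
                   recipient_shared_fraction = ov$recipient_shared_fraction,
                   adjusted_fraction = ov$adjusted_fraction,
                   shared_fraction_expanded = ov$shared_fraction_expanded,
                   shared_fraction_path_expanded =
                     ov$shared_fraction_path_expanded,
                   stringsAsFactors = FALSE)
      })
      list(background = bg, table = do.call(rbind, rows))
    })
    background <- res$background
    overlap_tab <- res$table
    jsonlite::write_json(
      list(fraction_all = background$fraction_all,
           fraction_expanded = background$fraction_expanded,
           fraction_path_expanded = background$fraction_path_expanded,
           n_pairs = background$n_pairs),
      file.path(config$out_dir, "public_background.json"),
      auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(config$out_dir,
                                    "public_background.json"))
    if (!is.null(overlap_tab)) {
      outputs <- c(outputs,
                   write_tsv(overlap_tab,
                             file.path(config$out_dir, "overlap.tsv")))
    }
  }

  # -- annotate -------------------------------------------------------
  annotation <- NULL
  cmv <- NULL
  if (!is.null(reference) && nrow(reference) > 0) {
    annotation <- t_stage("annotate", {
      rows <- lapply(norm$tables, function(tab) {
        summ <- category_summary(annotate(tab, reference), threshold)
        cbind(data.frame(sample_id = tab$sample_id, group = tab$group,
                         annotated_fraction_clonotypes =
                           summ$annotated_fraction_clonotypes,
                         annotated_fraction_templates =
                           summ$annotated_fraction_templates,
                         stringsAsFactors = FALSE),
              stats::setNames(
                as.list(summ$by_category$n_clonotypes),
                paste0("n_", summ$by_category$category)))
      })
      do.call(rbind, rows)
    })
    rownames(annotation) <- NULL
    outputs <- c(outputs,
                 write_tsv(annotation,
                           file.path(config$out_dir,
                                     "annotation_summary.tsv")))
    cmv_ref <- filter_reference(reference, "CMV")
    cmv_tables <- if (config$cmv_on_raw) raw else norm$tables
    cmv <- t_stage("cmv", data.frame(
      sample_id = vapply(cmv_tables, function(t) t$sample_id, character(1)),
      group = vapply(cmv_tables, function(t) t$group, character(1)),
      n_cmv_clonotypes = vapply(cmv_tables, cmv_clonotype_count,
                                integer(1), cmv_ref = cmv_ref),
      stringsAsFactors = FALSE))
    rownames(cmv) <- NULL
    outputs <- c(outputs,
                 write_tsv(cmv, file.path(config$out_dir,
                                          "cmv_counts.tsv")))
  }

  # -- hed ------------------------------------------------------------
  hed <- NULL
  if (!is.null(config$hla)) {
    hed <- t_stage("hed", {
      db <- read_allele_db(config$hla$allele_fasta)
      hed_table(config$hla$genotypes, db)
    })
    outputs <- c(outputs,
                 write_tsv(hed, file.path(config$out_dir, "hed.tsv")))
  }

  # -- manifest -------------------------------------------------------
  manifest <- list(
    package = "tcrdyn",
    package_version = as.character(utils::packageVersion("tcrdyn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = config$mode,
    seed = config$seed,
    common_depth = norm$depth,
    tau = threshold$tau,
    n_samples_in = length(raw),
    n_samples_normalized = length(norm$tables),
    files = lapply(stats::setNames(outputs, basename(outputs)),
                   function(f) list(md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort_raw = raw, normalized = norm,
                 threshold = threshold, metrics = metrics,
                 background = background, overlap = overlap_tab,
                 annotation = annotation, cmv = cmv, hed = hed,
                 manifest = manifest))
}

ingest_stage <- function(config) {
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$cohort)
    tables <- c(cohort$hc,
                unlist(lapply(cohort$pairs, function(p) {
                  c(list(p$donor), unname(p$recipient))
                }), recursive = FALSE))
    names(tables) <- vapply(tables, function(t) t$sample_id, character(1))
    list(tables = tables, pairing = config$pairing %||% cohort$pairing,
         reference = config$reference %||% cohort$reference)
  } else {
    samples <- config$samples
    if (is.character(samples)) {
      samples <- utils::read.delim(samples, sep = "\t", header = TRUE,
                                   colClasses = "character", quote = "",
                                   stringsAsFactors = FALSE)
    }
    stopifnot(all(c("sample_id", "group", "file") %in% names(samples)))
    tables <- lapply(seq_len(nrow(samples)), function(i) {
      path <- file.path(config$input_dir, samples$file[i])
      if (!file.exists(path)) {
        stop("sample file not found: ", path, call. = FALSE)
      }
      tab <- read_clonotype_table(path, group = samples$group[i])
      if (tab$sample_id != samples$sample_id[i]) {
        stop("sample id mismatch in ", path, ": manifest says ",
             samples$sample_id[i], ", file says ", tab$sample_id,
             call. = FALSE)
      }
      tab
    })
    names(tables) <- samples$sample_id
    pairing <- config$pairing
    if (is.character(pairing)) {
      pairing <- utils::read.delim(pairing, sep = "\t", header = TRUE,
                                   colClasses = "character", quote = "",
                                   stringsAsFactors = FALSE)
    }
    reference <- config$reference
    if (!is.null(reference) &&
        !inherits(reference, "specificity_reference")) {
      reference <- build_reference(reference)
    }
    list(tables = tables, pairing = pairing, reference = reference)
  }
}
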