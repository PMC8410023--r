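# Shared fixtures and independent brute-force oracles. Fixtures are
# built in code at test time; nothing binary is stored.

write_immunoseq_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste("rearrangement", "amino_acid", "v_resolved", "j_resolved",
                  "templates", "frame_type", sep = "\t")
  writeLines(c(header, rows), path)
  path
}

immunoseq_row <- function(nt = "TGTGCCAGCAGT", aa = "CASSLGF",
                          v = "TCRBV05-01", j = "TCRBJ02-01",
                          templates = 1, frame = "In") {
  paste(nt, aa, v, j, templates, frame, sep = "\t")
}

write_airr_fixture <- function(rows, path = tempfile(fileext = ".tsv"),
                               with_stop_codon = FALSE) {
  cols <- c("junction", "junction_aa", "v_call", "j_call",
            "duplicate_count", "productive")
  if (with_stop_codon) cols <- c(cols, "stop_codon")
  writeLines(c(paste(cols, collapse = "\t"), rows), path)
  path
}

# a random clonotype table with heavy-tailed sizes, deterministic per seed
random_table <- function(seed, n_clones = NULL, sample_id = NULL,
                         group = "other") {
  withr::with_seed(seed, {
    n <- n_clones %||% sample(3:40, 1)
    sizes <- rclonesize(n, alpha = 2.5, max_size = 500)
    keys <- random_cdr3(n)
    clonotype_table(stats::setNames(as.integer(sizes), keys),
                    sample_id = sample_id %||% paste0("rand_", seed),
                    group = group)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- independent oracles --------------------------------------------

# recompute all repertoire metrics from the raw expanded template list
# (one entry per template), sharing no code with compute_metrics()
oracle_metrics <- function(table, tau, hyper_cutoff = 100) {
  templates <- rep(table$data$clonotype_key, table$data$templates)
  counts <- table(templates)
  sizes <- as.integer(counts)
  depth <- length(templates)
  list(
    richness = length(counts),
    n_expanded = sum(sizes > 1),
    n_path_expanded = sum(sizes > tau),
    n_hyperexpanded = sum(sizes > hyper_cutoff),
    mean_expansion_size = mean(sizes[sizes > 1]),
    isi = 1 / sum((sizes / depth)^2),
    occ_nonexpanded = sum(sizes[sizes == 1]) / depth,
    occ_normal = sum(sizes[sizes > 1 & sizes <= tau]) / depth,
    occ_pathological = sum(sizes[sizes > tau]) / depth
  )
}

# shared keys by explicit double loop
oracle_shared <- function(a, b) {
  out <- character(0)
  for (ka in a$data$clonotype_key) {
    for (kb in b$data$clonotype_key) {
      if (ka == kb) out <- c(out, ka)
    }
  }
  sort(out)
}

# exact joint law of downsampled counts by enumerating all template
# subsets of size `depth` (feasible for total templates <= 12)
oracle_downsample_pmf <- function(sizes, depth) {
  n_total <- sum(sizes)
  stopifnot(n_total <= 12)
  clone_of <- rep(seq_along(sizes), sizes)
  subsets <- utils::combn(n_total, depth)
  keys <- apply(subsets, 2, function(s) {
    paste(tabulate(clone_of[s], nbins = length(sizes)), collapse = ",")
  })
  table(keys) / ncol(subsets)
}
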