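# Synthetic cohort generator: reproducibility, construction guarantees
# and statistical calibration.

small_config <- function(...) {
  defaults <- list(n_hc = 4, n_pairs = 2, depth_law = c(2000L, 2000L),
                   analysis_depth = 2000L, public_pool_size = 1000L,
                   n_decoys = 40L, master_seed = 11L)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

test_that("identical config and seed reproduce the cohort byte-exactly", {
  cfg <- small_config()
  c1 <- suppressMessages(generate_cohort(cfg))
  c2 <- suppressMessages(generate_cohort(cfg))
  expect_identical(c1$hc, c2$hc)
  expect_identical(c1$pairs, c2$pairs)
  expect_identical(as.data.frame(c1$reference), as.data.frame(c2$reference))
  # and writing a table twice gives identical bytes
  p1 <- tempfile(); p2 <- tempfile()
  write_clonotype_table(c1$hc[[1]], p1)
  write_clonotype_table(c2$hc[[1]], p2)
  expect_identical(readLines(p1), readLines(p2))
  # different master seed changes the draw
  c3 <- suppressMessages(generate_cohort(small_config(master_seed = 12L)))
  expect_false(identical(c1$hc[[1]], c3$hc[[1]]))
})

test_that("repertoires honor depth, richness and key format", {
  cfg <- small_config()
  tab <- generate_repertoire(cfg, "healthy_control", seed = 3)
  expect_equal(tab$total_templates, 2000)
  expect_true(all(grepl("^C[A-Z]{6,18}F$", tab$data$clonotype_key)))
  expect_true(all(tab$data$templates >= 1))
  # infeasible richness/depth combination errors
  expect_error(tcrdyn:::adjust_sizes_to_depth(rep(1L, 50), 40),
               "infeasible")
})

test_that("clone-size sampler matches the truncated power-law pmf", {
  alpha <- 2.5; max_size <- 100
  pmf <- tcrdyn:::power_law_pmf(alpha, max_size)
  draws <- withr::with_seed(17, rclonesize(2e4, alpha, max_size))
  bins <- c(1, 2, 3, 4, 6, 11, 101) # right-open size classes
  expected <- vapply(seq_len(length(bins) - 1), function(i) {
    sum(pmf[bins[i]:(bins[i + 1] - 1)])
  }, numeric(1))
  observed <- table(cut(draws, breaks = c(bins - 0.5),
                        include.lowest = FALSE))
  gof <- suppressWarnings(stats::chisq.test(as.integer(observed),
                                            p = expected))
  expect_gt(gof$p.value, 0.01)
})

test_that("carry-over construction obeys its ground truth", {
  cfg <- small_config(carryover_fraction = 1, public_rate = 0)
  p <- suppressWarnings(generate_pair_with_timepoints(cfg, "x"))
  donor_keys <- p$donor$data$clonotype_key
  d30 <- p$recipient$d30
  # carryover 1, public 0: recipient keys (minus spikes) all from donor
  spikes <- p$ground_truth$timepoints$d30$spike_keys
  core <- setdiff(d30$data$clonotype_key, spikes)
  expect_true(all(core %in% donor_keys))
  # pre-transplant sample is the recipient's own repertoire
  expect_length(p$ground_truth$timepoints$pre$carryover_keys, 0)
  # carryover 0: overlap is public background only (here 0)
  cfg0 <- small_config(carryover_fraction = 0, public_rate = 0)
  p0 <- generate_pair_with_timepoints(cfg0, "y")
  expect_length(intersect(p0$recipient$d30$data$clonotype_key,
                          p0$donor$data$clonotype_key), 0)
})

test_that("zero public rate yields no cross-sample sharing", {
  cfg <- small_config(public_rate = 0, n_hc = 3)
  hc <- lapply(1:3, function(i) {
    generate_repertoire(cfg, "healthy_control", seed = i,
                        sample_id = paste0("hc", i))
  })
  for (i in 1:2) for (j in (i + 1):3) {
    expect_length(shared_clonotypes(hc[[i]], hc[[j]]), 0)
  }
})

test_that("spike clones are classified pathologically expanded", {
  cfg <- small_config()
  hc <- lapply(1:4, function(i) {
    generate_repertoire(cfg, "healthy_control", seed = 100 + i,
                        sample_id = paste0("hc", i))
  })
  th <- derive_threshold(hc)
  hits <- 0L; total <- 0L
  for (pid in c("s1", "s2", "s3")) {
    p <- generate_pair_with_timepoints(cfg, pid)
    for (tp in c("d30", "d100", "d180")) {
      spikes <- p$ground_truth$timepoints[[tp]]$spike_keys
      sizes <- tcrdyn:::clone_sizes(p$recipient[[tp]])[spikes]
      hits <- hits + sum(sizes > th$tau)
      total <- total + length(spikes)
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("reference db holds labeled keys plus decoys, and only those", {
  cfg <- small_config()
  cohort <- suppressMessages(generate_cohort(cfg))
  all_keys <- unique(unlist(lapply(c(cohort$hc,
                                     lapply(cohort$pairs, `[[`, "donor")),
                                   function(t) t$data$clonotype_key)))
  ref <- cohort$reference
  in_cohort <- ref$cdr3_aa %in% cohort$labels$cdr3_aa
  expect_true(all(ref$antigen_source[!in_cohort] == "Decoy"))
  expect_setequal(setdiff(ref$cdr3_aa, ref$cdr3_aa[in_cohort]),
                  setdiff(ref$cdr3_aa, cohort$labels$cdr3_aa))
  # zero label rates -> decoy-only reference, zero annotated fraction
  cfg0 <- small_config(category_label_rates = c(pathogen = 0, cancer = 0,
                                                autoimmune = 0,
                                                allergy = 0))
  cohort0 <- suppressMessages(generate_cohort(cfg0))
  expect_true(all(cohort0$reference$antigen_source == "Decoy"))
  summ <- category_summary(annotate(cohort0$hc[[1]], cohort0$reference))
  expect_equal(summ$annotated_fraction_clonotypes, 0)
})

test_that("annotated fraction grows with the spiked reference", {
  cfg <- small_config()
  cohort <- suppressMessages(generate_cohort(cfg))
  tab <- cohort$hc[[1]]
  decoy_only <- structure(
    cohort$reference[cohort$reference$antigen_source == "Decoy", ],
    class = c("specificity_reference", "data.frame"))
  f_full <- category_summary(
    annotate(tab, cohort$reference))$annotated_fraction_clonotypes
  f_decoy <- category_summary(
    annotate(tab, decoy_only))$annotated_fraction_clonotypes
  expect_gte(f_full, f_decoy)
  expect_equal(f_decoy, 0)
})
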