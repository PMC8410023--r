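# Diversity and expansion metrics, and the derived pathological
# expansion threshold.

test_that("ISI matches hand-worked and degenerate cases", {
  expect_equal(inverse_simpson(clonotype_table(c(A = 2L, B = 2L, C = 1L),
                                               "s")),
               25 / 9, tolerance = 1e-14)
  expect_equal(inverse_simpson(clonotype_table(c(A = 7L), "s")), 1)
  uniform <- clonotype_table(stats::setNames(rep(1L, 12),
                                             paste0("K", 1:12)), "s")
  expect_equal(inverse_simpson(uniform), 12)
  expect_error(inverse_simpson(clonotype_table(integer(0), "s")),
               "undefined")
})

test_that("ISI agrees with an independent implementation and its bounds", {
  skip_if_not_installed("vegan")
  for (seed in 1:25) {
    tab <- random_table(seed)
    isi <- inverse_simpson(tab)
    expect_equal(isi,
                 unname(vegan::diversity(tab$data$templates,
                                         index = "invsimpson")),
                 tolerance = 1e-12)
    expect_gte(isi, 1)
    expect_lte(isi, nrow(tab$data) + 1e-12)
  }
})

test_that("threshold reproduces the hand-worked t-interval", {
  ref <- list(
    clonotype_table(c(A = 4L, B = 4L, C = 1L), "r1"),
    clonotype_table(c(A = 5L, B = 5L, C = 1L), "r2"),
    clonotype_table(c(A = 6L, B = 6L, C = 1L), "r3"))
  th <- derive_threshold(ref)
  # means (4,5,6): 5 + qt(.975, 2) * sd/sqrt(3)
  expect_equal(th$mean_of_means, 5)
  expect_equal(th$upper_ci, 5 + stats::qt(0.975, 2) / sqrt(3),
               tolerance = 1e-12)
  expect_identical(th$tau, 7L)
  expect_equal(th$reference_n, 3)
})

test_that("threshold handles zero variance and unusable samples", {
  same <- list(clonotype_table(c(A = 3L, B = 1L), "a"),
               clonotype_table(c(X = 3L, Y = 1L), "b"))
  th <- derive_threshold(same)
  expect_equal(th$upper_ci, 3)
  expect_identical(th$tau, 3L)
  with_singletons <- c(same,
                       list(clonotype_table(c(Z = 1L, W = 1L), "c")))
  expect_warning(th2 <- derive_threshold(with_singletons), "no expanded")
  expect_identical(th2$tau, th$tau)
  expect_error(
    suppressWarnings(derive_threshold(
      list(clonotype_table(c(A = 2L), "a"),
           clonotype_table(c(B = 1L), "b")))),
    "at least 2")
})

test_that("threshold upper CI never grows when adding an at-mean sample", {
  base <- lapply(1:5, function(i) random_table(i, n_clones = 20))
  th <- derive_threshold(base)
  # append a sample whose expanded-clone mean equals the current mean
  m <- round(th$mean_of_means)
  extra <- clonotype_table(c(A = as.integer(m), B = as.integer(m), C = 1L),
                           "extra")
  th2 <- derive_threshold(c(base, list(extra)))
  expect_lte(th2$upper_ci, th$upper_ci + abs(m - th$mean_of_means) + 1e-9)
})

test_that("metrics match hand classification for the worked example", {
  tab <- clonotype_table(c(A = 200L, B = 6L, C = 3L, D = 1L, E = 1L), "s",
                         group = "recipient_d30")
  m <- compute_metrics(tab, fixed_threshold(5))
  expect_equal(m$richness, 5)
  expect_equal(m$n_expanded, 3)
  expect_equal(m$n_path_expanded, 2)
  expect_equal(m$n_hyperexpanded, 1)
  expect_equal(m$occ_pathological, 206 / 211)
  expect_equal(m$mean_path_expansion_size, 103)
  expect_equal(m$median_path_expansion_size, 103)
  # all expanded below tau
  m2 <- compute_metrics(clonotype_table(c(A = 2L, B = 2L, C = 1L), "s"),
                        fixed_threshold(5))
  expect_equal(m2$mean_expansion_size, 2)
  expect_equal(m2$n_path_expanded, 0)
  expect_true(is.na(m2$mean_path_expansion_size))
  # all singletons
  m3 <- compute_metrics(clonotype_table(c(A = 1L, B = 1L), "s"),
                        fixed_threshold(5))
  expect_equal(m3$n_expanded, 0)
  expect_equal(c(m3$occ_nonexpanded, m3$occ_normal, m3$occ_pathological),
               c(1, 0, 0))
})

test_that("occupancy partitions template space on random tables", {
  th <- fixed_threshold(5)
  for (seed in 1:200) {
    tab <- random_table(seed)
    m <- compute_metrics(tab, th)
    expect_equal(m$occ_nonexpanded + m$occ_normal + m$occ_pathological, 1,
                 tolerance = 1e-12)
    expect_true(all(c(m$occ_nonexpanded, m$occ_normal,
                      m$occ_pathological) >= 0))
    expect_true(m$n_hyperexpanded <= m$n_path_expanded &&
                  m$n_path_expanded <= m$n_expanded &&
                  m$n_expanded <= m$richness)
  }
})

test_that("metrics agree with the raw-template-list oracle", {
  th <- fixed_threshold(4)
  for (seed in 1:20) {
    tab <- random_table(seed, n_clones = 15)
    m <- compute_metrics(tab, th)
    o <- oracle_metrics(tab, tau = 4)
    expect_equal(m$richness, o$richness)
    expect_equal(m$n_expanded, o$n_expanded)
    expect_equal(m$n_path_expanded, o$n_path_expanded)
    expect_equal(m$isi, o$isi, tolerance = 1e-12)
    expect_equal(m$occ_pathological, o$occ_pathological, tolerance = 1e-12)
  }
})

test_that("downsampling does not inflate expected ISI", {
  tab <- random_table(5, n_clones = 40)
  isi0 <- inverse_simpson(tab)
  depth <- ceiling(tab$total_templates / 2)
  isis <- vapply(1:200, function(s) {
    inverse_simpson(downsample(tab, depth, seed = s))
  }, numeric(1))
  mc_se <- stats::sd(isis) / sqrt(length(isis))
  expect_lt(mean(isis), isi0 + 3 * mc_se)
})

test_that("rank distribution allocates template space by rank bin", {
  tab5 <- random_table(3, n_clones = 5)
  rd <- rank_distribution(tab5)
  expect_equal(unname(rd[1]), 1)
  expect_equal(sum(rd), 1)
  singles <- clonotype_table(
    stats::setNames(rep(1L, 10000),
                    withr::with_seed(1, random_cdr3(10000))), "s")
  expect_equal(unname(rank_distribution(singles)),
               c(0.001, 0.009, 0.09, 0.9, 0))
  mixed <- clonotype_table(
    stats::setNames(c(91L, rep(1L, 9)), paste0("K", 1:10)), "s")
  expect_equal(unname(rank_distribution(mixed)[1]), 1)
})

test_that("rank ties break deterministically by key", {
  sizes <- stats::setNames(rep(c(5L, 1L), c(6, 6)), paste0("K", 12:1))
  a <- rank_distribution(clonotype_table(sizes, "s"), bins = c(3L, 6L))
  b <- rank_distribution(clonotype_table(rev(sizes), "s"), bins = c(3L, 6L))
  expect_identical(a, b)
})

test_that("fold change is elementwise with guarded zero reference", {
  expect_equal(unname(group_fold_change(c(a = 6, b = 3), c(a = 3, b = 3))),
               c(2, 1))
  expect_warning(fc <- group_fold_change(c(a = 6, b = 1), c(a = 0, b = 1)),
                 "zero reference")
  expect_true(is.na(fc[["a"]]) && fc[["b"]] == 1)
})
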