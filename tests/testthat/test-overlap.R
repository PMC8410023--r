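# Pairwise sharing, overlap coefficients, public background and origin
# composition.

test_that("shared clonotypes respect size-class restriction", {
  th <- fixed_threshold(5)
  a <- clonotype_table(c(x = 6L, y = 1L), "a")
  b <- clonotype_table(c(x = 6L, z = 1L), "b")
  expect_equal(shared_clonotypes(a, b), "x")
  expect_equal(shared_clonotypes(a, b, "pathological", th), "x")
  expect_equal(shared_clonotypes(a, b, "expanded", th), "x")
  a2 <- clonotype_table(c(x = 2L, y = 5L), "a2")
  expect_length(shared_clonotypes(a2, b, "pathological", th), 0)
  # depth mismatch only matters for restricted classes
  c1 <- clonotype_table(c(x = 3L), "c1")
  expect_equal(shared_clonotypes(a, c1), "x")
  expect_error(shared_clonotypes(a, c1, "expanded", th), "common depth")
})

test_that("overlap coefficients match hand computation and are symmetric", {
  a <- clonotype_table(c(x = 2L, y = 1L, z = 1L), "a")
  b <- clonotype_table(c(x = 1L, w = 3L), "b")
  expect_equal(overlap_coefficient(a, b, "count"), 0.5)
  expect_equal(overlap_coefficient(a, b, "weighted"), 0.25)
  for (seed in 1:15) {
    t1 <- random_table(seed)
    t2 <- random_table(seed + 100)
    for (meth in c("count", "weighted")) {
      v <- overlap_coefficient(t1, t2, meth)
      expect_equal(v, overlap_coefficient(t2, t1, meth))
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(overlap_coefficient(t1, t1, meth), 1)
    }
  }
  disjoint <- clonotype_table(c(q = 4L), "d")
  expect_equal(overlap_coefficient(a, disjoint, "count"), 0)
  expect_equal(overlap_coefficient(a, disjoint, "weighted"), 0)
})

test_that("shared sets match the brute-force double loop", {
  for (seed in 1:12) {
    t1 <- random_table(seed, n_clones = 25)
    # force some sharing by splicing keys from t1 into t2
    t2 <- withr::with_seed(seed + 500, {
      take <- sample(t1$data$clonotype_key, 8)
      sizes <- c(stats::setNames(sample(1:9, 8, TRUE), take),
                 stats::setNames(sample(1:9, 15, TRUE),
                                 random_cdr3(15, exclude = take)))
      clonotype_table(sizes, "t2")
    })
    expect_identical(shared_clonotypes(t1, t2), oracle_shared(t1, t2))
  }
})

test_that("public background is 1 for identical and 0 for disjoint cohorts", {
  th <- fixed_threshold(5)
  sizes <- stats::setNames(c(8L, 3L, 1L, 1L),
                           c("CAAF", "CBBF", "CCCF", "CDDF"))
  identical_cohort <- lapply(1:3, function(i) {
    clonotype_table(sizes, paste0("id", i))
  })
  bg1 <- public_background(identical_cohort, th)
  expect_equal(bg1$fraction_all, 1)
  expect_equal(bg1$fraction_expanded, 1)
  expect_equal(bg1$fraction_path_expanded, 1)
  expect_equal(bg1$n_pairs, 3)

  disjoint_cohort <- withr::with_seed(9, lapply(1:3, function(i) {
    clonotype_table(stats::setNames(rep(2L, 10), random_cdr3(10)),
                    paste0("dj", i))
  }))
  # equalize depths
  bg0 <- public_background(disjoint_cohort, th)
  expect_equal(bg0$fraction_all, 0)
  expect_equal(bg0$fraction_expanded, 0)
})

test_that("background follows mean-shared / mean-richness by hand", {
  th <- fixed_threshold(5)
  # 3 samples, 100 keys each, every pair sharing exactly 2 singletons
  keys <- withr::with_seed(4, random_cdr3(294))
  shared_ab <- keys[1:2]; shared_ac <- keys[3:4]; shared_bc <- keys[5:6]
  own <- split(keys[7:294], rep(1:3, each = 96))
  mk <- function(own_keys, sh1, sh2, id) {
    clonotype_table(stats::setNames(rep(1L, 100),
                                    c(own_keys, sh1, sh2)), id)
  }
  cohort <- list(mk(own[[1]], shared_ab, shared_ac, "a"),
                 mk(own[[2]], shared_ab, shared_bc, "b"),
                 mk(own[[3]], shared_ac, shared_bc, "c"))
  bg <- public_background(cohort, th)
  expect_equal(bg$fraction_all, 0.02)
  # excluding one pair removes its contribution
  bg2 <- public_background(cohort, th,
                           exclude_pairs = data.frame(x = "a", y = "b"))
  expect_equal(bg2$n_pairs, 2)
  expect_equal(bg2$fraction_all, 0.02)
  expect_error(public_background(cohort[1:2], th,
                                 exclude_pairs = data.frame(x = "a",
                                                            y = "b")),
               "no eligible")
})

test_that("donor-recipient overlap subtracts the background with a floor", {
  th <- fixed_threshold(5)
  keys <- withr::with_seed(5, random_cdr3(40))
  rec <- clonotype_table(stats::setNames(rep(1L, 40), keys), "r")
  bg <- structure(list(fraction_all = 0.009, fraction_expanded = 0.0016,
                       fraction_path_expanded = 0.0005, n_pairs = 10),
                  class = "public_background")
  self <- donor_recipient_overlap(rec, rec, bg)
  expect_equal(self$recipient_shared_fraction, 1)
  expect_equal(self$adjusted_fraction, 0.991)
  don <- clonotype_table(stats::setNames(rep(1L, 40),
                                         withr::with_seed(6,
                                                          random_cdr3(40))),
                         "d")
  none <- donor_recipient_overlap(rec, don, bg)
  expect_equal(none$adjusted_fraction, 0) # floored
  expect_equal(none$adjusted_fraction_raw, -0.009)
  # 2.5% raw sharing minus 0.9% background = 1.6%
  rec2 <- clonotype_table(
    stats::setNames(rep(1L, 40), c(don$data$clonotype_key[1],
                                   keys[1:39])), "r2")
  ov <- donor_recipient_overlap(rec2, don, bg)
  expect_equal(ov$recipient_shared_fraction, 0.025)
  expect_equal(ov$adjusted_fraction, 0.016)
})

test_that("origin composition assigns every recipient clonotype once", {
  th <- fixed_threshold(5)
  rec <- clonotype_table(c(x = 9L, y = 3L, z = 1L, w = 1L), "r")
  don <- clonotype_table(c(x = 8L, y = 1L, q = 5L), "d")
  oc <- origin_composition(rec, don, th)
  expect_equal(oc["pathological", "pathological"], 1)
  expect_equal(oc["normal", "nonexpanded"], 1)
  expect_equal(oc["nonexpanded", "absent"], 2)
  expect_equal(sum(oc), nrow(rec$data))
  expect_equal(unname(rowSums(oc)),
               unname(as.vector(table(factor(
                 ifelse(rec$data$templates == 1, "nonexpanded",
                        ifelse(rec$data$templates <= 5, "normal",
                               "pathological")),
                 levels = c("nonexpanded", "normal", "pathological"))))))
  # donor-disjoint recipient: all mass in "absent"
  alone <- clonotype_table(c(u = 2L, v = 1L), "a")
  don2 <- clonotype_table(c(m = 2L, n = 1L), "d2")
  oc2 <- origin_composition(alone, don2, th)
  expect_equal(sum(oc2[, "absent"]), 2)
  expect_equal(sum(oc2[, colnames(oc2) != "absent"]), 0)
})

test_that("expansion size correlation is Spearman with guards", {
  expect_equal(expansion_size_correlation(cbind(c(1, 5, 9, 2),
                                                c(2, 4, 8, 1))), 0.8)
  expect_equal(expansion_size_correlation(cbind(1:5, (1:5)^3)), 1)
  expect_equal(expansion_size_correlation(cbind(1:5, 5:1)), -1)
  expect_error(expansion_size_correlation(cbind(1:2, 2:1)), "at least 3")
  expect_warning(r <- expansion_size_correlation(cbind(rep(2, 4), 1:4)),
                 "tied")
  expect_true(is.na(r))
})
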