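# Synthetic cohort generator: healthy-control, donor and longitudinal
# recipient repertoires with known ground truth (carry-over keys, public
# pool, expansion spikes, specificity labels) for validating every
# pipeline stage.

#' Configuration for a synthetic transplant cohort
#'
#' Bundles the generative parameters of the cohort. Clone sizes follow
#' a truncated discrete power law \eqn{P(k) \propto k^{-\alpha}},
#' \eqn{k = 1..max\_size}: most clonotypes carry a single template, with
#' rare large clones. Sharing parameters are defined at the common
#' `analysis_depth` the cohort is destined to be normalized to:
#' `public_rate` is the expected fraction of clonotypes two unrelated
#' individuals share there, and `carryover_fraction` the expected
#' donor-derived fraction of a recipient repertoire measured there (the
#' generator inflates pre-subsampling counts to offset sampling loss in
#' deeper samples).
#'
#' @param n_hc Number of healthy-control samples.
#' @param n_pairs Number of donor-recipient pairs (each recipient gets
#'   pre, d30, d100 and d180 samples).
#' @param depth_law Length-2 integer vector: uniform range of per-sample
#'   template depths.
#' @param clone_size_law List with `alpha` (power-law exponent, > 1) and
#'   `max_size` (truncation).
#' @param richness_fraction Optional override of richness/depth; by
#'   default richness is depth divided by the mean clone size of the law.
#' @param public_pool_size Number of clonotype keys in the shared public
#'   pool.
#' @param public_rate Expected pairwise public-overlap fraction between
#'   unrelated samples at `analysis_depth`.
#' @param carryover_fraction Expected donor-derived fraction of each
#'   post-transplant recipient repertoire at `analysis_depth`.
#' @param carryover_rank_correlation Target rank correlation between
#'   donor and recipient sizes of carried-over clonotypes.
#' @param timepoint_effects Data frame with columns `timepoint`
#'   (`pre`/`d30`/`d100`/`d180`), `richness_multiplier` and `n_spikes`
#'   (number of pathologically expanded spike clones injected).
#' @param spike_size_law Length-2 vector: uniform range of spike clone
#'   sizes (templates at `analysis_depth`).
#' @param gvhd_mode Add hyperexpanded clones (> 100 templates) at
#'   post-transplant timepoints.
#' @param gvhd_size_law Length-2 vector: uniform size range of
#'   hyperexpanded clones when `gvhd_mode` is on.
#' @param n_gvhd_spikes Number of hyperexpanded clones per timepoint in
#'   `gvhd_mode`.
#' @param category_label_rates Named vector of per-category labeling
#'   probabilities applied to each clonotype key (pathogen, cancer,
#'   autoimmune, allergy).
#' @param cmv_weight Share of pathogen labels attributed to CMV (the
#'   rest split between EBV and influenza).
#' @param n_decoys Reference entries for CDR3 keys absent from all
#'   samples.
#' @param analysis_depth Common depth the cohort is meant to be
#'   normalized to.
#' @param master_seed Master seed; all per-sample seeds derive from it
#'   via [derive_seed()], so the cohort is byte-reproducible.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 131L,
                          n_pairs = 14L,
                          depth_law = c(5420L, 100000L),
                          clone_size_law = list(alpha = 3, max_size = 100L),
                          richness_fraction = NULL,
                          public_pool_size = 10000L,
                          public_rate = 0.009,
                          carryover_fraction = 0.025,
                          carryover_rank_correlation = 0.5,
                          timepoint_effects = data.frame(
                            timepoint = c("pre", "d30", "d100", "d180"),
                            richness_multiplier = c(1, 0.9, 0.85, 0.8),
                            n_spikes = c(0L, 20L, 30L, 50L)),
                          spike_size_law = c(8L, 40L),
                          gvhd_mode = FALSE,
                          gvhd_size_law = c(150L, 600L),
                          n_gvhd_spikes = 5L,
                          category_label_rates = c(pathogen = 0.04,
                                                   cancer = 0.01,
                                                   autoimmune = 0.008,
                                                   allergy = 0.004),
                          cmv_weight = 0.4,
                          n_decoys = 500L,
                          analysis_depth = 5420L,
                          master_seed = 20210L) {
  stopifnot(n_hc >= 0, n_pairs >= 0,
            length(depth_law) == 2, depth_law[1] <= depth_law[2],
            clone_size_law$alpha > 1, clone_size_law$max_size >= 1,
            public_rate >= 0, public_rate <= 1,
            carryover_fraction >= 0, carryover_fraction <= 1,
            all(category_label_rates >= 0), all(category_label_rates <= 1),
            cmv_weight >= 0, cmv_weight <= 1,
            is_count(analysis_depth))
  stopifnot(all(c("timepoint", "richness_multiplier", "n_spikes") %in%
                  names(timepoint_effects)))
  structure(
    list(n_hc = as.integer(n_hc), n_pairs = as.integer(n_pairs),
         depth_law = as.integer(depth_law),
         clone_size_law = clone_size_law,
         richness_fraction = richness_fraction,
         public_pool_size = as.integer(public_pool_size),
         public_rate = public_rate,
         carryover_fraction = carryover_fraction,
         carryover_rank_correlation = carryover_rank_correlation,
         timepoint_effects = timepoint_effects,
         spike_size_law = spike_size_law,
         gvhd_mode = isTRUE(gvhd_mode),
         gvhd_size_law = gvhd_size_law,
         n_gvhd_spikes = as.integer(n_gvhd_spikes),
         category_label_rates = category_label_rates,
         cmv_weight = cmv_weight,
         n_decoys = as.integer(n_decoys),
         analysis_depth = as.integer(analysis_depth),
         master_seed = as.integer(master_seed)),
    class = "cohort_config"
  )
}

# normalized pmf of the truncated power law
power_law_pmf <- function(alpha, max_size) {
  k <- seq_len(max_size)
  w <- k^(-alpha)
  w / sum(w)
}

power_law_mean <- function(alpha, max_size) {
  p <- power_law_pmf(alpha, max_size)
  sum(seq_len(max_size) * p)
}

#' Draw clone sizes from the truncated discrete power law
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param max_size Truncation point.
#' @return Integer vector of sizes in 1..max_size.
#' @export
rclonesize <- function(n, alpha, max_size) {
  stopifnot(n >= 0, alpha > 1, max_size >= 1)
  if (n == 0) return(integer(0))
  sample.int(max_size, n, replace = TRUE,
             prob = power_law_pmf(alpha, max_size))
}

# Expected fraction of clonotypes surviving a without-replacement
# subsample that retains a fraction phi of templates: a clone of size k
# loses all templates with probability ~ (1 - phi)^k.
subsample_survival <- function(alpha, max_size, phi) {
  if (phi >= 1) return(1)
  p <- power_law_pmf(alpha, max_size)
  sum(p * (1 - (1 - phi)^seq_len(max_size)))
}

#' Random CDR3-like amino-acid keys
#'
#' Uppercase strings starting with C and ending with F, total length
#' 8-20, interior drawn uniformly from the 20 standard residues. The
#' keyspace exceeds 20^6 per length class, so accidental collisions
#' between independently generated keys are negligible; collisions
#' within one call (or with `exclude`) are regenerated.
#'
#' @param n Number of keys.
#' @param exclude Optional character vector of keys to avoid.
#' @return Character vector of `n` distinct keys.
#' @export
random_cdr3 <- function(n, exclude = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(character(0))
  make <- function(m) {
    lens <- sample(8:20, m, replace = TRUE)
    out <- character(m)
    for (L in sort(unique(lens))) {
      idx <- which(lens == L)
      mat <- matrix(sample(AA_ALPHABET, length(idx) * (L - 2L),
                           replace = TRUE),
                    nrow = length(idx))
      out[idx] <- do.call(paste0, unname(as.data.frame(mat,
                                                       optional = TRUE)))
    }
    out
  }
  keys <- character(0)
  while (length(keys) < n) {
    cand <- paste0("C", make(n - length(keys)), "F")
    cand <- setdiff(unique(cand), c(keys, exclude))
    keys <- c(keys, cand)
  }
  keys
}

# Adjust an i.i.d. size draw to sum exactly to `depth` while keeping
# every clone present: surplus templates are removed uniformly from the
# above-singleton excess (hypergeometric), deficit templates are added
# with probability proportional to current size.
adjust_sizes_to_depth <- function(sizes, depth) {
  total <- sum(sizes)
  if (depth < length(sizes)) {
    stop("infeasible richness/depth combination: ", length(sizes),
         " clonotypes cannot fit in ", depth, " templates", call. = FALSE)
  }
  if (total == depth) return(sizes)
  if (total > depth) {
    m <- total - depth
    excess <- sizes - 1L
    cum <- cumsum(excess)
    picked <- sample.int(cum[length(cum)], m)
    removed <- tabulate(findInterval(picked, cum, left.open = TRUE) + 1L,
                        nbins = length(sizes))
    sizes - removed
  } else {
    m <- depth - total
    cum <- cumsum(sizes)
    picked <- sample.int(cum[length(cum)], m, replace = TRUE)
    added <- tabulate(findInterval(picked, cum, left.open = TRUE) + 1L,
                      nbins = length(sizes))
    sizes + added
  }
}

# The cohort-wide public clonotype pool, a pure function of the config.
public_pool <- function(config) {
  with_seed(derive_seed(config$master_seed, "public_pool"),
            random_cdr3(config$public_pool_size))
}

# pool-inclusion probability calibrated so that two unrelated samples
# share ~ public_rate * richness clonotypes at analysis depth
pool_inclusion_prob <- function(config, richness, survival) {
  if (config$public_rate <= 0) return(0)
  min(1, sqrt(config$public_rate * richness /
                (config$public_pool_size * survival)))
}

sample_depth <- function(config) {
  if (config$depth_law[1] == config$depth_law[2]) {
    config$depth_law[1]
  } else {
    sample(config$depth_law[1]:config$depth_law[2], 1)
  }
}

target_richness <- function(config, depth) {
  frac <- config$richness_fraction %||%
    (1 / power_law_mean(config$clone_size_law$alpha,
                        config$clone_size_law$max_size))
  max(1L, round(frac * depth))
}

#' Generate one baseline repertoire
#'
#' Draws a healthy-control or donor sample: depth from the depth law,
#' richness from the clone-size law's mean, clone sizes i.i.d. from the
#' truncated power law (then adjusted to hit the depth exactly), keys a
#' mix of public-pool and private CDR3-like strings. Deterministic in
#' `(config, role, seed)`.
#'
#' @param config A [cohort_config].
#' @param role `"healthy_control"` or `"donor"`.
#' @param seed Integer seed for this sample.
#' @param sample_id Sample identifier (default derived from role/seed).
#' @return A [clonotype_table].
#' @export
generate_repertoire <- function(config, role = c("healthy_control", "donor"),
                                seed, sample_id = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(config, "cohort_config"))
  sample_id <- sample_id %||% paste0(role, "_", seed)
  pool <- public_pool(config)
  with_seed(seed, {
    depth <- sample_depth(config)
    richness <- target_richness(config, depth)
    phi <- min(1, config$analysis_depth / depth)
    s <- subsample_survival(config$clone_size_law$alpha,
                            config$clone_size_law$max_size, phi)
    q <- pool_inclusion_prob(config, richness, s)
    pub_keys <- pool[stats::runif(length(pool)) < q]
    if (length(pub_keys) > richness) pub_keys <- pub_keys[seq_len(richness)]
    priv_keys <- random_cdr3(richness - length(pub_keys), exclude = pool)
    keys <- c(pub_keys, priv_keys)
    sizes <- rclonesize(richness, config$clone_size_law$alpha,
                        config$clone_size_law$max_size)
    sizes <- adjust_sizes_to_depth(sizes, depth)
    clonotype_table(stats::setNames(as.integer(sizes), keys),
                    sample_id = sample_id,
                    group = role)
  })
}

# reorder `sizes` over the carry subset so that their ranks correlate
# with the donor sizes of the carried keys (Gaussian copula)
rank_correlate <- function(sizes, donor_sizes, rho) {
  n <- length(sizes)
  if (n < 2 || rho == 0) return(sizes)
  z_donor <- stats::qnorm((rank(donor_sizes, ties.method = "random")) /
                            (n + 1))
  z <- rho * z_donor + sqrt(1 - rho^2) * stats::rnorm(n)
  sort(sizes)[rank(z, ties.method = "random")]
}

#' Generate a donor-recipient pair with longitudinal recipient samples
#'
#' The donor is a baseline repertoire. Each recipient timepoint mixes:
#' carried-over donor clonotypes (a configurable fraction, sizes
#' rank-correlated with the donor's), a public-pool draw, de novo
#' clonotypes, and injected pathological expansion spikes per the
#' timepoint effects (plus hyperexpanded clones in `gvhd_mode`). The
#' pre-transplant sample is the recipient's own repertoire: no
#' carry-over, no spikes. Ground truth for every construction choice is
#' returned alongside.
#'
#' @param config A [cohort_config].
#' @param pair_id Integer or string identifying the pair.
#' @return A list with `donor` (a [clonotype_table]), `recipient`
#'   (named list of [clonotype_table], one per timepoint) and
#'   `ground_truth` (carryover keys and count per timepoint, spike
#'   keys, donor id).
#' @export
generate_pair_with_timepoints <- function(config, pair_id) {
  stopifnot(inherits(config, "cohort_config"))
  donor_id <- sprintf("D_%s", pair_id)
  donor_seed <- derive_seed(config$master_seed, paste0("donor_", pair_id))
  donor <- generate_repertoire(config, "donor", donor_seed,
                               sample_id = donor_id)
  pool <- public_pool(config)
  donor_sizes <- clone_sizes(donor)
  donor_private <- setdiff(names(donor_sizes), pool)
  donor_depth <- donor$total_templates
  s_donor <- subsample_survival(
    config$clone_size_law$alpha, config$clone_size_law$max_size,
    min(1, config$analysis_depth / donor_depth))

  carry_master <- with_seed(
    derive_seed(config$master_seed, paste0("carry_", pair_id)),
    sample(donor_private))

  tps <- config$timepoint_effects
  recipient <- list()
  truth_tp <- list()
  for (i in seq_len(nrow(tps))) {
    tp <- tps$timepoint[i]
    rec_id <- sprintf("R_%s_%s", pair_id, tp)
    seed_tp <- derive_seed(config$master_seed,
                           paste0("recipient_", pair_id, "_", tp))
    recipient[[tp]] <- with_seed(seed_tp, {
      depth <- sample_depth(config)
      base_rich <- target_richness(config, depth)
      richness <- max(1L, round(base_rich * tps$richness_multiplier[i]))
      phi <- min(1, config$analysis_depth / depth)
      s <- subsample_survival(config$clone_size_law$alpha,
                              config$clone_size_law$max_size, phi)

      post <- tp != "pre"
      carry_n <- if (post && config$carryover_fraction > 0) {
        round(config$carryover_fraction * richness / s_donor)
      } else 0L
      if (post && config$carryover_fraction > 0 && carry_n < 1) {
        warning("carryover_fraction x richness < 1 for pair ", pair_id,
                " at ", tp, "; generating zero carry-over", call. = FALSE)
        carry_n <- 0L
      }
      carry_n <- min(carry_n, length(carry_master), richness)
      carry_keys <- carry_master[seq_len(carry_n)]

      q <- pool_inclusion_prob(config, richness, s)
      pub_keys <- pool[stats::runif(length(pool)) < q]
      n_pub <- min(length(pub_keys), richness - carry_n)
      pub_keys <- pub_keys[seq_len(n_pub)]
      denovo_keys <- random_cdr3(richness - carry_n - n_pub,
                                 exclude = pool)
      keys <- c(carry_keys, pub_keys, denovo_keys)

      sizes <- rclonesize(richness, config$clone_size_law$alpha,
                          config$clone_size_law$max_size)
      if (carry_n >= 2) {
        sizes[seq_len(carry_n)] <- rank_correlate(
          sizes[seq_len(carry_n)], donor_sizes[carry_keys],
          config$carryover_rank_correlation)
      }

      # pathological expansion spikes, sized at analysis-depth scale
      n_spk <- tps$n_spikes[i]
      spike_keys <- character(0)
      spike_sizes <- integer(0)
      if (post && n_spk > 0) {
        spike_keys <- random_cdr3(n_spk, exclude = c(pool, keys))
        spike_sizes <- round(stats::runif(n_spk, config$spike_size_law[1],
                                          config$spike_size_law[2]) / phi)
      }
      if (post && config$gvhd_mode && config$n_gvhd_spikes > 0) {
        gk <- random_cdr3(config$n_gvhd_spikes,
                          exclude = c(pool, keys, spike_keys))
        gs <- round(stats::runif(config$n_gvhd_spikes,
                                 config$gvhd_size_law[1],
                                 config$gvhd_size_law[2]) / phi)
        spike_keys <- c(spike_keys, gk)
        spike_sizes <- c(spike_sizes, gs)
      }

      # spike sizes are a construction guarantee: budget their templates
      # first and fit the baseline repertoire into the remainder
      spike_sizes <- pmax(1L, as.integer(spike_sizes))
      base_depth <- max(depth - sum(spike_sizes), length(keys))
      sizes <- adjust_sizes_to_depth(sizes, base_depth)
      all_keys <- c(keys, spike_keys)
      all_sizes <- c(sizes, spike_sizes)
      truth_tp[[tp]] <- list(carryover_keys = carry_keys,
                             public_keys = pub_keys,
                             spike_keys = spike_keys)
      clonotype_table(stats::setNames(as.integer(all_sizes), all_keys),
                      sample_id = rec_id,
                      group = paste0("recipient_", tp))
    })
  }
  list(donor = donor, recipient = recipient,
       ground_truth = list(pair_id = as.character(pair_id),
                           donor_id = donor_id,
                           donor_survival = s_donor,
                           timepoints = truth_tp))
}

#' Assign ground-truth specificity labels to clonotype keys
#'
#' Each key is labeled with each category independently at the
#' configured rate; pathogen labels get an antigen source (CMV at
#' `cmv_weight`, the rest EBV/influenza). A key may carry several
#' category labels or none.
#'
#' @param config A [cohort_config].
#' @param keys Character vector of clonotype keys to label.
#' @return Data frame: `cdr3_aa`, `category`, `antigen_source`,
#'   `disease` (zero rows if no label is drawn).
#' @export
label_clonotypes <- function(config, keys) {
  stopifnot(inherits(config, "cohort_config"))
  keys <- unique(keys)
  rates <- config$category_label_rates
  with_seed(derive_seed(config$master_seed, "labels"), {
    parts <- lapply(names(rates), function(cat) {
      hit <- keys[stats::runif(length(keys)) < rates[[cat]]]
      if (length(hit) == 0) return(NULL)
      src <- switch(cat,
        pathogen = sample(c("CMV", "EBV", "InfluenzaA"), length(hit),
                          replace = TRUE,
                          prob = c(config$cmv_weight,
                                   (1 - config$cmv_weight) / 2,
                                   (1 - config$cmv_weight) / 2)),
        cancer = sample(c("Melanoma", "AML"), length(hit), replace = TRUE),
        autoimmune = rep("HomoSapiens", length(hit)),
        allergy = rep("Allergen", length(hit)),
        rep("Unknown", length(hit)))
      disease <- switch(cat,
        pathogen = paste0(src, " infection"),
        cancer = src,
        autoimmune = rep("Autoimmunity", length(hit)),
        allergy = rep("Allergy", length(hit)),
        rep("Other", length(hit)))
      data.frame(cdr3_aa = hit, category = cat, antigen_source = src,
                 disease = disease, stringsAsFactors = FALSE)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0) {
      data.frame(cdr3_aa = character(), category = character(),
                 antigen_source = character(), disease = character(),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, parts)
    }
  })
}

#' Build the synthetic specificity reference for a cohort
#'
#' The reference contains exactly the ground-truth labeled cohort keys
#' plus `n_decoys` decoy entries for keys absent from every sample, all
#' under the provenance tag `synthetic-db`.
#'
#' @param config A [cohort_config].
#' @param labels Ground-truth labels from [label_clonotypes()].
#' @param cohort_keys All clonotype keys occurring in the cohort
#'   (decoys are kept disjoint from these).
#' @return A `specificity_reference` (see [build_reference()]).
#' @export
generate_reference_db <- function(config, labels,
                                  cohort_keys = labels$cdr3_aa) {
  stopifnot(inherits(config, "cohort_config"), is.data.frame(labels))
  decoys <- with_seed(derive_seed(config$master_seed, "decoys"), {
    dk <- random_cdr3(config$n_decoys, exclude = cohort_keys)
    if (length(dk) == 0) {
      NULL
    } else {
      data.frame(cdr3_aa = dk,
                 category = sample(SPECIFICITY_CATEGORIES[1:4], length(dk),
                                   replace = TRUE),
                 antigen_source = "Decoy", disease = "Decoy",
                 stringsAsFactors = FALSE)
    }
  })
  entries <- rbind(labels[, c("cdr3_aa", "category", "antigen_source",
                              "disease")],
                   decoys)
  df <- data.frame(
    cdr3 = entries$cdr3_aa,
    antigen_epitope = paste0("EP", seq_len(nrow(entries))),
    antigen_species = entries$antigen_source,
    category = entries$category,
    disease = entries$disease,
    source = "synthetic-db",
    stringsAsFactors = FALSE
  )
  suppressMessages(build_reference(list(df)))
}

#' Generate a full synthetic cohort
#'
#' Healthy controls, donor-recipient pairs with longitudinal recipient
#' samples, ground-truth specificity labels and the matching synthetic
#' reference, plus a pairing manifest. Byte-reproducible for a fixed
#' `(config, master_seed)`.
#'
#' @param config A [cohort_config].
#' @return A list with `hc` (list of [clonotype_table]), `pairs` (list
#'   from [generate_pair_with_timepoints()]), `pairing` (data frame:
#'   recipient_id, donor_id, timepoint), `labels`, `reference`, and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  hc <- lapply(seq_len(config$n_hc), function(i) {
    generate_repertoire(config, "healthy_control",
                        derive_seed(config$master_seed, paste0("hc_", i)),
                        sample_id = sprintf("HC_%03d", i))
  })
  names(hc) <- vapply(hc, function(t) t$sample_id, character(1))
  pairs <- lapply(seq_len(config$n_pairs), function(i) {
    generate_pair_with_timepoints(config, sprintf("%02d", i))
  })
  names(pairs) <- vapply(pairs, function(p) p$donor$sample_id, character(1))
  pairing <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(recipient_id = vapply(p$recipient, function(t) t$sample_id,
                                     character(1)),
               donor_id = p$donor$sample_id,
               timepoint = names(p$recipient),
               stringsAsFactors = FALSE)
  }))
  rownames(pairing) <- NULL
  all_keys <- unique(c(
    unlist(lapply(hc, function(t) t$data$clonotype_key), use.names = FALSE),
    unlist(lapply(pairs, function(p) {
      c(p$donor$data$clonotype_key,
        unlist(lapply(p$recipient, function(t) t$data$clonotype_key),
               use.names = FALSE))
    }), use.names = FALSE)))
  labels <- label_clonotypes(config, all_keys)
  reference <- generate_reference_db(config, labels, cohort_keys = all_keys)
  list(hc = hc, pairs = pairs, pairing = pairing, labels = labels,
       reference = reference, config = config)
}
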