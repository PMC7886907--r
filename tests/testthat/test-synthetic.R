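test_that("site generation is reproducible and properly normalized", {
  cfg <- synthetic_config(n_chromosomes = 3, chrom_length = 2e6,
                          n_sites = 80, spacing_mean = 2e4, seed = 77)
  s1 <- generate_sites(cfg)
  s2 <- generate_sites(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 240)
  expect_equal(mean(s1$x), cfg$signal_to_background, tolerance = 1e-12)
  expect_true(all(s1$pos <= cfg$chrom_length))
  expect_true(all(diff(s1$pos[s1$chrom == "chr1"]) > 0))
  expect_true(all(s1$orientation %in% c("forward", "reverse")))

  # unit background convention: mean normalized intensity exactly one
  unit <- generate_sites(synthetic_config(n_chromosomes = 1,
                                          chrom_length = 1e6,
                                          n_sites = 30,
                                          signal_to_background = 1,
                                          seed = 78))
  expect_equal(mean(unit$x), 1, tolerance = 1e-12)

  two <- generate_sites(synthetic_config(n_chromosomes = 1,
                                         chrom_length = 1e6, n_sites = 2,
                                         seed = 79))
  expect_equal(nrow(enumerate_pairs(two, 1e6)), 1)
})

test_that("bernoulli labels of isolated pairs hit the closed-form rate", {
  # 400 chromosomes, each a single isolated pair with p_i = p_j = 0.5
  # and w = 1, no decay: closed-form p_ij = 0.25 exactly
  sites <- dplyr::bind_rows(lapply(1:400, function(i)
    make_sites(c(1000, 2000), x = 8.5,
               orientation = c("forward", "reverse"),
               chrom = sprintf("c%03d", i))))
  sites$site_id <- paste0(sites$chrom, "_", sites$site_id)
  params <- lce_params(a = 8.5, w = 1, lam = NA)
  pr <- generate_labels(sites, params, "bernoulli_closed_form", seed = 3)
  expect_equal(nrow(pr), 400)
  expect_true(all(pr$p_ij == 0.25))
  # exact binomial 99.9% CI around 0.25 at n = 400
  ci <- stats::qbinom(c(0.0005, 0.9995), 400, 0.25) / 400
  expect_gte(mean(pr$label), ci[1])
  expect_lte(mean(pr$label), ci[2])
})

test_that("the extrusion mechanism never forms two overlapping loops", {
  # three sites: the long loop (1,3) and any loop touching site 2 are
  # mutually exclusive because a loop never spans an occupied site
  sites <- make_sites(c(1000, 2000, 3000), x = 30,
                      orientation = c("forward", "forward", "reverse"))
  hits_13 <- 0
  both <- 0
  for (seed in 1:200) {
    pr <- generate_labels(sites, lce_params(w = 1, lam = NA),
                          "occupancy_then_extrude", seed = seed)
    l13 <- pr$label[pr$pos_i == 1000 & pr$pos_j == 3000]
    l12 <- pr$label[pr$pos_i == 1000 & pr$pos_j == 2000]
    l23 <- pr$label[pr$pos_i == 2000 & pr$pos_j == 3000]
    hits_13 <- hits_13 + l13
    both <- both + (l13 & (l12 | l23))
  }
  expect_gt(hits_13, 0)
  expect_equal(both, 0)
})

test_that("empirical orientation preference converges to the ratio law", {
  # many isolated two-site chromosomes with matched x and d, half
  # convergent and half tandem: label frequency ratio approaches w
  n <- 1200
  ori2 <- rep(c("reverse", "forward"), n / 2)
  sites <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    make_sites(c(1000, 2000), x = 25.5,
               orientation = c("forward", ori2[i]),
               chrom = sprintf("c%04d", i))))
  sites$site_id <- paste0(sites$chrom, "_", sites$site_id)
  pr <- generate_labels(sites, lce_params(w = 3, lam = NA),
                        "bernoulli_closed_form", seed = 9)
  conv <- pr$ori_class == "convergent"
  ratio <- mean(pr$label[conv]) / mean(pr$label[!conv])
  expect_equal(ratio, 3, tolerance = 0.35)
})

test_that("brute-force enumeration equals the closed form (s = 0)", {
  sites <- tiny_landscape(seed = 21, n_chromosomes = 1, n_sites = 8)
  for (params in list(lce_params(lam = NA), lce_params(w = 2.5),
                      lce_params(decay = "powerlaw", k = 0.5))) {
    bf <- brute_force_pij(sites, params)
    sc <- score_pairs(enumerate_pairs(sites, 1e6), sites, params)
    m <- dplyr::inner_join(
      dplyr::select(bf, "pos_i", "pos_j", "p_exact"),
      dplyr::select(sc, "pos_i", "pos_j", "p_ij"),
      by = c("pos_i", "pos_j"))
    expect_equal(m$p_exact, m$p_ij, tolerance = 1e-12)
  }
  expect_error(brute_force_pij(tiny_landscape(n_sites = 20)), "too large")
  expect_error(brute_force_pij(sites, lce_params(s = 0.5)), "s = 0")
})

test_that("three-site marginals match hand enumeration", {
  # sites with p = (1/2, 1/3, 1/2); convergent ends, internal forward;
  # w = 2, no decay. Hand marginals under the exclusion mechanism:
  #  (1,2): p1*p2*(1/w)      [tandem f-f]
  #  (2,3): p2*p3*1          [convergent f-r]
  #  (1,3): p1*(1-p2)*p3*1   [requires middle unoccupied]
  sites <- make_sites(c(0, 1000, 2000), x = c(8.5, 4.25, 8.5),
                      orientation = c("forward", "forward", "reverse"))
  bf <- brute_force_pij(sites, lce_params(a = 8.5, w = 2, lam = NA))
  expect_equal(bf$p_exact[bf$pos_i == 0 & bf$pos_j == 1000],
               0.5 * (1 / 3) * 0.5)
  expect_equal(bf$p_exact[bf$pos_i == 1000 & bf$pos_j == 2000],
               (1 / 3) * 0.5)
  expect_equal(bf$p_exact[bf$pos_i == 0 & bf$pos_j == 2000],
               0.5 * (2 / 3) * 0.5)
  # overlapping-loop probabilities sum below one (mutual exclusion)
  expect_lte(bf$p_exact[bf$pos_i == 0 & bf$pos_j == 2000] +
               bf$p_exact[bf$pos_i == 1000 & bf$pos_j == 2000], 1)
})

test_that("predicted loop lengths are unimodal with a heavy right tail", {
  sim <- simulate_landscape(synthetic_config(seed = 13))
  len <- sim$pairs$d[sim$pairs$label == 1]
  expect_gt(length(len), 100)
  expect_gt(mean(len), stats::median(len)) # right skew
  h <- graphics::hist(len, breaks = 20, plot = FALSE)$counts
  expect_equal(which.max(h), 1) # mode at short lengths, long tail
  expect_gt(max(len), 5 * stats::median(len))
})

test_that("synthetic PET counts make the count filters meaningful", {
  sim <- simulate_landscape(synthetic_config(seed = 14))
  pos <- sim$pairs[sim$pairs$label == 1, ]
  expect_true(all(pos$pet_count >= 1))
  expect_true(all(sim$pairs$pet_count[sim$pairs$label == 0] == 0))
  med <- stats::median(pos$pet_count)
  expect_gte(med, 4)
  expect_lte(med, 9)
  # counts track probability
  expect_gt(stats::cor(pos$p_ij, pos$pet_count, method = "spearman"), 0.3)
})
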