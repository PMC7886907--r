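test_that("binding probability follows the chemical-equilibrium form", {
  p <- lce_params(a = 8.5)
  expect_equal(binding_probability(0, p), 0)
  expect_equal(binding_probability(8.5, p), 0.5)
  expect_equal(binding_probability(25.5, p), 0.75)
  expect_error(binding_probability(-1, p), "x")
  # strictly increasing in x (tanh checked below numeric saturation)
  xs <- seq(0, 50, length.out = 200)
  pb <- binding_probability(xs, lce_params(a = 8.5))
  expect_true(all(diff(pb) > 0) && all(pb >= 0 & pb < 1))
  xt <- seq(0, 0.5, length.out = 100)
  pt <- binding_probability(xt, lce_params(a = 8.5, binding = "tanh"))
  expect_true(all(diff(pt) > 0) && all(pt >= 0 & pt < 1))
  expect_equal(binding_probability(1, lce_params(a = 2, binding = "tanh")),
               tanh(2))
})

test_that("orientation weights are 1, 1/w, 1/w^2 and errors on ambiguity", {
  p <- lce_params(w = 3)
  expect_equal(orientation_weight("forward", "reverse", p), 1)
  expect_equal(orientation_weight("forward", "forward", p), 1 / 3)
  expect_equal(orientation_weight("reverse", "reverse", p), 1 / 3)
  expect_equal(orientation_weight("reverse", "forward", p), 1 / 9)
  expect_error(orientation_weight("ambiguous", "forward", p), "ambiguous")
  # general two-parameter form overrides w
  pg <- lce_params(w1 = 2, w2 = 10)
  expect_equal(orientation_weight("forward", "forward", pg), 1 / 2)
  expect_equal(orientation_weight("reverse", "forward", pg), 1 / 10)
})

test_that("distance decay covers exponential, power-law and disabled", {
  expect_equal(distance_decay(123, lce_params(lam = NA)), 1)
  expect_equal(distance_decay(3e5, lce_params(lam = 3e5)), exp(-1))
  expect_equal(distance_decay(1e-9, lce_params(lam = 3e5)), 1,
               tolerance = 1e-12)
  ppl <- lce_params(decay = "powerlaw", k = 1)
  expect_equal(distance_decay(2000, ppl), 0.5) # kb units
  expect_equal(distance_decay(500, ppl), 1)    # clamped below 1 kb
  expect_error(distance_decay(0, lce_params()), "positive")
  expect_error(distance_decay(-5, lce_params()), "positive")
})

test_that("approximate loop competition is the internal-site product", {
  expect_equal(lc_approx(numeric(0)), 1)
  expect_equal(lc_approx(c(0.5, 0.5)), 0.25)
  # from intensities through the occupancy map
  p <- binding_probability(c(8.5, 25.5), lce_params(a = 8.5))
  expect_equal(lc_approx(p), 0.125)
  # pass-through attenuation
  expect_equal(lc_approx(0.5, s = 0.4), 0.7)
  expect_equal(lc_approx(c(0.3, 0.8), s = 1), 1)
  # monotone nonincreasing as sites are added
  ps <- runif(20)
  vals <- vapply(0:20, function(k) lc_approx(ps[seq_len(k)]), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("loop probability decomposes exactly into its four terms", {
  sites <- make_sites(c(1000, 5000), orientation = c("forward", "reverse"))
  pr <- loop_probability(sites, "s01", "s02", lce_params(a = 8.5, lam = NA))
  expect_equal(pr$p_ij, 0.25)
  expect_equal(pr$p_ij, pr$w_ij * pr$p_i * pr$p_j * pr$D_ij * pr$LC_ij)

  tandem <- make_sites(c(1000, 5000), orientation = "forward")
  expect_equal(loop_probability(tandem, "s01", "s02",
                                lce_params(lam = NA))$p_ij, 0.25 / 3)

  with_internal <- make_sites(c(1000, 3000, 5000),
                              orientation = c("forward", "forward",
                                              "reverse"))
  pr3 <- loop_probability(with_internal, "s01", "s03",
                          lce_params(lam = NA))
  expect_equal(pr3$LC_ij, 0.5)
  expect_equal(pr3$p_ij, 0.125)

  cross <- dplyr::bind_rows(make_sites(1000, chrom = "chr1"),
                            make_sites(2000, chrom = "chr2"))
  cross$site_id <- c("a", "b")
  expect_error(loop_probability(cross, "a", "b", lce_params()),
               "different chromosomes")
})

test_that("with w = 1, no decay and no internal sites p_ij = p_i * p_j", {
  for (x1 in c(1, 8.5, 40)) for (x2 in c(2, 17)) {
    sites <- make_sites(c(0, 800), x = c(x1, x2),
                        orientation = c("reverse", "forward"))
    pr <- loop_probability(sites, "s01", "s02",
                           lce_params(a = 8.5, w = 1, lam = NA, s = 0.3))
    expect_equal(pr$p_ij, pr$p_i * pr$p_j)
  }
})

test_that("orientation ratio law holds exactly at fixed sites/distance", {
  base <- function(o1, o2)
    loop_probability(make_sites(c(0, 9000), x = c(12, 30),
                                orientation = c(o1, o2)),
                     "s01", "s02", lce_params(w = 3))$p_ij
  expect_equal(base("forward", "reverse") / base("forward", "forward"), 3)
  expect_equal(base("forward", "reverse") / base("reverse", "forward"), 9)
})

test_that("probabilities respect normalization and monotonicity", {
  sites <- tiny_landscape()
  params <- lce_params()
  sc <- score_pairs(enumerate_pairs(sites, 5e5), sites, params)
  expect_true(all(sc$p_ij >= 0 & sc$p_ij < 1))
  expect_true(all(sc$p_ij <= pmin(sc$p_i, sc$p_j) + 1e-12))
  expect_true(all(sc$LC_ij > 0 & sc$LC_ij <= 1))
  expect_true(all(sc$w_ij > 0 & sc$w_ij <= 1))

  # nondecreasing in anchor intensity
  up <- sites
  up$x <- up$x * 1.5
  sc_up <- score_pairs(enumerate_pairs(up, 5e5), up, params)
  # LC also strengthens, so compare with competition frozen
  expect_true(all(sc_up$p_i >= sc$p_i))

  # nonincreasing in distance (exponential mode, other terms fixed)
  d <- c(1e4, 1e5, 5e5, 1e6)
  expect_true(all(diff(distance_decay(d, params)) < 0))

  # nondecreasing in s
  s_vals <- c(0, 0.3, 0.7, 1)
  mats <- sapply(s_vals, function(s) {
    p <- params; p$s <- s
    score_pairs(enumerate_pairs(sites, 5e5), sites, p)$p_ij
  })
  expect_true(all(diff(t(mats)) >= -1e-14))

  # nonincreasing in w for non-convergent pairs
  sc_w5 <- score_pairs(enumerate_pairs(sites, 5e5), sites,
                       lce_params(w = 5))
  nonconv <- sc$ori_class != "convergent"
  expect_true(all(sc_w5$p_ij[nonconv] <= sc$p_ij[nonconv]))
  expect_equal(sc_w5$p_ij[!nonconv], sc$p_ij[!nonconv])
})

test_that("score_pairs agrees with single-pair computation", {
  sites <- tiny_landscape(seed = 7, n_chromosomes = 1, n_sites = 20)
  sc <- score_pairs(enumerate_pairs(sites, 1e6), sites, lce_params())
  for (r in c(1, 10, nrow(sc))) {
    one <- loop_probability(sites, sc$site_i[r], sc$site_j[r],
                            lce_params())
    expect_equal(sc$p_ij[r], one$p_ij)
    expect_equal(sc$LC_ij[r], one$LC_ij)
  }
})
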