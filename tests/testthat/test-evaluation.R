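test_that("an exact-twin negative is the selected match", {
  sites <- make_sites(c(0, 10000, 500000, 510000),
                      orientation = c("forward", "reverse",
                                      "forward", "reverse"))
  pairs <- score_pairs(enumerate_pairs(sites, 50000), sites,
                       lce_params())
  # two identical convergent pairs; first labelled positive
  pairs$label <- c(1L, 0L)
  m <- matched_negatives(pairs, "distance", seed = 1)
  expect_equal(nrow(m), 2)
  expect_equal(attr(m, "dropped"), 0)
  expect_equal(sort(m$label), c(0L, 1L))
})

test_that("positives without candidates are dropped and counted", {
  sites <- make_sites(c(0, 10000, 500000, 510000),
                      orientation = c("forward", "reverse",
                                      "forward", "forward"))
  pairs <- score_pairs(enumerate_pairs(sites, 50000), sites, lce_params())
  pairs$label <- c(1L, 0L) # tandem negative cannot match convergent positive
  m <- matched_negatives(pairs, "distance", seed = 1)
  expect_equal(nrow(m), 0)
  expect_equal(attr(m, "dropped"), 1)
  expect_error(matched_negatives(pairs, "distance", factor = 1), "factor")
})

test_that("matched sets satisfy their constraints and separate features", {
  sim <- simulate_landscape(synthetic_config(n_chromosomes = 4,
                                             chrom_length = 4e6,
                                             n_sites = 160,
                                             seed = 31))
  dm <- matched_negatives(sim$pairs, "distance", seed = 2)
  expect_gt(sum(dm$label == 1), 30)
  # constraints hold for every emitted match (factor 2)
  for (id in unique(dm$match_id)) {
    two <- dm[dm$match_id == id, ]
    expect_equal(two$ori_class[1], two$ori_class[2])
    pp <- two$p_i * two$p_j
    expect_lte(max(pp) / min(pp), 2)
    expect_lte(max(two$D_ij) / min(two$D_ij), 2)
  }
  # loop competition remains discriminative when distance is matched
  expect_gt(auroc(dm$LC_ij, dm$label), 0.6)

  lm <- matched_negatives(sim$pairs, "loop_competition", seed = 2)
  expect_gt(sum(lm$label == 1), 30)
  # distance alone is uninformative when competition is matched
  expect_lt(abs(auroc(lm$D_ij, lm$label) - 0.5), 0.12)
})

ep_toy <- function() {
  # one loop spanning [1000, 5000] (anchor midpoints)
  dplyr::tibble(loop_id = "L", chrom = "chr1",
                a1_start = 900L, a1_end = 1100L,
                a2_start = 4900L, a2_end = 5100L, pet_count = 10L)
}

test_that("crossing and containment counts follow the definitions", {
  loops <- ep_toy()
  links <- dplyr::tibble(
    chrom = "chr1",
    enh_start = c(2000L, 4000L), enh_end = c(2100L, 4100L),
    prom_start = c(3000L, 6000L), prom_end = c(3100L, 6100L),
    label = c(TRUE, FALSE)
  )
  ep <- ep_constraint(links, loops)
  # link 1 nested inside the loop: contained, not crossing
  expect_equal(ep$per_link$cross, c(0L, 1L))
  expect_equal(ep$per_link$contain, c(1L, 0L))

  # counts are invariant under translating the whole assembly
  shift <- 70000L
  links2 <- dplyr::mutate(links,
                          enh_start = enh_start + shift,
                          enh_end = enh_end + shift,
                          prom_start = prom_start + shift,
                          prom_end = prom_end + shift)
  loops2 <- dplyr::mutate(loops,
                          a1_start = a1_start + shift,
                          a1_end = a1_end + shift,
                          a2_start = a2_start + shift,
                          a2_end = a2_end + shift)
  ep2 <- ep_constraint(links2, loops2)
  expect_equal(ep2$per_link$cross, ep$per_link$cross)
  expect_equal(ep2$per_link$contain, ep$per_link$contain)
})

test_that("enrichment ratios use the pseudo-count rule on zeros", {
  loops <- ep_toy()
  links <- dplyr::tibble(
    chrom = "chr1",
    enh_start = c(2000L, 2500L, 4000L, 4500L),
    enh_end = c(2050L, 2550L, 4050L, 4550L),
    prom_start = c(3000L, 3500L, 6000L, 6500L),
    prom_end = c(3050L, 3550L, 6050L, 6550L),
    label = c(TRUE, TRUE, FALSE, FALSE)
  )
  ep <- ep_constraint(links, loops)
  s <- ep$summary
  # the crossing group holds only false links: raw ratio undefined (0/2)
  expect_equal(s$n_true[s$group == "cross"], 0)
  expect_equal(s$n_false[s$group == "cross"], 2)
  expect_equal(s$tf_ratio_adj[s$group == "cross"], 0.5 / 2.5)
  # not-cross group holds the two true links
  expect_equal(s$tf_ratio_adj[s$group == "not_cross"], 2.5 / 0.5)
  enr <- ep$enrichment
  expect_equal(enr$enrichment_adj[enr$comparison == "not_cross vs cross"],
               25)
  # empty loop set: zero counts, flagged enrichment
  ep0 <- ep_constraint(links, loops[0, ])
  expect_true(all(ep0$per_link$cross == 0))
  expect_true(all(is.na(ep0$enrichment$enrichment)))
})

test_that("cell-type comparison partitions the top loop sets", {
  a <- dplyr::tibble(
    loop_id = paste0("a", 1:3), chrom = "chr1",
    a1_start = c(100L, 5000L, 9000L), a1_end = c(300L, 5200L, 9200L),
    a2_start = c(2000L, 7000L, 12000L), a2_end = c(2200L, 7200L, 12200L),
    pet_count = c(10L, 8L, 6L))
  # two loops anchor-match a's first two; one is elsewhere
  b <- dplyr::tibble(
    loop_id = paste0("b", 1:3), chrom = "chr1",
    a1_start = c(150L, 5100L, 50000L), a1_end = c(350L, 5300L, 50200L),
    a2_start = c(2100L, 7100L, 60000L), a2_end = c(2300L, 7300L, 60200L),
    pet_count = c(5L, 4L, 3L))
  cc <- suppressWarnings(celltype_compare(a, b, top_n = 10000))
  expect_equal(cc$summary$n_shared, c(2L, 2L))
  expect_equal(nrow(cc$specific_a), 1)
  expect_equal(cc$specific_a$loop_id, "a3")

  ident <- suppressWarnings(celltype_compare(a, a, top_n = 10000))
  expect_equal(ident$summary$frac_shared, c(1, 1))

  bshift <- dplyr::mutate(b, chrom = "chr2")
  disj <- suppressWarnings(celltype_compare(a, bshift, top_n = 10000))
  expect_equal(disj$summary$n_shared, c(0L, 0L))

  # top_n selection by PET count
  cc2 <- suppressWarnings(celltype_compare(a, b, top_n = 2))
  expect_equal(nrow(cc2$shared_a) + nrow(cc2$specific_a), 2)
  expect_warning(expect_warning(celltype_compare(a, b, top_n = 5),
                                "using all"), "using all")
})

test_that("predicted loops respect the call threshold", {
  sites <- tiny_landscape(seed = 40, n_chromosomes = 1, n_sites = 30)
  sc <- score_pairs(enumerate_pairs(sites, 1e6), sites, lce_params())
  pl <- predicted_loops(sc, threshold = 0.05)
  expect_true(all(pl$p_ij >= 0.05))
  expect_equal(nrow(pl), sum(sc$p_ij >= 0.05))
})
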