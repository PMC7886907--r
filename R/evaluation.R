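#' Matched-negative sampling to isolate loop competition from distance
#'
#' Distance and loop competition are correlated: distant anchors are more
#' likely to harbor a competing loop. To isolate their individual
#' contributions, each positive pair is matched to one negative pair with
#' the same orientation class whose joint binding term `p_i * p_j` and
#' whose matching term agree within a factor (default 2). In
#' `mode = "distance"` the distance decay `D_ij` is matched and loop
#' competition stays free; in `mode = "loop_competition"` the `LC_ij`
#' term is matched and distance stays free. Sampling is without
#' replacement, greedy over positives in seeded random order; positives
#' with no eligible negative are dropped and counted.
#'
#' @param pairs Scored, labelled pair tibble (needs `p_i`, `p_j`,
#'   `D_ij`, `LC_ij`, `d`, `ori_class`, `label`).
#' @param mode `"distance"` or `"loop_competition"`.
#' @param factor Maximum allowed ratio between matched terms (`> 1`).
#' @param seed Optional integer seed controlling match order and
#'   candidate choice.
#' @return Tibble of the retained positives and their matched negatives,
#'   with a shared `match_id`; attribute `dropped` counts unmatched
#'   positives. Matching constraints are re-asserted on every emitted
#'   pair before returning.
#' @export
matched_negatives <- function(pairs,
                              mode = c("distance", "loop_competition"),
                              factor = 2, seed = NULL) {
  mode <- match.arg(mode)
  if (factor <= 1) stop("`factor` must exceed 1", call. = FALSE)
  need <- c("p_i", "p_j", "D_ij", "LC_ij", "ori_class", "label")
  if (!all(need %in% names(pairs)))
    stop("`pairs` must be scored (see score_pairs()) and labelled",
         call. = FALSE)
  pp <- pairs$p_i * pairs$p_j
  mt <- if (mode == "distance") pairs$D_ij else pairs$LC_ij
  y <- as.logical(pairs$label)
  pos_idx <- which(y)
  neg_idx <- which(!y)
  lf <- log(factor)

  draw <- function() {
    order_pos <- sample(pos_idx)
    taken <- rep(FALSE, length(mt))
    match_pos <- integer(0)
    match_neg <- integer(0)
    for (p in order_pos) {
      ok <- neg_idx[!taken[neg_idx] &
                      pairs$ori_class[neg_idx] == pairs$ori_class[p] &
                      ratio_ok(pp[neg_idx], pp[p], lf) &
                      ratio_ok(mt[neg_idx], mt[p], lf)]
      if (length(ok) == 0L) next
      pick <- if (length(ok) == 1L) ok else sample(ok, 1L)
      taken[pick] <- TRUE
      match_pos <- c(match_pos, p)
      match_neg <- c(match_neg, pick)
    }
    list(pos = match_pos, neg = match_neg)
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  out <- dplyr::bind_rows(
    dplyr::mutate(pairs[m$pos, ], match_id = seq_along(m$pos)),
    dplyr::mutate(pairs[m$neg, ], match_id = seq_along(m$neg))
  )
  # post-hoc assertion of the matching constraints
  ppo <- out$p_i * out$p_j
  mto <- if (mode == "distance") out$D_ij else out$LC_ij
  for (id in seq_along(m$pos)) {
    rows <- which(out$match_id == id)
    stopifnot(length(rows) == 2L,
              out$ori_class[rows[1]] == out$ori_class[rows[2]],
              ratio_ok(ppo[rows[1]], ppo[rows[2]], lf),
              ratio_ok(mto[rows[1]], mto[rows[2]], lf))
  }
  attr(out, "dropped") <- length(pos_idx) - length(m$pos)
  attr(out, "mode") <- mode
  out
}

# |log(a/b)| <= lf, treating two zeros as matched
ratio_ok <- function(a, b, lf) {
  both0 <- a == 0 & b == 0
  ifelse(both0, TRUE, abs(log(a) - log(b)) <= lf)
}

#' Convert scored pairs to called loops
#'
#' Pairs with `p_ij >= threshold` become predicted loops with 1-bp
#' anchors at the site midpoints; useful for feeding model predictions
#' into [ep_constraint()] or [celltype_compare()].
#'
#' @param pairs Scored pair tibble.
#' @param threshold Probability call threshold.
#' @param score Score column to threshold.
#' @return Loop tibble in the [read_loops()] layout (with the score as a
#'   pseudo PET count rank preserved in `p_ij`).
#' @export
predicted_loops <- function(pairs, threshold = 0.05, score = "p_ij") {
  keep <- pairs[[score]] >= threshold
  dplyr::tibble(
    loop_id = sprintf("pred_%06d", seq_len(sum(keep))),
    chrom = pairs$chrom[keep],
    a1_start = pairs$pos_i[keep], a1_end = pairs$pos_i[keep] + 1L,
    a2_start = pairs$pos_j[keep], a2_end = pairs$pos_j[keep] + 1L,
    pet_count = 1L,
    p_ij = pairs[[score]][keep]
  )
}

#' Do CTCF loops constrain enhancer-promoter links?
#'
#' For each enhancer-promoter link (the segment between the enhancer and
#' promoter midpoints) counts the CTCF loops it crosses (exactly one
#' loop-anchor midpoint strictly inside the link span) and the loops that
#' contain it (both link endpoints within the loop span). Links are then
#' grouped by whether they cross or are contained by at least one loop,
#' and true/false-label ratios and their between-group enrichments are
#' reported. Zero-count ratios are additionally stabilized with a +0.5
#' Haldane-style pseudo-count; raw counts are always reported alongside.
#'
#' @param ep_links Tibble with columns `chrom`, `enh_start`, `enh_end`,
#'   `prom_start`, `prom_end`, `label` (logical or 0/1: validated
#'   interacting vs non-interacting).
#' @param loops Loop tibble ([read_loops()] or [predicted_loops()]).
#' @return An `lce_ep` object: per-link counts, group summaries and
#'   enrichment ratios. With an empty loop set all counts are zero and
#'   the enrichments are flagged `NA`.
#' @export
ep_constraint <- function(ep_links, loops) {
  need <- c("chrom", "enh_start", "enh_end", "prom_start", "prom_end",
            "label")
  if (!all(need %in% names(ep_links)))
    stop("`ep_links` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  e_mid <- (ep_links$enh_start + ep_links$enh_end) / 2
  p_mid <- (ep_links$prom_start + ep_links$prom_end) / 2
  lo <- pmin(e_mid, p_mid)
  hi <- pmax(e_mid, p_mid)
  m1 <- (loops$a1_start + loops$a1_end) / 2
  m2 <- (loops$a2_start + loops$a2_end) / 2

  n <- nrow(ep_links)
  cross <- integer(n)
  contain <- integer(n)
  for (r in seq_len(n)) {
    same <- loops$chrom == ep_links$chrom[r]
    in1 <- m1[same] > lo[r] & m1[same] < hi[r]
    in2 <- m2[same] > lo[r] & m2[same] < hi[r]
    cross[r] <- sum(xor(in1, in2))
    contain[r] <- sum(m1[same] <= lo[r] & m2[same] >= hi[r])
  }
  per_link <- dplyr::mutate(ep_links, cross = cross, contain = contain)

  grp_summary <- function(flag, name_yes, name_no) {
    dplyr::tibble(
      group = c(name_yes, name_no),
      n_true = c(sum(flag & ep_links$label), sum(!flag & ep_links$label)),
      n_false = c(sum(flag & !ep_links$label),
                  sum(!flag & !ep_links$label))
    ) |>
      dplyr::mutate(
        tf_ratio = ifelse(.data$n_false == 0, NA_real_,
                          .data$n_true / .data$n_false),
        tf_ratio_adj = (.data$n_true + 0.5) / (.data$n_false + 0.5)
      )
  }
  summary <- dplyr::bind_rows(
    grp_summary(cross >= 1, "cross", "not_cross"),
    grp_summary(contain >= 1, "contain", "not_contain")
  )
  enr <- function(top, bottom) {
    s <- summary[match(c(top, bottom), summary$group), ]
    dplyr::tibble(
      comparison = paste(top, "vs", bottom),
      enrichment = s$tf_ratio[1] / s$tf_ratio[2],
      enrichment_adj = s$tf_ratio_adj[1] / s$tf_ratio_adj[2]
    )
  }
  enrichment <- dplyr::bind_rows(enr("not_cross", "cross"),
                                 enr("contain", "not_contain"))
  if (nrow(loops) == 0L) {
    enrichment$enrichment <- NA_real_
    enrichment$enrichment_adj <- NA_real_
  }
  structure(list(per_link = per_link, summary = summary,
                 enrichment = enrichment, n_loops = nrow(loops)),
            class = "lce_ep")
}

#' @export
print.lce_ep <- function(x, ...) {
  cat("<lce_ep>", nrow(x$per_link), "E-P links vs", x$n_loops, "loops\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  print(as.data.frame(x$enrichment), row.names = FALSE)
  invisible(x)
}

#' Compare the strongest loops of two cell types
#'
#' Selects the `top_n` loops by PET count in each set and partitions each
#' top set into shared and cell-type-specific loops. Two loops are the
#' same when both anchors overlap by at least 1 bp (anchor 1 with anchor
#' 1, anchor 2 with anchor 2, same chromosome).
#'
#' @param loops_a,loops_b Loop tibbles with `pet_count`.
#' @param top_n Number of strongest loops per set (all loops with a
#'   warning when fewer are available).
#' @return An `lce_celltype` object: the four partitions and a summary
#'   tibble of counts and shared fractions.
#' @export
celltype_compare <- function(loops_a, loops_b, top_n = 10000) {
  top <- function(l, nm) {
    if (nrow(l) < top_n)
      warning("only ", nrow(l), " loops in ", nm, "; using all",
              call. = FALSE)
    dplyr::slice_head(
      dplyr::arrange(l, dplyr::desc(.data$pet_count), .data$chrom,
                     .data$a1_start, .data$a2_start),
      n = min(top_n, nrow(l)))
  }
  a <- top(loops_a, "set A")
  b <- top(loops_b, "set B")
  shared_a <- loops_shared(a, b)
  shared_b <- loops_shared(b, a)
  structure(
    list(shared_a = a[shared_a, ], specific_a = a[!shared_a, ],
         shared_b = b[shared_b, ], specific_b = b[!shared_b, ],
         summary = dplyr::tibble(
           set = c("A", "B"),
           n_top = c(nrow(a), nrow(b)),
           n_shared = c(sum(shared_a), sum(shared_b)),
           frac_shared = c(mean(shared_a), mean(shared_b))
         )),
    class = "lce_celltype"
  )
}

# logical: does each loop of `a` have a both-anchor overlap in `b`?
loops_shared <- function(a, b) {
  out <- rep(FALSE, nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (length(ib) == 0L) next
    ov1 <- IRanges::findOverlaps(
      IRanges::IRanges(a$a1_start[ia] + 1L, a$a1_end[ia]),
      IRanges::IRanges(b$a1_start[ib] + 1L, b$a1_end[ib]))
    ov2 <- IRanges::findOverlaps(
      IRanges::IRanges(a$a2_start[ia] + 1L, a$a2_end[ia]),
      IRanges::IRanges(b$a2_start[ib] + 1L, b$a2_end[ib]))
    k1 <- paste(S4Vectors::queryHits(ov1), S4Vectors::subjectHits(ov1))
    k2 <- paste(S4Vectors::queryHits(ov2), S4Vectors::subjectHits(ov2))
    hit <- unique(S4Vectors::queryHits(ov1)[k1 %in% k2])
    out[ia[hit]] <- TRUE
  }
  out
}

#' @export
print.lce_celltype <- function(x, ...) {
  cat("<lce_celltype>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
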