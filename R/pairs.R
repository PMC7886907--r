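#' Enumerate candidate CTCF site pairs within a genomic span
#'
#' All same-chromosome ordered pairs of retained (unambiguously oriented,
#' intensity-normalized) sites with midpoint distance
#' `0 < d <= max_span`. Over 96% of measured CTCF loops fall within
#' 1 Mb, the default span.
#'
#' @param sites Site tibble with `site_id`, `chrom`, `pos`, `x`,
#'   `orientation`.
#' @param max_span Maximum pair distance in bp.
#' @param drop_ambiguous Drop sites whose orientation is `"ambiguous"` or
#'   unset before pairing (default). With `FALSE`, such sites raise an
#'   error.
#' @return Pair tibble: `chrom`, `site_i`, `site_j`, `pos_i`, `pos_j`,
#'   `d`, `x_i`, `x_j`, `ori_i`, `ori_j`, `ori_class`.
#' @export
enumerate_pairs <- function(sites, max_span = 1e6, drop_ambiguous = TRUE) {
  need <- c("site_id", "chrom", "pos", "x", "orientation")
  if (!all(need %in% names(sites)))
    stop("`sites` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  keep <- sites$orientation %in% c("forward", "reverse")
  if (!all(keep)) {
    if (!drop_ambiguous)
      stop(sum(!keep), " site(s) without unambiguous orientation",
           call. = FALSE)
    sites <- sites[keep, ]
  }
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos)
  out <- lapply(split(sites, sites$chrom), function(sc) {
    n <- nrow(sc)
    if (n < 2L) return(NULL)
    hi <- findInterval(sc$pos + max_span, sc$pos)
    cnt <- hi - seq_len(n)
    if (sum(cnt) == 0L) return(NULL)
    i <- rep.int(seq_len(n), cnt)
    j <- i + sequence(cnt)
    dplyr::tibble(
      chrom = sc$chrom[i],
      site_i = sc$site_id[i], site_j = sc$site_id[j],
      pos_i = sc$pos[i], pos_j = sc$pos[j],
      d = sc$pos[j] - sc$pos[i],
      x_i = sc$x[i], x_j = sc$x[j],
      ori_i = sc$orientation[i], ori_j = sc$orientation[j]
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) return(out)
  dplyr::mutate(out, ori_class = orientation_class(.data$ori_i, .data$ori_j))
}

#' Label candidate pairs with measured loops
#'
#' A pair is positive when each anchor of a measured loop overlaps
#' exactly one retained site's peak interval (>= 1 bp overlap), those two
#' sites are the pair's anchors, and the loop's PET count reaches
#' `min_pet`. Loops with an anchor overlapping more than one peak cannot
#' be assigned unambiguously and are dropped (counted in the
#' `dropped_ambiguous` attribute); loops whose anchors match no peak are
#' counted in `unmatched_loops`, and if no loop at all touches a peak a
#' genome-assembly mismatch warning is raised. All other pairs are
#' negatives with `pet_count = 0`.
#'
#' @param pairs Pair tibble from [enumerate_pairs()].
#' @param loops Loop tibble from [read_loops()].
#' @param sites Optional site tibble carrying `peak_start` / `peak_end`;
#'   when omitted, each site is treated as the 1-bp interval at `pos`.
#' @param min_pet Minimum PET count for a positive label (4 matches
#'   deeply sequenced ChIA-PET libraries such as GM12878; 3 suits
#'   shallower ones such as HeLa).
#' @return `pairs` with integer `label` and `pet_count` columns, plus
#'   attributes `dropped_ambiguous` and `unmatched_loops`.
#' @export
label_pairs <- function(pairs, loops, sites = NULL, min_pet = 4) {
  if (is.null(sites)) {
    sites <- sites_from_pairs(pairs)
    sites$site_id <- paste0(sites$chrom, ":", sites$pos)
    sites$peak_start <- sites$pos
    sites$peak_end <- sites$pos + 1L
  }
  hits <- match_anchors(loops, sites)
  n_amb <- sum(hits$n1 > 1L | hits$n2 > 1L)
  matched <- !is.na(hits$pos1) & !is.na(hits$pos2) &
    hits$n1 == 1L & hits$n2 == 1L
  n_unmatched <- sum(hits$n1 == 0L | hits$n2 == 0L)
  if (nrow(loops) > 0L && all(hits$n1 == 0L & hits$n2 == 0L))
    warning("no loop anchor overlaps any peak; ",
            "are loops and peaks on the same assembly?", call. = FALSE)
  if (n_amb > 0L)
    message(n_amb, " loop(s) dropped: anchor overlaps more than one peak")

  lk <- dplyr::tibble(
    chrom = loops$chrom[matched],
    pos_i = pmin(hits$pos1[matched], hits$pos2[matched]),
    pos_j = pmax(hits$pos1[matched], hits$pos2[matched]),
    pet = loops$pet_count[matched]
  ) |>
    dplyr::filter(.data$pos_i < .data$pos_j) |>
    dplyr::group_by(.data$chrom, .data$pos_i, .data$pos_j) |>
    dplyr::summarise(pet = sum(.data$pet), .groups = "drop")

  out <- pairs |>
    dplyr::left_join(lk, by = c("chrom", "pos_i", "pos_j")) |>
    dplyr::mutate(
      pet_count = dplyr::coalesce(.data$pet, 0L),
      label = as.integer(.data$pet_count >= min_pet)
    ) |>
    dplyr::select(-"pet")
  attr(out, "dropped_ambiguous") <- n_amb
  attr(out, "unmatched_loops") <- n_unmatched
  out
}

# For each loop anchor: number of overlapping site peaks and, when
# unique, the matched site's pos. 0-based half-open intervals.
match_anchors <- function(loops, sites) {
  n <- nrow(loops)
  res <- list(n1 = integer(n), pos1 = rep(NA_real_, n),
              n2 = integer(n), pos2 = rep(NA_real_, n))
  for (ch in unique(loops$chrom)) {
    li <- which(loops$chrom == ch)
    sc <- sites[sites$chrom == ch, ]
    if (nrow(sc) == 0L) next
    peaks <- IRanges::IRanges(sc$peak_start + 1L, sc$peak_end)
    for (side in 1:2) {
      a_start <- if (side == 1) loops$a1_start[li] else loops$a2_start[li]
      a_end <- if (side == 1) loops$a1_end[li] else loops$a2_end[li]
      anc <- IRanges::IRanges(a_start + 1L, a_end)
      ov <- IRanges::findOverlaps(anc, peaks)
      cnt <- tabulate(S4Vectors::queryHits(ov), length(li))
      first <- sc$pos[S4Vectors::subjectHits(ov)[
        !duplicated(S4Vectors::queryHits(ov))]]
      uq <- unique(S4Vectors::queryHits(ov))
      if (side == 1) {
        res$n1[li] <- cnt
        res$pos1[li[uq]] <- first
      } else {
        res$n2[li] <- cnt
        res$pos2[li[uq]] <- first
      }
    }
  }
  res
}
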