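#' Specify a CTCF-binding site perturbation
#'
#' Models CRISPR-style edits of a single binding site: `delete` zeroes
#' the binding intensity (the site row is retained so the competition
#' bookkeeping stays explicit, but its occupancy becomes 0), `invert`
#' flips the motif orientation leaving intensity unchanged, and `scale`
#' multiplies the intensity by `factor`. When post-perturbation ChIP
#' measurements exist, `new_x` replaces the normalized intensity
#' directly.
#'
#' @param site_id Identifier of the targeted site.
#' @param action One of `"delete"`, `"invert"`, `"scale"`.
#' @param factor Multiplier for `action = "scale"` (`>= 0`).
#' @param new_x Optional replacement normalized intensity.
#' @return An `lce_perturbation` object.
#' @export
perturbation <- function(site_id, action = c("delete", "invert", "scale"),
                         factor = 1, new_x = NULL) {
  action <- match.arg(action)
  if (action == "scale" && (!is.numeric(factor) || factor < 0))
    stop("`factor` must be >= 0", call. = FALSE)
  structure(list(site_id = site_id, action = action, factor = factor,
                 new_x = new_x),
            class = "lce_perturbation")
}

#' Apply a perturbation to a site table
#'
#' @param sites Site tibble.
#' @param pert An [perturbation()] object.
#' @return The modified site tibble.
#' @export
apply_perturbation <- function(sites, pert) {
  stopifnot(inherits(pert, "lce_perturbation"))
  r <- match(pert$site_id, sites$site_id)
  if (is.na(r)) stop("unknown site_id '", pert$site_id, "'", call. = FALSE)
  if (pert$action == "delete") {
    sites$x[r] <- 0
  } else if (pert$action == "invert") {
    sites$orientation[r] <- switch(sites$orientation[r],
                                   forward = "reverse",
                                   reverse = "forward",
                                   sites$orientation[r])
    if (!is.null(pert$new_x)) sites$x[r] <- pert$new_x
  } else {
    sites$x[r] <- if (!is.null(pert$new_x)) pert$new_x
                  else sites$x[r] * pert$factor
  }
  sites
}

#' Predict before/after loop probabilities for a perturbation
#'
#' @param sites Site tibble.
#' @param pert An [perturbation()] object.
#' @param params Model parameters.
#' @param max_span Candidate pair span (bp).
#' @return Scored pair tibble with `p_ij_before`, `p_ij_after` and their
#'   ratio.
#' @export
perturbation_effect <- function(sites, pert, params = lce_params(),
                                max_span = 1e6) {
  before <- score_pairs(enumerate_pairs(sites, max_span), sites, params)
  sites2 <- apply_perturbation(sites, pert)
  after <- score_pairs(enumerate_pairs(sites2, max_span), sites2, params)
  key <- c("chrom", "site_i", "site_j")
  dplyr::full_join(
    dplyr::select(before, dplyr::all_of(key), "pos_i", "pos_j", "d",
                  "ori_class", p_ij_before = "p_ij"),
    dplyr::select(after, dplyr::all_of(key),
                  ori_class_after = "ori_class", p_ij_after = "p_ij"),
    by = key
  ) |>
    dplyr::mutate(
      p_ij_before = dplyr::coalesce(.data$p_ij_before, 0),
      p_ij_after = dplyr::coalesce(.data$p_ij_after, 0),
      ratio = .data$p_ij_after / .data$p_ij_before
    )
}

#' Predicted contact-ratio map around a weakened CTCF site
#'
#' Bins the window around the targeted site and, for every bin pair,
#' sums the model loop probabilities before (strong motif) and after
#' (weak motif) the perturbation. The ratio map mirrors the
#' population-genotype comparison design: bin pairs whose spanned
#' interval crosses the target are classified `Crossing`, bin pairs on
#' one side `Outside`, and bins directly overlapping the target are
#' `Gray` (excluded from both classes). Under reduced competition every
#' Crossing ratio is at least 1.
#'
#' @param sites Site tibble.
#' @param pert A weakening [perturbation()] (`delete` or `scale` with
#'   `factor < 1`).
#' @param params Model parameters.
#' @param window Half-width of the mapped window around the target (bp).
#' @param bin Bin width in bp (must not exceed `window`).
#' @param max_span Candidate pair span (bp).
#' @return An `lce_contact_map`: tibble of bin pairs with `p_before`,
#'   `p_after`, `ratio` and `class`; attribute `target_pos`.
#' @export
crossing_outside_map <- function(sites, pert, params = lce_params(),
                                 window = 8e5, bin = 4e4,
                                 max_span = 1e6) {
  if (window < bin) stop("`window` must be at least `bin`", call. = FALSE)
  if (pert$action == "invert" ||
      (pert$action == "scale" && pert$factor >= 1 && is.null(pert$new_x)))
    stop("the perturbation must weaken the target (delete or scale < 1)",
         call. = FALSE)
  r <- match(pert$site_id, sites$site_id)
  if (is.na(r)) stop("unknown site_id", call. = FALSE)
  target_pos <- sites$pos[r]
  target_chrom <- sites$chrom[r]

  eff <- perturbation_effect(sites, pert, params, max_span) |>
    dplyr::filter(.data$chrom == target_chrom,
                  .data$pos_i >= target_pos - window,
                  .data$pos_j <= target_pos + window)
  breaks <- seq(target_pos - window, target_pos + window, by = bin)
  eff$bin_i <- findInterval(eff$pos_i, breaks, rightmost.closed = TRUE)
  eff$bin_j <- findInterval(eff$pos_j, breaks, rightmost.closed = TRUE)
  target_bin <- findInterval(target_pos, breaks, rightmost.closed = TRUE)

  map <- eff |>
    dplyr::group_by(.data$bin_i, .data$bin_j) |>
    dplyr::summarise(p_before = sum(.data$p_ij_before),
                     p_after = sum(.data$p_ij_after),
                     .groups = "drop") |>
    dplyr::mutate(
      start_i = breaks[.data$bin_i], start_j = breaks[.data$bin_j],
      ratio = .data$p_after / .data$p_before,
      class = dplyr::case_when(
        .data$bin_i == target_bin | .data$bin_j == target_bin ~ "Gray",
        .data$bin_i < target_bin & .data$bin_j > target_bin ~ "Crossing",
        TRUE ~ "Outside"
      )
    )
  structure(map, class = c("lce_contact_map", class(map)),
            target_pos = target_pos, bin = bin)
}

#' Scan pass-through probability as a WAPL-loss model
#'
#' Recomputes all loop probabilities for each Cohesin pass-through
#' probability `s` and calls loops at a fixed probability threshold.
#' Because every competing-loop factor `1 - (1 - s) p` rises with `s`,
#' loop probabilities - and hence the called-loop count - are
#' nondecreasing in `s`; long loops, which face more competitors, gain
#' the most, so the mean called-loop length grows as well.
#'
#' @param sites Site tibble.
#' @param params Model parameters (its `s` is overridden by `s_values`).
#' @param s_values Pass-through probabilities to scan, within `[0, 1]`.
#' @param call_threshold Probability above which a pair is called a loop.
#' @param max_span Candidate pair span (bp).
#' @return Tibble with columns `s`, `n_loops`, `mean_length`.
#' @export
waplko_scan <- function(sites, params = lce_params(),
                        s_values = seq(0, 1, by = 0.1),
                        call_threshold = 0.05, max_span = 1e6) {
  if (any(s_values < 0 | s_values > 1))
    stop("`s_values` must lie in [0, 1]", call. = FALSE)
  pairs <- enumerate_pairs(sites, max_span)
  purrr::map_dfr(s_values, function(s) {
    p <- params
    p$s <- s
    sc <- score_pairs(pairs, sites, p)
    called <- sc$p_ij >= call_threshold
    dplyr::tibble(
      s = s,
      n_loops = sum(called),
      mean_length = if (any(called)) mean(sc$d[called]) else NA_real_
    )
  })
}
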