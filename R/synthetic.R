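#' Configuration for synthetic CTCF landscape generation
#'
#' Describes a genome of chromosomes carrying CTCF-binding sites with
#' geometric inter-site spacing, log-normal binding intensities and
#' i.i.d. motif orientations, plus the "true" model parameters used to
#' draw loop labels. The defaults emulate the statistical shape of a
#' mammalian CTCF landscape at reduced scale: 10 chromosomes of 5 Mb
#' with 200 sites each (mean spacing 25 kb).
#'
#' @param n_chromosomes,chrom_length,n_sites Genome geometry; `n_sites`
#'   is per chromosome (`>= 2`).
#' @param spacing_mean Mean inter-site spacing in bp (geometric
#'   distribution).
#' @param intensity_sdlog Log-scale standard deviation of the log-normal
#'   raw signal; 1.25 gives the broad dynamic range typical of CTCF
#'   ChIP-seq peak strengths.
#' @param signal_to_background Ratio of the mean peak signal to the
#'   genome-background signal used for normalization. Peaks are enriched
#'   over background, so their normalized intensity `x` averages well
#'   above 1; with `signal_to_background = 1` the site-mean of `x` is
#'   exactly 1.
#' @param p_forward Probability of a forward-strand motif.
#' @param params True [lce_params()] generating the labels.
#' @param mechanism Label-drawing mechanism, see [generate_labels()].
#' @param pet_coef Poisson coefficient for synthetic PET counts; the
#'   default was calibrated once so the median positive PET count is
#'   about 6, keeping the usual count filters (3-4 PETs) meaningful.
#' @param max_span Candidate pair span in bp.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An `lce_synth_config` object.
#' @export
synthetic_config <- function(n_chromosomes = 10, chrom_length = 5e6,
                             n_sites = 200, spacing_mean = 25e3,
                             intensity_sdlog = 1.25,
                             signal_to_background = 10,
                             p_forward = 0.5,
                             params = lce_params(),
                             mechanism = c("bernoulli_closed_form",
                                           "occupancy_then_extrude"),
                             pet_coef = 60, max_span = 1e6, seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_sites >= 2, n_chromosomes >= 1, chrom_length > 0,
            spacing_mean > 0, intensity_sdlog > 0,
            signal_to_background > 0,
            p_forward >= 0, p_forward <= 1, inherits(params, "lce_params"))
  structure(
    list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
         n_sites = n_sites, spacing_mean = spacing_mean,
         intensity_sdlog = intensity_sdlog,
         signal_to_background = signal_to_background,
         p_forward = p_forward, params = params, mechanism = mechanism,
         pet_coef = pet_coef, max_span = max_span,
         seed = as.integer(seed)),
    class = "lce_synth_config"
  )
}

#' Generate a synthetic CTCF site landscape
#'
#' Site positions are cumulative geometric spacings (redrawn, up to 1000
#' attempts, if a chromosome overflows its length); raw signals are
#' log-normal; normalized intensity is `x = signal_raw / background`
#' where the background is set so that `mean(x)` equals
#' `signal_to_background` exactly. Peaks are 500 bp intervals centered
#' on the site. Deterministic given `cfg$seed`.
#'
#' @param cfg An [synthetic_config()] object.
#' @return A site tibble (columns as in [read_narrowpeak()] plus `x`).
#' @export
generate_sites <- function(cfg) {
  stopifnot(inherits(cfg, "lce_synth_config"))
  withr::with_seed(cfg$seed, {
    chroms <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
      pos <- NULL
      for (attempt in seq_len(1000L)) {
        sp <- stats::rgeom(cfg$n_sites, 1 / cfg$spacing_mean) + 1L
        cand <- cumsum(sp)
        if (cand[cfg$n_sites] <= cfg$chrom_length) { pos <- cand; break }
      }
      if (is.null(pos))
        stop("sites do not fit in chrom_length after 1000 attempts; ",
             "increase chrom_length or reduce n_sites/spacing_mean",
             call. = FALSE)
      dplyr::tibble(
        chrom = sprintf("chr%d", ci),
        pos = as.integer(pos),
        orientation = ifelse(
          stats::runif(cfg$n_sites) < cfg$p_forward, "forward", "reverse"),
        signal_raw = stats::rlnorm(cfg$n_sites, meanlog = 0,
                                   sdlog = cfg$intensity_sdlog)
      )
    })
    sites <- dplyr::bind_rows(chroms)
    background <- mean(sites$signal_raw) / cfg$signal_to_background
    sites |>
      dplyr::mutate(
        site_id = sprintf("%s_s%04d", .data$chrom,
                          stats::ave(seq_len(nrow(sites)), sites$chrom,
                                     FUN = seq_along)),
        peak_start = pmax(0L, .data$pos - 250L),
        peak_end = pmin(as.integer(cfg$chrom_length), .data$pos + 250L),
        x = .data$signal_raw / background
      ) |>
      dplyr::select("site_id", "chrom", "peak_start", "peak_end", "pos",
                    "orientation", "signal_raw", "x")
  })
}

#' Draw loop labels from the model
#'
#' Two mechanisms. `bernoulli_closed_form` draws each pair's label
#' independently as `Bernoulli(p_ij)` from the approximate-competition
#' closed form — labels embody the model exactly, pair by pair.
#' `occupancy_then_extrude` is mechanistic: CTCF occupancy is sampled
#' per site as `Bernoulli(p_i)`, then each chromosome is walked and a
#' loop candidate is placed between every pair of successive occupied
#' sites (so a formed loop excludes all candidates overlapping it) and
#' accepted with the orientation/distance probability `w_ij * D_ij`.
#' Positives receive a synthetic PET count `1 + Poisson(pet_coef *
#' p_ij)`.
#'
#' @param sites Site tibble from [generate_sites()].
#' @param params True model parameters.
#' @param mechanism See above.
#' @param seed Integer seed.
#' @param max_span Candidate pair span (bp).
#' @param pet_coef Poisson coefficient for PET counts.
#' @return Labelled, scored pair tibble.
#' @export
generate_labels <- function(sites, params = lce_params(),
                            mechanism = c("bernoulli_closed_form",
                                          "occupancy_then_extrude"),
                            seed = 1, max_span = 1e6, pet_coef = 60) {
  mechanism <- match.arg(mechanism)
  pairs <- score_pairs(enumerate_pairs(sites, max_span), sites, params)
  withr::with_seed(as.integer(seed), {
    if (mechanism == "bernoulli_closed_form") {
      lab <- stats::rbinom(nrow(pairs), 1L, pairs$p_ij)
    } else {
      occ_p <- binding_probability(sites$x, params)
      occ <- stats::rbinom(nrow(sites), 1L, occ_p) == 1L
      lab <- rep(0L, nrow(pairs))
      for (ch in unique(sites$chrom)) {
        sc <- sites[sites$chrom == ch & occ, ]
        if (nrow(sc) < 2L) next
        sc <- dplyr::arrange(sc, .data$pos)
        pi_ <- sc$pos[-nrow(sc)]
        pj_ <- sc$pos[-1L]
        keep <- (pj_ - pi_) <= max_span
        if (!any(keep)) next
        idx <- match(paste(ch, pi_[keep], pj_[keep]),
                     paste(pairs$chrom, pairs$pos_i, pairs$pos_j))
        acc <- pairs$w_ij[idx] * pairs$D_ij[idx]
        lab[idx] <- stats::rbinom(length(idx), 1L, acc)
      }
    }
    pet <- ifelse(lab == 1L,
                  1L + stats::rpois(nrow(pairs), pet_coef * pairs$p_ij),
                  0L)
    dplyr::mutate(pairs, label = as.integer(lab),
                  pet_count = as.integer(pet))
  })
}

#' Simulate a full labelled landscape
#'
#' Convenience wrapper: [generate_sites()] then [generate_labels()]
#' (label seed derived as `cfg$seed + 1`).
#'
#' @param cfg An [synthetic_config()] object.
#' @return List with elements `sites` and `pairs`.
#' @export
simulate_landscape <- function(cfg) {
  sites <- generate_sites(cfg)
  pairs <- generate_labels(sites, cfg$params, cfg$mechanism,
                           seed = cfg$seed + 1L, max_span = cfg$max_span,
                           pet_coef = cfg$pet_coef)
  list(sites = sites, pairs = pairs)
}

#' Exact loop probabilities under the extrusion-with-exclusion mechanism
#'
#' Brute-force enumeration oracle for small instances: sums over all
#' `2^n` CTCF occupancy configurations, weights each by its probability,
#' and accumulates for every candidate pair the probability that the two
#' anchors are successive occupied sites (loops never span an occupied
#' site, so overlapping loops are mutually exclusive by construction)
#' times the orientation/distance acceptance `w_ij * D_ij`. Defined for
#' the complete-blocking model (`s = 0`).
#'
#' @param sites Site tibble (at most `max_sites` rows).
#' @param params Model parameters with `s = 0`.
#' @param max_span Candidate pair span (bp).
#' @param max_sites Enumeration cap (default 12).
#' @return Pair tibble with column `p_exact`.
#' @export
brute_force_pij <- function(sites, params = lce_params(), max_span = 1e6,
                            max_sites = 12L) {
  if (nrow(sites) > max_sites)
    stop("instance too large for enumeration (", nrow(sites), " sites, ",
         "cap ", max_sites, ")", call. = FALSE)
  if (params$s != 0)
    stop("the exclusion mechanism is defined for complete blocking ",
         "(s = 0)", call. = FALSE)
  pairs <- enumerate_pairs(sites, max_span)
  pairs$p_exact <- 0
  for (ch in unique(sites$chrom)) {
    sc <- dplyr::arrange(sites[sites$chrom == ch, ], .data$pos)
    n <- nrow(sc)
    if (n < 2L) next
    p <- binding_probability(sc$x, params)
    for (cfg_idx in 0:(2^n - 1)) {
      occ <- as.logical(bitwAnd(cfg_idx, 2^(0:(n - 1))))
      w_cfg <- prod(ifelse(occ, p, 1 - p))
      if (w_cfg == 0 || sum(occ) < 2L) next
      oi <- which(occ)
      for (k in seq_len(length(oi) - 1L)) {
        i <- oi[k]; j <- oi[k + 1L]
        if (sc$pos[j] - sc$pos[i] > max_span) next
        row <- which(pairs$chrom == ch & pairs$pos_i == sc$pos[i] &
                       pairs$pos_j == sc$pos[j])
        acc <- orientation_weight(sc$orientation[i], sc$orientation[j],
                                  params) *
          distance_decay(sc$pos[j] - sc$pos[i], params)
        pairs$p_exact[row] <- pairs$p_exact[row] + w_cfg * acc
      }
    }
  }
  pairs
}
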