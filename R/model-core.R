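#' Occupancy probability of a CTCF-binding site
#'
#' Maps normalized ChIP-seq intensity `x` (signal divided by its genome
#' average) to the probability that the site is CTCF-bound, via the
#' chemical-equilibrium form `p = x / (x + a)` (`binding = "hill"`) or the
#' alternative saturating form `p = tanh(a * x)` (`binding = "tanh"`).
#' Both are strictly increasing in `x` and map 0 to 0.
#'
#' @param x Numeric vector of normalized intensities (`>= 0`).
#' @param params An [lce_params()] object.
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @examples
#' binding_probability(c(0, 8.5, 25.5), lce_params(a = 8.5))
#' @export
binding_probability <- function(x, params = lce_params()) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(is.na(x)) || any(x < 0))
    stop("normalized intensity `x` must be >= 0 and non-missing",
         call. = FALSE)
  switch(params$binding,
         hill = x / (x + params$a),
         tanh = tanh(params$a * x))
}

#' Orientation class of an ordered CTCF site pair
#'
#' For a pair ordered by coordinate (`ori_i` upstream), forward/reverse
#' motifs facing each other are `convergent`, same-direction motifs are
#' `tandem`, and motifs facing away are `divergent`.
#'
#' @param ori_i,ori_j Character vectors with values `"forward"` or
#'   `"reverse"`; `"ambiguous"` is an error (such sites must be excluded
#'   before pairing).
#' @return Character vector with values `"convergent"`, `"tandem"`,
#'   `"divergent"`.
#' @export
orientation_class <- function(ori_i, ori_j) {
  ok <- c("forward", "reverse")
  if (any(is.na(ori_i)) || any(is.na(ori_j)) ||
      !all(ori_i %in% ok) || !all(ori_j %in% ok))
    stop("orientations must be 'forward' or 'reverse'; ",
         "ambiguous sites must be removed before pairing", call. = FALSE)
  dplyr::case_when(
    ori_i == "forward" & ori_j == "reverse" ~ "convergent",
    ori_i == ori_j ~ "tandem",
    TRUE ~ "divergent"
  )
}

#' Orientation weight of a CTCF site pair
#'
#' Convergent pairs carry weight 1 (the reference configuration), tandem
#' pairs `1/w` and divergent pairs `1/w^2`; with the general
#' parameterization (`w1`, `w2` set in `params`) tandem is `1/w1` and
#' divergent `1/w2`.
#'
#' @inheritParams orientation_class
#' @inheritParams binding_probability
#' @return Numeric vector of weights in `(0, 1]`.
#' @examples
#' orientation_weight("forward", "reverse", lce_params(w = 3)) # 1
#' orientation_weight("forward", "forward", lce_params(w = 3)) # 1/3
#' @export
orientation_weight <- function(ori_i, ori_j, params = lce_params()) {
  cls <- orientation_class(ori_i, ori_j)
  pen <- ori_penalties(params)
  unname(c(convergent = 1, tandem = pen[1], divergent = pen[2])[cls])
}

#' Distance decay term
#'
#' Probability that translocating Cohesin survives the extrusion of a loop
#' of genomic span `d`. A constant per-bp dissociation rate gives
#' `exp(-d / lambda)`; the power-law alternative is `min(1, (d/1000)^-k)`
#' with `d` expressed in kb so the term never exceeds 1 beyond 1 kb;
#' `decay = "none"` returns 1 (distance ignored).
#'
#' @param d Numeric vector of midpoint-to-midpoint distances in bp (`> 0`).
#' @inheritParams binding_probability
#' @return Numeric vector in `(0, 1]`.
#' @export
distance_decay <- function(d, params = lce_params()) {
  if (!is.numeric(d) || any(is.na(d)) || any(d <= 0))
    stop("distances `d` must be positive", call. = FALSE)
  switch(params$decay,
         exponential = exp(-d / params$lam),
         powerlaw = pmin(1, (d / 1000)^(-params$k)),
         none = rep(1, length(d)))
}

#' Approximate loop-competition term from internal site occupancies
#'
#' The approximate loop-competition model requires every retained CTCF
#' site strictly between the two anchors to be unoccupied:
#' `LC_ij = prod(1 - p_m)` over internal sites `m`. With pass-through
#' probability `s > 0` each factor relaxes to `1 - (1 - s) * p_m`.
#' The product is accumulated in log space.
#'
#' @param p_internal Numeric vector of occupancy probabilities of the
#'   sites strictly between the anchors (may be empty).
#' @param s Pass-through probability in `[0, 1]`.
#' @return A single number in `(0, 1]`; 1 for the empty product.
#' @examples
#' lc_approx(numeric(0)) # 1
#' lc_approx(c(0.5, 0.5)) # 0.25
#' lc_approx(0.5, s = 0.4) # 0.7
#' @export
lc_approx <- function(p_internal, s = 0) {
  if (length(p_internal) == 0L) return(1)
  if (any(is.na(p_internal)) || any(p_internal < 0) || any(p_internal > 1))
    stop("occupancy probabilities must lie in [0, 1]", call. = FALSE)
  if (length(s) != 1L || is.na(s) || s < 0 || s > 1)
    stop("`s` must lie in [0, 1]", call. = FALSE)
  exp(sum(log1p(-(1 - s) * p_internal)))
}

# Internal: add occupancy, orientation, distance and approximate-LC
# columns to a pair table. `sites` must contain every retained site of
# the chromosomes involved (needed for the internal-site product).
score_pairs_impl <- function(pairs, sites, params) {
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos)
  if (anyDuplicated(sites[c("chrom", "pos")]))
    stop("duplicated site positions within a chromosome", call. = FALSE)
  p_site <- binding_probability(sites$x, params)
  lut <- sites |>
    dplyr::mutate(.l = log1p(-(1 - params$s) * p_site)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.cs = cumsum(.data$.l)) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "pos", ".l", ".cs")

  out <- pairs |>
    dplyr::left_join(dplyr::select(lut, "chrom", "pos", .cs_i = ".cs"),
                     by = c("chrom", pos_i = "pos")) |>
    dplyr::left_join(dplyr::rename(lut, .l_j = ".l", .cs_j = ".cs"),
                     by = c("chrom", pos_j = "pos"))
  if (anyNA(out$.cs_i) || anyNA(out$.cs_j))
    stop("some pair anchors are absent from `sites`; supply the full ",
         "retained site table", call. = FALSE)

  d <- out$pos_j - out$pos_i
  if (any(d <= 0)) stop("pairs must satisfy pos_i < pos_j", call. = FALSE)
  out |>
    dplyr::mutate(
      d = d,
      ori_class = orientation_class(.data$ori_i, .data$ori_j),
      p_i = binding_probability(.data$x_i, params),
      p_j = binding_probability(.data$x_j, params),
      w_ij = orientation_weight(.data$ori_i, .data$ori_j, params),
      D_ij = if (params$decay == "none") 1 else distance_decay(d, params),
      # cumulative-sum differences can leave |eps| ~ 1e-16 residue
      LC_ij = pmin(1, exp(.data$.cs_j - .data$.l_j - .data$.cs_i)),
      p_ij = .data$w_ij * .data$p_i * .data$p_j * .data$D_ij * .data$LC_ij
    ) |>
    dplyr::select(-".cs_i", -".cs_j", -".l_j")
}

#' Score candidate pairs with the closed-form loop probability
#'
#' Populates, for every candidate pair, the four model terms and their
#' product: occupancy probabilities `p_i`, `p_j`, orientation weight
#' `w_ij`, distance decay `D_ij`, the approximate loop-competition term
#' `LC_ij` (product of `1 - p_m` over all retained sites strictly between
#' the anchors, regardless of their orientation) and the loop probability
#' `p_ij = w_ij * p_i * p_j * D_ij * LC_ij`.
#'
#' @param pairs A pair table as produced by [enumerate_pairs()]: columns
#'   `chrom`, `pos_i`, `pos_j`, `x_i`, `x_j`, `ori_i`, `ori_j` (extra
#'   columns pass through).
#' @param sites The full retained site table (columns `chrom`, `pos`,
#'   `x`); defaults to the sites reconstructable from `pairs`, which is
#'   exact whenever every retained site appears in at least one pair.
#' @inheritParams binding_probability
#' @return The pair tibble with columns `d`, `ori_class`, `p_i`, `p_j`,
#'   `w_ij`, `D_ij`, `LC_ij`, `p_ij` added or replaced.
#' @seealso [solve_loops()] for the full iterative loop-competition term.
#' @export
score_pairs <- function(pairs, sites = NULL, params = lce_params()) {
  stopifnot(is.data.frame(pairs))
  need <- c("chrom", "pos_i", "pos_j", "x_i", "x_j", "ori_i", "ori_j")
  if (!all(need %in% names(pairs)))
    stop("`pairs` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(sites)) sites <- sites_from_pairs(pairs)
  score_pairs_impl(pairs, sites, params)
}

#' Reconstruct the site table underlying a pair table
#'
#' @param pairs A pair table with anchor columns.
#' @return Tibble with columns `chrom`, `pos`, `x`, `orientation`.
#' @export
sites_from_pairs <- function(pairs) {
  dplyr::bind_rows(
    dplyr::tibble(chrom = pairs$chrom, pos = pairs$pos_i, x = pairs$x_i,
                  orientation = pairs$ori_i),
    dplyr::tibble(chrom = pairs$chrom, pos = pairs$pos_j, x = pairs$x_j,
                  orientation = pairs$ori_j)
  ) |>
    dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Loop probability for a single pair of sites
#'
#' Convenience wrapper around [score_pairs()] for one pair, identified by
#' site id. Errors if the two sites lie on different chromosomes.
#'
#' @param sites Site table with columns `site_id`, `chrom`, `pos`, `x`,
#'   `orientation`.
#' @param site_i,site_j Site ids of the two anchors.
#' @inheritParams binding_probability
#' @return One-row tibble with the decomposed terms and `p_ij`.
#' @export
loop_probability <- function(sites, site_i, site_j, params = lce_params()) {
  a <- sites[match(site_i, sites$site_id), ]
  b <- sites[match(site_j, sites$site_id), ]
  if (anyNA(a$pos) || anyNA(b$pos))
    stop("unknown site id", call. = FALSE)
  if (a$chrom != b$chrom)
    stop("sites lie on different chromosomes", call. = FALSE)
  if (a$pos > b$pos) { tmp <- a; a <- b; b <- tmp }
  pair <- dplyr::tibble(
    chrom = a$chrom, site_i = a$site_id, site_j = b$site_id,
    pos_i = a$pos, pos_j = b$pos, x_i = a$x, x_j = b$x,
    ori_i = a$orientation, ori_j = b$orientation
  )
  score_pairs_impl(pair, sites, params)
}
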