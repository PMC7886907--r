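#' Model parameters for the loop competition and extrusion model
#'
#' Bundles the constants of the loop probability model. The probability
#' that two CTCF-binding sites `i < j` anchor a loop decomposes as
#' `p_ij = w_ij * p_i * p_j * D_ij * LC_ij`, where `p_i` is the occupancy
#' probability of a site, `w_ij` the orientation weight, `D_ij` a distance
#' decay and `LC_ij` the loop-competition term.
#'
#' @param a Dimensionless ratio of the genome-average dissociation constant
#'   to nuclear CTCF concentration, `<Kd>/[CTCF]`. Converts normalized
#'   ChIP-seq intensity `x` into an occupancy probability `p = x/(x + a)`.
#'   Default 8.5, the value that maximizes agreement with GM12878 ChIA-PET
#'   loops.
#' @param w Orientation penalty (`>= 1`). Convergent motif pairs carry
#'   weight 1, tandem pairs `1/w`, divergent pairs `1/w^2`. Default 3.
#' @param w1,w2 Optional general tandem and divergent penalties. When both
#'   are supplied they override `w` and `w^2`.
#' @param lam Decay length lambda of the exponential distance term, in bp
#'   (interpretable as Cohesin processivity). `NA` or `NULL` disables the
#'   distance term (`D_ij = 1`); this also sets `decay = "none"`.
#'   Default 3e6.
#' @param decay One of `"exponential"` (`exp(-d/lam)`), `"powerlaw"`
#'   (`min(1, (d/1000)^-k)`; distances in kb so the term stays below 1
#'   over the modeled range) or `"none"`.
#' @param k Power-law exponent, used only when `decay = "powerlaw"`.
#' @param s Cohesin pass-through probability in `[0, 1]`. With `s > 0`
#'   every competing-loop factor `1 - p` becomes `1 - (1 - s) * p`,
#'   attenuating loop competition; models WAPL loss. Default 0
#'   (complete blocking).
#' @param binding Occupancy parameterization: `"hill"` for `x/(x + a)` or
#'   `"tanh"` for `tanh(a * x)` (an alternative saturating form with its
#'   own scale `a`).
#'
#' @return An object of class `lce_params`.
#' @examples
#' lce_params()
#' lce_params(w = 3.5, lam = NA) # no distance term
#' @export
lce_params <- function(a = 8.5, w = 3, w1 = NULL, w2 = NULL,
                       lam = 3e6,
                       decay = c("exponential", "powerlaw", "none"),
                       k = 1, s = 0,
                       binding = c("hill", "tanh")) {
  decay <- match.arg(decay)
  binding <- match.arg(binding)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a single positive number", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 1)
    stop("`w` must be a single number >= 1", call. = FALSE)
  if (xor(is.null(w1), is.null(w2)))
    stop("supply both `w1` and `w2`, or neither", call. = FALSE)
  if (!is.null(w1)) {
    if (w1 < 1 || w2 < 1)
      stop("`w1` and `w2` must be >= 1", call. = FALSE)
  }
  if (is.null(lam) || (length(lam) == 1L && is.na(lam))) {
    lam <- NA_real_
    if (decay == "exponential") decay <- "none"
  }
  if (decay == "exponential" && (!is.finite(lam) || lam <= 0))
    stop("`lam` must be positive for exponential decay", call. = FALSE)
  if (decay == "powerlaw" && (!is.numeric(k) || k <= 0))
    stop("`k` must be positive for power-law decay", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1)
    stop("`s` must lie in [0, 1]", call. = FALSE)
  structure(
    list(a = a, w = w, w1 = w1, w2 = w2, lam = as.numeric(lam),
         decay = decay, k = k, s = s, binding = binding),
    class = "lce_params"
  )
}

#' @export
print.lce_params <- function(x, ...) {
  cat("<lce_params>\n")
  cat("  binding :", x$binding, "(a =", x$a, ")\n")
  if (is.null(x$w1)) {
    cat("  orientation: w =", x$w,
        sprintf("(convergent 1, tandem %.4g, divergent %.4g)\n",
                1 / x$w, 1 / x$w^2))
  } else {
    cat("  orientation: w1 =", x$w1, ", w2 =", x$w2, "\n")
  }
  cat("  decay   :", x$decay,
      if (x$decay == "exponential") paste0("(lambda = ", x$lam, " bp)")
      else if (x$decay == "powerlaw") paste0("(k = ", x$k, ")")
      else "", "\n")
  cat("  pass-through s =", x$s, "\n")
  invisible(x)
}

# tandem and divergent penalties as a length-2 vector c(1/w1, 1/w2)
ori_penalties <- function(params) {
  if (!is.null(params$w1)) c(1 / params$w1, 1 / params$w2)
  else c(1 / params$w, 1 / params$w^2)
}

#' Solver settings for the iterative loop-competition fixed point
#'
#' @param b Over-relaxation rate (`>= 0`); the update is
#'   `p_new = (p_proposed + b * p_old) / (1 + b)`. `b = 0` is plain
#'   fixed-point iteration; larger values damp more strongly. The solution
#'   is independent of `b` over a wide range; only the approach speed
#'   changes.
#' @param tol Convergence threshold on the maximum absolute change of any
#'   pair probability between iterations.
#' @param max_iter Iteration cap; non-convergence is flagged, not silent.
#'
#' @return An object of class `lce_solver_control`.
#' @export
solver_control <- function(b = 1, tol = 1e-6, max_iter = 500L) {
  stopifnot(is.numeric(b), length(b) == 1L, b >= 0,
            is.numeric(tol), tol > 0,
            is.numeric(max_iter), max_iter >= 1)
  structure(list(b = b, tol = tol, max_iter = as.integer(max_iter)),
            class = "lce_solver_control")
}
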