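# Shared in-code fixtures and independent oracles.

# Minimal site table at given positions (single chromosome by default).
make_sites <- function(pos, x = 8.5, orientation = "forward",
                       chrom = "chr1") {
  n <- length(pos)
  dplyr::tibble(
    site_id = sprintf("s%02d", seq_len(n)),
    chrom = rep_len(chrom, n),
    peak_start = as.integer(pos - 250L),
    peak_end = as.integer(pos + 250L),
    pos = as.integer(pos),
    orientation = rep_len(orientation, n),
    signal_raw = rep_len(x, n),
    x = rep_len(x, n)
  )
}

# Independent dense fixed-point oracle for the full loop-competition
# system: explicit overlap matrix, heavily damped iteration run to a
# much tighter tolerance than the package solver, from several
# initializations (all must agree).
fp_oracle <- function(pos_i, pos_j, q, s = 0, tol = 1e-12) {
  n <- length(q)
  ov <- outer(seq_len(n), seq_len(n),
              function(i, j) pos_i[j] < pos_j[i] & pos_i[i] < pos_j[j])
  diag(ov) <- FALSE
  solve_from <- function(p) {
    for (it in 1:20000) {
      target <- q * vapply(seq_len(n), function(i)
        prod(1 - (1 - s) * p[ov[i, ]]), numeric(1))
      if (max(abs(target - p)) < tol) return(target)
      p <- 0.5 * p + 0.5 * target
    }
    stop("oracle did not converge")
  }
  sols <- lapply(list(q, rep(0, n), rep(0.99 * min(1, max(q)), n)),
                 solve_from)
  for (k in 2:length(sols))
    stopifnot(max(abs(sols[[k]] - sols[[1]])) < 1e-8)
  sols[[1]]
}

# A small deterministic two-chromosome landscape used by several tests.
tiny_landscape <- function(seed = 42, n_chromosomes = 2, n_sites = 60) {
  cfg <- synthetic_config(n_chromosomes = n_chromosomes,
                          chrom_length = 2e6, n_sites = n_sites,
                          spacing_mean = 3e4, seed = seed)
  generate_sites(cfg)
}
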