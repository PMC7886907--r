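#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR PFM text layout: a `>` header line followed by four
#' rows of per-position counts, either bracketed (`A [ 87 167 ... ]`) or
#' raw. Counts are converted to a log2-odds position weight matrix
#' against the background with a pseudocount.
#'
#' @param path File path.
#' @param pseudocount Added to every count before frequency conversion.
#' @param background Base composition, a length-4 vector summing to 1;
#'   uniform by default.
#' @return An `lce_pwm` object: list with `motif_id`, `counts` (4 x L),
#'   `pwm` (4 x L log2-odds, rows ACGT), `max_score`, `min_score`.
#' @export
read_jaspar <- function(path, pseudocount = 0.8,
                        background = rep(0.25, 4)) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  motif_id <- if (any(hdr)) sub("^>\\s*", "", lines[which(hdr)[1]]) else "motif"
  rows <- lines[!hdr]
  if (length(rows) < 4L)
    stop("JASPAR PFM must have four base rows", call. = FALSE)
  rows <- rows[1:4]
  base_letters <- toupper(substr(trimws(rows), 1, 1))
  parse_row <- function(r) {
    r <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", r)
    r <- gsub("[][]", " ", r)
    as.numeric(strsplit(trimws(r), "[ \t]+")[[1]])
  }
  counts <- do.call(rbind, lapply(rows, parse_row))
  if (all(base_letters %in% c("A", "C", "G", "T")))
    counts <- counts[match(c("A", "C", "G", "T"), base_letters), ]
  if (anyNA(counts) || !is.matrix(counts))
    stop("could not parse PFM counts in ", path, call. = FALSE)
  rownames(counts) <- c("A", "C", "G", "T")
  freq <- sweep(counts + pseudocount, 2,
                colSums(counts + pseudocount), "/")
  pwm <- log2(freq / background)
  structure(
    list(motif_id = motif_id, counts = counts, pwm = pwm,
         max_score = sum(apply(pwm, 2, max)),
         min_score = sum(apply(pwm, 2, min))),
    class = "lce_pwm"
  )
}

#' @export
print.lce_pwm <- function(x, ...) {
  cat("<lce_pwm>", x$motif_id, "- length", ncol(x$pwm),
      sprintf("(score range %.2f .. %.2f)\n", x$min_score, x$max_score))
  invisible(x)
}

best_hit_score <- function(pwm_mat, seq) {
  L <- ncol(pwm_mat)
  if (length(seq) < L) return(-Inf)
  np <- length(seq) - L + 1L
  max(Biostrings::PWMscoreStartingAt(pwm_mat, seq, starting.at = seq_len(np)))
}

#' Annotate CTCF motif orientation from sequence
#'
#' Scores the strongest position-weight-matrix hit within each peak on
#' both strands. The site orientation is the strand of the maximum
#' log-odds hit (`forward` for the plus strand); sites whose best score
#' falls below `threshold * max_score` on both strands, or whose two
#' strands tie exactly, are marked `ambiguous` and are excluded from
#' pairing downstream. A sequence and its reverse complement always
#' receive opposite strands.
#'
#' @param sites Site tibble with `chrom`, `peak_start`, `peak_end`.
#' @param pwm An `lce_pwm` object from [read_jaspar()].
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file
#'   covering every peak.
#' @param threshold Fraction of the maximum achievable PWM score required
#'   to call an orientation (default 0.8).
#' @return `sites` with `orientation` set and `motif_score` added.
#' @export
annotate_orientation <- function(sites, pwm, genome, threshold = 0.8) {
  stopifnot(inherits(pwm, "lce_pwm"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chr) > 0L)
    stop("chromosome(s) missing from FASTA: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  cutoff <- threshold * pwm$max_score
  n <- nrow(sites)
  ori <- character(n)
  score <- numeric(n)
  for (r in seq_len(n)) {
    chr_seq <- genome[[sites$chrom[r]]]
    from <- max(1L, sites$peak_start[r] + 1L)
    to <- min(length(chr_seq), sites$peak_end[r])
    if (to < from) { ori[r] <- "ambiguous"; score[r] <- -Inf; next }
    seg <- Biostrings::subseq(chr_seq, from, to)
    fwd <- best_hit_score(pwm$pwm, seg)
    rev <- best_hit_score(pwm$pwm, Biostrings::reverseComplement(seg))
    best <- max(fwd, rev)
    score[r] <- best
    ori[r] <- if (!is.finite(best) || best < cutoff || fwd == rev)
      "ambiguous" else if (fwd > rev) "forward" else "reverse"
  }
  dplyr::mutate(sites, orientation = ori, motif_score = score)
}
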