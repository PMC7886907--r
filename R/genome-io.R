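#' Read CTCF ChIP-seq peaks from a narrowPeak or BED file
#'
#' Accepts ENCODE narrowPeak (BED6+4) or any BED6+ file with a numeric
#' signal column. Coordinates are 0-based half-open throughout the
#' package. The site coordinate `pos` used for all distances is the peak
#' summit (`start + peak offset`) when a non-negative offset is present
#' in column 10, otherwise the interval midpoint.
#'
#' @param path File path.
#' @param signal_col Which column to use as binding intensity: one of
#'   `"signalValue"` (column 7, default), `"score"` (column 5),
#'   `"pValue"` (column 8) or `"qValue"` (column 9). Which ChIP-seq
#'   statistic best reflects binding strength varies between pipelines,
#'   so this is selectable.
#' @return A site tibble: `site_id`, `chrom`, `peak_start`, `peak_end`,
#'   `pos`, `orientation` (from the strand column when it is `+`/`-`,
#'   otherwise `NA`: unset), `signal_raw`. Normalized intensity `x` is
#'   added by [normalize_signal()].
#' @export
read_narrowpeak <- function(path,
                            signal_col = c("signalValue", "score",
                                           "pValue", "qValue")) {
  signal_col <- match.arg(signal_col)
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(dplyr::tibble(site_id = character(), chrom = character(),
                         peak_start = integer(), peak_end = integer(),
                         pos = integer(), orientation = character(),
                         signal_raw = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  col_needed <- c(signalValue = 7L, score = 5L, pValue = 8L, qValue = 9L)
  need <- max(6L, col_needed[[signal_col]])
  if (any(nf < need))
    stop(sprintf("line %d of %s has %d fields; at least %d required",
                 which(nf < need)[1], path, nf[nf < need][1], need),
         call. = FALSE)
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad) > 0L)
    stop(sprintf("invalid interval at line %d of %s ('%s')",
                 bad[1], path, lines[bad[1]]), call. = FALSE)
  signal <- suppressWarnings(as.numeric(get(col_needed[[signal_col]])))
  if (anyNA(signal))
    stop(sprintf("non-numeric signal at line %d of %s",
                 which(is.na(signal))[1], path), call. = FALSE)
  offset <- if (max(nf) >= 10L)
    suppressWarnings(as.integer(get(10L))) else rep(NA_integer_, length(nf))
  pos <- ifelse(!is.na(offset) & offset >= 0L, start + offset,
                start + (end - start) %/% 2L)
  strand <- if (max(nf) >= 6L) get(6L) else rep(".", length(nf))
  name <- get(4L)
  chrom <- get(1L)
  dplyr::tibble(
    site_id = ifelse(is.na(name) | name == ".",
                     paste0(chrom, ":", start, "-", end), name),
    chrom = chrom, peak_start = start, peak_end = end,
    pos = as.integer(pos),
    orientation = dplyr::case_when(strand == "+" ~ "forward",
                                   strand == "-" ~ "reverse",
                                   TRUE ~ NA_character_),
    signal_raw = signal
  )
}

#' Write sites as a narrowPeak file
#'
#' @param sites Site tibble (see [read_narrowpeak()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(sites, path) {
  strand <- dplyr::case_when(
    sites$orientation == "forward" ~ "+",
    sites$orientation == "reverse" ~ "-",
    TRUE ~ "."
  )
  df <- data.frame(sites$chrom, sites$peak_start, sites$peak_end,
                   sites$site_id, 0L, strand,
                   format(sites$signal_raw, trim = TRUE, digits = 10),
                   -1L, -1L, sites$pos - sites$peak_start)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read measured loops from a BEDPE file
#'
#' Expects at least 8 tab-separated columns
#' (`chrom1 start1 end1 chrom2 start2 end2 name score`); the score column
#' holds the PET count. Inter-chromosomal records are dropped with a
#' message; anchors are reordered so anchor 1 is upstream.
#'
#' @param path File path.
#' @return Loop tibble: `loop_id`, `chrom`, `a1_start`, `a1_end`,
#'   `a2_start`, `a2_end`, `pet_count`.
#' @export
read_loops <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 8L)
    stop("BEDPE file must have at least 8 columns (PET count in column 8)",
         call. = FALSE)
  s1 <- as.integer(df[[2]]); e1 <- as.integer(df[[3]])
  s2 <- as.integer(df[[5]]); e2 <- as.integer(df[[6]])
  pet <- as.integer(round(as.numeric(df[[8]])))
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2) |
                 s1 >= e1 | s2 >= e2 | is.na(pet) | pet < 1)
  if (length(bad) > 0L)
    stop(sprintf("invalid BEDPE record at line %d of %s", bad[1], path),
         call. = FALSE)
  inter <- df[[1]] != df[[4]]
  if (any(inter)) {
    message(sum(inter), " inter-chromosomal record(s) dropped")
    df <- df[!inter, ]; s1 <- s1[!inter]; e1 <- e1[!inter]
    s2 <- s2[!inter]; e2 <- e2[!inter]; pet <- pet[!inter]
  }
  swap <- s1 > s2
  out <- dplyr::tibble(
    loop_id = if (all(df[[7]] == ".")) sprintf("loop_%06d", seq_len(nrow(df)))
              else df[[7]],
    chrom = df[[1]],
    a1_start = ifelse(swap, s2, s1), a1_end = ifelse(swap, e2, e1),
    a2_start = ifelse(swap, s1, s2), a2_end = ifelse(swap, e1, e2),
    pet_count = pet
  )
  out
}

#' Write loops as a BEDPE file
#'
#' @param loops Loop tibble (see [read_loops()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  df <- data.frame(loops$chrom, loops$a1_start, loops$a1_end,
                   loops$chrom, loops$a2_start, loops$a2_end,
                   loops$loop_id, loops$pet_count, ".", ".")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read / write the internal pair-table exchange format
#'
#' A tab-separated table with header columns `chrom`, `pos_i`, `pos_j`,
#' `x_i`, `x_j`, `ori_i`, `ori_j`, `label`, `pet_count` (extra columns
#' are preserved). Round-trips exactly.
#'
#' @param path File path.
#' @return A pair tibble.
#' @export
read_pairs <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos_i", "pos_j", "x_i", "x_j", "ori_i", "ori_j")
  if (!all(need %in% names(out)))
    stop("pair table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out
}

#' @rdname read_pairs
#' @param pairs Pair tibble.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' Normalize ChIP-seq signal to the genome average
#'
#' Computes the dimensionless binding intensity
#' `x = signal_raw / genome_mean`. When `genome_mean` is not supplied the
#' mean signal over the retained sites is used, making `mean(x)` exactly
#' 1; supplying the genome-wide average signal of the track (background
#' included) instead reproduces the convention in which peaks carry
#' `x >> 1`.
#'
#' @param sites Site tibble with `signal_raw`.
#' @param genome_mean Optional genome-average signal (positive scalar).
#' @return `sites` with column `x` added.
#' @export
normalize_signal <- function(sites, genome_mean = NULL) {
  if (!"signal_raw" %in% names(sites) || anyNA(sites$signal_raw))
    stop("`signal_raw` must be present for all sites", call. = FALSE)
  denom <- if (is.null(genome_mean)) mean(sites$signal_raw) else genome_mean
  if (!is.finite(denom) || denom <= 0)
    stop("signal normalization failed: non-positive mean signal",
         call. = FALSE)
  dplyr::mutate(sites, x = .data$signal_raw / denom)
}
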