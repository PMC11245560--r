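#' Count canonical k-mers and build a depth-frequency spectrum
#'
#' Every k-mer is counted in canonical form (the lexicographic minimum of
#' the k-mer and its reverse complement), so counts are strand-invariant.
#' Windows containing non-ACGT characters are skipped and tallied. The
#' spectrum is the histogram mapping multiplicity (how often a distinct
#' k-mer was seen) to the number of distinct k-mers at that multiplicity.
#'
#' @param reads a `read_set`, character vector of sequences, or a
#'   FASTA/FASTQ path.
#' @param k odd k-mer length in `[3, 31]` (default 17).
#' @return an object of class `kmer_spectrum`: data frame (multiplicity,
#'   count) sorted by multiplicity, with attributes `k`, `total_kmers`,
#'   `n_skipped`, `n_distinct` and, when known, `read_length`.
#' @export
count_kmers <- function(reads, k = 17L) {
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L)
    stop("k must be an odd integer >= 3 (canonical form would tie otherwise)")
  read_length <- NA_integer_
  if (inherits(reads, "read_set")) {
    read_length <- reads$read_length
    seqs <- reads$reads
  } else if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    seqs <- unname(read_seqs(reads))
    if (length(unique(nchar(seqs))) == 1L) read_length <- nchar(seqs[1])
  } else if (is.character(reads)) {
    seqs <- reads
    if (length(seqs) && length(unique(nchar(seqs))) == 1L)
      read_length <- nchar(seqs[1])
  } else stop("unsupported read container")
  res <- .count_kmers_cpp(seqs, k)
  o <- order(res$multiplicity)
  spec <- data.frame(multiplicity = res$multiplicity[o], count = res$count[o])
  structure(spec, k = k, total_kmers = res$total_kmers,
            n_skipped = res$n_skipped, n_distinct = res$n_distinct,
            read_length = read_length,
            class = c("kmer_spectrum", "data.frame"))
}

#' Construct a k-mer spectrum from a histogram
#'
#' @param multiplicity,count parallel vectors (multiplicity >= 1).
#' @param k k-mer length the histogram was computed at.
#' @param read_length optional read length (enables the coverage-unit
#'   conversion in [detect_peaks()]).
#' @return a `kmer_spectrum`.
#' @export
kmer_spectrum <- function(multiplicity, count, k = 17L, read_length = NA) {
  stopifnot(length(multiplicity) == length(count), all(multiplicity >= 1),
            all(count >= 0))
  o <- order(multiplicity)
  structure(data.frame(multiplicity = as.integer(multiplicity[o]),
                       count = as.numeric(count[o])),
            k = as.integer(k), total_kmers = sum(multiplicity * count),
            n_skipped = 0, n_distinct = sum(count),
            read_length = read_length,
            class = c("kmer_spectrum", "data.frame"))
}

# densify a spectrum into a vector indexed 1..max multiplicity
dense_spectrum <- function(spec) {
  maxm <- max(spec$multiplicity)
  v <- numeric(maxm)
  v[spec$multiplicity] <- spec$count
  v
}

# prominence of local maxima of a numeric series: height minus the higher of
# the two key saddles (lowest point to descend before reaching higher ground)
peak_prominences <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(p) {
    h <- y[p]
    left_base <- if (p > 1L) {
      seg <- y[seq_len(p - 1L)]
      higher <- which(seg > h)
      from <- if (length(higher)) max(higher) + 1L else 1L
      min(seg[seq.int(from, p - 1L)])
    } else -Inf
    right_base <- if (p < n) {
      seg <- y[seq.int(p + 1L, n)]
      higher <- which(seg > h)
      to <- if (length(higher)) min(higher) - 1L else length(seg)
      if (to >= 1L) min(seg[seq_len(to)]) else h
    } else -Inf
    if (!is.finite(left_base) && !is.finite(right_base)) return(h)
    h - max(left_base, right_base)
  }, 0)
}

#' Detect peaks in a k-mer spectrum
#'
#' The histogram is smoothed with a centered moving average; the
#' low-multiplicity error region (below the first local minimum, or a
#' configured cutoff) is excluded; local maxima whose prominence reaches
#' `min_prominence_fraction` of the global maximum (over the retained
#' region) are reported. Peak positions come from the smoothed series,
#' heights from the raw histogram.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param smooth_window odd moving-average window (default 3).
#' @param min_prominence_fraction prominence threshold as a fraction of the
#'   global maximum.
#' @param error_cutoff multiplicity at or below which mass is treated as
#'   sequencing error; `NULL` detects the first local minimum.
#' @return data frame (position, height, smoothed_height, prominence,
#'   coverage) sorted by position; `coverage` converts the k-mer
#'   multiplicity to per-base coverage units via `position * L / (L - k + 1)`
#'   when the read length `L` is known (`NA` otherwise). Attribute
#'   `"error_cutoff"` records the cutoff used.
#' @export
detect_peaks <- function(spectrum, smooth_window = 3L,
                         min_prominence_fraction = 0.1,
                         error_cutoff = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (nrow(spectrum) == 0L) stop("spectrum is empty")
  if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
  y <- dense_spectrum(spectrum)
  half <- (smooth_window - 1L) / 2L
  # edge-replicated padding: no artificial boundary rise or fall
  padded <- c(rep(y[1], half), y, rep(y[length(y)], half))
  s <- as.numeric(stats::filter(padded,
                                rep(1 / smooth_window, smooth_window),
                                sides = 2))
  s <- s[seq_along(y) + half]
  if (is.null(error_cutoff)) {
    # first index after which the smoothed series starts rising
    rise <- which(diff(s) > 0)
    error_cutoff <- if (length(rise)) rise[1] else 1L
  }
  region <- seq_along(s) > error_cutoff
  if (!any(region & s > 0)) {
    warning("all spectrum mass lies at or below the error cutoff")
    out <- data.frame(position = integer(), height = numeric(),
                      smoothed_height = numeric(), prominence = numeric(),
                      coverage = numeric())
    attr(out, "error_cutoff") <- error_cutoff
    return(out)
  }
  n <- length(s)
  cand <- which(region &
                  s >= c(-Inf, s[-n]) & s >= c(s[-1], -Inf) & s > 0)
  # collapse plateaus to their first index
  if (length(cand) > 1L) cand <- cand[c(TRUE, diff(cand) > 1L)]
  gmax <- max(s[region])
  prom <- peak_prominences(s, cand)
  keep <- prom >= min_prominence_fraction * gmax
  pos <- cand[keep]
  L <- attr(spectrum, "read_length")
  k <- attr(spectrum, "k")
  coverage <- if (!is.null(L) && length(L) == 1L && is.finite(L))
    pos * L / (L - k + 1) else rep(NA_real_, length(pos))
  out <- data.frame(position = pos, height = y[pos],
                    smoothed_height = s[pos],
                    prominence = prom[keep],
                    coverage = coverage)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "error_cutoff") <- error_cutoff
  out
}

#' Call ploidy from detected spectrum peaks
#'
#' Diploid-like requires exactly two retained peaks whose position ratio is
#' 2 within `tolerance` (a heterozygous peak at half the coverage of the
#' homozygous peak); one peak is haploid-like; anything else is
#' indeterminate.
#'
#' @param peaks data frame from [detect_peaks()].
#' @param tolerance relative tolerance on the ratio-2 condition.
#' @return an object of class `ploidy_call`: list with `call`
#'   (`"haploid-like"`, `"diploid-like"`, `"indeterminate"`), `peaks`, and
#'   `peak_position_ratio` (`NA` unless two peaks).
#' @export
call_ploidy <- function(peaks, tolerance = 0.2) {
  ratio <- NA_real_
  if (nrow(peaks) == 2L) {
    ratio <- max(peaks$position) / min(peaks$position)
    call <- if (ratio >= 2 * (1 - tolerance) && ratio <= 2 * (1 + tolerance))
      "diploid-like" else "indeterminate"
  } else if (nrow(peaks) == 1L) call <- "haploid-like"
  else call <- "indeterminate"
  structure(list(call = call, peaks = peaks, peak_position_ratio = ratio),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("ploidy call: %s (%d peak(s)%s)\n", x$call, nrow(x$peaks),
              if (is.finite(x$peak_position_ratio))
                sprintf(", position ratio %.2f", x$peak_position_ratio)
              else ""))
  invisible(x)
}

#' Write a k-mer spectrum as two-column TSV
#'
#' @param spectrum a `kmer_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  write.table(as.data.frame(spectrum), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
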