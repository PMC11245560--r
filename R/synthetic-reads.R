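#' Simulate whole-genome shotgun reads
#'
#' Reads are drawn uniformly over start positions of every haplotype so that
#' the total expected per-base coverage over the genome equals `depth`: a
#' haploid genome is sampled at `depth`, a diploid hybrid at `depth / 2` per
#' haplotype (so homozygous positions still see `depth` in total).
#' Substitution errors are applied at `error_rate` per base; half of the
#' reads are reverse-complemented.
#'
#' @param x a `lineage_genome`, `hybrid_genome`, or named character vector of
#'   sequences (treated as a single haplotype set).
#' @param depth expected per-base fold coverage (> 0).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param seed integer RNG seed.
#' @return an object of class `read_set`: list with `reads` (character
#'   vector), `read_length`, `depth`, `n_haplotypes`, `seed`.
#' @export
simulate_reads <- function(x, depth, read_length = 150L, error_rate = 0,
                           seed = 1L) {
  assert_scalar_number(depth, "depth", 0, Inf, closed_lower = FALSE)
  assert_scalar_number(error_rate, "error_rate", 0, 1)
  read_length <- as.integer(read_length)
  if (inherits(x, "hybrid_genome")) {
    haps <- list(A = physical_seqs(x$hap_a), B = physical_seqs(x$hap_b))
  } else if (inherits(x, "lineage_genome")) {
    haps <- list(H = physical_seqs(x))
  } else if (is.character(x)) {
    haps <- list(H = x)
  } else stop("unsupported genome object")
  n_hap <- length(haps)
  per_hap_depth <- depth / n_hap
  withr::local_seed(seed)
  reads <- vector("list", 0L)
  for (hap in haps) {
    for (cn in names(hap)) {
      L <- nchar(hap[[cn]])
      if (read_length > L)
        stop("read_length exceeds chromosome length for ", cn)
      n_reads <- rpois(1L, per_hap_depth * L / read_length)
      if (n_reads == 0L) next
      starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
      reads[[length(reads) + 1L]] <-
        substring(hap[[cn]], starts, starts + read_length - 1L)
    }
  }
  reads <- unlist(reads, use.names = FALSE) %||% character()
  if (error_rate > 0 && length(reads)) {
    n_err <- rbinom(length(reads), read_length, error_rate)
    idx <- which(n_err > 0L)
    for (i in idx) {
      pos <- sample.int(read_length, n_err[i])
      reads[i] <- mutate_seq(reads[i], pos)$seq
    }
  }
  if (length(reads) > 1L) {
    flip <- sample(c(TRUE, FALSE), length(reads), replace = TRUE)
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
  }
  structure(list(reads = reads, read_length = read_length, depth = depth,
                 n_haplotypes = n_hap, seed = as.integer(seed)),
            class = "read_set")
}

#' Write a read set as FASTQ (constant high quality)
#'
#' @param reads a `read_set` or character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- paste0("read", seq_along(dss))
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(dss), function(w)
    strrep("I", w), ""))
  Biostrings::writeXStringSet(dss, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ into a plain character vector
#'
#' @param path input file (format guessed from extension).
#' @return named character vector of sequences.
#' @export
read_seqs <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  dss <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(dss), names(dss))
}
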