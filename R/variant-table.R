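#' Per-site, per-sample genotype table with allele depths
#'
#' The substrate for SNP filtering, windowed heterozygosity, allele-frequency
#' profiles and parentage analyses. Genotypes follow VCF conventions:
#' `"0"`/`"1"` for haploid calls, `"0/1"` for diploid calls, `"."`/`"./."`
#' for missing. Allele depths are comma-separated per-allele read counts
#' (REF first).
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated alternative alleles), `qual`.
#' @param gt character matrix sites x samples of genotype strings.
#' @param ad character matrix sites x samples of comma-separated depths.
#' @param dp numeric matrix sites x samples of total depths.
#' @param chrom_lengths optional named vector of chromosome lengths (used by
#'   windowed statistics).
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, ad = NULL, dp = NULL,
                          chrom_lengths = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)))
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(sites)) stop("gt rows must match sites")
  if (is.null(colnames(gt))) stop("gt must have sample column names")
  for (cn in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == cn]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within each chromosome")
  }
  if (!is.null(ad)) {
    ad <- as.matrix(ad)
    stopifnot(identical(dim(ad), dim(gt)))
  }
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    stopifnot(identical(dim(dp), dim(gt)))
  }
  structure(list(sites = sites, gt = gt, ad = ad, dp = dp,
                 chrom_lengths = chrom_lengths),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%s)\n",
              nrow(x$sites), ncol(x$gt),
              paste(colnames(x$gt), collapse = ", ")))
  invisible(x)
}

n_sites <- function(vt) nrow(vt$sites)

vt_samples <- function(vt) colnames(vt$gt)

# TRUE where the genotype string is missing
gt_is_missing <- function(gt) is.na(gt) | gt == "." | gt == "./." | gt == ".|."

# list of integer allele-index vectors, NULL for missing
gt_alleles <- function(gt_vec) {
  out <- strsplit(gt_vec, "[/|]")
  lapply(seq_along(out), function(i) {
    if (gt_is_missing(gt_vec[i])) return(NULL)
    suppressWarnings(as.integer(out[[i]]))
  })
}

# logical matrix: genotype heterozygous (two called, different alleles)
gt_is_het <- function(gt) {
  h <- matrix(FALSE, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  idx <- !gt_is_missing(gt)
  vals <- gt[idx]
  parts <- strsplit(vals, "[/|]")
  h[idx] <- vapply(parts, function(p)
    length(p) == 2L && p[1] != p[2], logical(1))
  h
}

# numeric matrix list: per-cell vector of allele depths
ad_split <- function(ad_vec) {
  lapply(strsplit(ad_vec, ","), function(x) suppressWarnings(as.numeric(x)))
}

subset_sites <- function(vt, keep) {
  variant_table(vt$sites[keep, , drop = FALSE],
                vt$gt[keep, , drop = FALSE],
                if (!is.null(vt$ad)) vt$ad[keep, , drop = FALSE],
                if (!is.null(vt$dp)) vt$dp[keep, , drop = FALSE],
                vt$chrom_lengths)
}

#' Simulate a variant table from lineage and hybrid truth
#'
#' Sites are all positions (in ancestral coordinates) at which any included
#' sample differs from the reference lineage, plus all hybrid heterozygous
#' sites. Haploid samples carry all reads on their single allele; diploid
#' heterozygous sites split `depth` reads `Binomial(depth, 0.5)` between the
#' two alleles. Site QUAL values are drawn high by default, with an optional
#' fraction of low-QUAL sites so quality filters are exercisable.
#'
#' @param lineages a `lineage_set`.
#' @param hybrid optional `hybrid_genome` built from the same lineage set.
#' @param samples lineage ids (haploid samples) to include; the hybrid is
#'   always included when supplied.
#' @param depth per-site read depth (> 0).
#' @param reference lineage id whose genome provides REF alleles.
#' @param low_qual_fraction fraction of sites given QUAL below 20.
#' @param seed integer RNG seed.
#' @return a [variant_table()] with one column per haploid sample and, when
#'   `hybrid` is given, a diploid column named after the hybrid id.
#' @export
simulate_variant_table <- function(lineages, hybrid = NULL,
                                   samples = names(lineages$genomes),
                                   depth = 50L, reference = samples[1],
                                   low_qual_fraction = 0, seed = 1L) {
  stopifnot(inherits(lineages, "lineage_set"))
  if (depth <= 0) stop("depth must be positive")
  withr::local_seed(seed)
  ref_seqs <- lineages$genomes[[reference]]$seqs
  if (is.null(ref_seqs)) stop("unknown reference lineage")
  hap_seqs <- lapply(lineages$genomes[samples], `[[`, "seqs")
  names(hap_seqs) <- samples
  dip <- NULL
  if (!is.null(hybrid)) {
    stopifnot(inherits(hybrid, "hybrid_genome"))
    dip <- list(a = hybrid$hap_a$seqs, b = hybrid$hap_b$seqs)
  }
  out_sites <- list(); out_gt <- list(); out_ad <- list(); out_dp <- list()
  sample_names <- c(samples, if (!is.null(dip)) hybrid$id)
  for (cn in names(ref_seqs)) {
    pos <- integer()
    for (s in samples)
      pos <- union(pos, string_mismatch_positions(ref_seqs[[cn]],
                                                  hap_seqs[[s]][[cn]]))
    if (!is.null(dip)) {
      pos <- union(pos, string_mismatch_positions(ref_seqs[[cn]], dip$a[[cn]]))
      pos <- union(pos, string_mismatch_positions(ref_seqs[[cn]], dip$b[[cn]]))
    }
    pos <- sort(pos)
    if (!length(pos)) next
    ref_al <- substring(ref_seqs[[cn]], pos, pos)
    allele_mat <- cbind(
      do.call(cbind, lapply(samples, function(s)
        substring(hap_seqs[[s]][[cn]], pos, pos))),
      if (!is.null(dip)) cbind(substring(dip$a[[cn]], pos, pos),
                               substring(dip$b[[cn]], pos, pos)))
    n <- length(pos)
    gt <- matrix(NA_character_, n, length(sample_names),
                 dimnames = list(NULL, sample_names))
    ad <- matrix(NA_character_, n, length(sample_names),
                 dimnames = list(NULL, sample_names))
    alt_str <- character(n)
    for (i in seq_len(n)) {
      alleles <- ref_al[i]
      row <- allele_mat[i, ]
      alts <- setdiff(unique(row), ref_al[i])
      alleles <- c(alleles, alts)
      alt_str[i] <- paste(alts, collapse = ",")
      nal <- length(alleles)
      for (j in seq_along(samples)) {
        ai <- match(row[j], alleles) - 1L
        gt[i, j] <- as.character(ai)
        d <- numeric(nal); d[ai + 1L] <- depth
        ad[i, j] <- paste(d, collapse = ",")
      }
      if (!is.null(dip)) {
        j <- length(samples) + 1L
        a1 <- match(row[length(samples) + 1L], alleles) - 1L
        a2 <- match(row[length(samples) + 2L], alleles) - 1L
        gt[i, j] <- paste(sort(c(a1, a2)), collapse = "/")
        d <- numeric(nal)
        if (a1 == a2) d[a1 + 1L] <- depth
        else {
          d1 <- rbinom(1L, depth, 0.5)
          d[a1 + 1L] <- d1; d[a2 + 1L] <- depth - d1
        }
        ad[i, j] <- paste(d, collapse = ",")
      }
    }
    keep <- nzchar(alt_str)   # drop sites where every sample matches REF
    out_sites[[cn]] <- data.frame(chrom = cn, pos = pos,
                                  ref = ref_al, alt = alt_str,
                                  qual = 0)[keep, , drop = FALSE]
    out_gt[[cn]] <- gt[keep, , drop = FALSE]
    out_ad[[cn]] <- ad[keep, , drop = FALSE]
    out_dp[[cn]] <- matrix(depth, sum(keep), length(sample_names),
                           dimnames = list(NULL, sample_names))
  }
  sites <- do.call(rbind, out_sites)
  rownames(sites) <- NULL
  m <- nrow(sites)
  qual <- round(runif(m, 50, 200), 1)
  if (low_qual_fraction > 0) {
    nlow <- rbinom(1L, m, low_qual_fraction)
    if (nlow > 0) qual[sample.int(m, nlow)] <- round(runif(nlow, 2, 19.5), 1)
  }
  sites$qual <- qual
  variant_table(sites, do.call(rbind, out_gt), do.call(rbind, out_ad),
                do.call(rbind, out_dp),
                chrom_lengths = vapply(ref_seqs, nchar, 0L))
}

#' Write a variant table as VCF v4.2
#'
#' @param vt a [variant_table()].
#' @param path output file; `.gz` is appended by the writer.
#' @return the written path, invisibly.
#' @export
write_vcf <- function(vt, path) {
  meta <- c("##fileformat=VCFv4.2",
            "##source=hybridtriad",
            if (!is.null(vt$chrom_lengths))
              sprintf("##contig=<ID=%s,length=%d>", names(vt$chrom_lengths),
                      as.integer(vt$chrom_lengths)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">")
  fix <- cbind(CHROM = vt$sites$chrom, POS = as.character(vt$sites$pos),
               ID = rep(".", nrow(vt$sites)), REF = vt$sites$ref,
               ALT = vt$sites$alt, QUAL = as.character(vt$sites$qual),
               FILTER = rep("PASS", nrow(vt$sites)),
               INFO = rep(".", nrow(vt$sites)))
  gtm <- matrix(paste(vt$gt,
                      if (!is.null(vt$ad)) vt$ad else ".",
                      if (!is.null(vt$dp)) vt$dp else ".",
                      sep = ":"),
                nrow = nrow(vt$gt), dimnames = dimnames(vt$gt))
  gtm[gt_is_missing(vt$gt)] <- "./.:.:."
  gt <- cbind(FORMAT = rep("GT:AD:DP", nrow(vt$sites)), gtm)
  obj <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = if (grepl("\\.gz$", path)) path
                  else paste0(path, ".gz"))
  invisible(if (grepl("\\.gz$", path)) path else paste0(path, ".gz"))
}

#' Read a VCF into a variant table
#'
#' @param path a VCF file (plain or gzipped) with GT and, optionally, AD and
#'   DP FORMAT fields.
#' @return a [variant_table()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      qual = suppressWarnings(as.numeric(fix[, "QUAL"])))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  dp <- tryCatch({
    d <- vcfR::extract.gt(v, element = "DP")
    matrix(suppressWarnings(as.numeric(d)), nrow(d), dimnames = dimnames(d))
  }, error = function(e) NULL)
  rownames(gt) <- NULL
  if (!is.null(ad)) rownames(ad) <- NULL
  # contig lengths from header when present
  cl <- NULL
  contig <- grep("^##contig=", v@meta, value = TRUE)
  if (length(contig)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
    lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", contig)))
    cl <- setNames(lens, ids)
  }
  variant_table(sites, gt, ad, dp, chrom_lengths = cl)
}
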