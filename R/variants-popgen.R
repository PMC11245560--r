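#' SNP filtering policy
#'
#' Mirrors a two-stage variant filter: a per-sample mask (site quality and
#' depth window) followed by site-level filters (minor-allele frequency,
#' missingness, biallelic restriction).
#'
#' @param min_qual phred-scaled site quality threshold; genotypes at sites
#'   below it are set to missing.
#' @param min_dp,max_dp per-sample depth window; genotypes outside it are
#'   set to missing.
#' @param min_maf minimum minor-allele frequency over non-missing called
#'   alleles, in `[0, 0.5]`.
#' @param max_missing_fraction maximum fraction of samples allowed missing
#'   at a site.
#' @param biallelic_only keep only sites with exactly one ALT allele.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(min_qual = 20, min_dp = 10, max_dp = 400,
                          min_maf = 0.02, max_missing_fraction = 0.5,
                          biallelic_only = TRUE) {
  if (!(min_dp < max_dp)) stop("min_dp must be < max_dp")
  assert_scalar_number(min_maf, "min_maf", 0, 0.5)
  assert_scalar_number(max_missing_fraction, "max_missing_fraction", 0, 1)
  structure(list(min_qual = min_qual, min_dp = min_dp, max_dp = max_dp,
                 min_maf = min_maf,
                 max_missing_fraction = max_missing_fraction,
                 biallelic_only = isTRUE(biallelic_only)),
            class = "filter_policy")
}

#' Filter a variant table
#'
#' Applies the per-sample mask first (QUAL below threshold or DP outside the
#' window set the genotype to missing), then drops sites by minor-allele
#' frequency (computed over the remaining called alleles), missingness, and
#' the biallelic restriction. Site order is preserved and the operation is
#' idempotent.
#'
#' @param vt a [variant_table()].
#' @param policy a [filter_policy()].
#' @return a filtered [variant_table()]; attribute `"n_dropped"` records the
#'   number of sites removed.
#' @export
filter_variants <- function(vt, policy = filter_policy()) {
  stopifnot(inherits(vt, "variant_table"), inherits(policy, "filter_policy"))
  if (n_sites(vt) == 0L) return(vt)
  gt <- vt$gt
  low_qual <- vt$sites$qual < policy$min_qual
  gt[low_qual, ] <- NA_character_
  if (!is.null(vt$dp)) {
    bad_dp <- vt$dp < policy$min_dp | vt$dp > policy$max_dp
    gt[bad_dp] <- NA_character_
  }
  miss <- gt_is_missing(gt)
  n <- nrow(gt)
  keep <- rep(TRUE, n)
  # missingness
  keep <- keep & rowMeans(miss) <= policy$max_missing_fraction
  # biallelic restriction: exactly one ALT allele in the record
  if (policy$biallelic_only) {
    nalt <- lengths(strsplit(vt$sites$alt, ","))
    nalt[!nzchar(vt$sites$alt)] <- 0L
    keep <- keep & nalt == 1L
  }
  # MAF over non-missing called alleles
  if (policy$min_maf > 0) {
    maf <- vapply(seq_len(n), function(i) {
      if (!keep[i]) return(1)
      als <- unlist(gt_alleles(gt[i, !miss[i, ], drop = TRUE]))
      if (!length(als)) return(0)
      tab <- tabulate(als + 1L)
      tab <- tab[tab > 0]
      if (length(tab) < 2L) return(0)
      (sum(tab) - max(tab)) / sum(tab)
    }, 0)
    keep <- keep & maf >= policy$min_maf
  }
  out <- subset_sites(variant_table(vt$sites, gt, vt$ad, vt$dp,
                                    vt$chrom_lengths), keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Heterozygosity in non-overlapping windows
#'
#' Counts heterozygous genotypes per sample in tiling windows along each
#' chromosome. Windows are 0-based half-open `[start, start + window_bp)`;
#' VCF positions (1-based) are converted internally.
#'
#' @param vt a (filtered) [variant_table()] whose `chrom_lengths` are known.
#' @param window_bp window size in bp (default 100 kb).
#' @param mode `"per_snp"`: value = n_het / n_snps (`NA` when a window holds
#'   no called SNPs); `"per_bp"`: value = n_het / window_bp.
#' @param chrom_lengths named vector overriding `vt$chrom_lengths`.
#' @return data frame (chrom, start, end, sample, n_snps, n_het, value).
#' @export
heterozygosity_windows <- function(vt, window_bp = 100000L,
                                   mode = c("per_snp", "per_bp"),
                                   chrom_lengths = NULL) {
  mode <- match.arg(mode)
  if (window_bp <= 0) stop("window_bp must be positive")
  cl <- chrom_lengths %||% vt$chrom_lengths
  if (is.null(cl)) stop("chromosome lengths are required")
  miss <- gt_is_missing(vt$gt)
  het <- gt_is_het(vt$gt)
  out <- list()
  for (cn in names(cl)) {
    starts <- seq(0L, max(0L, cl[[cn]] - 1L), by = window_bp)
    idx <- which(vt$sites$chrom == cn)
    win_of <- ((vt$sites$pos[idx] - 1L) %/% window_bp) + 1L
    for (s in vt_samples(vt)) {
      called <- idx[!miss[idx, s]]
      wcalled <- ((vt$sites$pos[called] - 1L) %/% window_bp) + 1L
      n_snps <- tabulate(wcalled, nbins = length(starts))
      whet <- wcalled[het[called, s]]
      n_het <- tabulate(whet, nbins = length(starts))
      value <- if (mode == "per_snp") ifelse(n_snps > 0, n_het / n_snps, NA_real_)
               else n_het / window_bp
      out[[paste(cn, s)]] <- data.frame(
        chrom = cn, start = starts,
        end = pmin(starts + window_bp, cl[[cn]]),
        sample = s, n_snps = n_snps, n_het = n_het, value = value)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Alternative-allele frequency profile of one sample
#'
#' For each qualifying site the alternative-allele fraction is the ratio of
#' reads supporting alternative alleles to total reads, computed from the AD
#' field. Fractions are binned (default width 0.02, bins centered on 0,
#' 0.02, ..., 1) and the modal frequency is the center of the highest-mass
#' bin. Sites whose depths sum to zero are skipped and counted.
#'
#' @param vt a [variant_table()] with AD for `sample`.
#' @param sample sample name.
#' @param sites `"auto"` uses heterozygous sites when the sample has any
#'   (diploid profile), otherwise all non-reference variant sites (haploid
#'   profile); `"het"` and `"variant"` force either choice.
#' @param bin_width histogram bin width.
#' @return an object of class `allele_frequency_profile`: list with
#'   `fractions`, `histogram` (center, count), `modal_frequency`, `sample`,
#'   `n_skipped`.
#' @export
allele_frequency_profile <- function(vt, sample,
                                     sites = c("auto", "het", "variant"),
                                     bin_width = 0.02) {
  sites <- match.arg(sites)
  stopifnot(sample %in% vt_samples(vt))
  if (is.null(vt$ad)) stop("AD field is required for ", sample)
  gt <- vt$gt[, sample]
  miss <- gt_is_missing(gt)
  het <- gt_is_het(vt$gt)[, sample]
  alleles <- gt_alleles(gt)
  nonref <- !miss & vapply(alleles, function(a)
    !is.null(a) && any(a > 0L), TRUE)
  use <- switch(sites,
                het = het,
                variant = nonref,
                auto = if (any(het)) het else nonref)
  idx <- which(use)
  ads <- ad_split(vt$ad[idx, sample])
  tot <- vapply(ads, sum, 0)
  alt <- vapply(ads, function(d) sum(d[-1L]), 0)
  skip <- !is.finite(tot) | tot == 0
  frac <- (alt / tot)[!skip]
  centers <- seq(0, 1, by = bin_width)
  bins <- findInterval(frac, c(-Inf, centers[-1] - bin_width / 2))
  counts <- tabulate(bins, nbins = length(centers))
  modal <- centers[which.max(counts)]
  structure(list(fractions = frac,
                 histogram = data.frame(center = centers, count = counts),
                 modal_frequency = modal, sample = sample,
                 n_skipped = sum(skip)),
            class = "allele_frequency_profile")
}

IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                AA = "A", CC = "C", GG = "G", TT = "T")

#' Encode genotypes as an IUPAC character matrix
#'
#' Homozygous genotypes become the base, heterozygous genotypes the IUPAC
#' degenerate code of the unordered allele pair (e.g. G/T becomes K), and
#' missing genotypes become N. Sites carrying non-SNP alleles (length > 1)
#' are skipped and counted in attribute `"n_skipped"`.
#'
#' @param vt a biallelic SNP [variant_table()].
#' @return character matrix samples x sites with `chrom:pos` column names.
#' @export
encode_iupac_matrix <- function(vt) {
  alleles_site <- mapply(function(r, a) c(r, strsplit(a, ",")[[1]]),
                         vt$sites$ref, vt$sites$alt, SIMPLIFY = FALSE)
  snp_ok <- vapply(alleles_site, function(a) all(nchar(a) == 1L), TRUE)
  idx <- which(snp_ok)
  samples <- vt_samples(vt)
  out <- matrix("N", length(samples), length(idx),
                dimnames = list(samples,
                                paste0(vt$sites$chrom[idx], ":",
                                       vt$sites$pos[idx])))
  for (j in seq_along(idx)) {
    i <- idx[j]
    als <- alleles_site[[i]]
    g <- gt_alleles(vt$gt[i, ])
    for (s in seq_along(samples)) {
      a <- g[[s]]
      if (is.null(a) || anyNA(a)) next
      b <- sort(als[a + 1L])
      if (length(b) == 1L) b <- c(b, b)
      code <- IUPAC_PAIR[paste(b[1], b[2], sep = "")]
      out[s, j] <- if (is.na(code)) "N" else unname(code)
    }
  }
  attr(out, "n_skipped") <- sum(!snp_ok)
  out
}

#' Pairwise p-distance matrix from a character matrix
#'
#' d(i, j) is the fraction of mismatching sites among sites where neither
#' sample is N. Degenerate IUPAC codes are compared as literal symbols (K
#' vs G counts as a mismatch). A pair with zero comparable sites gets `NA`.
#'
#' @param mat character matrix samples x sites (e.g. from
#'   [encode_iupac_matrix()]).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 1L || ncol(mat) < 1L)
    stop("matrix must be nonempty")
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- mat[i, ] != "N" & mat[j, ] != "N"
    d[i, j] <- d[j, i] <- if (!any(ok)) NA_real_
                          else mean(mat[i, ok] != mat[j, ok])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomeration: at each step the pair minimising the Q-criterion
#' is joined; ties are broken by the lexicographically smallest pair of
#' active-node indices (tips in input order first, then internal nodes in
#' creation order). Branch lengths use the standard two-point formulas;
#' negative lengths are clamped to zero and counted in attribute
#' `"n_clamped"`.
#'
#' @param d symmetric distance matrix (>= 3 taxa) with row names.
#' @return an unrooted `phylo` tree (ape) with a basal trifurcation.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete distance matrix: no comparable sites for pair (%s, %s)",
                 labels[bad[1]], labels[bad[2]]))
  }
  # active nodes: tips are 1..n, internal nodes get ids n+1, n+2, ...
  active <- seq_len(n)
  next_internal <- n + 1L
  edges <- list()      # (parent_internal_id, child_id, length)
  n_clamped <- 0L
  D <- d
  while (length(active) > 3L) {
    m <- length(active)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { li <- 0; n_clamped <- n_clamped + 1L }
    if (lj < 0) { lj <- 0; n_clamped <- n_clamped + 1L }
    u <- next_internal; next_internal <- next_internal + 1L
    edges[[length(edges) + 1L]] <- c(u, active[i], li)
    edges[[length(edges) + 1L]] <- c(u, active[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active <- c(active[keep], u)
  }
  # final three-point resolution
  u <- next_internal
  x <- active[1]; y <- active[2]; z <- active[3]
  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (v in c(lx, ly, lz)) if (v < 0) n_clamped <- n_clamped + 1L
  edges[[length(edges) + 1L]] <- c(u, x, max(lx, 0))
  edges[[length(edges) + 1L]] <- c(u, y, max(ly, 0))
  edges[[length(edges) + 1L]] <- c(u, z, max(lz, 0))
  em <- do.call(rbind, edges)
  # renumber internal ids so the root (last created, id u) becomes n + 1
  n_internal <- u - n
  renum <- function(v) ifelse(v <= n, v, n + (u - v) + 1L)
  edge <- cbind(renum(em[, 1]), renum(em[, 2]))
  storage.mode(edge) <- "integer"
  tree <- structure(list(edge = edge,
                         edge.length = em[, 3],
                         tip.label = labels,
                         Nnode = as.integer(n_internal)),
                    class = "phylo")
  attr(tree, "n_clamped") <- n_clamped
  tree
}
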