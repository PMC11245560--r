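#' TMM normalisation to counts per million
#'
#' Computes trimmed-mean-of-M-values scaling factors: for each sample
#' against the reference, M-values (log2 count-rate ratios) over genes
#' expressed in both are trimmed 30% two-sided, A-values (log2 abundance)
#' 5% two-sided, and the surviving M-values are averaged with
#' precision (inverse asymptotic variance) weights. Factors are rescaled
#' to geometric mean 1 and CPM = count / (library size x factor) x 1e6.
#' The reference defaults to the sample whose upper quartile of the
#' count rate is closest to the mean upper quartile.
#'
#' @param counts integer matrix genes x samples, or a
#'   `triad_count_matrix`.
#' @param ref_sample optional reference sample name.
#' @param logratio_trim,abundance_trim two-sided trim fractions.
#' @param precision_weights weight surviving M-values by inverse asymptotic
#'   variance (default). With `FALSE` the factor is the plain trimmed mean
#'   of M-values, which is exactly invariant to rescaling a sample's
#'   counts (the weights depend on absolute library sizes).
#' @return an object of class `normalized_expression`: list with `cpm`,
#'   `factors`, `lib_size`, `effective_lib_size`, `ref_sample`, and slots
#'   for `fpkm`/`gene_lengths` filled by [fpkm()].
#' @export
tmm_normalize <- function(counts, ref_sample = NULL, logratio_trim = 0.3,
                          abundance_trim = 0.05, precision_weights = TRUE) {
  if (inherits(counts, "triad_count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
    ref_sample <- colnames(counts)[which.min(abs(uq - mean(uq)))]
  }
  stopifnot(ref_sample %in% colnames(counts))
  r <- counts[, ref_sample]
  Nr <- lib[ref_sample]
  factors <- vapply(colnames(counts), function(s) {
    if (s == ref_sample) return(1)
    tmm_factor(counts[, s], r, lib[s], Nr, logratio_trim, abundance_trim,
               precision_weights, s)
  }, 0)
  factors <- factors / exp(mean(log(factors)))
  cpm <- sweep(counts, 2, lib * factors, "/") * 1e6
  structure(list(cpm = cpm, factors = factors, lib_size = lib,
                 effective_lib_size = lib * factors,
                 ref_sample = ref_sample, fpkm = NULL, gene_lengths = NULL),
            class = "normalized_expression")
}

# one trimmed, precision-weighted TMM factor (sample obs vs reference r)
tmm_factor <- function(obs, r, No, Nr, logratio_trim, abundance_trim,
                       precision_weights = TRUE, name = "sample") {
  keep <- obs > 0 & r > 0
  if (!any(keep))
    stop("sample '", name, "' shares no expressed genes with the reference")
  o <- obs[keep]; rr <- r[keep]
  if (sum(keep) == 1L) {
    warning("only one gene shared with the reference; factor set to 1")
    return(1)
  }
  M <- log2((o / No) / (rr / Nr))
  A <- 0.5 * log2((o / No) * (rr / Nr))
  w <- if (precision_weights) (No - o) / (No * o) + (Nr - rr) / (Nr * rr)
       else rep(1, length(M))
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M)   # average ranks on ties, as the standard implementation
  rA <- rank(A)
  k <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(k)) {
    warning("trimming removed all genes; factor set to 1")
    return(1)
  }
  2^(sum(M[k] / w[k]) / sum(1 / w[k]))
}

#' FPKM from CPM and gene lengths
#'
#' FPKM = CPM x 1000 / CDS length (bp). Genes without a length are
#' excluded and counted in attribute `"n_excluded"` of the `fpkm` slot.
#'
#' @param norm a [tmm_normalize()] result.
#' @param gene_lengths named vector of CDS lengths in bp (> 0).
#' @return `norm` with `fpkm` and `gene_lengths` filled.
#' @export
fpkm <- function(norm, gene_lengths) {
  stopifnot(inherits(norm, "normalized_expression"))
  genes <- rownames(norm$cpm)
  len <- gene_lengths[genes]
  ok <- !is.na(len) & len > 0
  f <- norm$cpm[ok, , drop = FALSE] * 1000 / len[ok]
  attr(f, "n_excluded") <- sum(!ok)
  norm$fpkm <- f
  norm$gene_lengths <- len[ok]
  norm
}

#' Per-gene Welch t-test between two replicate groups
#'
#' Operates on log2(CPM + 1). The significance flag requires the
#' Benjamini-Hochberg adjusted p-value below `alpha` AND
#' |log2FC| >= `min_abs_log2fc` (the two-fold gate at the default).
#' Zero variance in both groups yields p = 1 when the means are equal and
#' p = 0 flagged degenerate when they differ.
#'
#' @param x,y numeric matrices genes x replicates (CPM scale), matched
#'   rows.
#' @param alpha significance level on the adjusted p-value.
#' @param min_abs_log2fc absolute log2 fold-change gate.
#' @param log transform to log2(x + 1) before testing (set `FALSE` if
#'   already log scale).
#' @return data frame (log2FC, t, df, p, padj, significant, degenerate).
#' @export
de_test <- function(x, y, alpha = 0.05, min_abs_log2fc = 1, log = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(x) >= 2L, ncol(y) >= 2L)
  if (log) { x <- log2(x + 1); y <- log2(y + 1) }
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  t <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  degenerate <- rep(FALSE, length(p))
  zero_var <- se2 == 0
  if (any(zero_var)) {
    eq <- zero_var & lfc == 0
    ne <- zero_var & lfc != 0
    p[eq] <- 1; t[eq] <- 0
    p[ne] <- 0; degenerate[ne] <- TRUE
  }
  padj <- p.adjust(p, method = "BH")
  data.frame(log2FC = lfc, t = t, df = df, p = p, padj = padj,
             significant = padj < alpha & abs(lfc) >= min_abs_log2fc,
             degenerate = degenerate,
             row.names = rownames(x))
}

#' Homoeolog expression bias within a hybrid
#'
#' Per homoeolog pair, the bias is log2(FPKM_A / FPKM_B) of replicate-mean
#' FPKM (homoeolog counts share the hybrid sample's effective library
#' size). A pair is dominant toward a subgenome iff |log2 ratio| > 1
#' (>2-fold) and the replicate-level test is significant. Pairs with mean
#' FPKM below `fpkm_floor` in either homoeolog are excluded and counted.
#' The global bias statistic is a two-sided t-test of the per-pair log
#' ratios against zero.
#'
#' @param tcm a `triad_count_matrix` with homoeolog counts.
#' @param fpkm_floor expression floor (FPKM) required of both homoeologs.
#' @param alpha significance level.
#' @param p_adjust `"none"` (default) gates dominance on the raw
#'   replicate-level t-test p-value (two-fold + t-test at 0.05, the usual
#'   dominant-pair rule); `"BH"` uses the adjusted p-value.
#' @return an object of class `homoeolog_bias_result`: list with `genes`
#'   (log2_ratio, dominant, direction), `summary` (n dominant toward A/B,
#'   n unbiased, n excluded, global t statistic and p-value).
#' @export
homoeolog_bias <- function(tcm, fpkm_floor = 1, alpha = 0.05,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(tcm, "triad_count_matrix"))
  nr <- ncol(tcm$homoeolog$A)
  hyb_cols <- tcm$samples$sample[tcm$samples$role == "hybrid"]
  norm <- tmm_normalize(tcm$counts)
  eff <- norm$effective_lib_size[hyb_cols]
  len <- tcm$gene_lengths[rownames(tcm$counts)]
  fp <- function(m) sweep(m, 2, eff, "/") * 1e9 / len
  fpA <- fp(tcm$homoeolog$A); fpB <- fp(tcm$homoeolog$B)
  cpA <- sweep(tcm$homoeolog$A, 2, eff, "/") * 1e6
  cpB <- sweep(tcm$homoeolog$B, 2, eff, "/") * 1e6
  mA <- rowMeans(fpA); mB <- rowMeans(fpB)
  tested <- mA >= fpkm_floor & mB >= fpkm_floor
  ratio <- log2(mA / mB)
  de <- de_test(cpA[tested, , drop = FALSE], cpB[tested, , drop = FALSE],
                alpha = alpha, min_abs_log2fc = 1)
  de_sig <- if (p_adjust == "BH") de$significant
            else de$p < alpha & abs(de$log2FC) >= 1
  dominant <- rep(FALSE, length(ratio))
  dominant[tested] <- abs(ratio[tested]) > 1 & de_sig
  direction <- ifelse(!tested, NA_character_,
                      ifelse(dominant & ratio > 0, "A",
                             ifelse(dominant & ratio < 0, "B", "none")))
  gt <- t.test(ratio[tested])
  genes <- data.frame(gene = rownames(tcm$counts), log2_ratio = ratio,
                      mean_fpkm_a = mA, mean_fpkm_b = mB,
                      tested = tested, dominant = dominant,
                      direction = direction)
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 summary = list(n_dominant_a = sum(direction == "A",
                                                   na.rm = TRUE),
                                n_dominant_b = sum(direction == "B",
                                                   na.rm = TRUE),
                                n_unbiased = sum(direction == "none",
                                                 na.rm = TRUE),
                                n_excluded = sum(!tested),
                                global_t = unname(gt$statistic),
                                global_p = gt$p.value)),
            class = "homoeolog_bias_result")
}

#' Classify triad expression patterns
#'
#' Per gene, four Welch contrasts on log2(CPM + 1) are computed (hybrid vs
#' parent1, hybrid vs parent2, hybrid vs per-replicate mid-parent value,
#' parent1 vs parent2), each BH-adjusted across genes and gated at
#' `min_abs_log2fc`. The decision sequence is: TUR iff the hybrid is
#' significantly above both parents; TDR iff below both; Additive iff the
#' hybrid-vs-mid-parent contrast is non-significant; ELD_P1 iff the hybrid
#' matches parent1 (non-significant) while differing from parent2; ELD_P2
#' symmetric; UC otherwise. TUR genes split into NDE-TUR (parents
#' non-differential) and DE-TUR.
#'
#' @param tcm a `triad_count_matrix` (or list with `counts` and `samples`).
#' @param alpha significance level.
#' @param min_abs_log2fc fold-change gate (default 1 = two-fold).
#' @param p_adjust `"none"` (default) gates each contrast on its raw
#'   t-test p-value at `alpha`, the threshold rule used for triad
#'   classification in hybrid-expression studies; `"BH"` gates on the
#'   Benjamini-Hochberg adjusted p-value instead (more conservative at
#'   small replicate numbers).
#' @return an object of class `triad_classification`: data frame per gene
#'   (category, subtype, the four contrasts' log2FC, p and adjusted p),
#'   with attributes `"n_excluded"` (unexpressed genes) and
#'   `"category_counts"`.
#' @export
classify_triads <- function(tcm, alpha = 0.05, min_abs_log2fc = 1,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  counts <- tcm$counts
  samples <- tcm$samples
  norm <- tmm_normalize(counts)
  cpm <- norm$cpm
  expressed <- rowSums(counts) > 0
  cols <- function(role) samples$sample[samples$role == role]
  p1 <- cpm[expressed, cols("parent1"), drop = FALSE]
  p2 <- cpm[expressed, cols("parent2"), drop = FALSE]
  hy <- cpm[expressed, cols("hybrid"), drop = FALSE]
  # fixed replicate pairing for the per-replicate mid-parent value
  nrep <- min(ncol(p1), ncol(p2))
  mpv <- (p1[, seq_len(nrep), drop = FALSE] +
            p2[, seq_len(nrep), drop = FALSE]) / 2
  c_p1 <- de_test(hy, p1, alpha, min_abs_log2fc)
  c_p2 <- de_test(hy, p2, alpha, min_abs_log2fc)
  c_mpv <- de_test(hy, mpv, alpha, min_abs_log2fc)
  c_pp <- de_test(p1, p2, alpha, min_abs_log2fc)
  sig <- function(ct) {
    pv <- if (p_adjust == "BH") ct$padj else ct$p
    pv < alpha & abs(ct$log2FC) >= min_abs_log2fc
  }
  s1 <- sig(c_p1); s2 <- sig(c_p2); smpv <- sig(c_mpv); spp <- sig(c_pp)
  up1 <- s1 & c_p1$log2FC > 0
  dn1 <- s1 & c_p1$log2FC < 0
  up2 <- s2 & c_p2$log2FC > 0
  dn2 <- s2 & c_p2$log2FC < 0
  category <- rep("UC", nrow(c_p1))
  category[up1 & up2] <- "TUR"
  category[dn1 & dn2] <- "TDR"
  rest <- category == "UC"
  category[rest & !smpv] <- "Additive"
  rest <- category == "UC"
  category[rest & !s1 & s2] <- "ELD_P1"
  category[rest & s1 & !s2] <- "ELD_P2"
  subtype <- rep(NA_character_, length(category))
  subtype[category == "TUR"] <- ifelse(
    spp[category == "TUR"], "DE-TUR", "NDE-TUR")
  out <- data.frame(gene = rownames(cpm)[expressed],
                    category = category, subtype = subtype,
                    lfc_p1 = c_p1$log2FC, p_p1 = c_p1$p, padj_p1 = c_p1$padj,
                    lfc_p2 = c_p2$log2FC, p_p2 = c_p2$p, padj_p2 = c_p2$padj,
                    lfc_mpv = c_mpv$log2FC, p_mpv = c_mpv$p,
                    padj_mpv = c_mpv$padj,
                    lfc_pp = c_pp$log2FC, p_pp = c_pp$p, padj_pp = c_pp$padj)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!expressed)
  attr(out, "category_counts") <- table(factor(
    category, levels = c("Additive", "ELD_P1", "ELD_P2", "TUR", "TDR", "UC")))
  attr(out, "norm") <- norm
  class(out) <- c("triad_classification", "data.frame")
  out
}

#' Select transgressively upregulated genes for heatmap display
#'
#' NDE-TUR genes whose hybrid expression passes `min_fpkm` and whose
#' log2 fold-change over the higher-expressed parent exceeds
#' `min_log2fc`, ordered by that fold-change (descending).
#'
#' @param classification a [classify_triads()] result.
#' @param tcm the `triad_count_matrix` the classification came from.
#' @param min_fpkm hybrid mean FPKM threshold (exclusive).
#' @param min_log2fc hybrid-vs-max-parent log2FC threshold (exclusive).
#' @return data frame (gene, hybrid_fpkm, log2fc_vs_max_parent).
#' @export
select_tur_heatmap_genes <- function(classification, tcm, min_fpkm = 5,
                                     min_log2fc = 2) {
  stopifnot(inherits(classification, "triad_classification"))
  norm <- attr(classification, "norm")
  norm <- fpkm(norm, tcm$gene_lengths)
  hyb_cols <- tcm$samples$sample[tcm$samples$role == "hybrid"]
  hyb_fpkm <- rowMeans(norm$fpkm[, hyb_cols, drop = FALSE])
  cls <- classification
  cls$hybrid_fpkm <- hyb_fpkm[cls$gene]
  # fold-change over the higher parent = the smaller of the two contrasts
  cls$log2fc_vs_max_parent <- pmin(cls$lfc_p1, cls$lfc_p2)
  sel <- cls[!is.na(cls$subtype) & cls$subtype == "NDE-TUR" &
               cls$hybrid_fpkm > min_fpkm &
               cls$log2fc_vs_max_parent > min_log2fc,
             c("gene", "hybrid_fpkm", "log2fc_vs_max_parent")]
  sel <- sel[order(-sel$log2fc_vs_max_parent), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Summarise allele-specific reads per gene
#'
#' A read is informative iff it covers at least `min_snps_per_read`
#' distinguishing sites; it is assigned to a parent iff all its observed
#' alleles match that parent, and conflicting otherwise. A gene passes iff
#' it has at least `min_reads` assigned reads and a conflicting fraction
#' (conflicting / informative) below `max_conflict_fraction`. The allelic
#' ratio is parent1-assigned / total assigned.
#'
#' @param obs data frame (read_id, gene, site, allele, parent_match) with
#'   `parent_match` in `{"P1", "P2"}` per covered site.
#' @param min_snps_per_read minimum distinguishing sites per read.
#' @param min_reads minimum assigned reads per gene.
#' @param max_conflict_fraction maximum conflicting-read fraction
#'   (exclusive bound).
#' @return an object of class `ase_gene_summary`: data frame (gene, n_p1,
#'   n_p2, n_conflicting, n_informative, conflict_fraction, pass, ratio).
#' @export
summarize_ase <- function(obs, min_snps_per_read = 2L, min_reads = 20L,
                          max_conflict_fraction = 0.10) {
  stopifnot(all(c("read_id", "gene", "site", "parent_match") %in% names(obs)))
  dt <- data.table::as.data.table(obs)
  # reads spanning several genes are split per gene by the (gene, read) key
  per_read <- dt[, .(n_sites = .N,
                     n1 = sum(parent_match == "P1"),
                     n2 = sum(parent_match == "P2")),
                 by = .(gene, read_id)]
  per_read <- per_read[n_sites >= min_snps_per_read]
  per_read[, status := ifelse(n1 == n_sites, "P1",
                              ifelse(n2 == n_sites, "P2", "conflicting"))]
  g <- per_read[, .(n_p1 = sum(status == "P1"),
                    n_p2 = sum(status == "P2"),
                    n_conflicting = sum(status == "conflicting")),
                by = gene]
  g[, n_assigned := n_p1 + n_p2]
  g[, n_informative := n_assigned + n_conflicting]
  g[, conflict_fraction := ifelse(n_informative > 0,
                                  n_conflicting / n_informative, NA_real_)]
  g[, pass := n_assigned >= min_reads &
      conflict_fraction < max_conflict_fraction]
  g[, ratio := ifelse(pass, n_p1 / n_assigned, NA_real_)]
  out <- as.data.frame(g)
  class(out) <- c("ase_gene_summary", "data.frame")
  out
}

#' Partition parental expression divergence into cis and trans effects
#'
#' For each gene passing the allele-specific read gate: cis is the log2
#' allelic ratio in the hybrid (exact binomial test of assigned-read
#' counts against 0.5); P is the parental log2 ratio (Welch test on CPM);
#' trans = P - cis by construction (significance from a Fisher test of
#' hybrid allele counts against parental pseudo-counts). Categories:
#' conserved (neither cis nor trans significant), cis-only, trans-only,
#' compensatory (cis and trans significant, P not), cis+trans (both
#' significant, same sign), cis x trans (both significant, opposite sign,
#' |cis| < |trans|), ambiguous (remainder). All test families are
#' BH-adjusted across genes.
#'
#' @param ase an [summarize_ase()] result.
#' @param parent1_cpm,parent2_cpm CPM matrices (genes x replicates).
#' @param alpha significance level on adjusted p-values.
#' @param cpm_floor minimum mean parental CPM for a gene to be evaluated.
#' @return an object of class `cis_trans_call`: data frame (gene, cis,
#'   parental_log2, trans, p_cis, p_trans, p_parental adjusted values,
#'   category).
#' @export
cis_trans_partition <- function(ase, parent1_cpm, parent2_cpm, alpha = 0.05,
                                cpm_floor = 1) {
  stopifnot(inherits(ase, "ase_gene_summary"))
  genes <- intersect(ase$gene[ase$pass], rownames(parent1_cpm))
  m1 <- rowMeans(parent1_cpm[genes, , drop = FALSE])
  m2 <- rowMeans(parent2_cpm[genes, , drop = FALSE])
  genes <- genes[m1 >= cpm_floor & m2 >= cpm_floor]
  if (!length(genes)) stop("no genes pass the allele-specific read gate")
  a <- ase[match(genes, ase$gene), ]
  if (any(a$n_assigned == 0)) {
    drop <- a$n_assigned == 0
    genes <- genes[!drop]; a <- a[!drop, ]
  }
  cis <- log2((a$n_p1 + 0.5) / (a$n_p2 + 0.5))
  p_cis <- vapply(seq_len(nrow(a)), function(i)
    binom.test(a$n_p1[i], a$n_assigned[i], 0.5)$p.value, 0)
  de <- de_test(parent1_cpm[genes, , drop = FALSE],
                parent2_cpm[genes, , drop = FALSE],
                alpha = alpha, min_abs_log2fc = 0)
  P <- de$log2FC
  trans <- P - cis
  # trans: do hybrid allele counts depart from the parental ratio?
  p_trans <- vapply(seq_len(nrow(a)), function(i) {
    tot <- a$n_assigned[i]
    c1 <- round(m1[genes[i]] / (m1[genes[i]] + m2[genes[i]]) * tot)
    fisher.test(matrix(c(a$n_p1[i], a$n_p2[i], c1, tot - c1), 2))$p.value
  }, 0)
  q_cis <- p.adjust(p_cis, "BH")
  q_trans <- p.adjust(p_trans, "BH")
  q_par <- de$padj
  cis_sig <- q_cis < alpha
  trans_sig <- q_trans < alpha
  par_sig <- q_par < alpha
  category <- rep("ambiguous", length(genes))
  category[!cis_sig & !trans_sig] <- "conserved"
  category[cis_sig & !trans_sig] <- "cis-only"
  category[!cis_sig & trans_sig] <- "trans-only"
  both <- cis_sig & trans_sig
  category[both & !par_sig] <- "compensatory"
  category[both & par_sig & sign(cis) == sign(trans)] <- "cis+trans"
  category[both & par_sig & sign(cis) != sign(trans) &
             abs(cis) < abs(trans)] <- "cis_x_trans"
  out <- data.frame(gene = genes, cis = cis, parental_log2 = P,
                    trans = trans, padj_cis = q_cis, padj_trans = q_trans,
                    padj_parental = q_par, category = category)
  rownames(out) <- NULL
  class(out) <- c("cis_trans_call", "data.frame")
  out
}

#' Build a synthetic concatenated diploid reference annotation
#'
#' Joins two parental gene annotations into one two-subgenome universe,
#' prefixing gene identifiers with their subgenome tag, and pairs each
#' parental gene with its ortholog: by shared base identifier when the
#' annotations use a common naming (simulation truth), otherwise by
#' reciprocal best identity over supplied coding sequences.
#'
#' @param ann1,ann2 data frames with at least `gene_id` (and optionally
#'   coordinates and `length`).
#' @param prefixes two subgenome tags.
#' @param cds1,cds2 optional named character vectors of coding sequences
#'   for identity-based pairing.
#' @return list with `annotation` (combined, `subgenome` column) and
#'   `pairs` (gene_a, gene_b, identity; identity `NA` for truth pairing).
#' @export
build_synthetic_diploid_reference <- function(ann1, ann2,
                                              prefixes = c("A", "B"),
                                              cds1 = NULL, cds2 = NULL) {
  stopifnot("gene_id" %in% names(ann1), "gene_id" %in% names(ann2))
  a1 <- ann1; a2 <- ann2
  a1$subgenome <- prefixes[1]; a2$subgenome <- prefixes[2]
  a1$tagged_id <- paste0(prefixes[1], "_", a1$gene_id)
  a2$tagged_id <- paste0(prefixes[2], "_", a2$gene_id)
  combined <- rbind(a1, a2)
  if (anyDuplicated(combined$tagged_id))
    stop("duplicate gene id after prefixing: ",
         combined$tagged_id[duplicated(combined$tagged_id)][1])
  shared <- intersect(ann1$gene_id, ann2$gene_id)
  if (length(shared)) {
    pairs <- data.frame(gene_a = paste0(prefixes[1], "_", shared),
                        gene_b = paste0(prefixes[2], "_", shared),
                        identity = NA_real_)
  } else if (!is.null(cds1) && !is.null(cds2)) {
    pairs <- reciprocal_best_identity(cds1, cds2, prefixes)
  } else {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        identity = numeric())
  }
  list(annotation = combined, pairs = pairs)
}

# reciprocal best hit by p-identity over equal-length sequence pairs
reciprocal_best_identity <- function(cds1, cds2, prefixes) {
  id <- matrix(NA_real_, length(cds1), length(cds2),
               dimnames = list(names(cds1), names(cds2)))
  for (i in seq_along(cds1)) {
    r1 <- charToRaw(cds1[[i]])
    for (j in seq_along(cds2)) {
      if (nchar(cds1[[i]]) != nchar(cds2[[j]])) next
      id[i, j] <- mean(r1 == charToRaw(cds2[[j]]))
    }
  }
  best12 <- apply(id, 1, function(x) if (all(is.na(x))) NA else which.max(x))
  best21 <- apply(id, 2, function(x) if (all(is.na(x))) NA else which.max(x))
  keep <- which(!is.na(best12) & best21[best12] == seq_along(best12))
  data.frame(gene_a = paste0(prefixes[1], "_", names(cds1)[keep]),
             gene_b = paste0(prefixes[2], "_", names(cds2)[best12[keep]]),
             identity = id[cbind(keep, best12[keep])])
}
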