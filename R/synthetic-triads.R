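#' Configuration for simulating triad expression counts
#'
#' Describes a parent1/parent2/hybrid triad count experiment with planted
#' expression categories. Per gene, parental means are drawn around
#' `baseline_mean` (log-normal gene effect), the hybrid mean is set by the
#' planted category, and replicate counts are negative binomial. Hybrid
#' totals are split into homoeolog A/B counts, with a planted >2-fold bias
#' for a configurable fraction of genes, and allele-informative read
#' observations are generated with a conflict rate.
#'
#' Planted category rules (effect `e = effect_log2fc`, parents P1/P2):
#' Additive: hybrid = mid-parent (parents equal or `e` apart);
#' ELD_P1/ELD_P2: hybrid equals that parent, planted as the lower of the
#' two with parents `2e` apart (dominance toward the higher parent cannot
#' clear a two-fold mid-parent gate and is not planted); TUR: hybrid =
#' max-parent x 2^e (parents equal for the NDE subtype, `e` apart for DE);
#' TDR: hybrid = min-parent x 2^-e; UC: parents `3e` apart with the hybrid
#' between them but displaced from mid-parent.
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per condition.
#' @param category_proportions named fractions over Additive, ELD_P1,
#'   ELD_P2, TUR, TDR, UC summing to 1.
#' @param effect_log2fc magnitude of planted effects (log2 units).
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson).
#' @param baseline_mean expected baseline count.
#' @param homoeolog_bias_fraction fraction of genes with a >2-fold
#'   homoeolog bias.
#' @param homoeolog_bias_log2fc planted bias magnitude (log2).
#' @param ase_conflict_rate probability an allele-informative read is
#'   internally inconsistent.
#' @param ase_reads_per_gene informative reads simulated per gene.
#' @param lib_factor_range range of per-sample library-size factors
#'   (uniform); `c(1, 1)` disables library-size variation.
#' @param cistrans_proportions optional named fractions over `conserved`,
#'   `cis_only`, `trans_only`; when given, parental ratios and homoeolog
#'   splits are driven by the planted cis/trans class (categories are
#'   forced Additive).
#' @param seed integer RNG seed.
#' @return an object of class `triad_sim_config`.
#' @export
triad_sim_config <- function(n_genes = 2000L, n_replicates = 3L,
                             category_proportions = c(
                               Additive = 0.7, ELD_P1 = 0.07, ELD_P2 = 0.07,
                               TUR = 0.06, TDR = 0.06, UC = 0.04),
                             effect_log2fc = 2, nb_dispersion = 0.05,
                             baseline_mean = 300,
                             homoeolog_bias_fraction = 0.1,
                             homoeolog_bias_log2fc = 2,
                             ase_conflict_rate = 0.05,
                             ase_reads_per_gene = 100L,
                             lib_factor_range = c(0.8, 1.25),
                             cistrans_proportions = NULL, seed = 1L) {
  cats <- c("Additive", "ELD_P1", "ELD_P2", "TUR", "TDR", "UC")
  if (!all(names(category_proportions) %in% cats) ||
      any(category_proportions < 0) ||
      abs(sum(category_proportions) - 1) > 1e-9)
    stop("category_proportions must be nonnegative fractions over ",
         paste(cats, collapse = "/"), " summing to 1")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  assert_scalar_number(ase_conflict_rate, "ase_conflict_rate", 0, 1,
                       closed_upper = FALSE)
  if (!is.null(cistrans_proportions)) {
    if (!all(names(cistrans_proportions) %in%
             c("conserved", "cis_only", "trans_only")) ||
        abs(sum(cistrans_proportions) - 1) > 1e-9)
      stop("cistrans_proportions must cover conserved/cis_only/trans_only")
  }
  full <- setNames(numeric(length(cats)), cats)
  full[names(category_proportions)] <- category_proportions
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 category_proportions = full,
                 effect_log2fc = effect_log2fc,
                 nb_dispersion = nb_dispersion,
                 baseline_mean = baseline_mean,
                 homoeolog_bias_fraction = homoeolog_bias_fraction,
                 homoeolog_bias_log2fc = homoeolog_bias_log2fc,
                 ase_conflict_rate = ase_conflict_rate,
                 ase_reads_per_gene = as.integer(ase_reads_per_gene),
                 lib_factor_range = lib_factor_range,
                 cistrans_proportions = cistrans_proportions,
                 seed = as.integer(seed)),
            class = "triad_sim_config")
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu,
                                                 size = 1 / dispersion)
}

#' Simulate a triad count matrix with planted expression categories
#'
#' @param config a [triad_sim_config()].
#' @return an object of class `triad_count_matrix`: list with `counts`
#'   (genes x samples; parent1, parent2 and hybrid replicates), `samples`
#'   (sample sheet: sample, role, replicate), `homoeolog` (matrices `A` and
#'   `B` for hybrid replicates; A + B = hybrid total), `gene_lengths`
#'   (CDS bp), `ase` (read-level allele observations: read_id, gene, site,
#'   allele, parent_match), and `truth` (per-gene category, subtype, means,
#'   homoeolog split, cis/trans values and class).
#' @export
simulate_triad_counts <- function(config) {
  stopifnot(inherits(config, "triad_sim_config"))
  withr::local_seed(config$seed)
  ng <- config$n_genes; nr <- config$n_replicates
  e <- config$effect_log2fc
  genes <- sprintf("g%04d", seq_len(ng))
  base <- config$baseline_mean * 2^rnorm(ng, 0, 0.5)
  if (is.null(config$cistrans_proportions)) {
    category <- sample(names(config$category_proportions), ng, replace = TRUE,
                       prob = config$category_proportions)
  } else {
    category <- rep("Additive", ng)
  }
  dir <- sample(c(-1, 1), ng, replace = TRUE)   # +1: parent2 is higher
  # identifiable planted geometry (see the methods vignette): ELD genes put
  # the hybrid on the LOWER parent with parents 2e apart -- under a two-fold
  # mid-parent gate, dominance toward the higher parent can never clear the
  # gate (hybrid/MPV = 2r/(1+r) < 2) and is not planted; UC genes separate
  # the parents by 3e with the hybrid between parents but off mid-parent.
  dir[category == "ELD_P1"] <- 1
  dir[category == "ELD_P2"] <- -1
  mu1 <- numeric(ng); mu2 <- numeric(ng); muh <- numeric(ng)
  subtype <- rep(NA_character_, ng)
  parents_differ <- runif(ng) < 0.5
  for (i in seq_len(ng)) {
    gap <- switch(category[i],
                  Additive = if (parents_differ[i]) e else 0,
                  ELD_P1 = 2 * e, ELD_P2 = 2 * e,
                  TUR = if (parents_differ[i]) e else 0,
                  TDR = if (parents_differ[i]) e else 0,
                  UC = 3 * e)
    mu1[i] <- base[i] * 2^(-dir[i] * gap / 2)
    mu2[i] <- base[i] * 2^(dir[i] * gap / 2)
    muh[i] <- switch(category[i],
                     Additive = (mu1[i] + mu2[i]) / 2,
                     ELD_P1 = mu1[i],
                     ELD_P2 = mu2[i],
                     TUR = max(mu1[i], mu2[i]) * 2^e,
                     TDR = min(mu1[i], mu2[i]) * 2^(-e),
                     # toward the lower parent: far from both parents and
                     # from the (high-parent-dominated) arithmetic mid-parent
                     UC = base[i] * 2^(-0.5))
    if (category[i] == "TUR")
      subtype[i] <- if (gap == 0) "NDE-TUR" else "DE-TUR"
  }
  # homoeolog split ratio p (fraction of hybrid reads from subgenome A)
  biased <- runif(ng) < config$homoeolog_bias_fraction
  bias_dir <- ifelse(runif(ng) < 0.5, 1, -1)
  b <- config$homoeolog_bias_log2fc
  p_split <- ifelse(biased, 2^(bias_dir * b) / (1 + 2^(bias_dir * b)), 0.5)
  ct_class <- rep(NA_character_, ng)
  if (!is.null(config$cistrans_proportions)) {
    ct_class <- sample(names(config$cistrans_proportions), ng, replace = TRUE,
                       prob = config$cistrans_proportions)
    sgn <- sample(c(-1, 1), ng, replace = TRUE)
    for (i in seq_len(ng)) {
      if (ct_class[i] == "conserved") {
        mu1[i] <- mu2[i] <- base[i]; p_split[i] <- 0.5
      } else if (ct_class[i] == "cis_only") {
        mu1[i] <- base[i] * 2^(sgn[i] * e / 2)
        mu2[i] <- base[i] * 2^(-sgn[i] * e / 2)
        r <- mu1[i] / mu2[i]
        p_split[i] <- r / (1 + r)
      } else {
        mu1[i] <- base[i] * 2^(sgn[i] * e / 2)
        mu2[i] <- base[i] * 2^(-sgn[i] * e / 2)
        p_split[i] <- 0.5
      }
      muh[i] <- (mu1[i] + mu2[i]) / 2
    }
    biased <- abs(log2(p_split / (1 - p_split))) > 1
  }
  # library-size factors make TMM normalisation meaningful
  lib_factor <- runif(3 * nr, config$lib_factor_range[1],
                      config$lib_factor_range[2])
  counts <- matrix(0L, ng, 3 * nr)
  colnames(counts) <- c(paste0("P1_r", seq_len(nr)),
                        paste0("P2_r", seq_len(nr)),
                        paste0("H_r", seq_len(nr)))
  homA <- matrix(0L, ng, nr, dimnames = list(genes, paste0("H_r", seq_len(nr))))
  homB <- homA
  for (r in seq_len(nr)) {
    counts[, r] <- rnb(ng, mu1 * lib_factor[r], config$nb_dispersion)
    counts[, nr + r] <- rnb(ng, mu2 * lib_factor[nr + r], config$nb_dispersion)
    h <- rnb(ng, muh * lib_factor[2 * nr + r], config$nb_dispersion)
    a <- rbinom(ng, h, p_split)
    counts[, 2 * nr + r] <- h
    homA[, r] <- a
    homB[, r] <- h - a
  }
  rownames(counts) <- genes
  samples <- data.frame(
    sample = colnames(counts),
    role = rep(c("parent1", "parent2", "hybrid"), each = nr),
    replicate = rep(seq_len(nr), 3))
  gene_lengths <- setNames(sample(seq(300L, 3000L, by = 3L), ng,
                                  replace = TRUE), genes)
  # allele-informative read observations
  ase <- simulate_ase_observations(genes, p_split,
                                   config$ase_reads_per_gene,
                                   config$ase_conflict_rate)
  truth <- data.frame(gene = genes, category = category, subtype = subtype,
                      mean_p1 = mu1, mean_p2 = mu2, mean_hybrid = muh,
                      biased = biased,
                      bias_direction = ifelse(biased,
                                              ifelse(p_split > 0.5, "A", "B"),
                                              "none"),
                      p_split = p_split,
                      cis = log2(p_split / (1 - p_split)),
                      parental_log2 = log2(mu1 / mu2),
                      cistrans_class = ct_class)
  truth$trans <- truth$parental_log2 - truth$cis
  structure(list(counts = counts, samples = samples,
                 homoeolog = list(A = homA, B = homB),
                 gene_lengths = gene_lengths, ase = ase, truth = truth,
                 config = config),
            class = "triad_count_matrix")
}

# read-level allele observations: each informative read covers >= 2
# distinguishing sites; conflicting reads mix parental matches
simulate_ase_observations <- function(genes, p_split, reads_per_gene,
                                      conflict_rate) {
  ng <- length(genes)
  n_conf <- rbinom(ng, reads_per_gene, conflict_rate)
  n_assigned <- reads_per_gene - n_conf
  n_p1 <- rbinom(ng, n_assigned, p_split)
  # ~10% extra single-site (uninformative) reads
  n_single <- rbinom(ng, max(1L, round(reads_per_gene * 0.1)), 0.9)
  rows <- vector("list", ng)
  for (i in seq_len(ng)) {
    nr_tot <- reads_per_gene + n_single[i]
    sites_per_read <- c(2L + rpois(reads_per_gene, 0.5), rep(1L, n_single[i]))
    read_id <- paste0(genes[i], "_rd", seq_len(nr_tot))
    match1 <- c(rep("P1", n_p1[i]),
                rep("P2", n_assigned[i] - n_p1[i]),
                rep("conf", n_conf[i]),
                sample(c("P1", "P2"), n_single[i], replace = TRUE))
    rid <- rep(read_id, sites_per_read)
    kind <- rep(match1, sites_per_read)
    site_ord <- sequence(sites_per_read)
    pm <- ifelse(kind == "conf",
                 ifelse(site_ord == 1L, "P1",
                        ifelse(site_ord == 2L, "P2",
                               sample(c("P1", "P2"), length(kind),
                                      replace = TRUE))),
                 kind)
    rows[[i]] <- data.frame(read_id = rid, gene = genes[i],
                            site = paste0(genes[i], "_s", site_ord),
                            allele = "N", parent_match = pm)
  }
  out <- as.data.frame(data.table::rbindlist(rows))
  rownames(out) <- NULL
  out
}

#' Simulate a gene-to-term annotation map with optional spiked terms
#'
#' Genes are assigned to terms at random, except spiked terms whose
#' membership is biased toward a designated selected-gene subset at the
#' stated odds (sampling weight `odds` for selected genes, 1 otherwise).
#'
#' @param n_genes,n_terms universe and term counts.
#' @param term_size_range inclusive range of genes per term (min >= 1).
#' @param spiked_terms optional data frame (term index or name, odds >= 1).
#' @param selection_size size of the designated selected subset.
#' @param seed integer RNG seed.
#' @return list with `annotation` (gene, term), `selected_genes`,
#'   `universe`, `truth` (spiked term names).
#' @export
simulate_go_annotation <- function(n_genes = 5000L, n_terms = 100L,
                                   term_size_range = c(10L, 100L),
                                   spiked_terms = NULL,
                                   selection_size = 200L, seed = 1L) {
  if (term_size_range[1] < 1L || term_size_range[2] > n_genes)
    stop("term sizes must lie in [1, n_genes]")
  if (!is.null(spiked_terms) && any(spiked_terms$odds < 1))
    stop("spiked term odds must be >= 1")
  withr::local_seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  terms <- sprintf("T%04d", seq_len(n_terms))
  selected <- sample(genes, selection_size)
  w <- rep(1, n_genes)
  spiked <- character()
  ann <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
    odds <- 1
    if (!is.null(spiked_terms)) {
      hit <- which(spiked_terms$term == terms[t] | spiked_terms$term == t)
      if (length(hit)) {
        odds <- spiked_terms$odds[hit[1]]
        if ("size" %in% names(spiked_terms) &&
            !is.na(spiked_terms$size[hit[1]]))
          size <- spiked_terms$size[hit[1]]
        spiked <- c(spiked, terms[t])
      }
    }
    wt <- w
    wt[genes %in% selected] <- odds
    members <- sample(genes, size, prob = wt)
    ann[[t]] <- data.frame(gene = members, term = terms[t])
  }
  list(annotation = do.call(rbind, ann), selected_genes = selected,
       universe = genes, truth = list(spiked_terms = spiked))
}
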