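#' Pipeline configuration with study-default thresholds
#'
#' Collects every stage parameter with defaults mirroring the analysis
#' thresholds used throughout the package: k = 17 for ploidy spectra,
#' 100-kb heterozygosity windows, 500-bp identity windows, the two-fold
#' dominance gate, >= 2 distinguishing SNPs per allele-informative read,
#' >= 20 assigned reads and < 10% conflicts, alpha = 0.05, and the
#' FPKM > 5 / log2FC > 2 transgressive-gene gate. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults listed by
#'   `names(pipeline_config())`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_lineages = 4L, n_chromosomes = 2L, chrom_length = 200000L,
    divergence_within = 0.005, divergence_between = 0.02,
    novel_mutation_rate = 1e-5,
    parent_a = "L1", parent_b = "L3",
    read_depth = 60, read_length = 150L, k = 17L,
    vcf_depth = 50L, window_bp = 100000L, identity_window_bp = 500L,
    k_assign = 31L, ambiguity_margin = 0.05,
    n_genes = 1500L, n_replicates = 3L, effect_log2fc = 2,
    nb_dispersion = 0.05, baseline_mean = 300,
    homoeolog_bias_fraction = 0.1, ase_conflict_rate = 0.05,
    alpha = 0.05, min_abs_log2fc = 1, min_fpkm = 5, heatmap_log2fc = 2,
    min_snps_per_read = 2L, min_reads = 20L, max_conflict_fraction = 0.10,
    n_go_terms = 60L, go_spike_odds = 10)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

PIPELINE_DEPS <- list(simulate = character(),
                      ploidy = "simulate",
                      popgen = "simulate",
                      parentage = "simulate",
                      triads = "simulate",
                      enrich = "triads")

# transitive dependency closure of the requested stages
stage_closure <- function(stages) {
  all_stages <- names(PIPELINE_DEPS)
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  need <- stages
  repeat {
    more <- unique(unlist(PIPELINE_DEPS[need]))
    if (all(more %in% need)) break
    need <- union(need, more)
  }
  all_stages[all_stages %in% need]
}

#' Run the end-to-end demonstration pipeline on synthetic data
#'
#' Executes, in dependency order: synthetic genome/hybrid/read/variant/
#' count simulation; k-mer ploidy calling; SNP filtering with windowed
#' heterozygosity, allele-frequency profiles and a neighbor-joining tree;
#' parentage scoring and subgenome assignment; triad expression
#' classification; and term enrichment of the transgressively upregulated
#' set. Each stage writes plain-text outputs under its own subdirectory
#' and the run manifest records the seed, every parameter, per-stage row
#' counts and file checksums, so identical configurations reproduce
#' byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed from which all stage seeds derive.
#' @param config a [pipeline_config()].
#' @param stages optional subset of stages to run (dependencies are added
#'   automatically).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = pipeline_config(),
                         stages = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- stage_closure(stages %||% names(PIPELINE_DEPS))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "hybridtriad",
                   version = as.character(utils::packageVersion("hybridtriad")),
                   seed = as.integer(seed),
                   parameters = unclass(config),
                   stages = list())
  state <- new.env(parent = emptyenv())
  tsv <- function(x, stage, name) {
    dir.create(file.path(out_dir, stage), showWarnings = FALSE)
    path <- file.path(out_dir, stage, name)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  record <- function(stage, files, rows, t0) {
    manifest$stages[[stage]] <<- list(
      files = lapply(files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)),
             bytes = file.size(f))),
      rows = rows,
      seconds = round(as.numeric(Sys.time()) - t0, 2))
  }
  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    if (stage == "simulate") {
      dv <- matrix(config$divergence_between, config$n_lineages,
                   config$n_lineages)
      clade <- rep(1:2, length.out = config$n_lineages)
      dv[outer(clade, clade, "==")] <- config$divergence_within
      diag(dv) <- 0
      lcfg <- lineage_sim_config(config$n_lineages, config$n_chromosomes,
                                 config$chrom_length, dv, seed = seed)
      state$lineages <- simulate_lineages(lcfg)
      state$hybrid <- make_hybrid(state$lineages,
                                  hybrid_sim_config(config$parent_a,
                                                    config$parent_b,
                                                    config$novel_mutation_rate,
                                                    seed = seed + 1L))
      state$vt <- simulate_variant_table(state$lineages, state$hybrid,
                                         depth = config$vcf_depth,
                                         seed = seed + 2L)
      state$tcm <- simulate_triad_counts(triad_sim_config(
        n_genes = config$n_genes, n_replicates = config$n_replicates,
        effect_log2fc = config$effect_log2fc,
        nb_dispersion = config$nb_dispersion,
        baseline_mean = config$baseline_mean,
        homoeolog_bias_fraction = config$homoeolog_bias_fraction,
        ase_conflict_rate = config$ase_conflict_rate,
        seed = seed + 3L))
      f1 <- tsv(state$hybrid$het_sites, stage, "hybrid_het_sites.tsv")
      f2 <- tsv(cbind(state$vt$sites,
                      state$vt$gt)[seq_len(min(5000, n_sites(state$vt))), ],
                stage, "variant_table_head.tsv")
      f3 <- tsv(state$tcm$truth, stage, "triad_truth.tsv")
      fa <- file.path(out_dir, stage, "hybrid_genome.fa")
      write_genome_fasta(state$hybrid, fa)
      record(stage, list(f1, f2, f3, fa),
             list(het_sites = nrow(state$hybrid$het_sites),
                  variant_sites = n_sites(state$vt),
                  genes = nrow(state$tcm$truth)), t0)
    } else if (stage == "ploidy") {
      reads <- simulate_reads(state$hybrid, depth = config$read_depth,
                              read_length = config$read_length,
                              seed = seed + 4L)
      spec <- count_kmers(reads, k = config$k)
      peaks <- detect_peaks(spec)
      call <- call_ploidy(peaks)
      f1 <- tsv(as.data.frame(spec), stage, "kmer_spectrum.tsv")
      f2 <- tsv(peaks, stage, "peaks.tsv")
      f3 <- tsv(data.frame(call = call$call,
                           ratio = call$peak_position_ratio), stage,
                "ploidy_call.tsv")
      record(stage, list(f1, f2, f3),
             list(spectrum_rows = nrow(spec), peaks = nrow(peaks)), t0)
    } else if (stage == "popgen") {
      fvt <- filter_variants(state$vt, filter_policy())
      het <- heterozygosity_windows(fvt, window_bp = config$window_bp)
      afp <- allele_frequency_profile(fvt, state$hybrid$id)
      iup <- encode_iupac_matrix(fvt)
      d <- p_distance_matrix(iup)
      tree <- neighbor_joining(d)
      f1 <- tsv(het, stage, "heterozygosity_windows.tsv")
      f2 <- tsv(afp$histogram, stage, "allele_frequency_histogram.tsv")
      f3 <- tsv(data.frame(sample = rownames(d), d), stage,
                "p_distance.tsv")
      f4 <- file.path(out_dir, stage, "nj_tree.nwk")
      ape::write.tree(tree, f4)
      record(stage, list(f1, f2, f3, f4),
             list(filtered_sites = n_sites(fvt), windows = nrow(het),
                  modal_af = afp$modal_frequency), t0)
    } else if (stage == "parentage") {
      sites <- hybrid_het_sites(state$hybrid)
      cand <- candidate_alleles(state$lineages, sites)
      dst <- classify_diagnostic_snps(sites, cand)
      scores <- score_parental_pairs(dst)
      part <- assign_subgenomes(state$hybrid,
                                state$lineages$genomes[[config$parent_a]],
                                state$lineages$genomes[[config$parent_b]],
                                k = config$k_assign,
                                ambiguity_margin = config$ambiguity_margin)
      aln <- truth_alignments(state$hybrid$hap_a$seqs,
                              state$hybrid$hap_b$seqs)
      idw <- identity_windows(aln, window_bp = config$identity_window_bp)
      f1 <- tsv(dst$class_counts, stage, "diagnostic_class_counts.tsv")
      f2 <- tsv(scores, stage, "parental_pair_scores.tsv")
      f3 <- tsv(part, stage, "subgenome_partition.tsv")
      f4 <- tsv(idw$windows, stage, "identity_windows.tsv")
      record(stage, list(f1, f2, f3, f4),
             list(pairs = nrow(scores), chromosomes = nrow(part),
                  identity_windows = nrow(idw$windows),
                  best_pair = paste(scores$p[1], scores$q[1])), t0)
    } else if (stage == "triads") {
      cls <- classify_triads(state$tcm, alpha = config$alpha,
                             min_abs_log2fc = config$min_abs_log2fc)
      bias <- homoeolog_bias(state$tcm)
      ase <- summarize_ase(state$tcm$ase,
                           min_snps_per_read = config$min_snps_per_read,
                           min_reads = config$min_reads,
                           max_conflict_fraction = config$max_conflict_fraction)
      norm <- attr(cls, "norm")
      p1c <- norm$cpm[, state$tcm$samples$sample[
        state$tcm$samples$role == "parent1"], drop = FALSE]
      p2c <- norm$cpm[, state$tcm$samples$sample[
        state$tcm$samples$role == "parent2"], drop = FALSE]
      ct <- cis_trans_partition(ase, p1c, p2c, alpha = config$alpha)
      sel <- select_tur_heatmap_genes(cls, state$tcm,
                                      min_fpkm = config$min_fpkm,
                                      min_log2fc = config$heatmap_log2fc)
      state$cls <- cls
      f1 <- tsv(as.data.frame(cls), stage, "triad_classification.tsv")
      f2 <- tsv(bias$genes, stage, "homoeolog_bias.tsv")
      f3 <- tsv(ase, stage, "ase_summary.tsv")
      f4 <- tsv(ct, stage, "cis_trans.tsv")
      f5 <- tsv(sel, stage, "tur_heatmap_genes.tsv")
      record(stage, list(f1, f2, f3, f4, f5),
             list(classified = nrow(cls),
                  category_counts = as.list(attr(cls, "category_counts")),
                  ase_pass = sum(ase$pass)), t0)
    } else if (stage == "enrich") {
      tur <- state$cls$gene[state$cls$category == "TUR"]
      idx <- as.integer(sub("^g0*", "", tur))
      go <- simulate_go_annotation(
        n_genes = config$n_genes, n_terms = config$n_go_terms,
        spiked_terms = data.frame(term = c(1L, 2L),
                                  odds = config$go_spike_odds),
        selection_size = max(length(tur), 1L), seed = seed + 5L)
      # align the designated subset with the TUR genes themselves
      genes <- go$universe
      selection <- genes[idx]
      spike <- go$truth$spiked_terms
      ann <- go$annotation
      for (tm in spike) {
        sz <- sum(ann$term == tm)
        keepers <- ann[ann$term != tm, ]
        members <- withr::with_seed(seed + 6L, {
          m <- sample(selection, min(length(selection), round(sz * 0.6)))
          c(m, setdiff(sample(genes), m))[seq_len(sz)]
        })
        ann <- rbind(keepers, data.frame(gene = members, term = tm))
      }
      enr <- hypergeom_enrich(selection, ann, universe = genes)
      f1 <- tsv(enr, stage, "enrichment.tsv")
      record(stage, list(f1),
             list(terms = nrow(enr),
                  significant = sum(enr$padj < config$alpha)), t0)
    }
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read gene intervals from a GFF3 file
#'
#' @param path GFF3 file; `gene` features are returned as 0-based
#'   half-open intervals.
#' @return data frame (chrom, start, end, gene_id).
#' @export
read_gene_intervals <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr[gr$type == "gene"])
  data.frame(chrom = as.character(df$seqnames), start = df$start - 1L,
             end = df$end,
             gene_id = if ("ID" %in% names(df)) df$ID
                       else as.character(seq_len(nrow(df))))
}
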