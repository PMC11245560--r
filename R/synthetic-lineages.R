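#' Configuration for simulating diverged haploid lineages
#'
#' Describes a set of haploid lineages descending from a common ancestor by
#' substitution only, with optional chromosomal fusion and fission events
#' (dysploidy). Pairwise divergence is specified as a per-bp substitution
#' probability; internally an average-linkage hierarchy over the matrix is
#' walked root-to-leaf, so clade structure (small within-group, large
#' between-group divergence) is reproduced in expectation. A warning is
#' issued when the matrix is far from ultrametric and realized divergences
#' may deviate.
#'
#' @param n_lineages number of haploid lineages (>= 2).
#' @param n_chromosomes chromosomes per lineage before rearrangement events.
#' @param chrom_length chromosome length in bp.
#' @param divergence either a single per-bp divergence applied to every
#'   lineage pair, or a symmetric zero-diagonal matrix of per-bp divergences
#'   in `[0, 1)`.
#' @param fusion_fission_events list of events, each a list with elements
#'   `lineage` (e.g. `"L2"`), `kind` (`"fusion"` or `"fission"`), `chroms`
#'   (two chromosome names for fusion, one for fission) and, for fission,
#'   `breakpoint` (bp, strictly inside the chromosome).
#' @param seed integer RNG seed.
#' @return an object of class `lineage_sim_config`.
#' @export
lineage_sim_config <- function(n_lineages = 2L, n_chromosomes = 1L,
                               chrom_length = 100000L, divergence = 0.02,
                               fusion_fission_events = list(), seed = 1L) {
  stopifnot(n_lineages >= 2L, n_chromosomes >= 1L, chrom_length >= 1000L)
  if (is.matrix(divergence)) {
    if (nrow(divergence) != n_lineages || ncol(divergence) != n_lineages)
      stop("divergence matrix must be n_lineages x n_lineages")
    if (any(abs(divergence - t(divergence)) > 1e-12))
      stop("divergence matrix must be symmetric")
    if (any(diag(divergence) != 0))
      stop("divergence matrix must have zero diagonal")
    dv <- divergence
  } else {
    assert_scalar_number(divergence, "divergence", 0, 1, closed_upper = FALSE)
    dv <- matrix(divergence, n_lineages, n_lineages)
    diag(dv) <- 0
  }
  if (any(dv < 0 | dv >= 1)) stop("divergence values must lie in [0, 1)")
  for (ev in fusion_fission_events) {
    if (!all(c("lineage", "kind") %in% names(ev)) ||
        !ev$kind %in% c("fusion", "fission"))
      stop("each event needs 'lineage' and kind in {fusion, fission}")
    if (ev$kind == "fission") {
      bp <- ev$breakpoint %||% stop("fission event needs a 'breakpoint'")
      if (bp <= 0 || bp >= chrom_length)
        stop("fission breakpoint must lie strictly inside the chromosome")
    }
  }
  structure(list(n_lineages = as.integer(n_lineages),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 divergence = dv,
                 fusion_fission_events = fusion_fission_events,
                 seed = as.integer(seed)),
            class = "lineage_sim_config")
}

# Average-linkage hierarchy over dv/2: leaf-pair cophenetic distance x2
# approximates the requested divergence, so clade structure in the matrix
# (e.g. small within-group, large between-group rates) is reproduced.
divergence_hierarchy <- function(dv) {
  hc <- stats::hclust(stats::as.dist(dv / 2), method = "average")
  realized <- 2 * as.matrix(stats::cophenetic(hc))
  off <- upper.tri(dv) & dv > 0
  if (any(off) && max(abs(realized[off] - dv[off]) / dv[off]) > 0.25)
    warning("divergence matrix is far from ultrametric; realized pairwise ",
            "divergences may deviate from the requested values")
  hc
}

#' Simulate diverged haploid lineage genomes
#'
#' Draws a uniform-composition ancestral genome, derives each lineage by
#' substitutions accumulated along its root-to-leaf path through the
#' divergence hierarchy, and applies the configured fusion/fission events. Sequences are kept in ancestral
#' chromosome coordinates; the physical chromosome structure after
#' rearrangements is described by each genome's karyotype and realised by
#' [physical_seqs()].
#'
#' @param config a [lineage_sim_config()].
#' @return an object of class `lineage_set`: list with `genomes` (named list
#'   of `lineage_genome`), `ancestor` (named character vector of sequences)
#'   and `truth` (per-lineage mutation tables vs the ancestor, event
#'   records).
#' @export
simulate_lineages <- function(config) {
  stopifnot(inherits(config, "lineage_sim_config"))
  withr::local_seed(config$seed)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  ancestor <- setNames(
    vapply(chrom_names, function(.) random_dna(config$chrom_length), ""),
    chrom_names)
  ids <- paste0("L", seq_len(config$n_lineages))
  # walk the divergence hierarchy root-to-leaf, mutating each branch at a
  # per-bp rate equal to its height span
  mutate_branch <- function(seqs, rate) {
    if (rate <= 0) return(seqs)
    for (cn in chrom_names) {
      pos <- draw_mutation_positions(config$chrom_length, rate)
      seqs[[cn]] <- mutate_seq(seqs[[cn]], pos)$seq
    }
    seqs
  }
  leaf_seqs <- vector("list", config$n_lineages)
  if (config$n_lineages == 2L) {
    r <- config$divergence[1, 2] / 2
    leaf_seqs[[1]] <- mutate_branch(ancestor, r)
    leaf_seqs[[2]] <- mutate_branch(ancestor, r)
  } else {
    hc <- divergence_hierarchy(config$divergence)
    h <- hc$height
    descend <- function(node, seqs, node_height) {
      # node: row of hc$merge; negative entries are leaves
      for (child in hc$merge[node, ]) {
        if (child < 0) {
          leaf_seqs[[-child]] <<- mutate_branch(seqs, node_height)
        } else {
          descend(child, mutate_branch(seqs, node_height - h[child]),
                  h[child])
        }
      }
    }
    root <- nrow(hc$merge)
    descend(root, ancestor, h[root])
  }
  genomes <- list()
  mutations <- list()
  for (i in seq_along(ids)) {
    seqs <- leaf_seqs[[i]]
    mut <- list()
    for (cn in chrom_names) {
      pos <- string_mismatch_positions(ancestor[[cn]], seqs[[cn]])
      mut[[cn]] <- if (length(pos))
        data.frame(chrom = rep(cn, length(pos)), pos = pos,
                   from = substring(ancestor[[cn]], pos, pos),
                   to = substring(seqs[[cn]], pos, pos))
      else data.frame(chrom = character(), pos = integer(),
                      from = character(), to = character())
    }
    karyotype <- lapply(chrom_names, function(cn)
      list(name = cn, segments = data.frame(anc_chrom = cn, start = 1L,
                                            end = config$chrom_length)))
    names(karyotype) <- chrom_names
    genomes[[ids[i]]] <- structure(
      list(id = ids[i], seqs = seqs, karyotype = karyotype),
      class = "lineage_genome")
    mutations[[ids[i]]] <- do.call(rbind, mut)
  }
  events <- list()
  for (ev in config$fusion_fission_events) {
    genomes[[ev$lineage]] <- apply_karyotype_event(genomes[[ev$lineage]], ev)
    events[[length(events) + 1L]] <- ev
  }
  structure(list(genomes = genomes, ancestor = ancestor,
                 config = config,
                 truth = list(mutations = mutations, events = events)),
            class = "lineage_set")
}

apply_karyotype_event <- function(genome, ev) {
  kt <- genome$karyotype
  if (ev$kind == "fusion") {
    if (length(ev$chroms) != 2L || !all(ev$chroms %in% names(kt)))
      stop("fusion needs two existing chromosome names")
    a <- kt[[ev$chroms[1]]]; b <- kt[[ev$chroms[2]]]
    fused <- list(name = paste(ev$chroms, collapse = "_"),
                  segments = rbind(a$segments, b$segments))
    kt[[ev$chroms[1]]] <- NULL
    kt[[ev$chroms[2]]] <- NULL
    kt[[fused$name]] <- fused
  } else {
    if (length(ev$chroms) != 1L || !ev$chroms %in% names(kt))
      stop("fission needs one existing chromosome name")
    entry <- kt[[ev$chroms]]
    total <- sum(entry$segments$end - entry$segments$start + 1L)
    bp <- ev$breakpoint
    if (bp <= 0 || bp >= total)
      stop("fission breakpoint must lie strictly inside the chromosome")
    # split the segment list at offset bp
    left <- list(); right <- list(); off <- 0L
    for (s in seq_len(nrow(entry$segments))) {
      seg <- entry$segments[s, ]
      len <- seg$end - seg$start + 1L
      if (off + len <= bp) left[[length(left) + 1L]] <- seg
      else if (off >= bp) right[[length(right) + 1L]] <- seg
      else {
        cut <- seg$start + (bp - off) - 1L
        left[[length(left) + 1L]] <-
          data.frame(anc_chrom = seg$anc_chrom, start = seg$start, end = cut)
        right[[length(right) + 1L]] <-
          data.frame(anc_chrom = seg$anc_chrom, start = cut + 1L, end = seg$end)
      }
      off <- off + len
    }
    p1 <- list(name = paste0(entry$name, "_p1"), segments = do.call(rbind, left))
    p2 <- list(name = paste0(entry$name, "_p2"), segments = do.call(rbind, right))
    kt[[ev$chroms]] <- NULL
    kt[[p1$name]] <- p1
    kt[[p2$name]] <- p2
  }
  genome$karyotype <- kt
  genome
}

#' Physical chromosome sequences of a lineage genome
#'
#' Assembles the post-rearrangement chromosomes from the karyotype segment
#' map over the ancestral-coordinate sequences.
#'
#' @param genome a `lineage_genome`.
#' @return named character vector of chromosome sequences.
#' @export
physical_seqs <- function(genome) {
  stopifnot(inherits(genome, "lineage_genome"))
  out <- vapply(genome$karyotype, function(entry) {
    paste(vapply(seq_len(nrow(entry$segments)), function(s) {
      seg <- entry$segments[s, ]
      substr(genome$seqs[[seg$anc_chrom]], seg$start, seg$end)
    }, ""), collapse = "")
  }, "")
  names(out) <- vapply(genome$karyotype, `[[`, "", "name")
  out
}

#' Configuration for constructing a diploid hybrid
#'
#' @param parent_a,parent_b lineage identifiers (distinct).
#' @param novel_mutation_rate per-bp probability of a post-hybridization
#'   substitution on each haplotype, in `[0, 1)`. Should stay well below the
#'   parental divergence so novel alleles remain a minority class.
#' @param seed integer RNG seed.
#' @return an object of class `hybrid_sim_config`.
#' @export
hybrid_sim_config <- function(parent_a, parent_b, novel_mutation_rate = 0,
                              seed = 1L) {
  if (identical(parent_a, parent_b))
    stop("parent_a and parent_b must be distinct lineages")
  assert_scalar_number(novel_mutation_rate, "novel_mutation_rate", 0, 1,
                       closed_upper = FALSE)
  structure(list(parent_a = parent_a, parent_b = parent_b,
                 novel_mutation_rate = novel_mutation_rate,
                 seed = as.integer(seed)),
            class = "hybrid_sim_config")
}

#' Construct a diploid hybrid from two haploid lineages
#'
#' The hybrid carries one haplotype copied from each parent, each optionally
#' perturbed by novel substitutions. Ground truth labels every heterozygous
#' site as parent-derived or novel.
#'
#' @param lineages a `lineage_set` from [simulate_lineages()].
#' @param config a [hybrid_sim_config()] naming two lineages from `lineages`.
#' @return an object of class `hybrid_genome`: haplotypes `hap_a`/`hap_b`
#'   (each a `lineage_genome`), `het_sites` (data frame with ancestral
#'   coordinates, the two alleles, and provenance `"parental"`/`"novel"`),
#'   and `truth` (novel-mutation tables per haplotype, warnings).
#' @export
make_hybrid <- function(lineages, config) {
  stopifnot(inherits(lineages, "lineage_set"),
            inherits(config, "hybrid_sim_config"))
  pa <- lineages$genomes[[config$parent_a]]
  pb <- lineages$genomes[[config$parent_b]]
  if (is.null(pa) || is.null(pb)) stop("unknown parent lineage id")
  withr::local_seed(config$seed)
  warnings <- character()
  if (length(pa$karyotype) != length(pb$karyotype)) {
    msg <- "parents have unequal chromosome counts (dysploid hybrid)"
    warning(msg)
    warnings <- c(warnings, msg)
  }
  add_novel <- function(parent, tag) {
    seqs <- parent$seqs
    novel <- list()
    for (cn in names(seqs)) {
      pos <- draw_mutation_positions(nchar(seqs[[cn]]), config$novel_mutation_rate)
      m <- mutate_seq(seqs[[cn]], pos)
      seqs[[cn]] <- m$seq
      novel[[cn]] <- data.frame(chrom = rep(cn, length(pos)), pos = pos,
                                from = m$from, to = m$to)
    }
    hap <- parent
    hap$id <- paste0("hybrid_", tag)
    hap$seqs <- seqs
    list(hap = hap, novel = do.call(rbind, novel))
  }
  a <- add_novel(pa, "A")
  b <- add_novel(pb, "B")
  shared <- intersect(names(a$hap$seqs), names(b$hap$seqs))
  het <- list()
  for (cn in shared) {
    pos <- string_mismatch_positions(a$hap$seqs[[cn]], b$hap$seqs[[cn]])
    if (!length(pos)) next
    allele_a <- strsplit(paste(substring(a$hap$seqs[[cn]], pos, pos),
                               collapse = ""), "")[[1]]
    allele_b <- strsplit(paste(substring(b$hap$seqs[[cn]], pos, pos),
                               collapse = ""), "")[[1]]
    novel_pos <- union(a$novel$pos[a$novel$chrom == cn],
                       b$novel$pos[b$novel$chrom == cn])
    het[[cn]] <- data.frame(
      chrom = rep(cn, length(pos)), pos = pos,
      allele_a = allele_a, allele_b = allele_b,
      provenance = ifelse(pos %in% novel_pos, "novel", "parental"))
  }
  het <- if (length(het)) do.call(rbind, het) else
    data.frame(chrom = character(), pos = integer(), allele_a = character(),
               allele_b = character(), provenance = character())
  rownames(het) <- NULL
  structure(list(id = paste0(config$parent_a, "x", config$parent_b),
                 parent_a = config$parent_a, parent_b = config$parent_b,
                 hap_a = a$hap, hap_b = b$hap,
                 het_sites = het,
                 truth = list(novel_a = a$novel, novel_b = b$novel,
                              warnings = warnings),
                 config = config),
            class = "hybrid_genome")
}

#' Write genome sequences as FASTA
#'
#' @param x a `lineage_genome`, `hybrid_genome`, or named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path) {
  seqs <- genome_seqs(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

# physical sequences of any genome-bearing object, named per haplotype for
# hybrids ("A_<chrom>", "B_<chrom>")
genome_seqs <- function(x) {
  if (inherits(x, "lineage_genome")) return(physical_seqs(x))
  if (inherits(x, "hybrid_genome")) {
    a <- physical_seqs(x$hap_a); b <- physical_seqs(x$hap_b)
    return(c(setNames(a, paste0("A_", names(a))),
             setNames(b, paste0("B_", names(b)))))
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("cannot extract sequences from this object")
}
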