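#' Heterozygous sites of a simulated hybrid
#'
#' Convenience accessor returning the truth heterozygous-site table of a
#' [make_hybrid()] genome in ancestral coordinates.
#'
#' @param hybrid a `hybrid_genome`.
#' @return data frame (chrom, pos, allele_a, allele_b, provenance).
#' @export
hybrid_het_sites <- function(hybrid) {
  stopifnot(inherits(hybrid, "hybrid_genome"))
  hybrid$het_sites
}

#' Candidate-parent alleles at a set of sites
#'
#' Looks up each candidate lineage's base at every site (ancestral
#' coordinates shared by construction in the simulation).
#'
#' @param lineages a `lineage_set`.
#' @param sites data frame with `chrom` and `pos`.
#' @param candidates lineage ids to evaluate.
#' @return character matrix sites x candidates.
#' @export
candidate_alleles <- function(lineages, sites,
                              candidates = names(lineages$genomes)) {
  stopifnot(inherits(lineages, "lineage_set"))
  out <- vapply(candidates, function(id) {
    seqs <- lineages$genomes[[id]]$seqs
    al <- character(nrow(sites))
    for (cn in unique(sites$chrom)) {
      i <- sites$chrom == cn
      al[i] <- substring(seqs[[cn]], sites$pos[i], sites$pos[i])
    }
    al
  }, character(nrow(sites)))
  matrix(out, nrow = nrow(sites), dimnames = list(NULL, candidates))
}

#' Classify hybrid heterozygous SNPs by parental provenance
#'
#' For every heterozygous site (optionally restricted to single-copy gene
#' intervals) and every candidate parent pair (p, q), the site is
#' pair-explained iff the unordered hybrid allele pair equals the unordered
#' (allele_p, allele_q) pair with distinct alleles. Independently of the
#' pair, a site is novel-allele iff at least one hybrid allele occurs in no
#' candidate, and shared iff all candidates carry the same allele and it is
#' among the hybrid alleles; remaining sites are conflicting for that pair.
#' This partition is one consistent reading of a diagnostic-class taxonomy
#' whose fine binning differs between studies.
#'
#' @param het_sites data frame (chrom, pos, allele_a, allele_b).
#' @param candidates character matrix sites x candidate parents of alleles.
#' @param intervals optional data frame (chrom, start, end), 0-based
#'   half-open; sites outside every interval are excluded and counted.
#' @return an object of class `diagnostic_snp_table`: list with `sites`
#'   (flags `novel`, `shared`), `explained` (logical matrix sites x pairs),
#'   `pairs`, `class_counts` (per pair per class), `n_excluded`.
#' @export
classify_diagnostic_snps <- function(het_sites, candidates, intervals = NULL) {
  stopifnot(is.matrix(candidates), nrow(candidates) == nrow(het_sites),
            ncol(candidates) >= 2L)
  n_excluded <- 0L
  if (!is.null(intervals)) {
    inside <- rep(FALSE, nrow(het_sites))
    for (r in seq_len(nrow(intervals))) {
      hit <- het_sites$chrom == intervals$chrom[r] &
        het_sites$pos - 1L >= intervals$start[r] &
        het_sites$pos - 1L < intervals$end[r]
      inside <- inside | hit
    }
    n_excluded <- sum(!inside)
    het_sites <- het_sites[inside, , drop = FALSE]
    candidates <- candidates[inside, , drop = FALSE]
  }
  n <- nrow(het_sites)
  cand_ids <- colnames(candidates)
  novel <- vapply(seq_len(n), function(i)
    !(het_sites$allele_a[i] %in% candidates[i, ]) ||
      !(het_sites$allele_b[i] %in% candidates[i, ]), TRUE)
  shared <- vapply(seq_len(n), function(i) {
    u <- unique(candidates[i, ])
    length(u) == 1L && u %in% c(het_sites$allele_a[i], het_sites$allele_b[i])
  }, TRUE)
  pairs <- t(utils::combn(cand_ids, 2L))
  colnames(pairs) <- c("p", "q")
  explained <- matrix(FALSE, n, nrow(pairs),
                      dimnames = list(NULL, paste(pairs[, 1], pairs[, 2],
                                                  sep = ":")))
  for (j in seq_len(nrow(pairs))) {
    ap <- candidates[, pairs[j, 1]]
    aq <- candidates[, pairs[j, 2]]
    explained[, j] <- ap != aq &
      ((het_sites$allele_a == ap & het_sites$allele_b == aq) |
         (het_sites$allele_a == aq & het_sites$allele_b == ap))
  }
  class_counts <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
    cls <- ifelse(explained[, j], "pair-explained",
                  ifelse(novel, "novel-allele",
                         ifelse(shared, "shared", "conflicting")))
    data.frame(p = pairs[j, 1], q = pairs[j, 2],
               pair_explained = sum(cls == "pair-explained"),
               shared = sum(cls == "shared"),
               novel_allele = sum(cls == "novel-allele"),
               conflicting = sum(cls == "conflicting"))
  }))
  structure(list(sites = cbind(het_sites, novel = novel, shared = shared),
                 explained = explained,
                 pairs = as.data.frame(pairs),
                 class_counts = class_counts,
                 n_excluded = n_excluded),
            class = "diagnostic_snp_table")
}

#' Score candidate parental pairs
#'
#' Ranks all candidate pairs by the fraction of evaluated heterozygous
#' sites they explain (both hybrid alleles matched, one to each parent).
#' A best pair explaining less than `floor` raises a flag signalling a
#' possibly missing or extinct parent.
#'
#' @param dst a [classify_diagnostic_snps()] result.
#' @param floor explained-fraction floor for the missing-parent flag.
#' @return data frame ranked by explained fraction (descending), with
#'   attributes `"margin"` (top minus runner-up) and
#'   `"missing_parent_flag"`.
#' @export
score_parental_pairs <- function(dst, floor = 0.9) {
  stopifnot(inherits(dst, "diagnostic_snp_table"))
  n <- nrow(dst$sites)
  if (n == 0L) stop("no evaluated sites")
  n_explained <- colSums(dst$explained)
  res <- data.frame(p = dst$pairs$p, q = dst$pairs$q,
                    n_explained = n_explained,
                    n_unexplained = n - n_explained,
                    explained_fraction = n_explained / n)
  res <- res[order(-res$explained_fraction, res$p, res$q), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "margin") <- if (nrow(res) > 1L)
    res$explained_fraction[1] - res$explained_fraction[2] else NA_real_
  attr(res, "missing_parent_flag") <- res$explained_fraction[1] < floor
  res
}

#' Assign hybrid chromosomes to subgenomes by k-mer containment
#'
#' The support of a hybrid chromosome toward a parent is the fraction of
#' its canonical k-mers present anywhere in that parent's genome. A
#' chromosome is labelled A when support toward `parent_a` exceeds
#' `parent_b` by at least `ambiguity_margin`, B for the converse, and
#' ambiguous otherwise. A precomputed per-chromosome coverage table (e.g.
#' from whole-genome alignment) may replace the containment computation.
#'
#' @param hybrid a `hybrid_genome` or named character vector of hybrid
#'   chromosome sequences.
#' @param parent_a,parent_b `lineage_genome`s or named character vectors.
#' @param k odd k-mer length (default 31).
#' @param ambiguity_margin minimum support difference for a call.
#' @param unique_only drop parent k-mers occurring more than once (crude
#'   repeat mask).
#' @param coverage optional data frame (chromosome, support_a, support_b)
#'   replacing the k-mer computation.
#' @return an object of class `subgenome_partition`: data frame
#'   (chromosome, support_a, support_b, margin, label).
#' @export
assign_subgenomes <- function(hybrid, parent_a, parent_b, k = 31L,
                              ambiguity_margin = 0.05, unique_only = FALSE,
                              coverage = NULL) {
  if (!is.null(coverage)) {
    stopifnot(all(c("chromosome", "support_a", "support_b") %in%
                    names(coverage)))
    res <- coverage
  } else {
    seqs <- genome_seqs(hybrid)
    pa <- genome_seqs(parent_a)
    pb <- genome_seqs(parent_b)
    if (!length(seqs) || !length(pa) || !length(pb))
      stop("genomes must be nonempty")
    sa <- .kmer_containment_cpp(unname(seqs), unname(pa), as.integer(k),
                                isTRUE(unique_only))
    sb <- .kmer_containment_cpp(unname(seqs), unname(pb), as.integer(k),
                                isTRUE(unique_only))
    short <- nchar(seqs) < k
    if (any(short))
      warning("chromosome(s) shorter than k labelled ambiguous: ",
              paste(names(seqs)[short], collapse = ", "))
    res <- data.frame(chromosome = names(seqs),
                      support_a = as.numeric(sa), support_b = as.numeric(sb))
  }
  margin <- res$support_a - res$support_b
  label <- ifelse(is.na(margin), "ambiguous",
                  ifelse(margin >= ambiguity_margin, "A",
                         ifelse(margin <= -ambiguity_margin, "B",
                                "ambiguous")))
  out <- data.frame(res, margin = margin, label = label)
  rownames(out) <- NULL
  class(out) <- c("subgenome_partition", "data.frame")
  out
}

#' Truth alignments between two haplotypes
#'
#' Builds per-chromosome gapless alignment blocks (runs of `=` and `X`)
#' between equal-length haplotype sequences sharing coordinates, as emitted
#' by the substitution-only simulator. Indel features for identity-window
#' tests can be added as explicit `I`/`D` runs in hand-built blocks.
#'
#' @param a_seqs,b_seqs named character vectors with matching names and
#'   lengths.
#' @return data frame (query, qstart, qlen, target, cigar) with `qstart`
#'   0-based; class `alignment_set`.
#' @export
truth_alignments <- function(a_seqs, b_seqs) {
  stopifnot(identical(names(a_seqs), names(b_seqs)))
  blocks <- lapply(names(a_seqs), function(cn) {
    eq <- charToRaw(a_seqs[[cn]]) == charToRaw(b_seqs[[cn]])
    r <- rle(eq)
    cigar <- paste0(r$lengths, ifelse(r$values, "=", "X"), collapse = "")
    data.frame(query = cn, qstart = 0L, qlen = nchar(a_seqs[[cn]]),
               target = cn, cigar = cigar)
  })
  out <- do.call(rbind, blocks)
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Read pairwise alignments from PAF with extended CIGAR
#'
#' Parses the 12 mandatory PAF columns plus the `cg:Z` tag. Alignments
#' whose CIGAR uses ambiguous `M` operations (match-or-mismatch) are
#' rejected: identity windows need the extended `=`/`X` encoding.
#'
#' @param path PAF file.
#' @return an `alignment_set` data frame (query, qstart, qlen, target,
#'   cigar).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  blocks <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) stop("malformed PAF record")
    cg <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (!length(cg))
      stop("alignment lacks a cg:Z CIGAR tag; extended CIGAR is required")
    cigar <- sub("^cg:Z:", "", cg[1])
    if (grepl("[0-9]M", cigar))
      stop("CIGAR contains 'M' operations; extended (=/X) CIGAR is required")
    data.frame(query = f[1], qstart = as.integer(f[3]),
               qlen = as.integer(f[4]) - as.integer(f[3]),
               target = f[6], cigar = cigar)
  })
  out <- do.call(rbind, blocks)
  class(out) <- c("alignment_set", "data.frame")
  out
}

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.frame(op = ops, len = lens)
}

#' Windowed pairwise identity along the query
#'
#' Divides each query sequence into non-overlapping windows and computes,
#' per window, aligned columns (matches + mismatches + indel columns,
#' query-anchored: `I` columns occupy query positions, `D` columns are
#' attributed to the window holding the preceding query position), matching
#' columns, identity, SNP count and indel-event count. Windows whose
#' aligned coverage falls below `coverage_floor * window_bp` report a
#' missing identity. Genome-wide totals accumulate mismatch columns (SNPs)
#' and distinct gap events (indels).
#'
#' @param alignments an `alignment_set` (from [truth_alignments()] or
#'   [read_paf()]).
#' @param window_bp window size on the query (default 500).
#' @param coverage_floor minimum aligned fraction for a window to report an
#'   identity.
#' @param query_lengths optional named vector of full query lengths (for
#'   window grids extending beyond the aligned blocks).
#' @return an object of class `identity_track`: list with `windows` (query,
#'   start, end, aligned, matches, mismatches, indel_cols, indel_events,
#'   identity) and `totals` (aligned, matches, snps, indel_events).
#' @export
identity_windows <- function(alignments, window_bp = 500L,
                             coverage_floor = 0.5, query_lengths = NULL) {
  stopifnot(inherits(alignments, "data.frame"))
  if (window_bp <= 0) stop("window_bp must be positive")
  acc <- new.env(parent = emptyenv())
  acc$tab <- list()   # per (query, window): counts
  bump <- function(query, win, what, amt) {
    key <- paste0(query, "#", win)
    cur <- acc$tab[[key]] %||% c(matches = 0, mismatches = 0, ins = 0,
                                 del = 0, events = 0)
    cur[what] <- cur[what] + amt
    acc$tab[[key]] <- cur
  }
  # distribute `len` columns starting at query offset q0 (0-based) over windows
  spread <- function(query, q0, len, what) {
    while (len > 0L) {
      win <- q0 %/% window_bp
      take <- min(len, (win + 1L) * window_bp - q0)
      bump(query, win, what, take)
      q0 <- q0 + take
      len <- len - take
    }
    q0
  }
  for (b in seq_len(nrow(alignments))) {
    q <- alignments$query[b]
    qpos <- alignments$qstart[b]
    runs <- parse_cigar(alignments$cigar[b])
    for (r in seq_len(nrow(runs))) {
      op <- runs$op[r]; len <- runs$len[r]
      if (op == "=") qpos <- spread(q, qpos, len, "matches")
      else if (op == "X") qpos <- spread(q, qpos, len, "mismatches")
      else if (op == "I") {
        qpos <- spread(q, qpos, len, "ins")
        bump(q, (qpos - 1L) %/% window_bp, "events", 1)
      } else if (op == "D") {
        win <- max(qpos - 1L, 0L) %/% window_bp
        bump(q, win, "del", len)
        bump(q, win, "events", 1)
      } else stop("unsupported CIGAR op: ", op)
    }
  }
  keys <- names(acc$tab)
  parts <- strsplit(keys, "#", fixed = TRUE)
  tab <- do.call(rbind, acc$tab)
  windows <- data.frame(query = vapply(parts, `[`, "", 1),
                        win = as.integer(vapply(parts, `[`, "", 2)))
  windows$start <- windows$win * window_bp
  windows$end <- windows$start + window_bp
  if (!is.null(query_lengths))
    windows$end <- pmin(windows$end, query_lengths[windows$query])
  windows$matches <- tab[, "matches"]
  windows$mismatches <- tab[, "mismatches"]
  windows$indel_cols <- tab[, "ins"] + tab[, "del"]
  windows$indel_events <- tab[, "events"]
  windows$aligned <- windows$matches + windows$mismatches + windows$indel_cols
  windows$identity <- ifelse(windows$aligned >= coverage_floor * window_bp,
                             windows$matches / windows$aligned, NA_real_)
  windows <- windows[order(windows$query, windows$start),
                     c("query", "start", "end", "aligned", "matches",
                       "mismatches", "indel_cols", "indel_events",
                       "identity")]
  rownames(windows) <- NULL
  totals <- list(aligned = sum(windows$aligned),
                 matches = sum(windows$matches),
                 snps = sum(windows$mismatches),
                 indel_events = sum(windows$indel_events))
  structure(list(windows = windows, totals = totals,
                 window_bp = window_bp, coverage_floor = coverage_floor),
            class = "identity_track")
}
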