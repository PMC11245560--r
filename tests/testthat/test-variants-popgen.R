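test_that("filter policy applies per-sample masks then site filters", {
  vt <- toy_variant_table()
  # QUAL 19 at one site: genotypes masked, site dropped by missingness
  vt$sites$qual[1] <- 19
  out <- filter_variants(vt, filter_policy(min_maf = 0.02,
                                           max_missing_fraction = 0.5))
  expect_false(100 %in% out$sites$pos)
  # hand-applied default policy: QUAL site (1) masked then dropped by
  # missingness, monomorphic site (5, MAF 0) and triallelic site (7) drop
  expect_equal(out$sites$pos, c(200L, 300L, 400L, 600L, 800L, 900L, 1000L))
  # clean toy, default policy: 10 sites in, 8 out (MAF-0 + triallelic)
  out2 <- filter_variants(toy_variant_table(), filter_policy())
  expect_equal(nrow(out2$sites), 8L)
  # raising the MAF floor to 0.2 additionally drops the two 1/8-MAF sites
  out3 <- filter_variants(toy_variant_table(),
                          filter_policy(min_maf = 0.2))
  expect_equal(out3$sites$pos, c(100L, 200L, 400L, 600L, 800L, 1000L))
})

test_that("DP window masks genotypes per sample", {
  vt <- toy_variant_table()
  vt$dp[2, "s1"] <- 5       # below min_dp
  vt$dp[2, "s2"] <- 500     # above max_dp
  out <- filter_variants(vt, filter_policy(min_maf = 0,
                                           max_missing_fraction = 1,
                                           biallelic_only = FALSE))
  expect_true(gt_is_missing(out$gt[out$sites$pos == 200L, "s1"]))
  expect_true(gt_is_missing(out$gt[out$sites$pos == 200L, "s2"]))
  expect_false(gt_is_missing(out$gt[out$sites$pos == 200L, "s3"]))
})

test_that("a permissive policy is the identity and filtering is idempotent", {
  vt <- toy_variant_table()
  perm <- filter_policy(min_maf = 0, max_missing_fraction = 1,
                        biallelic_only = FALSE)
  out <- filter_variants(vt, perm)
  expect_equal(out$sites, vt$sites)
  expect_equal(out$gt, vt$gt)
  pol <- filter_policy()
  once <- filter_variants(vt, pol)
  twice <- filter_variants(once, pol)
  expect_equal(once$sites, twice$sites)
  expect_equal(once$gt, twice$gt)
  expect_error(filter_policy(min_dp = 400, max_dp = 10), "min_dp")
})

test_that("heterozygosity windows count het genotypes with the right denominators", {
  vt <- toy_variant_table()
  hw <- heterozygosity_windows(vt, window_bp = 500L,
                               chrom_lengths = c(chr1 = 1000L))
  w1s1 <- hw[hw$start == 0 & hw$sample == "s1", ]
  expect_equal(w1s1$n_snps, 5L)
  expect_equal(w1s1$n_het, 3L)   # sites 100,200,400 het for s1; 300,500 hom
  expect_equal(w1s1$value, 3 / 5)
  hb <- heterozygosity_windows(vt, window_bp = 500L, mode = "per_bp",
                               chrom_lengths = c(chr1 = 1000L))
  expect_equal(hb$value[hb$start == 0 & hb$sample == "s1"], 3 / 500)
  # empty window reports NA, not zero
  hw2 <- heterozygosity_windows(vt, window_bp = 500L,
                                chrom_lengths = c(chr1 = 2000L))
  expect_true(is.na(hw2$value[hw2$start == 1000 & hw2$sample == "s1"]))
  expect_error(heterozygosity_windows(vt, window_bp = 0), "window_bp")
})

test_that("windowed heterozygosity recovers the planted het density", {
  sim <- small_hybrid_sim(divergence = 0.02, chrom_length = 100000L, seed = 31)
  vt <- simulate_variant_table(sim$lineages, sim$hybrid, depth = 50, seed = 5)
  hw <- heterozygosity_windows(vt, window_bp = 10000L)
  hyb <- hw[hw$sample == sim$hybrid$id, ]
  # the hybrid is heterozygous at (almost) every variant site it carries;
  # per-bp mode recovers the planted divergence
  hb <- heterozygosity_windows(vt, window_bp = 10000L, mode = "per_bp")
  dens <- mean(hb$value[hb$sample == sim$hybrid$id])
  expect_lt(abs(dens - 0.02), 3 * sqrt(0.02 * 0.98 / 100000))
})

test_that("allele-frequency fractions, histogram and modal bin behave", {
  vt <- toy_variant_table()
  afp <- allele_frequency_profile(vt, "s1", sites = "het")
  expect_true(all(afp$fractions == 0.5))
  expect_equal(afp$modal_frequency, 0.5)
  expect_equal(sum(afp$histogram$count), length(afp$fractions))
  # zero-depth site is skipped and counted
  vt$ad[2, "s1"] <- "0,0"
  afp2 <- allele_frequency_profile(vt, "s1", sites = "het")
  expect_equal(afp2$n_skipped, 1L)
})

test_that("haploid and diploid modal allele frequencies separate", {
  sim <- small_hybrid_sim(divergence = 0.02, chrom_length = 200000L, seed = 33)
  vt <- simulate_variant_table(sim$lineages, sim$hybrid, depth = 50, seed = 7)
  dip <- allele_frequency_profile(vt, sim$hybrid$id)
  hap <- allele_frequency_profile(vt, "L2")
  expect_gte(dip$modal_frequency, 0.48)
  expect_lte(dip$modal_frequency, 0.52)
  expect_equal(hap$modal_frequency, 1.0)
})

test_that("IUPAC encoding maps genotype classes to degenerate bases", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                      ref = c("G", "A", "C", "AT"),
                      alt = c("T", "G", "T", "A"), qual = 60)
  gt <- matrix(c("0/1", "0/0", ".", "0",
                 "1/1", "0/1", "0/1", "0"), 4, 2,
               dimnames = list(NULL, c("x", "y")))
  vt <- variant_table(sites, gt)
  m <- encode_iupac_matrix(vt)
  expect_equal(m["x", "chr1:10"], "K")   # G/T
  expect_equal(m["x", "chr1:20"], "A")   # A/A
  expect_equal(m["x", "chr1:30"], "N")   # missing
  expect_equal(m["y", "chr1:10"], "T")   # T/T
  expect_equal(m["y", "chr1:20"], "R")   # A/G
  expect_equal(m["y", "chr1:30"], "Y")   # C/T
  expect_equal(attr(m, "n_skipped"), 1L) # the indel site
})

test_that("p-distance compares literal symbols and excludes N", {
  m <- rbind(a = c("A", "C", "G", "T"),
             b = c("A", "C", "G", "A"),
             c = c("A", "C", "G", "T"),
             k = c("K", "C", "G", "T"))
  d <- p_distance_matrix(m)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "k"], 0.25)  # K vs G... K vs A at column 1
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  m2 <- rbind(a = c("A", "N"), b = c("N", "C"))
  expect_true(is.na(p_distance_matrix(m2)["a", "b"]))
})

test_that("neighbor joining solves the three-taxon closed form", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  tr <- neighbor_joining(d)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("t1", "t2", "t3")]), c(0.05, 0.15, 0.25))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(42)
  for (i in 1:5) {
    rt <- ape::rtree(7)
    dd <- ape::cophenetic.phylo(rt)
    tr <- neighbor_joining(dd)
    pl <- ape::cophenetic.phylo(tr)[rownames(dd), colnames(dd)]
    expect_lt(max(abs(pl - dd)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rt)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("a four-taxon additive matrix beats the two alternative topologies", {
  # path lengths on ((a,b),(c,d)): internal branch 1, tips 1
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  # exhaustive oracle: the split {a,b}|{c,d} is the only one whose
  # four-point condition holds with equality margin
  s1 <- d["a", "b"] + d["c", "d"]
  s2 <- d["a", "c"] + d["b", "d"]
  s3 <- d["a", "d"] + d["b", "c"]
  expect_true(s1 < s2 && s1 < s3 && s2 == s3)
  split <- ape::prop.part(ape::unroot(tr))
  expect_lt(max(abs(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]] - d)),
            1e-9)
})

test_that("NJ ties break on the lexicographically smallest pair", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- neighbor_joining(d)
  # first join must be (1, 2): their parent is shared and distinct from others
  pa <- tr$edge[tr$edge[, 2] == 1, 1]
  pb <- tr$edge[tr$edge[, 2] == 2, 1]
  expect_equal(pa, pb)
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
  dna <- d; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(neighbor_joining(dna), "a, b")
})

test_that("NJ groups simulated clades monophyletically", {
  ok <- vapply(1:8, function(s) {
    ls <- clade_lineages(between = 0.02, within = 0.005,
                         chrom_length = 20000L, seed = s)
    vt <- simulate_variant_table(ls, depth = 30, seed = s + 100)
    m <- encode_iupac_matrix(filter_variants(vt, filter_policy(
      min_maf = 0, max_missing_fraction = 1)))
    tr <- neighbor_joining(p_distance_matrix(m))
    rooted <- ape::root(tr, "L3")
    ape::is.monophyletic(rooted, c("L1", "L2"))
  }, TRUE)
  expect_true(all(ok))
})

test_that("variant tables round-trip through VCF", {
  sim <- small_hybrid_sim(divergence = 0.01, chrom_length = 20000L, seed = 35)
  vt <- simulate_variant_table(sim$lineages, sim$hybrid, depth = 30, seed = 9)
  path <- tempfile(fileext = ".vcf.gz")
  write_vcf(vt, path)
  back <- read_vcf(path)
  expect_equal(back$sites$pos, vt$sites$pos)
  expect_equal(back$sites$ref, vt$sites$ref)
  expect_equal(unname(back$gt), unname(vt$gt))
  expect_equal(unname(back$ad), unname(vt$ad))
  expect_equal(back$chrom_lengths, vt$chrom_lengths)
})
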