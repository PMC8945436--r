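toy_regions <- function() {
  data.frame(region_id = c("r1", "r2", "r3"),
             region_class = c("target_site", "target_site", "mirna"),
             chrom = c("chrU", "chrU", "chrM"),
             start = c(90L, 200L, 0L), end = c(110L, 220L, 22L),
             sequence = c("ACGTACGTACGTACGTACGT", "TTTTACGCGTTTTTTTTTAC",
                          "GGGGCGGGGGGGGGGGGGGGGA"),
             stringsAsFactors = FALSE)
}

test_that("variant assignment respects half-open boundaries", {
  regions <- toy_regions()
  v <- data.frame(chrom = c("chrU", "chrU", "chrU", "chrM"),
                  pos = c(100L, 110L, 89L, 21L),
                  ref = "C", alt = "T", maf = 0.01)
  a <- assign_variants(v, regions)
  expect_equal(nrow(a), 2L)                       # pos=end and pos<start drop
  expect_equal(a$region_id, c("r1", "r3"))
  expect_equal(a$region_offset, c(10L, 21L))
})

test_that("variant assignment equals a brute-force interval check", {
  set.seed(71)
  regions <- toy_regions()
  v <- data.frame(chrom = sample(c("chrU", "chrM"), 50, TRUE),
                  pos = sample.int(250, 50) - 1L, ref = "A", alt = "G",
                  maf = 0.05)
  got <- assign_variants(v, regions)
  for (i in seq_len(nrow(v))) {
    inside <- which(regions$chrom == v$chrom[i] &
                      v$pos[i] >= regions$start & v$pos[i] < regions$end)
    hit <- got$pos == v$pos[i] & got$chrom == v$chrom[i]
    expect_equal(sum(hit), length(inside))
  }
})

test_that("dinucleotide classification follows the CpG definition", {
  # ...A[C]G..., C>T: CpG deamination
  cl <- classify_dinucleotide("C", "T", "A", "G")
  expect_equal(cl$dinuc_class, "CG"); expect_true(cl$is_c_to_t)
  # ...C[G]T..., G>A: complement-strand deamination
  cl <- classify_dinucleotide("G", "A", "C", "T")
  expect_equal(cl$dinuc_class, "CG"); expect_true(cl$is_c_to_t)
  # ...A[C]A..., C>T: not CpG
  cl <- classify_dinucleotide("C", "T", "A", "A")
  expect_equal(cl$dinuc_class, "nonCG"); expect_false(cl$is_c_to_t)
  # missing flank at region edge
  cl <- classify_dinucleotide("C", "T", "A", NA)
  expect_equal(cl$dinuc_class, "nonCG"); expect_true(cl$flank_missing)
})

test_that("classification is strand-symmetric", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(72)
  for (i in 1:100) {
    prev <- sample(names(comp), 1); nxt <- sample(names(comp), 1)
    ref <- sample(names(comp), 1)
    alt <- sample(setdiff(names(comp), ref), 1)
    fwd <- classify_dinucleotide(ref, alt, prev, nxt)
    # reverse complement: flanks swap and complement
    rev <- classify_dinucleotide(comp[[ref]], comp[[alt]], comp[[nxt]], comp[[prev]])
    expect_equal(fwd$dinuc_class, rev$dinuc_class)
    expect_equal(fwd$is_c_to_t, rev$is_c_to_t)
  }
})

test_that("MAF binning is right-closed with the rare bin first", {
  b <- bin_by_maf(c(0.0005, 0.001, 0.0011, 0.5))
  expect_equal(unname(b), c(2L, 1L, 0L, 0L, 0L, 1L))
  expect_error(bin_by_maf(0.6), "outside")
  expect_error(bin_by_maf(0), "outside")
  # counts match direct tabulation on uniform draws
  set.seed(73)
  maf <- runif(1000, 1e-6, 0.5)
  edges <- default_maf_bins()
  got <- bin_by_maf(maf, edges)
  direct <- table(cut(maf, c(0, edges), right = TRUE))
  expect_equal(unname(got), as.integer(direct))
  expect_equal(sum(got), 1000L)
})

test_that("normalization is raw * 1000 / (n_syn * length)", {
  expect_equal(normalize_counts(2, 4, 500), 1.0)
  expect_equal(normalize_counts(c(0, 0, 0), 10, 100), c(0, 0, 0))
  expect_equal(normalize_counts(8, 5, 400), 2 * normalize_counts(8, 5, 800))
  expect_error(normalize_counts(1, 0, 100), "pseudo-count")
})

test_that("profile counts are conserved across bins and classes", {
  set.seed(74)
  regions <- toy_regions()
  v <- data.frame(chrom = "chrU", pos = c(91:108, 201:218),
                  ref = "C", alt = "T", maf = runif(36, 1e-4, 0.5))
  a <- classify_variants(assign_variants(v, regions), regions)
  p_cg <- mutation_profile(a, "target_site", "CG", 10, 1000)
  p_non <- mutation_profile(a, "target_site", "nonCG", 10, 1000)
  expect_equal(sum(p_cg$raw_counts) + sum(p_non$raw_counts), nrow(a))
  expect_equal(p_cg$normalized_counts,
               p_cg$raw_counts * 1000 / (10 * 1000))
})

test_that("identical profiles give KS statistic 0", {
  set.seed(75)
  regions <- toy_regions()
  v <- data.frame(chrom = "chrU", pos = 201:218, ref = "C", alt = "T",
                  maf = runif(18, 1e-4, 0.5))
  a <- classify_variants(assign_variants(v, regions), regions)
  p <- mutation_profile(a, "target_site", "nonCG", 10, 1000)
  cmp <- suppressWarnings(compare_profiles(p, p))  # self-comparison ties
  expect_equal(cmp$ks_statistic, 0)
})

test_that("the mid-p KS test is calibrated where the asymptotic one is not", {
  set.seed(79)
  pv <- replicate(400, ks_midp_test(sample_maf(60), sample_maf(40))$p.value)
  rate <- mean(pv < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
  # identical distributions, strong planted difference detected
  expect_lt(ks_midp_test(sample_maf(300), runif(300, 0.2, 0.5))$p.value, 1e-6)
})

test_that("planted CpG hypermutability is recovered by the rate test", {
  sites <- data.frame(region_id = sprintf("s%03d", 1:300),
                      region_class = "target_site", chrom = "chrU",
                      start = (0:299) * 20L, end = (0:299) * 20L + 8L,
                      sequence = "TCCGTCCA", stringsAsFactors = FALSE)
  loci <- gen_mirna_loci(400, rng_seed = 76)
  gv <- gen_variants(sites, loci, base_rate = 0.05, cpg_multiplier_utr = 10,
                     rng_seed = 77)
  regions <- rbind(sites, loci)
  a <- classify_variants(assign_variants(gv$variants, regions), regions)
  n_t <- sum(a$region_class == "target_site" & a$dinuc_class == "CG")
  n_m <- sum(a$region_class == "mirna" & a$dinuc_class == "CG")
  tst <- rate_ratio_test(n_t, n_m, gv$truth$cpg_exposures[["target_site"]],
                         gv$truth$cpg_exposures[["mirna"]],
                         alternative = "greater")
  expect_lt(tst$p.value, 0.01)
  # per-site rate ratio should be near the planted multiplier
  ratio <- (n_t / gv$truth$cpg_exposures[["target_site"]]) /
    (n_m / gv$truth$cpg_exposures[["mirna"]])
  expect_gt(ratio, 10 / 2)  # recovery bound: at least half the planted ratio
})

test_that("null mutation data give a calibrated rate test (light check)", {
  set.seed(78)
  pv <- replicate(200, {
    c1 <- rbinom(1, 700, 0.05); c2 <- rbinom(1, 500, 0.05)
    rate_ratio_test(c1, c2, 700, 500)$p.value
  })
  expect_gt(mean(pv < 0.05), 0.01)
  expect_lt(mean(pv < 0.05), 0.12)
})
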