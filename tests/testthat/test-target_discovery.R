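test_that("seed extraction takes mature positions 2..(1+seed_len)", {
  expect_equal(extract_seed("UGGACGGAGAACUGAUAAGGGU", 7), "GGACGGA")
  expect_equal(extract_seed("UCGUACCGUGAGUAAUAAUGCG", 7), "CGUACCG")
  expect_equal(extract_seed("ACGUACGU", 6), "CGUACG")
  expect_error(extract_seed("ACGU", 7), "short")
  expect_error(extract_seed("ACGUACGUAC", 5), "seed_len")
})

test_that("CG dimer finder enumerates every occurrence", {
  expect_equal(find_cg_dimers("CGUACCG"), c(0L, 5L))
  expect_equal(find_cg_dimers("CUCUAGC"), integer(0))
  expect_equal(find_cg_dimers("GC"), integer(0))
  expect_error(find_cg_dimers(""), "empty")
  # agreement with a naive scan on random seeds
  set.seed(41)
  for (i in 1:50) {
    s <- rand_rna(7)
    expect_equal(find_cg_dimers(s), oracle_scan_offsets("CG", chartr("U", "T", s)))
  }
})

test_that("seed-match pattern is the DNA reverse complement", {
  expect_equal(seed_match_pattern("GGACGGA"), "TCCGTCC")
  expect_equal(seed_match_pattern("CGUACCG"), "CGGTACG")
  expect_error(seed_match_pattern("GGACGGT"), "RNA")
})

test_that("seed target search equals the naive substring-scan oracle", {
  utr <- data.frame(gene_id = "g1", sequence = "AAATCCGTCCAAA")
  s <- find_seed_targets("GGACGGA", utr)
  expect_equal(nrow(s), 1L)
  expect_equal(s$utr_offset, 3L)
  expect_equal(s$site_type, "seed")

  expect_equal(nrow(find_seed_targets("GGACGGA",
                                      data.frame(gene_id = "g", sequence = "AAAA"))),
               0L)

  # overlapping occurrences are all reported
  utr2 <- data.frame(gene_id = "g2", sequence = "CGCGCGCG")
  s2 <- find_seed_targets("CGCGCG", utr2)  # pattern CGCGCG
  expect_equal(s2$utr_offset, oracle_scan_offsets("CGCGCG", utr2$sequence))
  expect_equal(nrow(s2), 2L)

  # property: random sequences, random seeds
  set.seed(42)
  for (i in 1:30) {
    seed <- rand_rna(7)
    utrs <- data.frame(gene_id = c("a", "b"),
                       sequence = c(rand_dna(300), rand_dna(300)))
    got <- find_seed_targets(seed, utrs)
    pat <- seed_match_pattern(seed)
    for (g in utrs$gene_id) {
      expect_equal(got$utr_offset[got$gene_id == g],
                   oracle_scan_offsets(pat, utrs$sequence[utrs$gene_id == g]))
    }
  }
})

test_that("N bases never match in site searches", {
  utrs <- data.frame(gene_id = "g", sequence = "AATCNGTCCTCCGTCC")
  s <- find_seed_targets("GGACGGA", utrs)
  expect_equal(s$utr_offset, 9L)  # only the N-free occurrence
})

test_that("bulge pattern enumeration inserts each base at each target CG", {
  bp <- enumerate_bulge_patterns("GGACGGA")
  expect_setequal(bp$pattern, c("TCCAGTCC", "TCCCGTCC", "TCCGGTCC", "TCCTGTCC"))
  expect_equal(unique(bp$cg_index), 2L)
  expect_equal(nrow(enumerate_bulge_patterns("AUACCUC")), 0L)

  # two CG dimers in the match pattern: deduplicated against brute force
  bp2 <- enumerate_bulge_patterns("CGUACCG")  # match CGGTACG, CG at 0 and 5
  brute <- unique(unlist(lapply(overlap_pos <- c(0L, 5L), function(k)
    paste0(substr("CGGTACG", 1, k + 1), c("A", "C", "G", "T"),
           substr("CGGTACG", k + 2, 7)))))
  expect_setequal(bp2$pattern, brute)
  expect_lte(nrow(bp2), 4L * 2L)
})

test_that("every reported site's UTR substring equals its pattern", {
  set.seed(43)
  seed <- "GGACGGA"
  utrs <- data.frame(gene_id = sprintf("g%d", 1:5),
                     sequence = vapply(1:5, function(i) rand_dna(400), ""))
  # plant one canonical and one bulge occurrence so the check always runs
  substr(utrs$sequence[1], 11, 17) <- "TCCGTCC"
  substr(utrs$sequence[2], 101, 108) <- "TCCAGTCC"
  sites <- rbind(
    find_seed_targets(seed, utrs)[, 1:8],
    find_bulge_targets(seed, utrs, enumerate_bulge_patterns(seed), "cg_bulge")[, 1:8])
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      utr_seq <- utrs$sequence[utrs$gene_id == sites$gene_id[i]]
      expect_equal(substr(utr_seq, sites$utr_offset[i] + 1,
                          sites$utr_offset[i] + sites$site_len[i]),
                   sites$pattern[i])
    }
  }
})

test_that("random-bulge controls are reproducible, legal, and uniform", {
  seed <- "GGACGGA"
  a <- generate_random_bulge_controls(seed, 200, rng_seed = 7)
  b <- generate_random_bulge_controls(seed, 200, rng_seed = 7)
  expect_identical(a, b)

  space <- control_pattern_space(seed)
  big <- generate_random_bulge_controls(seed, 10000, rng_seed = 8)
  # no inserted base between a target-side C and G of a CG dimer
  mp <- seed_match_pattern(seed)
  cg_gaps <- find_cg_dimers(chartr("T", "U", mp)) + 1L
  expect_false(any(big$insert_index %in% cg_gaps))
  # all emitted combinations lie in the legal space
  expect_true(all(big$pattern %in% space$pattern))
  # no control pattern contains the intact canonical match
  expect_false(any(grepl(mp, big$pattern, fixed = TRUE)))
  # insertion-point histogram uniform over legal points
  pts <- table(big$insert_index)
  expect_gt(stats::chisq.test(pts)$p.value, 0.01)
})

test_that("bulge target search recovers planted sites and flags seed overlap", {
  seed <- "GGACGGA"
  utrs <- data.frame(gene_id = c("g1", "g2", "g3"),
                     sequence = c("AAAATCCAGTCCAAAA",   # planted A-bulge
                                  "AAAATCCGTCCAAAAA",   # perfect site only
                                  "TTTTTTTTTTTTTTTT"))
  pats <- enumerate_bulge_patterns(seed)
  got <- find_bulge_targets(seed, utrs, pats, "cg_bulge")
  expect_equal(got$gene_id, "g1")
  expect_equal(got$bulge_base, "A")
  expect_equal(got$utr_offset, 4L)
  expect_false(got$also_seed)
})

test_that("planted site mixture is recovered exactly at cohort scale", {
  mir <- gen_mirnas(2, 2, rng_seed = 50)
  coh <- gen_utr_cohort(mir$catalog,
                        site_plan = c(seed = 30L, cg_bulge = 50L,
                                      random_bulge = 0L),
                        n_background = 20L, utr_len = 120L, n_species = 3L,
                        rng_seed = 51)
  focal <- coh$truth$focal_mirna
  utrs <- coh$utrs
  seed_sites <- find_seed_targets(focal$seed, utrs)
  bulge_sites <- find_bulge_targets(focal$seed, utrs,
                                    enumerate_bulge_patterns(focal$seed),
                                    "cg_bulge")
  truth <- coh$truth$sites
  # every planted site is found at its planted offset
  for (i in seq_len(nrow(truth))) {
    found <- if (truth$site_type[i] == "seed") seed_sites else bulge_sites
    hit <- found$gene_id == truth$gene_id[i] &
      found$utr_offset == truth$utr_offset[i]
    expect_true(any(hit))
  }
})
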