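# miR-184-like record: seed GGACGGA, match pattern TCCGTCC
mir184 <- data.frame(mirna_id = "mir-184", mature = "UGGACGGAGAACUGAUAAGGGU",
                     stringsAsFactors = FALSE)

test_that("chimera splitting assigns at the mature boundary", {
  target <- "AAATCCGTCCAAATTTGGGCCCAAA"
  read <- paste0(rna_to_dna(mir184$mature), target)
  out <- split_chimera(read, mir184)
  expect_equal(out$reason, "assigned")
  expect_equal(out$mirna_id, "mir-184")
  expect_equal(out$mirna_part, rna_to_dna(mir184$mature))
  expect_equal(out$target_part, target)
})

test_that("a single mismatch in the miRNA part is tolerated, two are not", {
  target <- strrep("A", 25)
  mat <- rna_to_dna(mir184$mature)
  one_mm <- mat; substr(one_mm, 5, 5) <- "T"
  expect_equal(split_chimera(paste0(one_mm, target), mir184)$reason, "assigned")
  two_mm <- one_mm; substr(two_mm, 9, 9) <- "C"
  expect_equal(split_chimera(paste0(two_mm, target), mir184)$reason, "no_mirna")
})

test_that("ties between equally matching catalog miRNAs are unassigned", {
  cat2 <- data.frame(mirna_id = c("a", "b"),
                     mature = c("ACGUACGUACGUACGUACGUAC",
                                "ACGUACGUACGUACGUACGUAC"))
  read <- paste0(rna_to_dna(cat2$mature[1]), strrep("T", 20))
  expect_equal(split_chimera(read, cat2)$reason, "ambiguous")
  expect_equal(split_chimera(strrep("T", 40), cat2)$reason, "no_mirna")
})

test_that("mirna-last orientation splits from the read suffix", {
  target <- "CCCTCCGTCCAAA"
  read <- paste0(target, rna_to_dna(mir184$mature))
  out <- split_chimera(read, mir184, orientation = "mirna_last")
  expect_equal(out$target_part, target)
  both <- split_chimera(read, mir184, orientation = "both")
  expect_equal(both$reason, "assigned")
})

test_that("interaction classification follows the stated precedence", {
  seed <- "GGACGGA"
  expect_equal(classify_interaction(seed, "AAATCCGTCCAAA"), "canonical_seed")
  expect_equal(classify_interaction(seed, "AAATCCAGTCCAA"), "cg_bulge")
  # canonical beats cg_bulge when both occur
  expect_equal(classify_interaction(seed, "TCCGTCCAATCCAGTCC"), "canonical_seed")
  # G:U wobble: seed G pairs target T (window TCTGTCC pairs with one G:U)
  expect_equal(classify_interaction(seed, "AAATCTGTCCAAA"), "gu_wobble")
  # one defect that is not a wobble
  expect_equal(classify_interaction(seed, "AAATACGTCCAAA"), "one_nt_mismatch")
  expect_equal(classify_interaction(seed, strrep("A", 20)), "unclassified")
  expect_equal(classify_interaction(seed, NA_character_), "unclassified")
})

test_that("non-CG insertions classify by precedence against a window oracle", {
  seed <- "GGACGGA"
  seed_chars <- strsplit(seed, "")[[1]]
  mp <- seed_match_pattern(seed)
  cg_gaps <- find_cg_dimers(chartr("T", "U", mp)) + 1L
  other <- unique(unlist(lapply(setdiff(0:7, cg_gaps), function(k)
    paste0(substr(mp, 1, k), c("A", "C", "G", "T"), substr(mp, k + 1, 7)))))
  # patterns identical to a CG-gap insertion (inserting a copy of the C or
  # G next to the dimer) belong to the cg_bulge class and are excluded
  cg_set <- enumerate_bulge_patterns(seed)$pattern
  other <- setdiff(other, cg_set)
  window_oracle <- function(tp) {
    n <- nchar(tp)
    saw_gu <- FALSE; saw_mm <- FALSE
    for (s in 1:(n - 6)) {
      wr <- rev(strsplit(chartr("T", "U", substr(tp, s, s + 6)), "")[[1]])
      stat <- vapply(1:7, function(i) {
        p <- paste0(seed_chars[i], wr[i])
        if (p %in% c("AU", "UA", "CG", "GC")) "wc"
        else if (p %in% c("GU", "UG")) "gu" else "bad"
      }, "")
      if (all(stat != "bad") && any(stat == "gu")) saw_gu <- TRUE
      if (sum(stat == "bad") == 1) saw_mm <- TRUE
    }
    if (saw_gu) "gu_wobble" else if (saw_mm) "one_nt_mismatch" else "other_bulge"
  }
  for (p in other) {
    tp <- paste0("AAAA", p, "AAAA")  # A-flanks cannot complete a seed match
    if (grepl(mp, tp, fixed = TRUE)) next  # degenerate: still canonical
    expect_equal(classify_interaction(seed, tp), window_oracle(tp), info = p)
  }
})

test_that("wobble/mismatch windows agree with a brute-force pairing check", {
  seed <- "GGACGGA"
  seed_chars <- strsplit(seed, "")[[1]]
  brute_class <- function(w) {
    wr <- rev(strsplit(chartr("T", "U", w), "")[[1]])
    stat <- vapply(1:7, function(i) {
      p <- paste0(seed_chars[i], wr[i])
      if (p %in% c("AU", "UA", "CG", "GC")) "wc"
      else if (p %in% c("GU", "UG")) "gu" else "bad"
    }, "")
    if (all(stat != "bad") && any(stat == "gu")) "gu"
    else if (sum(stat == "bad") == 1) "mm" else "other"
  }
  set.seed(101)
  for (i in 1:300) {
    w <- rand_dna(7)
    got <- classify_interaction(seed, w)  # exactly one 7-mer window
    expected <- switch(brute_class(w),
                       gu = "gu_wobble", mm = "one_nt_mismatch", NULL)
    if (w == "TCCGTCC") expected <- "canonical_seed"
    if (!is.null(expected)) expect_equal(got, expected, info = w)
    else expect_true(got %in% c("unclassified", "other_bulge"), info = w)
  }
})

test_that("classification is total: every read gets exactly one class", {
  set.seed(102)
  classes <- c("canonical_seed", "cg_bulge", "gu_wobble", "one_nt_mismatch",
               "other_bulge", "unclassified")
  for (i in 1:200) {
    got <- classify_interaction("GGACGGA", rand_dna(sample(7:30, 1)))
    expect_length(got, 1L)
    expect_true(got %in% classes)
  }
})

test_that("shuffling preserves both multisets and is reproducible", {
  mir <- gen_mirnas(4, 0, rng_seed = 103)
  ch <- gen_chimeras(mir, n_reads = 60, rng_seed = 104)
  real <- classify_reads(ch$reads, mir$catalog)
  s1 <- shuffle_pairs(real, 11)
  s2 <- shuffle_pairs(real, 11)
  expect_identical(s1, s2)
  expect_equal(sort(s1$target_part), sort(real$target_part))
  expect_equal(s1$mirna_id, real$mirna_id)
  expect_error(shuffle_pairs(real[1, ], 1), "at least 2")
})

test_that("scrambling preserves per-read length and composition", {
  mir <- gen_mirnas(4, 0, rng_seed = 105)
  ch <- gen_chimeras(mir, n_reads = 40, rng_seed = 106)
  real <- classify_reads(ch$reads, mir$catalog)
  sc1 <- scramble_reads(real, 12)
  sc2 <- scramble_reads(real, 12)
  expect_identical(sc1, sc2)
  for (i in seq_len(nrow(real))) {
    expect_equal(sort(strsplit(sc1$target_part[i], "")[[1]]),
                 sort(strsplit(real$target_part[i], "")[[1]]))
  }
})

test_that("planted chimera mixtures are recovered and enriched over nulls", {
  mir <- gen_mirnas(6, 10, rng_seed = 107)
  ch <- gen_chimeras(mir, class_mixture = c(canonical_seed = 0.3,
                                            cg_bulge = 0.5, other = 0.2),
                     n_reads = 300, rng_seed = 108)
  real <- classify_reads(ch$reads, mir$catalog)
  # closed loop: classifier recovers the planted class of every read
  expect_equal(real$interaction_class,
               ch$truth$reads$class[match(real$read_id, ch$truth$reads$read_id)])
  shuf <- reclassify_reads(shuffle_pairs(real, 13), mir$catalog)
  scram <- reclassify_reads(scramble_reads(real, 14), mir$catalog)
  enr <- enrichment_report(real, shuf, scram)
  expect_equal(unname(enr$proportions["canonical_seed", "real"]), 0.3,
               tolerance = 0.01)
  expect_equal(unname(enr$proportions["cg_bulge", "real"]), 0.5,
               tolerance = 0.01)
  expect_true(all(enr$fold_enrichment["cg_bulge", ] > 1))
  expect_true(all(enr$cg_bulge_tests < 0.01))
  # shuffled cg_bulge proportion collapses towards background
  expect_lt(enr$proportions["cg_bulge", "shuffled"], 0.2)
})

test_that("identical real and null sets give unit fold enrichment", {
  mir <- gen_mirnas(3, 0, rng_seed = 109)
  ch <- gen_chimeras(mir, n_reads = 30, rng_seed = 110)
  real <- classify_reads(ch$reads, mir$catalog)
  enr <- enrichment_report(real, real, real)
  present <- enr$counts[, "real"] > 0
  expect_true(all(enr$fold_enrichment[present, ] == 1))
  expect_true(all(enr$cg_bulge_tests == 1))
})

test_that("planted non-canonical to canonical ratio is recovered", {
  # plant the headline ratio ~1.7 (non-canonical 63%, canonical 37%)
  mir <- gen_mirnas(5, 0, rng_seed = 111)
  ch <- gen_chimeras(mir, class_mixture = c(canonical_seed = 0.37,
                                            cg_bulge = 0.33, other = 0.30),
                     n_reads = 300, rng_seed = 112)
  real <- classify_reads(ch$reads, mir$catalog)
  shuf <- reclassify_reads(shuffle_pairs(real, 15), mir$catalog)
  scram <- reclassify_reads(scramble_reads(real, 16), mir$catalog)
  enr <- enrichment_report(real, shuf, scram)
  planted_ratio <- 0.63 / 0.37
  se <- 3 * sqrt(0.37 * 0.63 / 300) / 0.37^2  # delta-method scale for p/(1-p)
  expect_lt(abs(enr$noncanonical_canonical_ratio - planted_ratio), se)
})

test_that("mixture validation and tiny inputs behave", {
  mir <- gen_mirnas(2, 0, rng_seed = 113)
  expect_error(gen_chimeras(mir, c(canonical_seed = 0.5, cg_bulge = 0.3)),
               "sum to 1")
  one <- gen_chimeras(mir, c(cg_bulge = 1), n_reads = 1, rng_seed = 114)
  real <- classify_reads(one$reads, mir$catalog)
  expect_equal(real$interaction_class, "cg_bulge")
})
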