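# A small fully-aligned fixture: one 20-nt UTR on chrU starting at 100,
# one block covering it, with controllable per-species texts.
fix_utr <- function(seq = "AAAATCCGTCCAAAAAAAAA", strand = "+") {
  data.frame(gene_id = "g1", transcript_id = "g1", sequence = seq,
             chrom = "chrU", start = 100L, end = 100L + nchar(seq),
             strand = strand, stringsAsFactors = FALSE)
}
fix_site <- function(offset = 4L, len = 7L, pattern = "TCCGTCC",
                     type = "seed") {
  data.frame(gene_id = "g1", utr_offset = offset, site_len = len,
             site_type = type, pattern = pattern, source_seed = "GGACGGA",
             stringsAsFactors = FALSE)
}

test_that("projection returns per-species gap-stripped subsequences", {
  utr <- fix_utr()
  blocks <- list(toy_block(c(utr$sequence,
                             "AAAATCCGTCCAAAAAAAAA",
                             "AAAATCAGTCCAAAAAAAAA"), 100L))
  proj <- project_site(fix_site(), utr, blocks)
  expect_equal(proj$species, c("hg", "sp1", "sp2"))
  expect_equal(proj$seq[proj$species == "hg"], "TCCGTCC")
  expect_equal(proj$seq[proj$species == "sp1"], "TCCGTCC")
  expect_equal(proj$seq[proj$species == "sp2"], "TCAGTCC")
  expect_false(any(proj$missing))
})

test_that("a species row entirely gapped under the site is missing", {
  utr <- fix_utr()
  blocks <- list(toy_block(c(utr$sequence,
                             paste0("AAAA", strrep("-", 7), "AAAAAAAAA")),
                           100L))
  proj <- project_site(fix_site(), utr, blocks)
  expect_true(proj$missing[proj$species == "sp1"])
  res <- site_conservation_rate(fix_site(), proj, "exact")
  expect_equal(res$n_species_total, 1L)  # only the reference remains
  expect_equal(res$n_species_conserved, 1L)
})

test_that("sites spanning two contiguous blocks are stitched", {
  utr <- fix_utr()
  blocks <- list(toy_block(c("AAAATCC", "AAAATCC"), 100L),
                 toy_block(c("GTCCAAAAAAAAA", "GTCCAAAAAAAAA"), 107L))
  proj <- project_site(fix_site(), utr, blocks)
  expect_equal(proj$seq[proj$species == "hg"], "TCCGTCC")
  expect_equal(proj$seq[proj$species == "sp1"], "TCCGTCC")
})

test_that("sites spanning a break between blocks are unprojectable", {
  utr <- fix_utr()
  blocks <- list(toy_block(c("AAAATCC", "AAAATCC"), 100L),
                 toy_block(c("TCCAAAAAAAAA", "TCCAAAAAAAAA"), 108L))
  expect_null(project_site(fix_site(), utr, blocks))
})

test_that("conservation rate is invariant to gap-only column insertion", {
  utr <- fix_utr()
  plain <- list(toy_block(c(utr$sequence,
                            "AAAATCCGTCCAAAAAAAAA",
                            "AAAATCAGTCCAAAAAAAAA"), 100L))
  padded <- list(toy_block(c("AAAAT-CCGTCCAAAAAAAAA",
                             "AAAAT-CCGTCCAAAAAAAAA",
                             "AAAAT-CAGTCCAAAAAAAAA"), 100L))
  r1 <- site_conservation_rate(fix_site(), project_site(fix_site(), utr, plain),
                               "exact")
  r2 <- site_conservation_rate(fix_site(), project_site(fix_site(), utr, padded),
                               "exact")
  expect_equal(r1$n_species_conserved, r2$n_species_conserved)
  expect_equal(r1$n_species_conserved, 2L)
})

test_that("pattern-mode intactness tolerates a different bulge base", {
  utr <- fix_utr("AAAATCCAGTCCAAAAAAAA")
  site <- fix_site(4L, 8L, "TCCAGTCC", "cg_bulge")
  blocks <- list(toy_block(c(utr$sequence,
                             "AAAATCCTGTCCAAAAAAAA",   # bulge base differs
                             "AAAATCCGTCCAAAAAAAAA"),  # no bulge at all
                           100L))
  proj <- project_site(site, utr, blocks)
  pset <- enumerate_bulge_patterns("GGACGGA")$pattern
  res <- site_conservation_rate(site, proj, "pattern", pset)
  expect_equal(res$n_species_conserved, 2L)  # hg + the T-bulge species
  exact <- site_conservation_rate(site, proj, "exact")
  expect_equal(exact$n_species_conserved, 1L)
})

test_that("a hand-built 23-species alignment scores the expected rate", {
  utr <- fix_utr()
  intact <- "AAAATCCGTCCAAAAAAAAA"
  broken <- "AAAATCAGTCCAAAAAAAAA"
  texts <- c(intact, rep(intact, 4), rep(broken, 18))  # hg + 4 intact + 18 broken
  blocks <- list(toy_block(texts, 100L))
  proj <- project_site(fix_site(), utr, blocks)
  res <- site_conservation_rate(fix_site(), proj, "exact")
  expect_equal(res$n_species_total, 23L)
  expect_equal(res$n_species_conserved, 5L)
  # saturation and floor
  all_same <- list(toy_block(rep(intact, 23), 100L))
  expect_equal(site_conservation_rate(
    fix_site(), project_site(fix_site(), utr, all_same), "exact")$n_species_conserved,
    23L)
  none <- list(toy_block(c(intact, rep(broken, 22)), 100L))
  expect_equal(site_conservation_rate(
    fix_site(), project_site(fix_site(), utr, none), "exact")$n_species_conserved,
    1L)
})

test_that("minus-strand sites are projected in UTR orientation", {
  # UTR on the minus strand: genome holds the reverse complement
  genome_seq <- "AAAAAAAAAGGACGGATTTT"  # revcomp contains TCCGTCC at offset 4
  utr <- fix_utr(revcomp_dna(genome_seq), strand = "-")
  blocks <- list(toy_block(c(genome_seq, genome_seq), 100L))
  site <- fix_site(4L, 7L, "TCCGTCC")
  proj <- project_site(site, utr, blocks)
  expect_equal(proj$seq[proj$species == "hg"], "TCCGTCC")
  expect_equal(site_conservation_rate(site, proj, "exact")$n_species_conserved, 2L)
})

test_that("histogram counts are conserved and split by class", {
  rates <- data.frame(site_type = c("seed", "seed", "cg_bulge"),
                      rate = c(7L, 7L, 3L))
  h <- conservation_histogram(rates, n_species = 10L)
  expect_equal(sum(h$count), nrow(rates))
  expect_equal(h$count[h$site_type == "seed" & h$rate == 7], 2L)
  expect_equal(nrow(conservation_histogram(rates[0, ])), 0L)
  # binomial expectation at planted retention
  set.seed(61)
  r <- sample_conservation_rates(400L, 23L, 0.6)
  h2 <- conservation_histogram(data.frame(site_type = "seed", rate = r))
  expect_equal(sum(h2$count), 400L)
  mu <- 1 + 22 * 0.6
  se <- sqrt(22 * 0.6 * 0.4 / 400)
  expect_lt(abs(mean(r) - mu), 3 * se)
})

test_that("class comparison detects planted retention differences", {
  set.seed(62)
  bulge <- sample_conservation_rates(200L, 23L, 0.8)
  ctrl <- sample_conservation_rates(200L, 23L, 0.3)
  seed <- sample_conservation_rates(200L, 23L, 0.8)
  cmp <- compare_site_classes(seed, bulge, ctrl)
  t_bc <- cmp$tests[cmp$tests$group_a == "cg_bulge" &
                      cmp$tests$group_b == "random_bulge", ]
  expect_lt(t_bc$p_value, 0.01)
  expect_equal(t_bc$higher, "cg_bulge")
  w <- capture_warnings(cmp0 <- compare_site_classes(seed, bulge, integer(0)))
  expect_true(all(grepl("fewer than 3", w)))  # one per pair touching the group
  expect_true(all(is.na(
    cmp0$tests$p_value[cmp0$tests$group_a == "random_bulge" |
                         cmp0$tests$group_b == "random_bulge"])))
})

test_that("score_conservation drops unprojectable sites and logs them", {
  utr <- fix_utr()
  # block covers only part of the UTR; site extends past it
  blocks <- list(toy_block(c("AAAATCC", "AAAATCC"), 100L))
  sites <- fix_site()
  scored <- suppressMessages(score_conservation(sites, utr, blocks))
  expect_equal(nrow(scored), 0L)
  expect_equal(attr(scored, "n_unprojectable"), 1L)
})
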