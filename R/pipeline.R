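#' Per-miRNA seed and bulge target summary
#'
#' Runs the canonical seed search for every catalog miRNA and the CG-bulge
#' search for the CG-seed miRNAs, and summarises target-gene counts.
#'
#' @param catalog data.frame with columns `mirna_id`, `mature` (RNA).
#' @param utrs data.frame with columns `gene_id`, `sequence`.
#' @param seed_len seed length.
#' @return list with `summary` (data.frame `mirna_id`, `seed`, `has_cg`,
#'   `n_target_genes`, `n_bulge_genes`, `n_seed_sites`, `n_bulge_sites`)
#'   and `sites` (combined site table with a `mirna_id` column).
#' @export
run_targets <- function(catalog, utrs, seed_len = 7L) {
  rows <- vector("list", nrow(catalog))
  site_tabs <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    rec <- mirna_record(catalog$mirna_id[i], catalog$mature[i], seed_len)
    seed_sites <- find_seed_targets(rec$seed, utrs)
    bulge_sites <- if (rec$has_cg) {
      find_bulge_targets(rec$seed, utrs, enumerate_bulge_patterns(rec$seed),
                         "cg_bulge")
    } else {
      seed_sites[0, ]
    }
    rows[[i]] <- data.frame(
      mirna_id = rec$mirna_id, seed = rec$seed, has_cg = rec$has_cg,
      n_target_genes = count_target_genes(seed_sites),
      n_bulge_genes = count_target_genes(bulge_sites),
      n_seed_sites = nrow(seed_sites), n_bulge_sites = nrow(bulge_sites),
      stringsAsFactors = FALSE)
    combined <- rbind(seed_sites,
                      if (nrow(bulge_sites)) bulge_sites[, names(seed_sites)])
    if (nrow(combined)) combined$mirna_id <- rec$mirna_id
    site_tabs[[i]] <- combined
  }
  list(summary = do.call(rbind, rows),
       sites = do.call(rbind, site_tabs[vapply(site_tabs, nrow, 0L) > 0]))
}

#' Group statistics for a conservative-target count table
#'
#' Classifies each row's seed by CG-dimer content and reports the
#' conservative/total target ratio per row (rounded to 4 decimals, the
#' printed-table display convention) and the group means of the
#' conservative-target counts, both exact and integer-truncated (the
#' display convention for the printed means).
#'
#' @param tbl data.frame with columns `seed`, `conservative_n`, `total_n`
#'   (e.g. the shipped `vert_mirna_targetscan_counts.tsv` fixture).
#' @return list with `per_row` (tbl plus `has_cg`, `ratio` columns),
#'   `n_cg`, `n_total`, `mean_cg`, `mean_noncg` (exact), `mean_cg_trunc`,
#'   `mean_noncg_trunc`.
#' @export
conserved_target_stats <- function(tbl) {
  stopifnot(all(c("seed", "conservative_n", "total_n") %in% names(tbl)))
  has_cg <- vapply(tbl$seed, function(s) length(find_cg_dimers(s)) > 0L, TRUE,
                   USE.NAMES = FALSE)
  ratio <- ifelse(tbl$total_n > 0, round(tbl$conservative_n / tbl$total_n, 4),
                  NA_real_)
  per_row <- cbind(tbl, has_cg = has_cg, ratio = ratio)
  mean_cg <- mean(tbl$conservative_n[has_cg])
  mean_noncg <- mean(tbl$conservative_n[!has_cg])
  list(per_row = per_row, n_cg = sum(has_cg), n_total = nrow(tbl),
       mean_cg = mean_cg, mean_noncg = mean_noncg,
       mean_cg_trunc = trunc(mean_cg), mean_noncg_trunc = trunc(mean_noncg))
}

# Greedy selection of non-overlapping sites (per chromosome), for building
# variant-assignment regions from a site table that may contain
# overlapping occurrences.
nonoverlapping_sites <- function(sites, utrs) {
  gstart <- utrs$start[match(sites$gene_id, utrs$gene_id)] + sites$utr_offset
  ord <- order(sites$gene_id, gstart)
  keep <- logical(nrow(sites))
  last_end <- -1L; last_gene <- ""
  for (i in ord) {
    if (sites$gene_id[i] != last_gene || gstart[i] >= last_end) {
      keep[i] <- TRUE
      last_gene <- sites$gene_id[i]
      last_end <- gstart[i] + sites$site_len[i]
    }
  }
  out <- sites[keep, , drop = FALSE]
  out$gstart <- gstart[keep]
  out
}

#' Default synthetic-study parameters
#'
#' The study conditions the end-to-end synthetic reproduction runs under:
#' 200 planted sites per class over 23 species with retention 0.7 (seed and
#' CG-bulge) versus 0.3 (random-bulge control); a 10x CpG mutation-rate
#' multiplier in binding sites against a 400-locus miRNA complement;
#' planted Spearman correlations -0.6 (seed) and -0.35 (bulge) over 12
#' samples and 100 genes per group; a -0.4 logFC over-expression shift
#' (+0.4 for knock-down) on 150 targets against 1000 background genes; and
#' a 30/50/20 canonical/CG-bulge/other chimera mixture over 300 reads.
#'
#' @return named list of parameters accepted by [reproduce_synthetic()].
#' @export
default_synthetic_params <- function() {
  list(n_cg = 8L, n_noncg = 52L,
       site_plan = c(seed = 200L, cg_bulge = 200L, random_bulge = 200L),
       n_background_genes = 100L, utr_len = 500L, n_species = 23L,
       retention = c(seed = 0.7, cg_bulge = 0.7, random_bulge = 0.3),
       divergence = 0.1,
       base_rate = 0.05, cpg_multiplier_utr = 10, n_mirna_loci = 400L,
       n_samples = 12L, n_per_group = 100L, n_background_expr = 1000L,
       rho_seed = -0.6, rho_bulge = -0.35,
       shift = 0.4, n_transfection_targets = 150L,
       n_background_fc = 1000L, fc_sd = 0.5,
       chimera_mixture = c(canonical_seed = 0.3, cg_bulge = 0.5, other = 0.2),
       n_reads = 300L, n_mfe_per_class = 100L,
       n_null_draws = 1000L, alpha = 0.01)
}

#' Run the full synthetic-study reproduction
#'
#' Generates every input with planted ground truth, round-trips the data
#' through the on-disk formats (FASTA/BED/MAF/VCF/TSV), runs each analysis
#' stage, and checks that every planted ordering is recovered:
#' conservation (seed and CG-bulge above the random-bulge control), CpG
#' mutability (binding-site CpG above miRNA CpG), expression correlation
#' (seed below bulge below background), transfection shifts (down after
#' over-expression, up after knock-down), and CLASH CG-bulge enrichment
#' over shuffle and scramble nulls with mixture recovery. The duplex-MFE
#' class comparison is computed and reported but not gated (the simplified
#' energy model is not expected to separate bulge classes reliably).
#'
#' @param rng_seed integer master seed; all randomness derives from it.
#' @param params parameter list, see [default_synthetic_params()];
#'   entries given here override the defaults.
#' @param dir directory for the on-disk round-trip and the JSON report
#'   (a temporary directory by default).
#' @return list of class `synthetic_report` with `checks` (data.frame:
#'   `check`, `value`, `p_value`, `pass`), `pass` (all gated checks), and
#'   per-stage details.
#' @export
reproduce_synthetic <- function(rng_seed = 1L, params = list(),
                                dir = tempfile("seedbulge_run")) {
  p <- utils::modifyList(default_synthetic_params(), params)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed0 <- as.integer(rng_seed) %% 100000000L
  alpha <- p$alpha

  ## ---- generate + round-trip the miRNA catalog
  mir <- gen_mirnas(p$n_cg, p$n_noncg, rng_seed = seed0 + 1L)
  mirna_fa <- file.path(dir, "mirnas.fa")
  write_fasta(stats::setNames(mir$catalog$mature, mir$catalog$mirna_id),
              mirna_fa)
  fa <- read_fasta(mirna_fa)
  catalog <- data.frame(mirna_id = fa$id, mature = fa$sequence,
                        stringsAsFactors = FALSE)
  catalog$seed <- vapply(catalog$mature, extract_seed, "", USE.NAMES = FALSE)
  catalog$has_cg <- vapply(catalog$seed,
                           function(s) length(find_cg_dimers(s)) > 0L, TRUE,
                           USE.NAMES = FALSE)
  focal <- catalog[catalog$has_cg, ][1, ]

  ## ---- UTR cohort with planted sites, through FASTA/BED/MAF
  ctrl_pats <- generate_random_bulge_controls(
    focal$seed, p$site_plan[["random_bulge"]], rng_seed = seed0 + 2L)
  cohort <- gen_utr_cohort(catalog, site_plan = p$site_plan,
                           n_background = p$n_background_genes,
                           utr_len = p$utr_len, n_species = p$n_species,
                           retention = p$retention, divergence = p$divergence,
                           control_patterns = ctrl_pats,
                           rng_seed = seed0 + 3L)
  write_fasta(stats::setNames(cohort$utrs$sequence, cohort$utrs$gene_id),
              file.path(dir, "utrs.fa"))
  write_regions(cohort$utrs, file.path(dir, "utrs.bed"))
  write_maf(cohort$blocks, file.path(dir, "alignment.maf"))
  utrs <- read_utrs(file.path(dir, "utrs.fa"), file.path(dir, "utrs.bed"))
  blocks <- read_maf(file.path(dir, "alignment.maf"), ref_species = "hg")

  ## ---- discovery + conservation
  sites_seed <- find_seed_targets(focal$seed, utrs)
  sites_bulge <- find_bulge_targets(focal$seed, utrs,
                                    enumerate_bulge_patterns(focal$seed),
                                    "cg_bulge")
  uniq_ctrl <- ctrl_pats[!duplicated(ctrl_pats$pattern), ]
  sites_ctrl <- find_bulge_targets(focal$seed, utrs, uniq_ctrl, "random_bulge")
  common <- intersect(names(sites_seed), names(sites_bulge))
  sites <- rbind(sites_seed[, common], sites_bulge[, common],
                 sites_ctrl[, common])
  scored <- score_conservation(sites, utrs, blocks, ref_species = "hg")
  rates <- data.frame(site_type = scored$site_type, rate = scored$rate)
  cons_cmp <- compare_site_classes(
    scored$rate[scored$site_type == "seed"],
    scored$rate[scored$site_type == "cg_bulge"],
    scored$rate[scored$site_type == "random_bulge"])
  tst <- cons_cmp$tests
  p_seed_ctrl <- tst$p_value[tst$group_a == "seed" & tst$group_b == "random_bulge"]
  p_bulge_ctrl <- tst$p_value[tst$group_a == "cg_bulge" & tst$group_b == "random_bulge"]
  chk_cons_seed <- p_seed_ctrl < alpha &&
    cons_cmp$medians[["seed"]] > cons_cmp$medians[["random_bulge"]]
  chk_cons_bulge <- p_bulge_ctrl < alpha &&
    cons_cmp$medians[["cg_bulge"]] > cons_cmp$medians[["random_bulge"]]

  ## ---- CpG mutation rates, through VCF
  site_regions <- nonoverlapping_sites(scored, utrs)
  site_regions <- data.frame(
    region_id = sprintf("site%04d", seq_len(nrow(site_regions))),
    region_class = "target_site", chrom = "chrU",
    start = site_regions$gstart,
    end = site_regions$gstart + site_regions$site_len,
    sequence = site_regions$pattern, stringsAsFactors = FALSE)
  loci <- gen_mirna_loci(p$n_mirna_loci, rng_seed = seed0 + 4L)
  gv <- gen_variants(site_regions, loci, base_rate = p$base_rate,
                     cpg_multiplier_utr = p$cpg_multiplier_utr,
                     rng_seed = seed0 + 5L)
  write_vcf_snvs(gv$variants, file.path(dir, "variants.vcf"))
  variants <- read_vcf_snvs(file.path(dir, "variants.vcf"))
  regions <- rbind(site_regions, loci)
  assigned <- classify_variants(assign_variants(variants, regions), regions)
  norm <- gv$normalizers
  prof <- function(rc, dc) {
    i <- match(rc, norm$region_class)
    mutation_profile(assigned, rc, dc, norm$n_synonymous[i],
                     norm$gene_length[i])
  }
  prof_t_cg <- prof("target_site", "CG")
  prof_m_cg <- prof("mirna", "CG")
  rate_test <- rate_ratio_test(
    sum(prof_t_cg$raw_counts), sum(prof_m_cg$raw_counts),
    gv$truth$cpg_exposures[["target_site"]],
    gv$truth$cpg_exposures[["mirna"]], alternative = "greater")
  chk_mut <- rate_test$p.value < alpha &&
    sum(prof_t_cg$normalized_counts) > sum(prof_m_cg$normalized_counts)
  ks_cmp <- compare_profiles(prof_t_cg, prof_m_cg)

  ## ---- expression correlation
  ex <- gen_expression(p$n_samples, p$n_per_group, p$n_background_expr,
                       p$rho_seed, p$rho_bulge, rng_seed = seed0 + 6L)
  rho_seed_grp <- spearman_profile(ex$mirna,
                                   ex$genes[ex$truth$seed_targets, ])
  rho_bulge_grp <- spearman_profile(ex$mirna,
                                    ex$genes[ex$truth$bulge_targets, ])
  null <- random_gene_null(p$n_per_group, ex$genes, ex$mirna,
                           n_draws = p$n_null_draws, rng_seed = seed0 + 7L,
                           exclude = c(ex$truth$seed_targets,
                                       ex$truth$bulge_targets))
  cmp_seed <- compare_rho_groups(rho_seed_grp, null$rhos)
  cmp_bulge <- compare_rho_groups(rho_bulge_grp, null$rhos)
  chk_expr <- cmp_seed$p_value < alpha && cmp_bulge$p_value < alpha &&
    cmp_seed$direction == "more_negative" &&
    cmp_bulge$direction == "more_negative" &&
    cmp_seed$median_target < cmp_bulge$median_target &&
    cmp_bulge$median_target < cmp_bulge$median_null

  ## ---- transfection shifts
  tf_over <- gen_transfection(p$n_transfection_targets,
                              p$n_transfection_targets, p$n_background_fc,
                              -p$shift, -p$shift, p$fc_sd,
                              rng_seed = seed0 + 8L)
  over_seed <- transfection_shift_test(tf_over$fold_changes,
                                       tf_over$truth$seed_targets,
                                       tf_over$truth$background, "down")
  over_bulge <- transfection_shift_test(tf_over$fold_changes,
                                        tf_over$truth$bulge_targets,
                                        tf_over$truth$background, "down")
  tf_kd <- gen_transfection(p$n_transfection_targets,
                            p$n_transfection_targets, p$n_background_fc,
                            p$shift, p$shift, p$fc_sd,
                            rng_seed = seed0 + 9L)
  kd_bulge <- transfection_shift_test(tf_kd$fold_changes,
                                      tf_kd$truth$bulge_targets,
                                      tf_kd$truth$background, "up")
  chk_tf <- over_seed$p_value < alpha && over_bulge$p_value < alpha &&
    kd_bulge$p_value < alpha && over_bulge$median_shift < 0 &&
    kd_bulge$median_shift > 0

  ## ---- duplex MFE (reported, not gated)
  nnp <- load_nn_params()
  mfe_by_class <- lapply(c(seed = "seed", cg_bulge = "cg_bulge",
                           random_bulge = "random_bulge"), function(cl) {
    sub <- scored[scored$site_type == cl, , drop = FALSE]
    if (nrow(sub) > p$n_mfe_per_class) {
      sub <- sub[seq_len(p$n_mfe_per_class), , drop = FALSE]
    }
    vapply(seq_len(nrow(sub)), function(i) {
      utr_seq <- utrs$sequence[match(sub$gene_id[i], utrs$gene_id)]
      site_duplex_mfe(focal$mature, utr_seq, sub$utr_offset[i],
                      sub$site_len[i], params = nnp)$mfe
    }, 0)
  })
  mfe_cmp <- compare_mfe_classes(mfe_by_class$seed, mfe_by_class$cg_bulge,
                                 mfe_by_class$random_bulge)

  ## ---- CLASH chimeras, through TSV
  ch <- gen_chimeras(catalog, p$chimera_mixture, p$n_reads,
                     rng_seed = seed0 + 10L)
  write_tsv_table(ch$reads, file.path(dir, "chimeras.tsv"))
  reads <- read_tsv_table(file.path(dir, "chimeras.tsv"))
  real <- classify_reads(reads, catalog)
  shuf <- reclassify_reads(shuffle_pairs(real, seed0 + 11L), catalog)
  scram <- reclassify_reads(scramble_reads(real, seed0 + 12L), catalog)
  enr <- enrichment_report(real, shuf, scram)
  planted <- ch$truth$mixture
  n_r <- p$n_reads
  mix_ok <- all(vapply(c("canonical_seed", "cg_bulge"), function(cl) {
    pe <- planted[[cl]]
    abs(enr$proportions[cl, "real"] - pe) <= 3 * sqrt(pe * (1 - pe) / n_r)
  }, TRUE))
  chk_clash <- all(enr$cg_bulge_tests < alpha) &&
    all(enr$fold_enrichment["cg_bulge", ] > 1) && mix_ok

  checks <- data.frame(
    check = c("conservation_seed_gt_control", "conservation_bulge_gt_control",
              "cpg_rate_site_gt_mirna", "expression_ordering",
              "transfection_directions", "clash_cg_bulge_enrichment"),
    value = c(cons_cmp$medians[["seed"]] - cons_cmp$medians[["random_bulge"]],
              cons_cmp$medians[["cg_bulge"]] - cons_cmp$medians[["random_bulge"]],
              unname((sum(prof_t_cg$raw_counts) / gv$truth$cpg_exposures[["target_site"]]) /
                       max(sum(prof_m_cg$raw_counts) /
                             gv$truth$cpg_exposures[["mirna"]], 1e-12)),
              cmp_bulge$median_target - cmp_bulge$median_null,
              over_bulge$median_shift,
              unname(enr$fold_enrichment["cg_bulge", "shuffled"])),
    p_value = c(p_seed_ctrl, p_bulge_ctrl, rate_test$p.value,
                cmp_bulge$p_value, over_bulge$p_value,
                max(enr$cg_bulge_tests)),
    pass = c(chk_cons_seed, chk_cons_bulge, chk_mut, chk_expr, chk_tf,
             chk_clash),
    stringsAsFactors = FALSE)

  report <- list(
    checks = checks, pass = all(checks$pass), rng_seed = rng_seed,
    params = p, dir = dir,
    conservation = list(comparison = cons_cmp,
                        histogram = conservation_histogram(
                          rates, n_species = p$n_species),
                        n_sites = nrow(scored)),
    mutation = list(rate_test_p = rate_test$p.value,
                    ks = ks_cmp,
                    load = c(target_cg = sum(prof_t_cg$normalized_counts),
                             mirna_cg = sum(prof_m_cg$normalized_counts)),
                    counts = c(target_cg = sum(prof_t_cg$raw_counts),
                               mirna_cg = sum(prof_m_cg$raw_counts)),
                    exposures = gv$truth$cpg_exposures),
    expression = list(seed = cmp_seed, bulge = cmp_bulge),
    transfection = list(over_seed = over_seed, over_bulge = over_bulge,
                        kd_bulge = kd_bulge),
    mfe = mfe_cmp,
    clash = enr)
  class(report) <- "synthetic_report"
  jsonlite::write_json(
    list(rng_seed = rng_seed, checks = checks, pass = report$pass),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = 10)
  report
}

#' @export
print.synthetic_report <- function(x, ...) {
  cat("Synthetic-study reproduction (seed ", x$rng_seed, ")\n\n", sep = "")
  df <- x$checks
  df$value <- signif(df$value, 4)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  cat("\nOverall:", if (x$pass) "all planted orderings recovered"
      else "RECOVERY FAILED", "\n")
  invisible(x)
}

#' Null-calibration of the pipeline's tests
#'
#' Re-runs each test's statistical core under its null (equal retention,
#' CpG multiplier 1, zero correlation and shift, identical chimera class
#' rates) `n_reps` times and reports the rejection rate at level `alpha`.
#' Sizes mirror the default study conditions.
#'
#' @param n_reps replicates per test (default 1000).
#' @param alpha nominal level (default 0.05).
#' @param rng_seed integer seed.
#' @return data.frame with columns `test`, `rejection_rate`, `n_reps`.
#' @export
calibrate_null_rejection <- function(n_reps = 1000L, alpha = 0.05,
                                     rng_seed = 1L) {
  set.seed(rng_seed)
  p <- default_synthetic_params()
  rej <- list(
    conservation_wilcoxon = function() {
      x <- sample_conservation_rates(200L, p$n_species, 0.5)
      y <- sample_conservation_rates(200L, p$n_species, 0.5)
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    },
    expression_wilcoxon = function() {
      z <- stats::rnorm(p$n_samples)
      gm <- matrix(stats::rnorm(300L * p$n_samples), 300L)
      colnames(gm) <- names(z) <- sprintf("s%02d", seq_len(p$n_samples))
      rho <- spearman_profile(z, gm)
      stats::wilcox.test(rho[1:100], rho[101:300], exact = FALSE)$p.value
    },
    transfection_wilcoxon = function() {
      fc <- stats::setNames(stats::rnorm(1150L, 0, p$fc_sd),
                            sprintf("g%04d", 1:1150))
      transfection_shift_test(fc, names(fc)[1:150], names(fc)[151:1150],
                              "down")$p_value
    },
    mutation_rate_binomial = function() {
      e1 <- 700L; e2 <- 500L
      c1 <- stats::rbinom(1L, e1, p$base_rate)
      c2 <- stats::rbinom(1L, e2, p$base_rate)
      if (c1 + c2 == 0L) return(1)
      rate_ratio_test(c1, c2, e1, e2)$p.value
    },
    mutation_ks = function() {
      ks_midp_test(sample_maf(400L), sample_maf(400L))$p.value
    },
    clash_two_proportion = function() {
      n <- p$n_reads
      c1 <- stats::rbinom(1L, n, 0.3)
      c2 <- stats::rbinom(1L, n, 0.3)
      suppressWarnings(stats::prop.test(c(c1, c2), c(n, n),
                                        correct = FALSE))$p.value
    })
  out <- lapply(names(rej), function(nm) {
    pv <- vapply(seq_len(n_reps), function(i) rej[[nm]](), 0)
    data.frame(test = nm, rejection_rate = mean(pv < alpha),
               n_reps = n_reps, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
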