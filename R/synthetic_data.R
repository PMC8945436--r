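#' Generate a synthetic miRNA catalog
#'
#' Mature sequences are random 22-mers; the CG group is constrained to
#' carry at least one CG dimer in its seed, the other group to carry none.
#' All miRNAs are labelled vertebrate-conserved in the tier table.
#'
#' @param n_cg,n_noncg group sizes (default 8 and 52, the composition of a
#'   vertebrate-conserved catalog).
#' @param rng_seed integer seed; identical seeds give identical catalogs.
#' @param mature_len mature length (default 22).
#' @param seed_len seed length.
#' @return list with `catalog` (data.frame `mirna_id`, `mature`, `seed`,
#'   `has_cg`) and `tiers` (data.frame `mirna_id`, `tier`).
#' @export
gen_mirnas <- function(n_cg = 8L, n_noncg = 52L, rng_seed = 1L,
                       mature_len = 22L, seed_len = 7L) {
  if (n_cg < 0L || n_noncg < 0L) stop("group sizes must be >= 0")
  set.seed(rng_seed)
  rna <- c("A", "C", "G", "U")
  one_seed <- function(want_cg) {
    repeat {
      s <- paste(sample(rna, seed_len, replace = TRUE), collapse = "")
      has <- grepl("CG", s, fixed = TRUE)
      if (want_cg && !has) {
        p <- sample.int(seed_len - 1L, 1L)
        substr(s, p, p + 1L) <- "CG"
        has <- TRUE
      }
      if (has == want_cg) return(s)
    }
  }
  n <- n_cg + n_noncg
  want <- rep(c(TRUE, FALSE), c(n_cg, n_noncg))
  mature <- character(n)
  for (i in seq_len(n)) {
    s <- one_seed(want[i])
    rest <- paste(sample(rna, mature_len - seed_len - 1L, replace = TRUE),
                  collapse = "")
    mature[i] <- paste0(sample(rna, 1L), s, rest)
  }
  ids <- sprintf("syn-mir-%03d", seq_len(n))
  catalog <- data.frame(mirna_id = ids, mature = mature,
                        seed = vapply(mature, extract_seed, "",
                                      seed_len = seed_len, USE.NAMES = FALSE),
                        has_cg = want, stringsAsFactors = FALSE)
  list(catalog = catalog,
       tiers = data.frame(mirna_id = ids, tier = "vertebrate",
                          stringsAsFactors = FALSE))
}

# Point-mutate one character of s at index i (0-based within s) to a
# different base.
mutate_base <- function(s, i, alphabet = c("A", "C", "G", "T")) {
  old <- substr(s, i + 1L, i + 1L)
  substr(s, i + 1L, i + 1L) <- sample(setdiff(alphabet, old), 1L)
  s
}

#' Generate a UTR cohort with planted sites and a species alignment
#'
#' Builds random-background UTRs, plants seed / CG-bulge / random-bulge
#' control sites of one focal CG miRNA, and emits an ungapped
#' `n_species`-way alignment in which each non-reference species retains
#' each planted site independently with its class's retention probability;
#' a non-retained site gets one point mutation at a non-bulge position (so
#' it breaks under both exact and pattern intactness). Background
#' positions diverge independently at rate `divergence` per species.
#'
#' @param mirnas catalog from [gen_mirnas()] (needs at least one CG miRNA),
#'   or a single miRNA record.
#' @param site_plan named counts of planted sites per class
#'   (`seed`, `cg_bulge`, `random_bulge`).
#' @param n_background genes without planted sites.
#' @param utr_len UTR length (nt).
#' @param n_species species in the alignment (reference included).
#' @param retention named per-class per-species retention probabilities.
#' @param divergence background per-position substitution probability.
#' @param background `"uniform"` or `"cpg_depleted"` (CpG observed/expected
#'   about 0.25, as in mammalian UTRs).
#' @param control_patterns optional data.frame from
#'   [generate_random_bulge_controls()]; generated internally by default.
#' @param rng_seed integer seed.
#' @return list with `utrs` (UTR table with coordinates), `blocks` (MAF
#'   blocks), `truth` (list: `sites` data.frame with planted positions and
#'   patterns, `focal_mirna`, `control_patterns`, `retained` matrix,
#'   `params`).
#' @export
gen_utr_cohort <- function(mirnas,
                           site_plan = c(seed = 200L, cg_bulge = 200L,
                                         random_bulge = 200L),
                           n_background = 100L, utr_len = 500L,
                           n_species = 23L,
                           retention = c(seed = 0.7, cg_bulge = 0.7,
                                         random_bulge = 0.3),
                           divergence = 0.1,
                           background = c("uniform", "cpg_depleted"),
                           control_patterns = NULL, rng_seed = 1L) {
  background <- match.arg(background)
  catalog <- if (is.data.frame(mirnas)) mirnas else mirnas$catalog
  focal <- catalog[catalog$has_cg, , drop = FALSE][1, ]
  if (is.na(focal$mirna_id)) stop("catalog has no CG miRNA")
  seed <- focal$seed
  if (is.null(control_patterns)) {
    control_patterns <- generate_random_bulge_controls(
      seed, max(site_plan[["random_bulge"]], 1L), rng_seed + 7919L)
  }
  cg_patterns <- enumerate_bulge_patterns(seed)
  seed_pattern <- seed_match_pattern(seed)
  # never plant a CG-bulge pattern that still contains the intact canonical
  # match (possible when the bulge base copies a neighbour); such a site
  # would be a canonical site and cross-contaminate the classes
  keep <- !vapply(cg_patterns$pattern, grepl, TRUE, pattern = seed_pattern,
                  fixed = TRUE, USE.NAMES = FALSE)
  cg_patterns <- cg_patterns[keep, , drop = FALSE]
  if (nrow(cg_patterns) == 0L) stop("no plantable CG-bulge pattern for seed ", seed)
  # pattern-mode accept set per class: a broken site must leave this set,
  # otherwise a single substitution can turn one legal pattern into another
  accept_set <- list(seed = seed_pattern,
                     cg_bulge = enumerate_bulge_patterns(seed)$pattern,
                     random_bulge = unique(control_pattern_space(seed)$pattern))

  set.seed(rng_seed)
  dna <- c("A", "C", "G", "T")
  bg_seq <- function(n) {
    s <- paste(sample(dna, n, replace = TRUE), collapse = "")
    if (background == "cpg_depleted") {
      # thin CG dinucleotides to ~1/4 of their random expectation
      repeat {
        cg <- overlap_match_offsets("CG", s)
        kill <- cg[stats::runif(length(cg)) < 0.75]
        if (length(kill) == 0L) break
        for (k in kill) s <- mutate_base(s, k + 1L, setdiff(dna, "G"))
      }
    }
    s
  }

  types <- rep(names(site_plan), site_plan)
  n_sites <- length(types)
  n_genes <- n_sites + n_background
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  gap <- 100L
  utr_start <- (seq_len(n_genes) - 1L) * (utr_len + gap)

  seqs <- character(n_genes)
  site_rows <- vector("list", n_sites)
  for (g in seq_len(n_genes)) {
    s <- bg_seq(utr_len)
    if (g <= n_sites) {
      type <- types[g]
      if (type == "seed") {
        pattern <- seed_pattern
        bulge_at <- NA_integer_
      } else if (type == "cg_bulge") {
        row <- sample.int(nrow(cg_patterns), 1L)
        pattern <- cg_patterns$pattern[row]
        bulge_at <- cg_patterns$cg_index[row] + 1L
      } else {
        row <- sample.int(nrow(control_patterns), 1L)
        pattern <- control_patterns$pattern[row]
        bulge_at <- control_patterns$insert_index[row]
      }
      off <- sample.int(utr_len - nchar(pattern) + 1L, 1L) - 1L
      substr(s, off + 1L, off + nchar(pattern)) <- pattern
      site_rows[[g]] <- data.frame(
        gene_id = gene_ids[g], site_type = type, utr_offset = off,
        site_len = nchar(pattern), pattern = pattern,
        bulge_index = bulge_at,  # 0-based index of the inserted base
        source_seed = seed, stringsAsFactors = FALSE)
    }
    seqs[g] <- s
  }
  truth_sites <- do.call(rbind, site_rows)

  species <- c("hg", sprintf("sp%02d", seq_len(n_species - 1L)))
  retained <- matrix(NA, n_sites, n_species - 1L,
                     dimnames = list(truth_sites$gene_id, species[-1]))
  blocks <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    ref_chars <- strsplit(seqs[g], "")[[1]]
    texts <- character(n_species)
    texts[1] <- seqs[g]
    site <- if (g <= n_sites) truth_sites[g, ] else NULL
    for (sp in seq_len(n_species - 1L)) {
      ch <- ref_chars
      mut <- which(stats::runif(utr_len) < divergence)
      if (length(mut)) {  # substitute to a different base, uniformly
        ch[mut] <- dna[((match(ch[mut], dna) - 1L +
                           sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L]
      }
      if (!is.null(site)) {
        span <- site$utr_offset + seq_len(site$site_len)
        keep <- stats::rbinom(1L, 1L, retention[[site$site_type]]) == 1L
        retained[g, sp] <- keep
        ch[span] <- ref_chars[span]  # restore, then break if not retained
        if (!keep) {
          core <- seq_len(site$site_len) - 1L
          if (!is.na(site$bulge_index)) core <- setdiff(core, site$bulge_index)
          acc <- accept_set[[site$site_type]]
          repeat {  # the broken site must leave its class's accept set
            k <- sample(core, 1L)
            pos <- site$utr_offset + k + 1L
            new_base <- sample(setdiff(dna, ref_chars[pos]), 1L)
            mutated <- ch[span]
            mutated[k + 1L] <- new_base
            if (!paste(mutated, collapse = "") %in% acc) {
              ch[pos] <- new_base
              break
            }
          }
        }
      }
      texts[sp + 1L] <- paste(ch, collapse = "")
    }
    blocks[[g]] <- list(species = species, chrom = rep("chrU", n_species),
                        start = rep(utr_start[g], n_species),
                        size = rep(utr_len, n_species),
                        strand = rep("+", n_species),
                        src_size = rep(n_genes * (utr_len + gap), n_species),
                        text = texts, width = utr_len, ref_species = "hg")
  }

  utrs <- data.frame(gene_id = gene_ids, transcript_id = gene_ids,
                     sequence = seqs, chrom = "chrU", start = utr_start,
                     end = utr_start + utr_len, strand = "+",
                     stringsAsFactors = FALSE)
  list(utrs = utrs, blocks = blocks,
       truth = list(sites = truth_sites, focal_mirna = focal,
                    control_patterns = control_patterns,
                    retained = retained,
                    params = list(site_plan = site_plan,
                                  retention = retention,
                                  n_species = n_species,
                                  divergence = divergence,
                                  utr_len = utr_len, rng_seed = rng_seed)))
}

#' Draw planted conservation rates directly
#'
#' The statistical core of the cohort generator: a site's conservation
#' rate is 1 (the reference) plus a Binomial(`n_species` - 1, `retention`)
#' count of retaining species. Used for fast calibration runs.
#'
#' @param n number of sites.
#' @param n_species species in the alignment.
#' @param retention per-species retention probability.
#' @return integer vector of conservation rates in `1..n_species`.
#' @export
sample_conservation_rates <- function(n, n_species, retention) {
  1L + stats::rbinom(n, n_species - 1L, retention)
}

#' Generate synthetic miRNA genomic loci
#'
#' Random 22-nt loci on their own chromosome, emulating the genome-wide
#' miRNA complement for mutation-rate exposure.
#'
#' @param n number of loci.
#' @param len locus length.
#' @param rng_seed integer seed.
#' @param chrom chromosome name.
#' @return region data.frame (`region_id`, `region_class = "mirna"`,
#'   `chrom`, `start`, `end`, `sequence`).
#' @export
gen_mirna_loci <- function(n = 400L, len = 22L, rng_seed = 1L,
                           chrom = "chrM") {
  set.seed(rng_seed)
  gap <- 50L
  start <- (seq_len(n) - 1L) * (len + gap)
  data.frame(region_id = sprintf("mirloc%03d", seq_len(n)),
             region_class = "mirna", chrom = chrom,
             start = start, end = start + len,
             sequence = vapply(seq_len(n), function(i) random_seq(len), ""),
             stringsAsFactors = FALSE)
}

#' Draw minor allele frequencies from the synthetic MAF law
#'
#' A rare-variant-dominated mixture: with probability `p_rare` the MAF is
#' uniform on (1e-5, 0.001], otherwise uniform on (0.001, 0.5].
#'
#' @param n number of draws.
#' @param p_rare rare-variant weight (default 0.9).
#' @return numeric vector in (0, 0.5].
#' @export
sample_maf <- function(n, p_rare = 0.9) {
  rare <- stats::runif(n) < p_rare
  ifelse(rare, stats::runif(n, 1e-5, 1e-3), stats::runif(n, 1e-3, 0.5))
}

#' Generate population variants with elevated UTR CpG mutability
#'
#' CpG positions in `target_site` regions mutate by deamination (C>T, G>A)
#' at `base_rate * cpg_multiplier_utr`; CpG positions in miRNA loci at
#' `base_rate`; non-CpG positions at `base_rate` everywhere (to a random
#' other base). MAFs follow [sample_maf()].
#'
#' @param site_regions region data.frame (class `target_site`, with
#'   `sequence`).
#' @param mirna_loci region data.frame from [gen_mirna_loci()].
#' @param base_rate per-position mutation probability.
#' @param cpg_multiplier_utr CpG rate multiplier in target regions (>= 1).
#' @param p_rare rare-variant weight of the MAF law.
#' @param n_synonymous,gene_length normalizers reported for the nearby
#'   gene (identical for both classes by default, so normalization is
#'   neutral to the comparison).
#' @param rng_seed integer seed.
#' @return list with `variants` (VCF-ready data.frame), `normalizers`
#'   (data.frame `region_class`, `n_synonymous`, `gene_length`), `truth`
#'   (parameters + per-class CpG exposures).
#' @export
gen_variants <- function(site_regions, mirna_loci, base_rate = 0.05,
                         cpg_multiplier_utr = 10, p_rare = 0.9,
                         n_synonymous = 100L, gene_length = 2000L,
                         rng_seed = 1L) {
  if (cpg_multiplier_utr < 1) stop("cpg_multiplier_utr must be >= 1")
  set.seed(rng_seed)
  regions <- rbind(site_regions[, c("region_id", "region_class", "chrom",
                                    "start", "end", "sequence")],
                   mirna_loci[, c("region_id", "region_class", "chrom",
                                  "start", "end", "sequence")])
  dna <- c("A", "C", "G", "T")
  rows <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    s <- strsplit(regions$sequence[r], "")[[1]]
    cg_off <- overlap_match_offsets("CG", regions$sequence[r])
    cpg_pos <- sort(unique(c(cg_off, cg_off + 1L)))  # 0-based C and G
    all_pos <- seq_along(s) - 1L
    noncpg_pos <- setdiff(all_pos, cpg_pos)
    rate_cpg <- base_rate *
      if (regions$region_class[r] == "target_site") cpg_multiplier_utr else 1
    hit_cpg <- cpg_pos[stats::runif(length(cpg_pos)) < rate_cpg]
    hit_non <- noncpg_pos[stats::runif(length(noncpg_pos)) < base_rate]
    ref_cpg <- s[hit_cpg + 1L]
    alt_cpg <- ifelse(ref_cpg == "C", "T", "A")  # deamination on either strand
    ref_non <- s[hit_non + 1L]
    alt_non <- vapply(ref_non, function(b) sample(setdiff(dna, b), 1L), "")
    pos <- c(hit_cpg, hit_non)
    if (length(pos) == 0L) next
    rows[[r]] <- data.frame(chrom = regions$chrom[r],
                            pos = regions$start[r] + pos,
                            ref = c(ref_cpg, ref_non),
                            alt = c(alt_cpg, alt_non),
                            stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  if (is.null(variants)) {
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           maf = numeric())
  } else {
    variants$maf <- sample_maf(nrow(variants), p_rare)
    variants <- variants[order(variants$chrom, variants$pos), ]
    rownames(variants) <- NULL
  }
  exposures <- c(
    target_site = count_cpg_positions(site_regions$sequence),
    mirna = count_cpg_positions(mirna_loci$sequence))
  list(variants = variants,
       normalizers = data.frame(
         region_class = c("target_site", "mirna"),
         n_synonymous = n_synonymous, gene_length = gene_length,
         stringsAsFactors = FALSE),
       truth = list(base_rate = base_rate,
                    cpg_multiplier_utr = cpg_multiplier_utr,
                    p_rare = p_rare, cpg_exposures = exposures,
                    rng_seed = rng_seed))
}

#' Generate miRNA and gene expression with planted rank correlations
#'
#' The miRNA vector is standard normal over samples; each target gene is
#' coupled to it through a Gaussian copula with Pearson parameter
#' `2 sin(pi * rho / 6)`, which targets Spearman correlation `rho`;
#' background genes are independent noise.
#'
#' @param n_samples samples (default 12).
#' @param n_per_group genes per target group.
#' @param n_background independent background genes.
#' @param rho_seed,rho_bulge target Spearman correlations (typically
#'   `-1 <= rho_seed <= rho_bulge <= 0` is violated; the seed group is the
#'   more negative one).
#' @param noise sd of additional independent noise added after coupling
#'   (attenuates the realised correlation; default 0).
#' @param rng_seed integer seed.
#' @return list with `mirna` (named numeric vector), `genes` (matrix,
#'   rownames = gene ids, colnames = sample ids), `truth` (gene ids per
#'   group and the planted parameters).
#' @export
gen_expression <- function(n_samples = 12L, n_per_group = 100L,
                           n_background = 1000L, rho_seed = -0.6,
                           rho_bulge = -0.35, noise = 0, rng_seed = 1L) {
  if (n_samples < 4L) stop("need at least 4 samples")
  set.seed(rng_seed)
  samples <- sprintf("s%02d", seq_len(n_samples))
  z <- stats::rnorm(n_samples)
  couple <- function(n, rho) {
    r <- 2 * sin(pi * rho / 6)
    g <- r * matrix(z, n, n_samples, byrow = TRUE) +
      sqrt(max(0, 1 - r^2)) * matrix(stats::rnorm(n * n_samples), n, n_samples)
    if (noise > 0) g <- g + noise * matrix(stats::rnorm(n * n_samples), n, n_samples)
    g
  }
  genes <- rbind(couple(n_per_group, rho_seed),
                 couple(n_per_group, rho_bulge),
                 matrix(stats::rnorm(n_background * n_samples),
                        n_background, n_samples))
  ids <- c(sprintf("seedtg%04d", seq_len(n_per_group)),
           sprintf("bulgetg%04d", seq_len(n_per_group)),
           sprintf("bg%04d", seq_len(n_background)))
  dimnames(genes) <- list(ids, samples)
  list(mirna = stats::setNames(z, samples), genes = genes,
       truth = list(seed_targets = ids[seq_len(n_per_group)],
                    bulge_targets = ids[n_per_group + seq_len(n_per_group)],
                    background = ids[-(seq_len(2L * n_per_group))],
                    rho_seed = rho_seed, rho_bulge = rho_bulge,
                    noise = noise, rng_seed = rng_seed))
}

#' Generate transfection fold changes with planted shifts
#'
#' Background genes draw logFC from `N(0, sd)`; target groups from
#' `N(shift, sd)`. Negative shifts emulate repression after
#' over-expression; positive shifts de-repression after knock-down.
#'
#' @param n_seed,n_bulge,n_background group sizes.
#' @param shift_seed,shift_bulge planted log-fold-change shifts.
#' @param sd logFC noise sd.
#' @param rng_seed integer seed.
#' @return list with `fold_changes` (named numeric), `truth` (gene sets and
#'   parameters).
#' @export
gen_transfection <- function(n_seed = 150L, n_bulge = 150L,
                             n_background = 1000L, shift_seed = -0.4,
                             shift_bulge = -0.4, sd = 0.5, rng_seed = 1L) {
  set.seed(rng_seed)
  ids <- c(sprintf("seedtg%04d", seq_len(n_seed)),
           sprintf("bulgetg%04d", seq_len(n_bulge)),
           sprintf("bg%04d", seq_len(n_background)))
  fc <- c(stats::rnorm(n_seed, shift_seed, sd),
          stats::rnorm(n_bulge, shift_bulge, sd),
          stats::rnorm(n_background, 0, sd))
  list(fold_changes = stats::setNames(fc, ids),
       truth = list(seed_targets = ids[seq_len(n_seed)],
                    bulge_targets = ids[n_seed + seq_len(n_bulge)],
                    background = ids[-(seq_len(n_seed + n_bulge))],
                    shift_seed = shift_seed, shift_bulge = shift_bulge,
                    sd = sd, rng_seed = rng_seed))
}

#' Generate synthetic CLASH chimeric reads
#'
#' Each read is a catalog mature sequence (as DNA) followed by a target
#' part constructed to satisfy exactly its assigned interaction class
#' ([classify_interaction()] is the constructive oracle: candidates are
#' redrawn until they classify as intended). Mixture proportions are
#' honoured exactly up to rounding. The alias class `"other"` splits
#' evenly over G:U wobble, one-nt mismatch and non-CG bulge.
#'
#' @param mirnas catalog from [gen_mirnas()]; CG miRNAs are used (the
#'   CG-bulge class requires one).
#' @param class_mixture named proportions over interaction classes
#'   (must sum to 1).
#' @param n_reads number of reads.
#' @param target_len target-part length.
#' @param seed_len seed length.
#' @param rng_seed integer seed.
#' @return list with `reads` (data.frame `read_id`, `sequence`), `truth`
#'   (data.frame `read_id`, `mirna_id`, `class`; plus the mixture).
#' @export
gen_chimeras <- function(mirnas,
                         class_mixture = c(canonical_seed = 0.3,
                                           cg_bulge = 0.5, other = 0.2),
                         n_reads = 300L, target_len = 30L, seed_len = 7L,
                         rng_seed = 1L) {
  if (abs(sum(class_mixture) - 1) > 1e-8) {
    stop("class_mixture must sum to 1")
  }
  mix <- class_mixture
  if ("other" %in% names(mix)) {
    w <- mix[["other"]] / 3
    mix <- mix[names(mix) != "other"]
    for (cl in c("gu_wobble", "one_nt_mismatch", "other_bulge")) {
      mix[cl] <- if (is.na(mix[cl])) w else mix[[cl]] + w
    }
  }
  allowed <- c("canonical_seed", "cg_bulge", "gu_wobble", "one_nt_mismatch",
               "other_bulge")
  if (!all(names(mix) %in% allowed)) {
    stop("unknown class in mixture: ",
         paste(setdiff(names(mix), allowed), collapse = ", "))
  }
  counts <- round(mix * n_reads)
  while (sum(counts) != n_reads) {  # fix rounding drift on the largest class
    counts[which.max(counts)] <- counts[which.max(counts)] +
      sign(n_reads - sum(counts))
  }
  catalog <- if (is.data.frame(mirnas)) mirnas else mirnas$catalog
  cg_cat <- catalog[catalog$has_cg, , drop = FALSE]
  if (nrow(cg_cat) == 0L) stop("catalog has no CG miRNA")
  set.seed(rng_seed)
  dna <- c("A", "C", "G", "T")

  make_core <- function(seed, class) {
    pat <- seed_match_pattern(seed)
    L <- nchar(pat)
    sets <- bulge_pattern_sets(seed)
    switch(class,
      canonical_seed = pat,
      cg_bulge = sample(sets$cg, 1L),
      other_bulge = sample(sets$other, 1L),
      gu_wobble = {
        seed_chars <- strsplit(seed, "")[[1]]
        eligible <- which(seed_chars %in% c("G", "U"))
        i <- eligible[sample.int(length(eligible), 1L)]
        j <- L - i + 1L
        substr(pat, j, j) <- if (seed_chars[i] == "G") "T" else "G"
        pat
      },
      one_nt_mismatch = {
        repeat {
          p <- pat
          j <- sample.int(L, 1L)
          substr(p, j, j) <- sample(setdiff(dna, substr(pat, j, j)), 1L)
          sc <- strsplit(seed, "")[[1]]
          d <- window_defects(sc, strsplit(p, "")[[1]])
          if (d$n_bad == 1L) return(p)
        }
      })
  }

  classes <- rep(names(counts), counts)
  classes <- sample(classes)  # interleave
  rows <- vector("list", n_reads)
  truth <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    repeat {
      k <- sample.int(nrow(cg_cat), 1L)
      seed <- cg_cat$seed[k]
      core <- make_core(seed, classes[i])
      n_flank <- target_len - nchar(core)
      lf <- sample.int(n_flank + 1L, 1L) - 1L
      tp <- paste0(random_seq(lf), core, random_seq(n_flank - lf))
      if (classify_interaction(seed, tp) == classes[i]) break
    }
    rows[[i]] <- data.frame(read_id = sprintf("read%04d", i),
                            sequence = paste0(rna_to_dna(cg_cat$mature[k]), tp),
                            stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(read_id = sprintf("read%04d", i),
                             mirna_id = cg_cat$mirna_id[k],
                             class = classes[i], stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, rows),
       truth = list(reads = do.call(rbind, truth), mixture = mix,
                    rng_seed = rng_seed))
}
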