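#' Assign variants to regions
#'
#' Each variant is labelled with at most one region per region class
#' (regions within a class must not overlap); variants outside all regions
#' are dropped. Intervals are 0-based half-open, so a variant at
#' `pos == end` is outside.
#'
#' @param variants data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `maf`.
#' @param regions data.frame with columns `region_id`, `region_class`
#'   (`"mirna"` or `"target_site"`), `chrom`, `start`, `end`, plus
#'   optionally `sequence` (region sequence on the + strand, used for
#'   dinucleotide context).
#' @return data.frame of assigned variants with `region_id`, `region_class`
#'   and `region_offset` columns appended (one row per variant-class
#'   assignment).
#' @export
assign_variants <- function(variants, regions) {
  empty <- cbind(variants[0, , drop = FALSE],
                 region_id = character(), region_class = character(),
                 region_offset = integer())
  if (nrow(variants) == 0L || nrow(regions) == 0L) return(empty)
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos + 1L, width = 1L))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(vgr, rgr)
  if (length(hits) == 0L) return(empty)
  vi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  key <- paste(vi, regions$region_class[ri])
  if (anyDuplicated(key)) {
    stop("overlapping regions within one region class")
  }
  out <- cbind(variants[vi, , drop = FALSE],
               region_id = regions$region_id[ri],
               region_class = regions$region_class[ri],
               region_offset = variants$pos[vi] - regions$start[ri])
  rownames(out) <- NULL
  out
}

#' Classify a variant's dinucleotide context
#'
#' CG class iff the reference base participates in a CpG: a reference `C`
#' followed by `G`, or a reference `G` preceded by `C` (the CpG is
#' strand-symmetric, so both genome strands are covered by reading the +
#' strand context). `is_c_to_t` is the CpG-deamination flag: C>T on the CpG
#' strand or G>A on its complement. A missing flank (region edge) gives
#' class nonCG with `flank_missing = TRUE`.
#'
#' @param ref,alt reference and alternate single bases.
#' @param prev_base,next_base flanking bases (`NA` when unavailable).
#' @return list with `dinuc_class` (`"CG"`/`"nonCG"`), `is_c_to_t`,
#'   `flank_missing`.
#' @export
classify_dinucleotide <- function(ref, alt, prev_base, next_base) {
  flank_missing <- (ref == "C" && is.na(next_base)) ||
    (ref == "G" && is.na(prev_base))
  cg <- (ref == "C" && !is.na(next_base) && next_base == "G") ||
    (ref == "G" && !is.na(prev_base) && prev_base == "C")
  is_c_to_t <- cg && ((ref == "C" && alt == "T") || (ref == "G" && alt == "A"))
  list(dinuc_class = if (cg) "CG" else "nonCG",
       is_c_to_t = is_c_to_t,
       flank_missing = flank_missing)
}

#' Classify assigned variants using their region sequences
#'
#' Vectorised wrapper around [classify_dinucleotide()]; the flanking bases
#' come from the region sequence at `region_offset` +/- 1.
#'
#' @param assigned data.frame from [assign_variants()].
#' @param regions region table with a `sequence` column.
#' @return `assigned` with columns `dinuc_class`, `is_c_to_t`,
#'   `flank_missing` appended.
#' @export
classify_variants <- function(assigned, regions) {
  n <- nrow(assigned)
  dinuc <- character(n); ctot <- logical(n); fl <- logical(n)
  seqs <- regions$sequence[match(assigned$region_id, regions$region_id)]
  for (i in seq_len(n)) {
    off <- assigned$region_offset[i]  # 0-based within region
    s <- seqs[i]
    prev_base <- if (off >= 1L) substr(s, off, off) else NA_character_
    next_base <- if (off + 2L <= nchar(s)) substr(s, off + 2L, off + 2L)
                 else NA_character_
    cl <- classify_dinucleotide(assigned$ref[i], assigned$alt[i],
                                prev_base, next_base)
    dinuc[i] <- cl$dinuc_class; ctot[i] <- cl$is_c_to_t; fl[i] <- cl$flank_missing
  }
  assigned$dinuc_class <- dinuc
  assigned$is_c_to_t <- ctot
  assigned$flank_missing <- fl
  assigned
}

#' Default minor-allele-frequency bin edges
#'
#' Left-open right-closed bins over (0, 0.5]; the first bin is the
#' rare-variant range MAF <= 0.001.
#' @return numeric vector of upper edges.
#' @export
default_maf_bins <- function() c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5)

#' Bin variants by minor allele frequency
#'
#' @param maf numeric vector of minor allele frequencies in (0, 0.5].
#' @param bin_edges ascending upper bin edges; bins are
#'   `(0, e1], (e1, e2], ...`.
#' @return named integer vector of per-bin counts (sums to `length(maf)`).
#' @export
bin_by_maf <- function(maf, bin_edges = default_maf_bins()) {
  if (is.unsorted(bin_edges, strictly = TRUE) || bin_edges[1] <= 0) {
    stop("bin_edges must be ascending and positive")
  }
  if (any(maf <= 0 | maf > utils::tail(bin_edges, 1))) {
    stop("maf outside (0, ", utils::tail(bin_edges, 1), "]")
  }
  # right-closed bins: maf equal to an edge belongs to the bin below
  idx <- findInterval(maf, bin_edges, left.open = TRUE) + 1L
  labels <- paste0("<=", format(bin_edges, trim = TRUE, scientific = FALSE))
  counts <- tabulate(idx, nbins = length(bin_edges))
  names(counts) <- labels
  counts
}

#' Normalize per-bin mutation counts by a neutral rate
#'
#' `normalized = raw * 1000 / (n_synonymous * gene_length)`: raw counts
#' scaled by the synonymous-mutation count of the nearby gene and its
#' length, times 1000 for display. For pooled profiles `gene_length` is the
#' mean length of the pooled genes.
#'
#' @param raw_counts non-negative numeric vector.
#' @param n_synonymous synonymous-mutation count of the nearby gene(s),
#'   must be >= 1.
#' @param gene_length gene length in nt (mean for pooled profiles).
#' @return numeric vector of the same length.
#' @export
normalize_counts <- function(raw_counts, n_synonymous, gene_length) {
  if (n_synonymous < 1) {
    stop("n_synonymous must be >= 1; configure a pseudo-count for genes ",
         "with no synonymous variants")
  }
  if (gene_length < 1) stop("gene_length must be >= 1")
  raw_counts * 1000 / (n_synonymous * gene_length)
}

#' Build a MAF-binned mutation profile for one region/dinucleotide class
#'
#' @param classified data.frame from [classify_variants()].
#' @param region_class `"mirna"` or `"target_site"`.
#' @param dinuc_class `"CG"` or `"nonCG"`.
#' @param n_synonymous,gene_length normalizers (see [normalize_counts()]).
#' @param bin_edges MAF bin edges.
#' @param c_to_t_only count only CpG-deamination changes (C>T / G>A)
#'   (default FALSE).
#' @return list of class `mutation_profile` with fields `region_class`,
#'   `dinuc_class`, `bin_edges`, `raw_counts`, `normalized_counts`,
#'   `normalizer`, `maf` (the per-variant MAFs behind the counts).
#' @export
mutation_profile <- function(classified, region_class, dinuc_class,
                             n_synonymous, gene_length,
                             bin_edges = default_maf_bins(),
                             c_to_t_only = FALSE) {
  sel <- classified$region_class == region_class &
    classified$dinuc_class == dinuc_class
  if (c_to_t_only) sel <- sel & classified$is_c_to_t
  maf <- classified$maf[sel]
  raw <- bin_by_maf(maf, bin_edges)
  structure(list(region_class = region_class, dinuc_class = dinuc_class,
                 bin_edges = bin_edges, raw_counts = raw,
                 normalized_counts = normalize_counts(raw, n_synonymous, gene_length),
                 normalizer = c(n_synonymous = n_synonymous,
                                gene_length = gene_length),
                 maf = maf),
            class = "mutation_profile")
}

#' Compare two mutation profiles (KS test)
#'
#' Two-sample Kolmogorov-Smirnov test either on the per-variant MAF samples
#' behind the profiles (default; what a distribution test is meant for) or
#' on the per-bin normalized values. The direction of difference reports
#' which profile carries more normalized mutation load.
#'
#' Two-sample KS test with a mid-p exact p-value
#'
#' The two-sample KS statistic is discrete, so the exact test is
#' conservative and the asymptotic one more so at moderate sizes; the
#' mid-p convention (half weight on the observed statistic) restores the
#' nominal level. Requires untied samples; with ties the asymptotic
#' p-value is returned with a warning.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_midp_test <- function(x, y) {
  n <- length(x); m <- length(y)
  d <- unname(suppressWarnings(stats::ks.test(x, y))$statistic)
  n_tied <- n + m - length(unique(c(x, y)))
  if (n_tied > 0L) {
    if (n_tied / (n + m) > 0.001) {
      warning("ties present; returning the asymptotic KS p-value")
    }
    return(list(statistic = d,
                p.value = suppressWarnings(stats::ks.test(x, y))$p.value))
  }
  eps <- 0.5 / (n * m)  # below the 1/lcm(n, m) lattice spacing of D
  p_ge <- 1 - stats::psmirnov(d, c(n, m))
  p_eq <- stats::psmirnov(d + eps, c(n, m)) - stats::psmirnov(d, c(n, m))
  list(statistic = d, p.value = max(0, min(1, p_ge - 0.5 * p_eq)))
}

#' @param profile_a,profile_b `mutation_profile` objects on the same bins.
#' @param on `"per_variant"` or `"per_bin"`.
#' @param method `"midp"` (default; exact distribution with the mid-p
#'   convention, see [ks_midp_test()]) or `"asymptotic"`.
#' @return list with `ks_statistic`, `p_value`, `higher_load` (name of the
#'   profile with the larger total normalized count), `load` (the two
#'   totals).
#' @export
compare_profiles <- function(profile_a, profile_b,
                             on = c("per_variant", "per_bin"),
                             method = c("midp", "asymptotic")) {
  on <- match.arg(on)
  method <- match.arg(method)
  if (!identical(profile_a$bin_edges, profile_b$bin_edges)) {
    stop("profiles are on different bins")
  }
  if (length(profile_a$maf) == 0L || length(profile_b$maf) == 0L) {
    stop("empty profile")
  }
  ab <- if (on == "per_variant") {
    list(profile_a$maf, profile_b$maf)
  } else {
    list(profile_a$normalized_counts, profile_b$normalized_counts)
  }
  ks <- if (method == "midp") {
    ks_midp_test(ab[[1]], ab[[2]])
  } else {
    suppressWarnings(stats::ks.test(ab[[1]], ab[[2]]))
  }
  load <- c(a = sum(profile_a$normalized_counts),
            b = sum(profile_b$normalized_counts))
  nm <- c(paste(profile_a$region_class, profile_a$dinuc_class),
          paste(profile_b$region_class, profile_b$dinuc_class))
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       higher_load = nm[which.max(load)],
       load = stats::setNames(load, nm))
}

#' Conditional binomial rate-ratio test between two mutation counts
#'
#' Conditional binomial test: given `count_a + count_b` mutations and the
#' per-class exposures (number of mutable positions, e.g. CpG sites), tests
#' whether class a's rate exceeds what equal per-site rates would give.
#' This is the directional test behind the "binding-site CpG mutates, miRNA
#' CpG does not" comparison, where a shape-only KS test is blind to a pure
#' rate difference.
#'
#' The default is the mid-p variant (half weight on the observed count),
#' the standard remedy for the conservatism of the exact binomial test at
#' discrete counts; `method = "exact"` gives [stats::binom.test()].
#'
#' @param count_a,count_b observed mutation counts.
#' @param exposure_a,exposure_b number of mutable positions per class.
#' @param alternative `"two.sided"`, `"greater"` (a's rate higher), or
#'   `"less"`.
#' @param method `"midp"` (default) or `"exact"`.
#' @return list with `p.value`, `estimate` (observed proportion of
#'   mutations in class a), `null_value` (exposure share of class a).
#' @export
rate_ratio_test <- function(count_a, count_b, exposure_a, exposure_b,
                            alternative = c("two.sided", "greater", "less"),
                            method = c("midp", "exact")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (exposure_a <= 0 || exposure_b <= 0) stop("exposures must be positive")
  n <- count_a + count_b
  if (n == 0L) stop("no mutations to compare")
  p0 <- exposure_a / (exposure_a + exposure_b)
  if (method == "exact") {
    ht <- stats::binom.test(count_a, n, p = p0, alternative = alternative)
    return(list(p.value = ht$p.value, estimate = count_a / n,
                null_value = p0))
  }
  lo <- stats::pbinom(count_a - 1L, n, p0) + 0.5 * stats::dbinom(count_a, n, p0)
  hi <- 1 - stats::pbinom(count_a, n, p0) + 0.5 * stats::dbinom(count_a, n, p0)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(lo, hi)),
              greater = hi,
              less = lo)
  list(p.value = p, estimate = count_a / n, null_value = p0)
}

#' Count CpG positions in a set of sequences
#'
#' Each CG dinucleotide contributes two mutable positions (the C and the
#' G), which is the exposure unit used by [rate_ratio_test()].
#'
#' @param seqs character vector of DNA sequences.
#' @return integer total CpG positions.
#' @export
count_cpg_positions <- function(seqs) {
  2L * sum(vapply(seqs, function(s) length(overlap_match_offsets("CG", s)), 0L))
}
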