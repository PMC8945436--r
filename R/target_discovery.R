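#' Extract the seed of a mature miRNA
#'
#' The seed is the 5' region of the mature sequence starting at position 2:
#' positions 2-7 (`seed_len = 6`) or 2-8 (`seed_len = 7`, the default used
#' throughout, which matches 7-mer seed tables).
#'
#' @param mature mature miRNA sequence (RNA).
#' @param seed_len seed length, 6 or 7.
#' @return RNA string of length `seed_len`.
#' @export
extract_seed <- function(mature, seed_len = 7L) {
  if (!seed_len %in% c(6L, 7L)) stop("seed_len must be 6 or 7")
  if (nchar(mature) < seed_len + 1L) {
    stop("mature sequence too short for seed extraction: ", mature)
  }
  substr(mature, 2L, 1L + seed_len)
}

#' Find CG dimers in a seed
#'
#' @param seed seed sequence (RNA).
#' @return integer vector of 0-based start indices of every `CG` occurrence
#'   (empty when absent).
#' @export
find_cg_dimers <- function(seed) {
  if (nchar(seed) == 0L) stop("empty seed")
  overlap_match_offsets("CG", seed)
}

#' Build a miRNA record
#'
#' @param mirna_id miRNA identifier.
#' @param mature mature sequence (RNA).
#' @param seed_len seed length (6 or 7).
#' @param conservation_tier one of `"vertebrate"`, `"mammal"`, `"primate"`,
#'   `"none"`.
#' @return list with fields `mirna_id`, `mature`, `seed`, `cg_positions`,
#'   `has_cg`, `conservation_tier`.
#' @export
mirna_record <- function(mirna_id, mature, seed_len = 7L,
                         conservation_tier = "none") {
  conservation_tier <- match.arg(conservation_tier,
                                 c("vertebrate", "mammal", "primate", "none"))
  seed <- extract_seed(mature, seed_len)
  cg <- find_cg_dimers(seed)
  list(mirna_id = mirna_id, mature = mature, seed = seed,
       cg_positions = cg, has_cg = length(cg) > 0L,
       conservation_tier = conservation_tier)
}

#' Seed-match pattern on the target strand
#'
#' The canonical binding site on the mRNA sense strand is the reverse
#' complement of the seed, written in the DNA alphabet.
#'
#' @param seed seed sequence (RNA, A/C/G/U only).
#' @return DNA string of the same length.
#' @export
seed_match_pattern <- function(seed) {
  if (grepl("[^ACGU]", seed)) stop("seed must be RNA over ACGU: ", seed)
  revcomp_dna(rna_to_dna(seed))
}

# Scan a set of UTR sequences for fixed patterns; returns one row per
# occurrence (overlapping occurrences included; N never matches because
# patterns are N-free).
scan_patterns <- function(utrs, patterns) {
  rows <- vector("list", 0L)
  for (p in seq_len(nrow(patterns))) {
    pat <- patterns$pattern[p]
    for (g in seq_len(nrow(utrs))) {
      off <- overlap_match_offsets(pat, utrs$sequence[g])
      if (length(off)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = utrs$gene_id[g], utr_offset = off,
          site_len = nchar(pat), site_type = patterns$site_type[p],
          bulge_base = patterns$bulge_base[p],
          bulge_gap_index = patterns$bulge_gap_index[p],
          pattern = pat, source_seed = patterns$source_seed[p],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), utr_offset = integer(),
                      site_len = integer(), site_type = character(),
                      bulge_base = character(), bulge_gap_index = integer(),
                      pattern = character(), source_seed = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find canonical seed-match sites in UTRs
#'
#' Every occurrence (including overlapping ones) of the perfect seed-match
#' pattern is reported as one site.
#'
#' @param seed seed sequence (RNA).
#' @param utrs data.frame with columns `gene_id`, `sequence` (DNA).
#' @return data.frame of target sites with `site_type = "seed"`.
#' @export
find_seed_targets <- function(seed, utrs) {
  pat <- seed_match_pattern(seed)
  scan_patterns(utrs, data.frame(pattern = pat, site_type = "seed",
                                 bulge_base = "", bulge_gap_index = NA_integer_,
                                 source_seed = seed, stringsAsFactors = FALSE))
}

#' Enumerate CG-bulge site patterns for a seed
#'
#' For every CG dimer in the seed-match pattern (the target-side CG that
#' pairs the seed's C and G), four patterns are produced by inserting each
#' nucleotide between that C and G. Patterns arising identically from
#' different CG occurrences are deduplicated.
#'
#' @param seed seed sequence (RNA).
#' @return data.frame with columns `pattern`, `cg_index` (0-based index of
#'   the target-side C in the unbulged match pattern), `bulge_base`,
#'   `bulge_gap_index`, `source_seed`; zero rows when the seed has no CG.
#' @export
enumerate_bulge_patterns <- function(seed) {
  match_pat <- seed_match_pattern(seed)
  cg_idx <- overlap_match_offsets("CG", match_pat)
  empty <- data.frame(pattern = character(), cg_index = integer(),
                      bulge_base = character(), bulge_gap_index = integer(),
                      source_seed = character(), stringsAsFactors = FALSE)
  if (length(cg_idx) == 0L) return(empty)
  rows <- expand.grid(cg_index = cg_idx, bulge_base = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  rows$pattern <- vapply(seq_len(nrow(rows)), function(i) {
    k <- rows$cg_index[i]
    paste0(substr(match_pat, 1L, k + 1L), rows$bulge_base[i],
           substr(match_pat, k + 2L, nchar(match_pat)))
  }, "")
  rows$bulge_gap_index <- rows$cg_index
  rows$source_seed <- seed
  rows <- rows[!duplicated(rows$pattern), c("pattern", "cg_index", "bulge_base",
                                            "bulge_gap_index", "source_seed")]
  rownames(rows) <- NULL
  rows
}

#' The space of legal random-bulge control insertions for a seed
#'
#' All (insertion point, base) combinations that produce a genuine bulge
#' control pattern: the insertion point is interior (a bulge must
#' interrupt pairing; a base appended outside the match leaves a perfect
#' canonical site), is not the gap between a target-side CG dimer (those
#' are the CG-bulge class), and the resulting pattern does not contain the
#' intact canonical match (inserting a copy of a neighbouring base can
#' leave the 7-mer untouched, which is again a canonical site, not a
#' bulge).
#'
#' @param seed seed sequence (RNA).
#' @return data.frame with columns `insert_index` (0-based: base inserted
#'   before that index of the match pattern), `bulge_base`, `pattern`.
#' @export
control_pattern_space <- function(seed) {
  match_pat <- seed_match_pattern(seed)
  L <- nchar(match_pat)
  cg_idx <- overlap_match_offsets("CG", match_pat)
  interior <- setdiff(seq_len(L - 1L), cg_idx + 1L)
  combos <- expand.grid(insert_index = interior,
                        bulge_base = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  combos$pattern <- vapply(seq_len(nrow(combos)), function(i) {
    paste0(substr(match_pat, 1L, combos$insert_index[i]), combos$bulge_base[i],
           substr(match_pat, combos$insert_index[i] + 1L, L))
  }, "")
  keep <- !vapply(combos$pattern, grepl, TRUE, pattern = match_pat,
                  fixed = TRUE, USE.NAMES = FALSE)
  combos <- combos[keep, , drop = FALSE]
  rownames(combos) <- NULL
  combos
}

#' Generate random-bulge control patterns
#'
#' Controls insert a uniformly random base at a uniformly random legal
#' insertion point of the seed-match pattern. Legal points are interior
#' and exclude the gap between a target-side CG dimer (that is the
#' CG-bulge class); combinations whose pattern still contains the intact
#' canonical match are excluded too, since such a site is a canonical
#' site, not a bulge (see [control_pattern_space()]). The point is drawn
#' uniformly over legal points, then the base uniformly over that point's
#' legal bases.
#'
#' @param seed seed sequence (RNA).
#' @param n_patterns number of control patterns to draw.
#' @param rng_seed integer seed; identical seeds give identical patterns.
#' @param dedupe drop duplicate patterns (default FALSE).
#' @return data.frame with columns `pattern`, `insert_index` (0-based: base
#'   inserted before that index of the match pattern), `bulge_base`,
#'   `source_seed`.
#' @export
generate_random_bulge_controls <- function(seed, n_patterns, rng_seed,
                                           dedupe = FALSE) {
  if (n_patterns < 1L) stop("n_patterns must be >= 1")
  space <- control_pattern_space(seed)
  if (nrow(space) == 0L) stop("no legal insertion point for seed ", seed)
  points <- sort(unique(space$insert_index))
  set.seed(rng_seed)
  k <- points[sample.int(length(points), n_patterns, replace = TRUE)]
  rows <- vapply(k, function(kk) {
    at <- which(space$insert_index == kk)
    at[sample.int(length(at), 1L)]
  }, 0L)
  out <- data.frame(pattern = space$pattern[rows], insert_index = k,
                    bulge_base = space$bulge_base[rows],
                    source_seed = seed, stringsAsFactors = FALSE)
  if (dedupe) out <- out[!duplicated(out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find bulge (or control) sites in UTRs
#'
#' Scans UTRs for a set of length `seed_len + 1` patterns. Sites whose
#' window overlaps a canonical seed site of the same seed are kept and
#' flagged in the `also_seed` column.
#'
#' @param seed seed sequence (RNA) that generated the patterns.
#' @param utrs data.frame with columns `gene_id`, `sequence`.
#' @param patterns data.frame from [enumerate_bulge_patterns()] or
#'   [generate_random_bulge_controls()].
#' @param site_type label for the sites: `"cg_bulge"` or `"random_bulge"`.
#' @return data.frame of target sites with an `also_seed` flag.
#' @export
find_bulge_targets <- function(seed, utrs, patterns,
                               site_type = c("cg_bulge", "random_bulge")) {
  site_type <- match.arg(site_type)
  if (nrow(patterns) == 0L) {
    out <- scan_patterns(utrs, data.frame(pattern = character(),
                                          site_type = character(),
                                          bulge_base = character(),
                                          bulge_gap_index = integer(),
                                          source_seed = character()))
    out$also_seed <- logical(0)
    return(out)
  }
  spec <- data.frame(pattern = patterns$pattern, site_type = site_type,
                     bulge_base = patterns$bulge_base,
                     bulge_gap_index = if (!is.null(patterns$bulge_gap_index))
                       patterns$bulge_gap_index else patterns$insert_index,
                     source_seed = seed, stringsAsFactors = FALSE)
  sites <- scan_patterns(utrs, spec)
  seed_pat <- seed_match_pattern(seed)
  sites$also_seed <- logical(nrow(sites))
  if (nrow(sites) > 0L) {
    for (g in unique(sites$gene_id)) {
      utr_seq <- utrs$sequence[match(g, utrs$gene_id)]
      seed_off <- overlap_match_offsets(seed_pat, utr_seq)
      if (length(seed_off)) {
        i <- which(sites$gene_id == g)
        sites$also_seed[i] <- vapply(i, function(j) {
          any(seed_off < sites$utr_offset[j] + sites$site_len[j] &
                seed_off + nchar(seed_pat) > sites$utr_offset[j])
        }, TRUE)
      }
    }
  }
  sites
}

#' Count distinct target genes in a site table
#'
#' "Target number" for a miRNA is the number of distinct genes with at least
#' one site; per-occurrence counts are available directly from the table.
#'
#' @param sites data.frame of target sites.
#' @return integer number of distinct `gene_id`s.
#' @export
count_target_genes <- function(sites) length(unique(sites$gene_id))
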