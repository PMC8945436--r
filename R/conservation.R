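#' Project a target site through a multi-species alignment
#'
#' Maps a site's UTR offset to reference genome coordinates, locates the
#' alignment block(s) covering it, and returns each species' gap-stripped
#' subsequence under the reference columns spanning the site (internal
#' insertion columns included). Sites spanning a break between
#' non-contiguous blocks, or falling outside every block, are unprojectable.
#' Projections from adjacent blocks with contiguous reference coordinates
#' are stitched.
#'
#' For minus-strand UTRs the species subsequences are reverse-complemented
#' so they are comparable to the UTR-space site pattern.
#'
#' @param site one row of a target-site table (needs `utr_offset`,
#'   `site_len`).
#' @param utr one row of a UTR table (needs `chrom`, `start`, `end`,
#'   `strand`).
#' @param blocks alignment blocks from [read_maf()].
#' @param ref_species reference species name.
#' @param candidates optional indices of blocks to consider (an interval
#'   prefilter computed by the caller; all blocks by default).
#' @return data.frame with columns `species`, `seq` (gap-stripped, possibly
#'   empty = missing), `missing`; or `NULL` when the site is unprojectable.
#' @export
project_site <- function(site, utr, blocks, ref_species = "hg",
                         candidates = NULL) {
  if (!is.null(candidates)) blocks <- blocks[candidates]
  if (utr$strand == "+") {
    gstart <- utr$start + site$utr_offset
  } else {
    gstart <- utr$end - site$utr_offset - site$site_len
  }
  gend <- gstart + site$site_len

  pieces <- list()
  covered <- integer(0)  # reference positions projected so far
  for (bl in blocks) {
    r <- match(ref_species, bl$species)
    if (!identical(bl$chrom[r], utr$chrom) && !is.na(bl$chrom[r])) next
    if (bl$strand[r] != "+") next  # reference rows are expected on +
    bstart <- bl$start[r]
    bend <- bstart + bl$size[r]
    if (gend <= bstart || gstart >= bend) next
    ref_chars <- strsplit(bl$text[r], "")[[1]]
    is_base <- ref_chars != "-"
    refpos <- rep(NA_integer_, length(ref_chars))
    refpos[is_base] <- bstart + seq_len(sum(is_base)) - 1L
    in_site <- !is.na(refpos) & refpos >= gstart & refpos < gend
    if (!any(in_site)) next
    cols <- seq(min(which(in_site)), max(which(in_site)))
    sub <- vapply(bl$text, function(txt) {
      gsub("-", "", substr(txt, cols[1], cols[length(cols)]), fixed = TRUE)
    }, "")
    pieces[[length(pieces) + 1L]] <- list(
      species = bl$species, sub = unname(sub),
      lo = min(refpos[in_site]), hi = max(refpos[in_site]) + 1L)
    covered <- c(covered, refpos[in_site])
  }
  if (length(pieces) == 0L) return(NULL)
  covered <- sort(unique(covered))
  if (!identical(covered, seq(gstart, gend - 1L))) return(NULL)  # block gap

  pieces <- pieces[order(vapply(pieces, `[[`, 0L, "lo"))]
  species <- sort(unique(unlist(lapply(pieces, `[[`, "species"))))
  seqs <- setNames(rep("", length(species)), species)
  present <- setNames(rep(TRUE, length(species)), species)
  for (pc in pieces) {
    idx <- match(species, pc$species)
    present <- present & !is.na(idx)
    add <- ifelse(is.na(idx), "", pc$sub[idx])
    seqs <- paste0(seqs, add)
  }
  seqs[!present] <- ""  # species missing from any covering block
  if (utr$strand == "-") {
    nz <- nchar(seqs) > 0L & !grepl("[^ACGTN]", seqs)
    seqs[nz] <- revcomp_dna(seqs[nz])
  }
  out <- data.frame(species = species, seq = unname(seqs),
                    missing = nchar(seqs) == 0L, stringsAsFactors = FALSE)
  # reference first, for readability
  out[order(out$species != ref_species), , drop = FALSE]
}

#' Score a site's conservation across species
#'
#' A species counts as intact under mode `"exact"` iff its gap-stripped
#' homologous subsequence equals the site pattern; under mode `"pattern"`
#' iff it equals any member of `pattern_set` (e.g. all CG-bulge patterns of
#' the seed, so a site conserved with a different bulge base still counts).
#' Missing species are excluded from the denominator.
#'
#' @param site one row of a target-site table (needs `pattern`).
#' @param projections data.frame from [project_site()].
#' @param mode `"exact"` or `"pattern"`.
#' @param pattern_set character vector of acceptable patterns for mode
#'   `"pattern"`.
#' @param ref_species reference species name.
#' @return list with `n_species_total`, `n_species_conserved`, `intact`
#'   (named logical vector over non-missing species).
#' @export
site_conservation_rate <- function(site, projections,
                                   mode = c("exact", "pattern"),
                                   pattern_set = NULL, ref_species = "hg") {
  mode <- match.arg(mode)
  ok <- !projections$missing
  proj <- projections[ok, , drop = FALSE]
  accept <- switch(mode,
                   exact = site$pattern,
                   pattern = {
                     if (is.null(pattern_set)) stop("pattern_set required for mode 'pattern'")
                     pattern_set
                   })
  intact <- proj$seq %in% accept
  names(intact) <- proj$species
  if (ref_species %in% proj$species && !intact[[ref_species]]) {
    stop("reference species is not intact for its own site; ",
         "site/UTR/alignment are inconsistent")
  }
  list(n_species_total = nrow(proj),
       n_species_conserved = sum(intact),
       intact = intact)
}

#' Conservation-rate histogram per site class
#'
#' @param rates data.frame with columns `site_type`, `rate` (integer
#'   conservation rates).
#' @param site_type optional filter to a single class.
#' @param n_species histogram support is `1..n_species` (defaults to the
#'   maximum observed rate).
#' @return data.frame with columns `site_type`, `rate`, `count`.
#' @export
conservation_histogram <- function(rates, site_type = NULL, n_species = NULL) {
  if (!is.null(site_type)) rates <- rates[rates$site_type %in% site_type, ]
  if (nrow(rates) == 0L) {
    return(data.frame(site_type = character(), rate = integer(),
                      count = integer()))
  }
  if (is.null(n_species)) n_species <- max(rates$rate)
  out <- do.call(rbind, lapply(split(rates, rates$site_type), function(d) {
    counts <- tabulate(d$rate, nbins = n_species)
    data.frame(site_type = d$site_type[1], rate = seq_len(n_species),
               count = counts, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[out$count > 0L | TRUE, , drop = FALSE]
}

#' Compare conservation rates between site classes
#'
#' Pairwise two-sided Wilcoxon rank-sum tests between the seed, CG-bulge
#' and random-bulge control classes, with group medians and the direction
#' of each difference. Groups with fewer than 3 observations are skipped
#' with a warning.
#'
#' @param rates_seed,rates_bulge,rates_control numeric vectors of
#'   conservation rates.
#' @return list with `medians` and a data.frame `tests` (columns `group_a`,
#'   `group_b`, `p_value`, `higher`).
#' @export
compare_site_classes <- function(rates_seed, rates_bulge, rates_control) {
  groups <- list(seed = rates_seed, cg_bulge = rates_bulge,
                 random_bulge = rates_control)
  medians <- vapply(groups, function(g) if (length(g)) stats::median(g) else NA_real_, 0)
  combos <- utils::combn(names(groups), 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    ga <- groups[[a]]; gb <- groups[[b]]
    if (length(ga) < 3L || length(gb) < 3L) {
      warning("group '", if (length(ga) < 3L) a else b,
              "' has fewer than 3 observations; test skipped")
      return(data.frame(group_a = a, group_b = b, p_value = NA_real_,
                        higher = NA_character_, stringsAsFactors = FALSE))
    }
    p <- stats::wilcox.test(ga, gb, exact = FALSE)$p.value
    higher <- if (stats::median(ga) > stats::median(gb)) a
              else if (stats::median(ga) < stats::median(gb)) b else "tie"
    data.frame(group_a = a, group_b = b, p_value = p, higher = higher,
               stringsAsFactors = FALSE)
  })
  list(medians = medians, tests = do.call(rbind, rows))
}

#' Score every site of a site table against an alignment
#'
#' Convenience wrapper: projects each site and scores its conservation
#' rate. Default intactness mode is `"exact"` for canonical seed sites and
#' `"pattern"` for bulge/control sites (a bulge conserved with a different
#' bulge base is the same biological class). Unprojectable sites are
#' dropped; their count is attached as attribute `n_unprojectable`.
#'
#' @param sites target-site table.
#' @param utrs UTR table (coordinates required).
#' @param blocks alignment blocks from [read_maf()].
#' @param ref_species reference species name.
#' @param mode `"auto"` (per-class default), `"exact"`, or `"pattern"`.
#' @return data.frame `sites` plus columns `rate`, `n_species`.
#' @export
score_conservation <- function(sites, utrs, blocks, ref_species = "hg",
                               mode = "auto") {
  pattern_sets <- new.env(parent = emptyenv())
  get_set <- function(seed, type) {
    key <- paste(seed, type)
    if (!is.null(pattern_sets[[key]])) return(pattern_sets[[key]])
    set <- switch(type,
      cg_bulge = enumerate_bulge_patterns(seed)$pattern,
      # controls conserved with any legal control insertion count as intact
      random_bulge = unique(control_pattern_space(seed)$pattern),
      NULL)
    pattern_sets[[key]] <- set
    set
  }
  # interval prefilter: reference span of every block, computed once
  ref_idx <- vapply(blocks, function(bl) match(ref_species, bl$species), 0L)
  bchrom <- vapply(seq_along(blocks), function(b)
    blocks[[b]]$chrom[ref_idx[b]], "")
  bstart <- vapply(seq_along(blocks), function(b)
    blocks[[b]]$start[ref_idx[b]], 0L)
  bend <- bstart + vapply(seq_along(blocks), function(b)
    blocks[[b]]$size[ref_idx[b]], 0L)

  rate <- rep(NA_integer_, nrow(sites))
  n_species <- rep(NA_integer_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    utr <- utrs[match(sites$gene_id[i], utrs$gene_id), , drop = FALSE]
    gstart <- if (utr$strand == "+") utr$start + sites$utr_offset[i]
              else utr$end - sites$utr_offset[i] - sites$site_len[i]
    gend <- gstart + sites$site_len[i]
    cand <- which((bchrom == utr$chrom | is.na(bchrom)) &
                    bstart < gend & bend > gstart)
    proj <- project_site(sites[i, ], utr, blocks, ref_species,
                         candidates = cand)
    if (is.null(proj)) next
    type <- sites$site_type[i]
    use_mode <- if (mode == "auto") {
      if (type == "seed") "exact" else "pattern"
    } else mode
    pset <- if (use_mode == "pattern") {
      ps <- get_set(sites$source_seed[i], type)
      if (is.null(ps)) sites$pattern[i] else ps
    } else NULL
    res <- site_conservation_rate(sites[i, ], proj, use_mode, pset, ref_species)
    rate[i] <- res$n_species_conserved
    n_species[i] <- res$n_species_total
  }
  out <- sites
  out$rate <- rate
  out$n_species <- n_species
  n_unproj <- sum(is.na(rate))
  if (n_unproj > 0L) {
    message("score_conservation: ", n_unproj, " unprojectable site(s) dropped")
  }
  out <- out[!is.na(out$rate), , drop = FALSE]
  attr(out, "n_unprojectable") <- n_unproj
  out
}
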