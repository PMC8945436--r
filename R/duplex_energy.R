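#' Load nearest-neighbor duplex parameters
#'
#' The shipped table holds the ten canonical Watson-Crick RNA stack free
#' energies (kcal/mol, 37 degrees C, the standard nearest-neighbor set),
#' a single simplified stack value for any stack involving a G:U wobble
#' pair, and affine bulge / internal-loop penalties. Stacks are expanded by
#' duplex rotational symmetry (`E(XY/ZW) = E(WZ/YX)`), so all 36 pair-pair
#' combinations resolve. The file is a plain TSV and can be swapped for a
#' different parameter set.
#'
#' @param path parameter TSV (default: the shipped table).
#' @return list with `stacks` (named numeric, keys `"XY/ZW"`),
#'   `wobble_stack`, `bulge_open`, `bulge_ext`, `iloop_open`, `iloop_ext`.
#' @export
load_nn_params <- function(path = system.file("extdata", "nn_duplex_params.tsv",
                                              package = "seedbulge")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  is_stack <- grepl("^stack:", tab$param)
  stacks <- stats::setNames(tab$value[is_stack],
                            sub("^stack:", "", tab$param[is_stack]))
  scal <- stats::setNames(tab$value[!is_stack], tab$param[!is_stack])
  # expand rotational symmetry: 5'-XY-3'/3'-ZW-5' == 5'-WZ-3'/3'-YX-5'
  rot <- function(key) {
    ch <- strsplit(key, "")[[1]]  # X Y / Z W
    paste0(ch[5], ch[4], "/", ch[2], ch[1])
  }
  for (key in names(stacks)) {
    r <- rot(key)
    if (!r %in% names(stacks)) stacks[r] <- stacks[[key]]
  }
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  for (p1 in pairs) for (p2 in pairs) {
    key <- paste0(substr(p1, 1, 1), substr(p2, 1, 1), "/",
                  substr(p1, 2, 2), substr(p2, 2, 2))
    if (!key %in% names(stacks)) {
      stacks[key] <- scal[["wobble_stack"]]
    }
  }
  list(stacks = stacks, wobble_stack = scal[["wobble_stack"]],
       bulge_open = scal[["bulge_open"]], bulge_ext = scal[["bulge_ext"]],
       iloop_open = scal[["iloop_open"]], iloop_ext = scal[["iloop_ext"]])
}

# Is (a, b) an allowed base pair? (RNA alphabet, antiparallel strands.)
pair_ok <- function(a, b, gu_wobble = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (!gu_wobble) return(wc)
  wc | (a == "G" & b == "U") | (a == "U" & b == "G")
}

# Loop cost between consecutive pairs with a unpaired bases on strand x and
# b on strand y; a == b == 0 means a stack (costed separately).
loop_cost <- function(a, b, params) {
  if (a == 0L && b == 0L) return(0)
  if (a == 0L || b == 0L) {
    size <- max(a, b)
    params$bulge_open + params$bulge_ext * (size - 1L)
  } else {
    params$iloop_open + params$iloop_ext * (a + b - 2L)
  }
}

#' Minimum free energy of a miRNA:target duplex
#'
#' Intermolecular-only dynamic program: the miRNA (5'->3') is hybridised
#' against the target (read 3'->5'), allowing Watson-Crick and optionally
#' G:U pairs, single-strand bulges and internal loops, with no
#' intramolecular structure. Consecutive pairs gain the nearest-neighbor
#' stack energy; loops pay affine penalties. The empty pairing has energy
#' 0, so the returned MFE is never positive. Equal-energy structures are
#' resolved deterministically (fixed scan order; 5'-most, then
#' shortest-span ending pair), so repeated calls return the same pairing.
#'
#' @param mirna miRNA-side strand (RNA, 5'->3').
#' @param target target-side strand; DNA or RNA accepted (converted to
#'   RNA), given 5'->3' as it appears in the UTR.
#' @param params parameter list from [load_nn_params()].
#' @param gu_wobble allow G:U pairs (default TRUE).
#' @param max_loop largest number of unpaired bases allowed on one side of
#'   a bulge or internal loop (default 10; loops beyond this are never
#'   energetically competitive under the affine penalties for the short
#'   seed-region duplexes scored here).
#' @return list of class `duplex_result` with `mfe` (kcal/mol), `pairs`
#'   (two-column matrix of 1-based indices into `mirna` and `target`),
#'   `structure` (dot-bracket pair of strings), `n_bulges`,
#'   `bulge_positions`.
#' @export
duplex_mfe <- function(mirna, target, params = load_nn_params(),
                       gu_wobble = TRUE, max_loop = 10L) {
  if (grepl("[^ACGU]", mirna)) stop("miRNA strand must be RNA over ACGU")
  target_rna <- dna_to_rna(target)
  if (grepl("[^ACGU]", target_rna)) stop("target strand has non-ACGT/U characters")
  x <- strsplit(mirna, "")[[1]]
  yr <- rev(strsplit(target_rna, "")[[1]])  # target 3'->5'
  n <- length(x); m <- length(yr)
  can_pair <- outer(x, yr, pair_ok, gu_wobble = gu_wobble)

  # loop penalty by unpaired span (a, b); [1,1] is the stacked case
  L <- max_loop
  C <- outer(0:L, 0:L, Vectorize(function(a, b) loop_cost(a, b, params)))
  C[1, 1] <- NA  # stacked: replaced by the stack energy per cell

  E <- matrix(Inf, n, m)    # best energy of a duplex whose last pair is (i,j)
  PRE <- matrix(0L, n, m)   # predecessor encoded as (ip-1)*m + jp; 0 = none
  for (i in seq_len(n)) {
    ips <- seq.int(max(1L, i - 1L - L), i - 1L)
    for (j in seq_len(m)) {
      if (!can_pair[i, j]) next
      best <- 0; best_pre <- 0L
      if (i > 1L && j > 1L) {
        jps <- seq.int(max(1L, j - 1L - L), j - 1L)
        cand <- E[ips, jps, drop = FALSE] +
          C[i - ips + 0L, j - jps + 0L, drop = FALSE]
        if (can_pair[i - 1L, j - 1L]) {
          key <- paste0(x[i - 1L], x[i], "/", yr[j - 1L], yr[j])
          cand[length(ips), length(jps)] <-
            E[i - 1L, j - 1L] + params$stacks[[key]]
        }
        k <- which.min(cand)  # deterministic: first minimum, smallest span last
        if (length(k) && is.finite(cand[k]) && cand[k] < best - 1e-9) {
          best <- cand[k]
          ip <- ips[(k - 1L) %% length(ips) + 1L]
          jp <- jps[(k - 1L) %/% length(ips) + 1L]
          best_pre <- (ip - 1L) * m + jp
        }
      }
      E[i, j] <- best; PRE[i, j] <- best_pre
    }
  }
  fin <- which(is.finite(E) & E < -1e-9, arr.ind = TRUE)
  if (nrow(fin) == 0L) {
    return(structure(list(mfe = 0, pairs = matrix(0L, 0, 2),
                          structure = c(strrep(".", n), strrep(".", m)),
                          n_bulges = 0L, bulge_positions = integer()),
                     class = "duplex_result"))
  }
  vals <- E[fin]
  ord <- order(vals, fin[, 1] + fin[, 2], fin[, 1])
  end <- fin[ord[1], ]
  # traceback
  pairs <- matrix(0L, 0, 2)
  i <- end[1]; j <- end[2]
  repeat {
    pairs <- rbind(c(i, j), pairs)
    pre <- PRE[i, j]
    if (pre == 0L) break
    i <- (pre - 1L) %/% m + 1L
    j <- (pre - 1L) %% m + 1L
  }
  mfe <- E[end[1], end[2]]
  # bulges: consecutive pairs with unpaired bases on exactly one side
  n_bulges <- 0L; bulge_pos <- integer()
  if (nrow(pairs) > 1L) {
    da <- diff(pairs[, 1]) - 1L
    db <- diff(pairs[, 2]) - 1L
    one_sided <- xor(da > 0L, db > 0L)
    n_bulges <- sum(one_sided)
    bulge_pos <- pairs[which(one_sided), 1]
  }
  sx <- rep(".", n); sx[pairs[, 1]] <- "("
  sy_r <- rep(".", m); sy_r[pairs[, 2]] <- ")"
  pairs_target <- cbind(mirna = pairs[, 1], target = m - pairs[, 2] + 1L)
  structure(list(mfe = mfe, pairs = pairs_target,
                 structure = c(paste(sx, collapse = ""),
                               paste(rev(sy_r), collapse = "")),
                 n_bulges = n_bulges, bulge_positions = bulge_pos),
            class = "duplex_result")
}

#' Seed-region duplex MFE for a target site
#'
#' Builds the duplex the site-class comparison scores: the miRNA side is
#' the mature 5' region through the seed plus `flank` downstream bases; the
#' target side is the site pattern plus `flank` flanking UTR bases on each
#' side.
#'
#' @param mature mature miRNA (RNA).
#' @param utr_seq UTR sequence containing the site.
#' @param utr_offset,site_len site location within the UTR (0-based).
#' @param seed_len seed length.
#' @param flank flanking bases (default 3).
#' @param params parameter list from [load_nn_params()].
#' @return `duplex_result` list.
#' @export
site_duplex_mfe <- function(mature, utr_seq, utr_offset, site_len,
                            seed_len = 7L, flank = 3L,
                            params = load_nn_params()) {
  mir_part <- substr(mature, 1L, min(nchar(mature), 1L + seed_len + flank))
  lo <- max(1L, utr_offset + 1L - flank)
  hi <- min(nchar(utr_seq), utr_offset + site_len + flank)
  duplex_mfe(mir_part, substr(utr_seq, lo, hi), params)
}

#' Compare duplex MFE between site classes
#'
#' Pairwise two-sided Wilcoxon rank-sum tests between seed, CG-bulge and
#' random-bulge duplex energies, with medians. Lower (more negative) MFE is
#' the stronger duplex.
#'
#' @param mfe_seed,mfe_bulge,mfe_random numeric vectors of energies
#'   (kcal/mol).
#' @return list with `medians`, `tests` (data.frame: `group_a`, `group_b`,
#'   `p_value`, `lower_mfe`), `low_power` flag.
#' @export
compare_mfe_classes <- function(mfe_seed, mfe_bulge, mfe_random) {
  groups <- list(seed = mfe_seed, cg_bulge = mfe_bulge,
                 random_bulge = mfe_random)
  if (any(vapply(groups, length, 0L) == 0L)) stop("empty energy group")
  medians <- vapply(groups, stats::median, 0)
  combos <- utils::combn(names(groups), 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    p <- if (length(groups[[a]]) < 2L || length(groups[[b]]) < 2L) NA_real_
         else suppressWarnings(
           stats::wilcox.test(groups[[a]], groups[[b]], exact = FALSE)$p.value)
    data.frame(group_a = a, group_b = b, p_value = p,
               lower_mfe = if (medians[a] < medians[b]) a
                           else if (medians[a] > medians[b]) b else "tie",
               stringsAsFactors = FALSE)
  })
  list(medians = medians, tests = do.call(rbind, rows),
       low_power = any(vapply(groups, length, 0L) < 3L))
}
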