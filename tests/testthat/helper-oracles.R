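# Independent oracles used to cross-check the package implementations.
# These deliberately use the dumbest correct algorithm available.

# Naive substring scan: every window of the subject is extracted and
# compared to the pattern directly (no regex machinery); all (overlapping)
# 0-based offsets are returned.
oracle_scan_offsets <- function(pattern, subject) {
  L <- nchar(pattern)
  n <- nchar(subject)
  if (L == 0L || n < L) return(integer(0))
  s <- seq_len(n - L + 1L)
  which(substring(subject, s, s + L - 1L) == pattern) - 1L
}

# Spearman rho by explicit rank transform then Pearson.
oracle_spearman <- function(a, b) {
  stats::cor(rank(a), rank(b))
}

# Exhaustive-enumeration duplex MFE. Enumerates every monotone set of base
# pairs between x (5'->3') and the reversed target, scoring stacks and
# affine loop penalties directly; the minimum over all sets (including the
# empty set, energy 0) is returned.
oracle_duplex_mfe <- function(mirna, target, params, gu_wobble = TRUE) {
  x <- strsplit(mirna, "")[[1]]
  yr <- rev(strsplit(chartr("Tt", "Uu", target), "")[[1]])
  n <- length(x); m <- length(yr)
  ok_pair <- function(a, b) {
    wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "C" && b == "G") || (a == "G" && b == "C")
    wc || (gu_wobble && ((a == "G" && b == "U") || (a == "U" && b == "G")))
  }
  can <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) can[i, j] <- ok_pair(x[i], yr[j])
  plist <- which(can, arr.ind = TRUE)
  if (nrow(plist) == 0L) return(0)
  step_cost <- function(i0, j0, i1, j1) {
    a <- i1 - i0 - 1L; b <- j1 - j0 - 1L
    if (a == 0L && b == 0L) {
      params$stacks[[paste0(x[i0], x[i1], "/", yr[j0], yr[j1])]]
    } else if (a == 0L || b == 0L) {
      params$bulge_open + params$bulge_ext * (max(a, b) - 1L)
    } else {
      params$iloop_open + params$iloop_ext * (a + b - 2L)
    }
  }
  best <- 0
  recurse <- function(last_i, last_j, e) {
    nxt <- plist[plist[, 1] > last_i & plist[, 2] > last_j, , drop = FALSE]
    for (r in seq_len(nrow(nxt))) {
      i1 <- nxt[r, 1]; j1 <- nxt[r, 2]
      e1 <- if (last_i == 0L) 0 else e + step_cost(last_i, last_j, i1, j1)
      if (e1 < best) best <<- e1
      recurse(i1, j1, e1)
    }
  }
  recurse(0L, 0L, 0)
  best
}

# Random DNA / RNA strings.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")

# A hand-written three-species MAF text fixture (width 12, one gap column
# in sp2, one all-gap row in block 2, opposite strands in block 3).
write_toy_maf <- function(path) {
  writeLines(c(
    "##maf version=1",
    "a score=1.0",
    "s hg.chr1 10 12 + 1000 ACGTACGTACGT",
    "s sp1.chr5 40 12 + 2000 ACGTACGTACGT",
    "s sp2.chr2 7 11 + 1500 ACGTAC-TACGT",
    "",
    "a score=2.0",
    "s hg.chr1 22 4 + 1000 AC-GT",
    "s sp1.chr5 52 5 + 2000 ACAGT",
    "s sp3.chr3 0 0 + 900 -----",
    "",
    "a score=3.0",
    "s hg.chr1 26 4 + 1000 GGCC",
    "s sp1.chr5 60 4 - 2000 GGCC",
    ""), path)
  path
}

# Tiny alignment-block constructors for projection tests (built in code,
# reference species "hg" on chrU).
toy_block <- function(texts, start, chrom = "chrU",
                      species = c("hg", paste0("sp", seq_len(length(texts) - 1L)))) {
  size <- nchar(gsub("-", "", texts, fixed = TRUE))
  list(species = species, chrom = rep(chrom, length(texts)),
       start = rep(start, length(texts)), size = size,
       strand = rep("+", length(texts)),
       src_size = rep(10000L, length(texts)),
       text = toupper(texts), width = nchar(texts[1]), ref_species = "hg")
}
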