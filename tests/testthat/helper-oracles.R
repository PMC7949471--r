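# independent brute-force oracles, deliberately written with no reference to
# the package internals they check

# plain-R affine-gap DP (three explicit state matrices, no traceback);
# free_ends = TRUE gives overlap alignment, FALSE global alignment.
# a gap of length L costs open + L * ext.
oracle_align_score <- function(pattern, subject, match = 1, mismatch = -1,
                               open = 2, ext = 1, free_ends = TRUE) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1); E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  if (!free_ends) {
    H[1, -1] <- -(open + ext * seq_len(n)); E[1, -1] <- H[1, -1]
    H[-1, 1] <- -(open + ext * seq_len(m)); F[-1, 1] <- H[-1, 1]
  }
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      sc <- if (p[i - 1] == s[j - 1] && p[i - 1] != "N") match else mismatch
      H[i, j] <- max(H[i - 1, j - 1] + sc, E[i, j], F[i, j])
    }
  }
  if (free_ends) max(H[m + 1, ], H[, n + 1]) else H[m + 1, n + 1]
}

# first-principles likelihood of one molecule's observations under one
# allele's reference bases at the covered key sites
oracle_likelihood <- function(obs_base, obs_q, ref_base) {
  stopifnot(length(obs_base) == length(ref_base))
  e <- 10^(-obs_q / 10)
  p <- ifelse(obs_base == ref_base, 1 - e, e / 3)
  sum(p) / length(p)
}

# brute-force assignment and counting over an evidence-level instance:
#   instance$alleles : list allele name -> character vector of bases at the
#                      gene's key sites (single gene per instance here is not
#                      assumed: names carry GENE*.. and sites are per gene)
#   instance$umis    : list of list(candidates=, sites=idx, base=, q=)
# ties are excluded (ambiguous) as under the default policy
oracle_assign_count <- function(instance) {
  counts <- setNames(rep(0, length(instance$alleles)),
                     names(instance$alleles))
  ambiguous <- 0; unassigned <- 0
  for (u in instance$umis) {
    cand <- u$candidates
    if (length(cand) == 1) {
      counts[cand] <- counts[cand] + 1
      next
    }
    gene_of <- function(a) sub("\\*.*$", "", a)
    lik <- sapply(cand, function(a) {
      ref <- instance$alleles[[a]]
      idx <- u$sites[[gene_of(a)]]
      if (is.null(idx) || length(idx) == 0) return(NA_real_)
      oracle_likelihood(u$base[[gene_of(a)]], u$q[[gene_of(a)]], ref[idx])
    })
    if (all(is.na(lik))) { unassigned <- unassigned + 1; next }
    best <- max(lik, na.rm = TRUE)
    top <- names(lik)[!is.na(lik) & abs(lik - best) < 1e-15]
    if (length(top) > 1) ambiguous <- ambiguous + 1
    else counts[top] <- counts[top] + 1
  }
  list(counts = counts, ambiguous = ambiguous, unassigned = unassigned)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
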