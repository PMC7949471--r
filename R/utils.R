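# internal helpers shared across modules

#' Gene symbol of an HLA allele name
#'
#' The gene is the substring before `*`, e.g. `"C"` for `"C*06:02"`.
#'
#' @param allele character vector of allele names.
#' @return character vector of gene symbols.
#' @export
gene_of_allele <- function(allele) {
  bad <- !grepl("\\*", allele)
  if (any(bad)) stop("not an HLA allele name (no '*'): ", allele[bad][1])
  sub("\\*.*$", "", allele)
}

#' Normalize an HLA allele name to 2-field resolution
#'
#' Names with more than two fields (e.g. `A*01:01:01:01`) are truncated to
#' the first two (`A*01:01`). Expression-variant suffix letters on the
#' retained fields are kept.
#'
#' @param allele character vector of allele names (`GENE*F1:F2...`).
#' @return character vector of 2-field allele names.
#' @export
normalize_allele_name <- function(allele) {
  ok <- grepl("^[A-Za-z0-9-]+\\*[0-9]+[A-Za-z]*(:[0-9]+[A-Za-z]*)+", allele)
  if (any(!ok)) {
    stop("malformed HLA allele name: '", allele[!ok][1],
         "' (expected GENE*FF:FF)")
  }
  gene <- sub("\\*.*$", "", allele)
  rest <- sub("^[^*]+\\*", "", allele)
  fields <- strsplit(rest, ":", fixed = TRUE)
  two <- vapply(fields, function(f) paste(f[seq_len(min(2L, length(f)))],
                                          collapse = ":"), character(1))
  paste0(gene, "*", two)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# phred+33 decoding/encoding; accepts one string or a vector of 1-char strings
phred_from_chars <- function(qual) utf8ToInt(paste(qual, collapse = "")) - 33L

phred_to_string <- function(q) intToUtf8(pmin(q, 93L) + 33L)

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared RNG discipline: every seeded entry point goes through this so a
# single integer seed reproduces a whole run
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
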