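#' Read an HLA allele catalog from FASTA
#'
#' Headers may be plain allele names (`>A*01:01`) or IMGT/HLA style with an
#' accession first (`>HLA:HLA00001 A*01:01:01:01 3503 bp`); the first
#' whitespace-delimited token containing `*` is taken as the allele name and
#' truncated to 2-field resolution. Records whose truncated names collide
#' with a *different* sequence raise an error; identical duplicates are
#' collapsed silently.
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @return named character vector of class `hla_catalog`: allele name ->
#'   nucleotide sequence.
#' @export
read_allele_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  name <- vapply(strsplit(headers, "[ \t]+"), function(tok) {
    hit <- grep("\\*", tok, value = TRUE)
    if (length(hit) == 0)
      stop("FASTA header carries no HLA allele name: '",
           paste(tok, collapse = " "), "'")
    hit[1]
  }, character(1))
  name <- normalize_allele_name(name)
  seq <- toupper(as.character(seqs))
  if (any(nchar(seq) == 0))
    stop("empty sequence for allele ", name[nchar(seq) == 0][1])
  if (any(!grepl("^[ACGTN]+$", seq)))
    stop("non-ACGTN characters in sequence of allele ",
         name[!grepl("^[ACGTN]+$", seq)][1])
  # collapse duplicates after truncation; unequal sequences are an error
  keep <- !duplicated(name)
  for (nm in unique(name[duplicated(name)])) {
    s <- unique(seq[name == nm])
    if (length(s) > 1)
      stop("allele name collision after 2-field truncation: '", nm,
           "' maps to ", length(s), " distinct sequences")
  }
  catalog <- setNames(seq[keep], name[keep])
  class(catalog) <- "hla_catalog"
  catalog
}

#' Read a genotype table
#'
#' Tab-separated with columns `sample`, `gene`, `allele1` and optional
#' `allele2` (header optional). One row per sample x gene; a missing or
#' repeated `allele2` means homozygous.
#'
#' @param path path to the TSV file.
#' @return data.table with columns sample, gene, allele1, allele2 (NA when
#'   homozygous).
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- identical(tolower(first[1]), "sample")
  gt <- data.table::fread(path, header = has_header, sep = "\t", fill = TRUE,
                          colClasses = "character")
  if (ncol(gt) < 3) stop("genotype table needs >= 3 columns")
  gt <- gt[, 1:min(4, ncol(gt)), with = FALSE]
  if (ncol(gt) == 3) gt[, V4 := NA_character_]
  data.table::setnames(gt, c("sample", "gene", "allele1", "allele2"))
  gt[allele2 == "", allele2 := NA_character_]
  gt[]
}

#' Build a sample's personalized HLA reference
#'
#' Collects the 1-2 allele sequences per gene that the genotype table lists
#' for the sample. Allele names are normalized to 2-field resolution; a
#' homozygous genotype (one allele, or the same allele listed twice)
#' contributes a single sequence.
#'
#' @param catalog an [read_allele_fasta()] catalog.
#' @param genotypes a genotype table ([read_genotype_table()] layout).
#' @param sample sample identifier present in `genotypes`.
#' @return object of class `personalized_ref`: list with `sample` and
#'   `alleles`, a per-gene list of named allele sequences.
#' @export
build_personalized_reference <- function(catalog, genotypes, sample) {
  gt <- data.table::as.data.table(genotypes)
  keep <- which(gt[["sample"]] == sample)  # masks the 'sample' column
  gt <- gt[keep]
  if (nrow(gt) == 0) stop("sample not in genotype table: ", sample)
  alleles <- list()
  for (r in seq_len(nrow(gt))) {
    gene <- gt$gene[r]
    names_r <- stats::na.omit(c(gt$allele1[r], gt$allele2[r]))
    names_r <- unique(normalize_allele_name(names_r))
    miss <- setdiff(names_r, names(catalog))
    if (length(miss) > 0)
      stop("sample ", sample, ", gene ", gene, ": allele '", miss[1],
           "' not in catalog")
    got_gene <- unique(gene_of_allele(names_r))
    if (length(got_gene) != 1 || !identical(got_gene, gene))
      stop("sample ", sample, ": allele names ", paste(names_r, collapse = ","),
           " do not belong to gene ", gene)
    alleles[[gene]] <- setNames(unclass(catalog)[names_r], names_r)
  }
  structure(list(sample = sample, alleles = alleles),
            class = "personalized_ref")
}

#' @export
print.personalized_ref <- function(x, ...) {
  cat("Personalized HLA reference for sample", x$sample, "\n")
  for (g in names(x$alleles))
    cat("  ", g, ": ", paste(names(x$alleles[[g]]), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# flat named vector of all allele sequences in a personalized reference
ref_sequences <- function(ref) unlist(unname(ref$alleles))

#' Multiple alignment of one gene's alleles
#'
#' Center-star progressive alignment (match 1, mismatch -1, linear gap -2).
#' A personalized reference carries at most two alleles per gene, so this
#' reduces to a single global pairwise alignment; the center-star merge is
#' kept general. A single-allele gene yields a trivial gapless one-row MSA.
#'
#' @param ref a `personalized_ref`.
#' @param gene gene symbol present in the reference.
#' @return object of class `gene_msa`: list with `gene`, `rows` (named
#'   gap-padded aligned sequences) and `colmap` (per allele, the MSA column
#'   of each sequence position).
#' @export
align_gene_alleles <- function(ref, gene) {
  seqs <- ref$alleles[[gene]]
  if (is.null(seqs)) stop("gene not in personalized reference: ", gene)
  if (length(seqs) == 1) {
    rows <- seqs
  } else {
    center <- which.max(nchar(seqs))
    others <- setdiff(seq_along(seqs), center)
    aln <- .align_pairwise_cpp(unname(seqs[others]), unname(seqs[center]),
                               match = 1, mismatch = -1,
                               gap_open = 0, gap_ext = 2,
                               free_ends = FALSE, keep_strings = TRUE)
    rows <- merge_center_star(seqs, center, others, aln)
  }
  colmap <- lapply(rows, function(r) {
    which(strsplit(r, "", fixed = TRUE)[[1]] != "-")
  })
  # ungapping invariant: each row must reproduce its input sequence
  stopifnot(identical(unname(gsub("-", "", rows, fixed = TRUE)),
                      unname(as.vector(seqs[names(rows)]))))
  structure(list(gene = gene, rows = rows, colmap = colmap),
            class = "gene_msa")
}

# merge pairwise alignments against a common center sequence into one MSA
merge_center_star <- function(seqs, center, others, aln) {
  # gap positions inserted into the center by each pairwise alignment,
  # keyed by the number of center bases preceding the gap
  gap_runs <- lapply(aln, function(a) {
    gs <- strsplit(a$gapped_subject, "", fixed = TRUE)[[1]]
    before <- cumsum(gs != "-")
    tabulate(before[gs == "-"] + 1L, nbins = nchar(seqs[center]) + 1L)
  })
  maxgap <- Reduce(pmax, gap_runs)
  ncenter <- nchar(seqs[center])

  pad_row <- function(gapped_seq, gapped_center) {
    sq <- strsplit(gapped_seq, "", fixed = TRUE)[[1]]
    ct <- strsplit(gapped_center, "", fixed = TRUE)[[1]]
    before <- cumsum(ct != "-")
    out <- character(0)
    for (slot in 0:ncenter) {
      idx <- which(before == slot & ct == "-")
      here <- sq[idx]
      if (length(here) < maxgap[slot + 1L])
        here <- c(here, rep("-", maxgap[slot + 1L] - length(here)))
      out <- c(out, here)
      if (slot < ncenter) {
        pos <- which(before == slot + 1L & ct != "-")[1]
        out <- c(out, sq[pos])
      }
    }
    paste(out, collapse = "")
  }

  rows <- vector("list", length(seqs))
  center_plain <- strsplit(unname(seqs[center]), "", fixed = TRUE)[[1]]
  out <- character(0)
  for (slot in 0:ncenter) {
    out <- c(out, rep("-", maxgap[slot + 1L]))
    if (slot < ncenter) out <- c(out, center_plain[slot + 1L])
  }
  rows[[center]] <- paste(out, collapse = "")
  for (k in seq_along(others))
    rows[[others[k]]] <- pad_row(aln[[k]]$gapped_pattern,
                                 aln[[k]]$gapped_subject)
  setNames(unlist(rows), names(seqs))
}

#' Shannon entropy of a symbol vector
#'
#' `H = -sum f_s log(f_s)` over the observed symbols, in units of
#' `log_base` (natural log by default, so a 50/50 binary column scores
#' `ln 2 ~ 0.693`).
#'
#' @param symbols character vector (one symbol per observation).
#' @param log_base logarithm base for the entropy units.
#' @return non-negative entropy value.
#' @export
shannon_entropy <- function(symbols, log_base = exp(1)) {
  f <- table(symbols) / length(symbols)
  -sum(f * log(f, base = log_base))
}

#' Find key polymorphic sites of a gene MSA
#'
#' Scores every MSA column by the Shannon entropy of its base composition
#' across the sample's alleles and keeps columns with entropy above the
#' threshold. Columns in which any allele carries a gap are skipped unless
#' `include_indel_sites = TRUE` (gap then counts as a fifth symbol, and the
#' gapped allele gets no coordinate at that site).
#'
#' @param msa a [align_gene_alleles()] result.
#' @param threshold entropy threshold; columns with `H > threshold` are key
#'   sites.
#' @param log_base entropy log base (natural log by default).
#' @param include_indel_sites keep columns containing gaps?
#' @return object of class `key_site_table`: list with `gene`, `alleles`,
#'   `column` (MSA column indices), `entropy`, `bases` (site x allele base
#'   matrix) and `pos` (site x allele matrix of allele coordinates, NA at
#'   gaps).
#' @export
find_key_sites <- function(msa, threshold = 0.5, log_base = exp(1),
                           include_indel_sites = FALSE) {
  alleles <- names(msa$rows)
  mat <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  rownames(mat) <- alleles
  ncolumns <- ncol(mat)
  empty <- structure(list(gene = msa$gene, alleles = alleles,
                          column = integer(0), entropy = numeric(0),
                          bases = matrix(character(0), 0, length(alleles),
                                         dimnames = list(NULL, alleles)),
                          pos = matrix(integer(0), 0, length(alleles),
                                       dimnames = list(NULL, alleles)),
                          threshold = threshold, log_base = log_base),
                     class = "key_site_table")
  if (length(alleles) < 2) return(empty)

  has_gap <- colSums(mat == "-") > 0
  H <- vapply(seq_len(ncolumns), function(k)
    shannon_entropy(mat[, k], log_base), numeric(1))
  keep <- H > threshold & (include_indel_sites | !has_gap)
  cols <- which(keep)
  if (length(cols) == 0) return(empty)

  bases <- t(mat[, cols, drop = FALSE])
  pos <- vapply(alleles, function(a) {
    match(cols, msa$colmap[[a]])
  }, integer(length(cols)))
  pos <- matrix(pos, nrow = length(cols),
                dimnames = list(NULL, alleles))
  structure(list(gene = msa$gene, alleles = alleles, column = cols,
                 entropy = H[cols], bases = bases, pos = pos,
                 threshold = threshold, log_base = log_base),
            class = "key_site_table")
}

#' @export
print.key_site_table <- function(x, ...) {
  cat("Key polymorphic sites for gene", x$gene, "-", length(x$column),
      "site(s), entropy >", x$threshold, "\n")
  invisible(x)
}

#' Long-format view of a key-site table
#'
#' One row per site x allele, suitable for TSV export
#' (`gene, msa_column, entropy, allele, base`). Columns are 1-based.
#'
#' @param sites a `key_site_table` (or list of them).
#' @return data.table.
#' @export
key_sites_as_table <- function(sites) {
  if (inherits(sites, "key_site_table")) sites <- list(sites)
  out <- data.table::rbindlist(lapply(sites, function(ks) {
    if (length(ks$column) == 0) return(NULL)
    data.table::data.table(
      gene = ks$gene,
      msa_column = rep(ks$column, length(ks$alleles)),
      entropy = rep(ks$entropy, length(ks$alleles)),
      allele = rep(ks$alleles, each = length(ks$column)),
      base = as.vector(ks$bases))
  }))
  if (nrow(out) == 0)
    out <- data.table::data.table(gene = character(0), msa_column = integer(0),
                                  entropy = numeric(0), allele = character(0),
                                  base = character(0))
  out[]
}

#' Build MSAs and key-site tables for every gene of a reference
#'
#' @param ref a `personalized_ref`.
#' @inheritParams find_key_sites
#' @return list of class `sample_index` with `ref`, `msa` (per gene) and
#'   `sites` (per gene).
#' @export
build_sample_index <- function(ref, threshold = 0.5, log_base = exp(1),
                               include_indel_sites = FALSE) {
  genes <- names(ref$alleles)
  msa <- lapply(genes, function(g) align_gene_alleles(ref, g))
  names(msa) <- genes
  sites <- lapply(msa, find_key_sites, threshold = threshold,
                  log_base = log_base,
                  include_indel_sites = include_indel_sites)
  structure(list(ref = ref, msa = msa, sites = sites),
            class = "sample_index")
}
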