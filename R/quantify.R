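#' Gene-level counts from an allele count table
#'
#' Sums allele values per sample x gene (the gene is the allele-name field
#' before `*`, reported with an `HLA-` prefix by default).
#'
#' @param table data.frame with `sample`, `allele` and a value column
#'   (`count` or `value`).
#' @param prefix string prepended to gene symbols in the output.
#' @return data.table `sample`, `gene`, `count`.
#' @export
gene_counts <- function(table, prefix = "HLA-") {
  dt <- data.table::as.data.table(table)
  if (nrow(dt) == 0)
    return(data.table::data.table(sample = character(0), gene = character(0),
                                  count = numeric(0)))
  val <- if ("count" %in% names(dt)) dt$count else dt$value
  dt <- data.table::data.table(sample = dt$sample,
                               gene = paste0(prefix,
                                             gene_of_allele(dt$allele)),
                               count = val)
  dt[, .(count = sum(count)), by = .(sample, gene)][]
}

#' Counts-per-million normalization
#'
#' `value = count * 1e6 / library_size`, the library size being the
#' sample's whole-transcriptome unique-molecule total (with the generic
#' HLA gene rows replaced by the allele-specific rows; see
#' [library_sizes_from_counts()]).
#'
#' @param table allele count table (`sample`, `allele`, `count`).
#' @param library_sizes named numeric vector (sample -> total count) or a
#'   two-column data.frame.
#' @return data.table `sample`, `allele`, `value`, `library_size` with
#'   attribute `route = "cdna-cpm"`.
#' @export
cpm_normalize <- function(table, library_sizes) {
  dt <- data.table::as.data.table(table)
  if (is.data.frame(library_sizes))
    library_sizes <- setNames(as.numeric(library_sizes[[2]]),
                              as.character(library_sizes[[1]]))
  miss <- setdiff(unique(dt$sample), names(library_sizes))
  if (length(miss) > 0)
    stop("missing library size for sample ", miss[1])
  if (any(library_sizes[unique(dt$sample)] <= 0))
    stop("library sizes must be positive")
  out <- dt[, .(sample, allele,
                value = count * 1e6 / library_sizes[sample],
                library_size = library_sizes[sample])]
  data.table::setattr(out, "route", "cdna-cpm")
  out[]
}

#' Per-sample library sizes from a whole-transcriptome count table
#'
#' Mirrors the merged-count-table bookkeeping of the cDNA route: the
#' generic HLA gene rows of the transcriptome table are dropped and
#' replaced by the allele-specific UMI counts before totaling.
#'
#' @param counts data.frame `sample`, `gene`, `count` (whole-transcriptome
#'   unique-UMI counts).
#' @param allele_counts the HLA allele count table replacing the HLA gene
#'   rows.
#' @param hla_genes gene labels (as they appear in `counts`) to drop.
#' @return named numeric vector of library sizes.
#' @export
library_sizes_from_counts <- function(counts, allele_counts,
                                      hla_genes = NULL) {
  ct <- data.table::as.data.table(counts)
  ac <- data.table::as.data.table(allele_counts)
  if (is.null(hla_genes))
    hla_genes <- unique(paste0("HLA-", gene_of_allele(ac$allele)))
  ct <- ct[!gene %in% hla_genes]
  base <- ct[, .(total = sum(count)), by = sample]
  extra <- ac[, .(extra = sum(count)), by = sample]
  m <- merge(base, extra, by = "sample", all = TRUE)
  m[is.na(total), total := 0][is.na(extra), extra := 0]
  setNames(m$total + m$extra, m$sample)
}

#' Scale amplicon counts onto the cDNA CPM scale
#'
#' Per sample, each allele's unique-UMI proportion of the amplicon library
#' is multiplied by the sample's total CPM-normalized unique UMIs over all
#' HLA alleles of the cDNA library, making the two routes directly
#' comparable.
#'
#' @param amplicon amplicon-route allele count table.
#' @param cdna_norm [cpm_normalize()] output for the cDNA route.
#' @return data.table `sample`, `allele`, `value` with attribute
#'   `route = "amplicon-scaled"`.
#' @export
amplicon_scale <- function(amplicon, cdna_norm) {
  amp <- data.table::as.data.table(amplicon)
  cd <- data.table::as.data.table(cdna_norm)
  miss <- setdiff(unique(amp$sample), unique(cd$sample))
  if (length(miss) > 0)
    stop("sample missing from the cDNA normalized table: ", miss[1])
  totals <- amp[, .(amp_total = sum(count)), by = sample]
  if (any(totals$amp_total <= 0))
    stop("amplicon total is zero for sample ",
         totals$sample[totals$amp_total <= 0][1])
  cdtot <- cd[, .(cdna_total = sum(value)), by = sample]
  out <- merge(amp, totals, by = "sample")
  out <- merge(out, cdtot, by = "sample")
  out <- out[, .(sample, allele,
                 value = count / amp_total * cdna_total)]
  data.table::setattr(out, "route", "amplicon-scaled")
  out[]
}

# the two allele rows of a heterozygous sample x gene, smaller name first
het_pair <- function(dt, sample, gene) {
  rows <- dt[which(dt$sample == sample &
                     gene_of_allele(dt$allele) == gene)]
  if (nrow(rows) != 2)
    stop("gene ", gene, " is not heterozygous in sample ", sample)
  val <- if ("count" %in% names(rows)) rows$count else rows$value
  ord <- order(rows$allele)
  list(alleles = rows$allele[ord], values = val[ord])
}

#' Log2 allele-to-allele expression ratio of a heterozygote
#'
#' `log2` of the count of the lexicographically smaller-named allele over
#' the other, a fixed orientation so that ratios are comparable across
#' data routes.
#'
#' @param table allele count (or normalized) table.
#' @param sample sample id.
#' @param gene gene symbol (without the `HLA-` prefix).
#' @return the log2 ratio.
#' @export
allele_log_ratio <- function(table, sample, gene) {
  dt <- data.table::as.data.table(table)
  p <- het_pair(dt, sample, gene)
  if (any(p$values == 0))
    stop("zero count for ", p$alleles[p$values == 0][1], " in sample ",
         sample, " (ratio undefined; excluded from correlation sets)")
  log2(p$values[1] / p$values[2])
}

#' Allelic imbalance of a heterozygote
#'
#' The proportion of the gene's expression attributed to the less expressed
#' allele, `p = min(c1, c2) / (c1 + c2)` in `[0, 0.5]`, binned (after
#' rounding to 2 decimals) into `0.01-0.20`, `0.21-0.40` and `0.41-0.50`;
#' proportions below 0.01 fold into the first bin.
#'
#' @inheritParams allele_log_ratio
#' @return list of class `imbalance_record`: `sample`, `gene`, `alleles`,
#'   `lesser_allele`, `p`, `bin`.
#' @export
allelic_imbalance <- function(table, sample, gene) {
  dt <- data.table::as.data.table(table)
  pr <- het_pair(dt, sample, gene)
  tot <- sum(pr$values)
  if (tot <= 0) stop("gene total is zero for ", gene, " in sample ", sample)
  p <- min(pr$values) / tot
  p2 <- round(p, 2)
  bin <- if (p2 <= 0.20) "0.01-0.20" else if (p2 <= 0.40) "0.21-0.40"
         else "0.41-0.50"
  structure(list(sample = sample, gene = gene, alleles = pr$alleles,
                 lesser_allele = pr$alleles[which.min(pr$values)],
                 p = p, bin = bin),
            class = "imbalance_record")
}

#' Group expression values and medians
#'
#' Collects normalized values into labelled groups (e.g. allelic lineages
#' pooling serologically equivalent alleles, or supplied haplotype labels)
#' and reports each group's values and median (midpoint convention for
#' even sizes). The built-in `"lineage"` labeller maps an allele to its
#' first name field (`DPB1*02:01 -> DPB1*02`).
#'
#' @param norm normalized table (`sample`, `allele`, `value`).
#' @param labels `"lineage"`, or a data.frame `sample`, `allele`, `group`;
#'   label rows naming absent table entries are ignored and counted in the
#'   `ignored` attribute.
#' @return list of class `group_expression`: `values` (named list of
#'   per-group value vectors) and `medians`.
#' @export
group_expression <- function(norm, labels = "lineage") {
  dt <- data.table::as.data.table(norm)
  ignored <- 0L
  if (identical(labels, "lineage")) {
    dt[, group := sub(":.*$", "", allele)]
  } else {
    lb <- data.table::as.data.table(labels)
    m <- merge(dt, lb, by = c("sample", "allele"))
    ignored <- nrow(lb) - nrow(unique(m[, .(sample, allele, group)]))
    if (ignored > 0)
      warning(ignored, " label row(s) name absent table entries; ignored")
    dt <- m
  }
  dt <- dt[!is.na(group)]
  values <- split(dt$value, dt$group)
  values <- values[sort(names(values))]
  structure(list(values = values,
                 medians = vapply(values, stats::median, numeric(1)),
                 ignored = ignored),
            class = "group_expression")
}

#' Log2 fold change between two expression groups
#'
#' `log2(median(g1) / median(g2))` over the groups' normalized values.
#'
#' @param groups a [group_expression()] result.
#' @param g1,g2 group labels.
#' @return the log2 fold change.
#' @export
lineage_fold_change <- function(groups, g1, g2) {
  for (g in c(g1, g2))
    if (!g %in% names(groups$medians) || length(groups$values[[g]]) == 0)
      stop("empty or unknown group: ", g)
  if (groups$medians[[g2]] == 0) stop("zero median in group ", g2)
  log2(groups$medians[[g1]] / groups$medians[[g2]])
}
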