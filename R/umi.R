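#' Number of distinct UMI barcodes of a given length
#'
#' `4^len` over the DNA alphabet; a 10-base UMI spans 1,048,576 barcodes.
#'
#' @param len UMI length in bases.
#' @return count of distinct barcodes.
#' @export
umi_space_size <- function(len) 4^len

#' Extract fixed-length UMIs from FASTQ reads
#'
#' The UMI is a fixed-length prefix of one mate (read 1 by default,
#' phred+33). It is removed from the sequence and qualities, attached to the
#' read record, and appended to the read name as `name_UMI` for interop with
#' name-encoded inputs. Reads whose UMI contains `N` are dropped and
#' counted (attribute `dropped`).
#'
#' @param fastq1 path to the (possibly gzipped) FASTQ of read 1.
#' @param fastq2 optional path to the mate FASTQ.
#' @param umi_len UMI length in bases.
#' @param umi_mate which mate carries the UMI prefix (1 or 2).
#' @return data.table of tagged reads with columns `id` (annotated
#'   `name_UMI`), `mate`, `seq`, `qual`, `umi`; attribute `dropped` holds
#'   the N-UMI drop count.
#' @export
extract_umis <- function(fastq1, fastq2 = NULL, umi_len = 10, umi_mate = 1) {
  stopifnot(umi_mate %in% c(1, 2))
  if (umi_mate == 2 && is.null(fastq2))
    stop("umi_mate = 2 requires fastq2")
  read_one <- function(path, mate) {
    fq <- ShortRead::readFastq(path)
    data.table::data.table(
      id = sub("[ \t].*$", "", as.character(ShortRead::id(fq))),
      mate = mate,
      seq = as.character(ShortRead::sread(fq)),
      qual = as.character(Biostrings::quality(Biostrings::quality(fq))))
  }
  r1 <- read_one(fastq1, if (is.null(fastq2)) 0L else 1L)
  reads <- r1
  if (!is.null(fastq2)) {
    r2 <- read_one(fastq2, 2L)
    if (nrow(r1) != nrow(r2) || !identical(r1$id, r2$id))
      stop("mismatched R1/R2 pairing between ", fastq1, " and ", fastq2)
    reads <- data.table::rbindlist(list(r1, r2))
  }
  carrier <- if (is.null(fastq2)) 0L else as.integer(umi_mate)
  is_carrier <- reads$mate == carrier
  short <- is_carrier & nchar(reads$seq) < umi_len
  if (any(short))
    stop("read shorter than the UMI length (", umi_len, "): ",
         reads$id[short][1])
  umi_of <- substr(reads$seq[is_carrier], 1, umi_len)
  # propagate the carrier's UMI to its mate via the read name
  umap <- setNames(umi_of, reads$id[is_carrier])
  reads[, umi := umap[id]]
  if (anyNA(reads$umi)) stop("read without a UMI-carrying mate: ",
                             reads$id[is.na(reads$umi)][1])
  reads[is_carrier, `:=`(seq = substr(seq, umi_len + 1L, nchar(seq)),
                         qual = substr(qual, umi_len + 1L, nchar(qual)))]
  dropped_ids <- unique(reads$id[grepl("N", reads$umi, fixed = TRUE)])
  reads <- reads[!id %in% dropped_ids]
  reads[, id := paste0(id, "_", umi)]
  if (nrow(reads) > 0 && any(nchar(reads$seq) == 0))
    stop("read reduced to an empty sequence after UMI removal: ",
         reads$id[nchar(reads$seq) == 0][1])
  data.table::setattr(reads, "dropped", length(dropped_ids))
  reads[]
}

#' Parse a UMI encoded in a read name
#'
#' Upstream extraction tools append the UMI to the read name as `name_UMI`;
#' this returns the trailing ACGT token.
#'
#' @param id character vector of read names.
#' @return character vector of UMIs.
#' @export
parse_name_encoded_umi <- function(id) {
  m <- regmatches(id, regexpr("_[ACGT]+$", id))
  ok <- grepl("_[ACGT]+$", id)
  if (any(!ok))
    stop("read name carries no trailing _UMI token: ", id[!ok][1])
  substring(m, 2)
}

#' Cluster UMIs allowing one mismatch
#'
#' Builds the graph whose edges join UMI variants at Hamming distance <= 1
#' and returns its connected components (single linkage), so reads sharing
#' a barcode up to one substitution collapse to one candidate molecule.
#' Group ids are assigned in sorted order of the canonical UMI (the most
#' frequent variant; ties broken lexicographically), so clustering is
#' order-invariant. The `directional` method of the UMI-tools family
#' (an edge only joins a variant to a neighbour at least twice as abundant)
#' is available as an option.
#'
#' @param umis character vector, one UMI per read (a multiset).
#' @param method `"single"` (default, connected components at distance <= 1)
#'   or `"directional"`.
#' @return data.table with one row per UMI variant: `umi`, `count`,
#'   `group` (integer id), `canonical`.
#' @export
cluster_umis <- function(umis, method = c("single", "directional")) {
  method <- match.arg(method)
  if (length(umis) == 0)
    return(data.table::data.table(umi = character(0), count = integer(0),
                                  group = integer(0), canonical = character(0)))
  if (length(unique(nchar(umis))) != 1)
    stop("mixed UMI lengths in one clustering scope")
  tab <- table(umis)
  variants <- names(tab)
  counts <- as.integer(tab)
  L <- nchar(variants[1])

  # neighbours at Hamming distance exactly 1 share a string with one
  # position masked; members of a mask-bucket are pairwise distance <= 1,
  # so star edges within each bucket preserve the components
  pairer <- if (method == "single") {
    function(ix) cbind(ix[1], ix[-1])          # star keeps components intact
  } else {
    function(ix) t(utils::combn(ix, 2))        # directional needs all pairs
  }
  edges <- list()
  for (p in seq_len(L)) {
    key <- paste0(substr(variants, 1, p - 1), ".",
                  substr(variants, p + 1, L))
    grp <- split(seq_along(variants), key)
    grp <- grp[lengths(grp) > 1]
    if (length(grp) > 0)
      edges[[p]] <- do.call(rbind, lapply(grp, pairer))
  }
  edges <- do.call(rbind, edges)
  if (method == "directional" && !is.null(edges)) {
    # count-gradient criterion: an edge survives only if one endpoint is at
    # least twice as abundant (minus one) as the other
    keep <- counts[edges[, 1]] >= 2 * counts[edges[, 2]] - 1 |
            counts[edges[, 2]] >= 2 * counts[edges[, 1]] - 1
    edges <- edges[keep, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = length(variants), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  dt <- data.table::data.table(umi = variants, count = counts, comp = comp)
  canon <- dt[order(comp, -count, umi),
              .(canonical = umi[1]), by = comp]
  dt <- merge(dt, canon, by = "comp", sort = FALSE)
  # deterministic ids: sorted by canonical UMI
  ids <- sort(unique(dt$canonical))
  dt[, group := match(canonical, ids)]
  dt[, comp := NULL]
  data.table::setorder(dt, group, -count, umi)
  dt[]
}

#' Map each read to its UMI group
#'
#' @param reads a tagged-read table ([extract_umis()]).
#' @param clusters a [cluster_umis()] result for the same scope.
#' @return data.table `id`, `group`.
#' @export
read_groups <- function(reads, clusters) {
  m <- match(reads$umi, clusters$umi)
  if (anyNA(m)) stop("read UMI absent from the clustering result")
  unique(data.table::data.table(id = reads$id, group = clusters$group[m]))
}
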