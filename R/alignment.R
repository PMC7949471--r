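#' Overlap (end-to-end) re-alignment of a read against an allele
#'
#' Optimal pairwise alignment with free end gaps on both sequences
#' (match 1, mismatch -1, gap open -2, gap extend -1; a gap of length L
#' costs `2 + L`). Traceback is deterministic: on ties the diagonal move is
#' preferred, then consuming a read base, then consuming an allele base.
#'
#' @param seq read sequence (character scalar).
#' @param allele_seq allele sequence.
#' @param qual optional phred+33 quality string of the read.
#' @return a `candidate_hit` list: `score`, read/allele intervals
#'   (`pstart`..`pend`, `sstart`..`send`, 1-based closed), `ppos`/`spos`
#'   (aligned base pairs), `nmatch`, `nmismatch`, `ncol` (alignment
#'   columns), `identity` (percent), `oriented_seq`, `oriented_qual`.
#' @export
overlap_realign <- function(seq, allele_seq, qual = NULL) {
  a <- .align_pairwise_cpp(seq, allele_seq, match = 1, mismatch = -1,
                           gap_open = 2, gap_ext = 1,
                           free_ends = TRUE, keep_strings = FALSE)[[1]]
  a$identity <- if (a$ncol > 0) 100 * a$nmatch / a$ncol else 0
  a$oriented_seq <- seq
  a$oriented_qual <- qual
  class(a) <- "candidate_hit"
  a
}

# align a set of unique read sequences against every allele of a reference,
# both orientations, returning one best hit per (sequence, allele)
align_unique_seqs <- function(useqs, alleles) {
  rc <- revcomp(useqs)
  res <- list()
  for (a in names(alleles)) {
    fw <- .align_batch_cpp(useqs, alleles[[a]], 1, -1, 2, 1)
    rv <- .align_batch_cpp(rc, alleles[[a]], 1, -1, 2, 1)
    use_r <- rv$score > fw$score              # ties keep the plus strand
    pick <- function(f) { x <- fw[[f]]; x[use_r] <- rv[[f]][use_r]; x }
    res[[a]] <- data.table::data.table(
      useq_idx = seq_along(useqs),
      allele = a,
      strand = ifelse(use_r, "-", "+"),
      score = pick("score"), nmatch = pick("nmatch"),
      nmismatch = pick("nmismatch"), ncol = pick("ncol"),
      pstart = pick("pstart"), pend = pick("pend"),
      sstart = pick("sstart"), send = pick("send"),
      ppos = pick("ppos"), spos = pick("spos"))
  }
  data.table::rbindlist(res)
}

#' Find candidate allele hits for tagged reads
#'
#' Aligns every read (both orientations; the better score is kept, ties go
#' to the plus strand) against every allele sequence of the personalized
#' reference by overlap alignment, and keeps hits passing the identity and
#' aligned-length filters. Duplicate read sequences are aligned once and
#' the results broadcast, so PCR copies cost nothing extra.
#'
#' @param reads tagged-read table ([extract_umis()] layout); a single read
#'   may be passed as a one-row data.frame.
#' @param ref a `personalized_ref`.
#' @param min_identity minimum percent identity over the aligned region.
#' @param min_aln_len minimum number of aligned base pairs
#'   (matches + mismatches).
#' @return data.table of candidate hits ordered by (read id, allele):
#'   `id`, `mate`, `umi`, `allele`, `gene`, `strand`, `score`, `identity`,
#'   `aln_len`, allele interval `sstart`/`send`, read interval
#'   `pstart`/`pend` (coordinates on the oriented read), list columns
#'   `ppos`/`spos` with the aligned base pairs, and the oriented sequence
#'   and qualities used.
#' @export
find_candidates <- function(reads, ref, min_identity = 90, min_aln_len = 50) {
  reads <- data.table::as.data.table(reads)
  alleles <- ref_sequences(ref)
  if (length(alleles) == 0) stop("empty personalized reference")
  if (nrow(reads) == 0) return(empty_hits())

  useqs <- unique(reads$seq)
  hits <- align_unique_seqs(useqs, as.list(alleles))
  hits[, aln_len := nmatch + nmismatch]
  hits[, identity := ifelse(ncol > 0, 100 * nmatch / ncol, 0)]
  hits <- hits[identity >= min_identity & aln_len >= min_aln_len]
  if (nrow(hits) == 0) return(empty_hits())

  reads[, useq_idx := match(seq, useqs)]
  out <- merge(reads, hits, by = "useq_idx", allow.cartesian = TRUE,
               sort = FALSE)
  out[, gene := gene_of_allele(allele)]
  out[, oriented_seq := ifelse(strand == "-", revcomp(seq), seq)]
  rq <- function(q) vapply(q, function(x) intToUtf8(rev(utf8ToInt(x))),
                           character(1), USE.NAMES = FALSE)
  out[, oriented_qual := qual]
  if (any(out$strand == "-"))
    out[strand == "-", oriented_qual := rq(qual)]
  out <- out[, .(id, mate, umi, allele, gene, strand, score, identity,
                 aln_len, sstart, send, pstart, pend, ppos, spos,
                 oriented_seq, oriented_qual)]
  data.table::setorder(out, id, allele, mate)
  out[]
}

empty_hits <- function() {
  data.table::data.table(
    id = character(0), mate = integer(0), umi = character(0),
    allele = character(0), gene = character(0), strand = character(0),
    score = numeric(0), identity = numeric(0), aln_len = integer(0),
    sstart = integer(0), send = integer(0), pstart = integer(0),
    pend = integer(0), ppos = list(), spos = list(),
    oriented_seq = character(0), oriented_qual = character(0))
}

#' Import candidate hits from a LAST MAF file
#'
#' Parses alignment blocks (`a` line, then an `s` line for the reference
#' allele and an `s` line for the read, with an optional `q` quality line
#' after the read). Blocks whose reference name does not resolve to an
#' allele of the personalized reference are skipped and counted in the
#' `skipped` attribute. Files from separate R1, R2 and paired-end
#' alignments may be imported and their hit tables concatenated; the
#' assignment step unions hits per read.
#'
#' @param path MAF file path.
#' @param ref a `personalized_ref`.
#' @param quals optional named character vector of phred+33 quality strings
#'   keyed by read id, used when the block has no `q` line.
#' @param default_q phred score assumed when no quality source is
#'   available.
#' @return hit table in the [find_candidates()] layout (no identity/length
#'   filtering applied); attribute `skipped` counts ignored blocks.
#' @export
read_maf <- function(path, ref, quals = NULL, default_q = 30) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  lines <- readLines(path)
  alleles <- ref_sequences(ref)
  skipped <- 0L
  rows <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!startsWith(ln, "a")) { i <- i + 1L; next }
    if (i + 2L > length(lines) || !startsWith(lines[i + 1L], "s") ||
        !startsWith(lines[i + 2L], "s"))
      stop("malformed MAF block at line ", i, ": expected two 's' lines")
    sref <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    sread <- strsplit(trimws(lines[i + 2L]), "[ \t]+")[[1]]
    if (length(sref) != 7 || length(sread) != 7)
      stop("malformed MAF 's' line at line ", i + 1L)
    qline <- NULL
    i <- i + 3L
    if (i <= length(lines) && startsWith(lines[i], "q")) {
      qline <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      i <- i + 1L
    }
    allele <- tryCatch(normalize_allele_name(sref[2]),
                       error = function(e) sref[2])
    if (!allele %in% names(alleles)) { skipped <- skipped + 1L; next }

    gref <- strsplit(sref[7], "", fixed = TRUE)[[1]]
    gread <- strsplit(sread[7], "", fixed = TRUE)[[1]]
    if (length(gref) != length(gread))
      stop("malformed MAF block ending at line ", i - 1L,
           ": unequal alignment texts")
    if (sref[5] != "+")
      stop("MAF block with reverse-strand reference at line ", i - 3L)
    sstart0 <- as.integer(sref[3]); rstart0 <- as.integer(sread[3])
    strand <- sread[5]
    read_id <- sread[2]
    srcsize <- as.integer(sread[6])

    spos_all <- sstart0 + cumsum(gref != "-")        # 1-based allele coords
    ppos_all <- rstart0 + cumsum(gread != "-")       # 1-based oriented read
    both <- gref != "-" & gread != "-"
    ppos <- ppos_all[both]; spos <- spos_all[both]
    nmatch <- sum(gref[both] == gread[both])
    nmismatch <- sum(both) - nmatch

    oriented_qual <- NULL
    if (!is.null(qline)) {
      gq <- strsplit(qline[3], "", fixed = TRUE)[[1]]
      oriented_qual <- paste(gq[gread != "-"], collapse = "")
      # the q line covers only the aligned read segment; pad to full length
      pre <- strrep("!", rstart0)
      post <- strrep("!", srcsize - max(ppos_all))
      oriented_qual <- paste0(pre, oriented_qual, post)
    } else if (!is.null(quals) && read_id %in% names(quals)) {
      oriented_qual <- quals[[read_id]]
      if (strand == "-") oriented_qual <- paste(
        rev(strsplit(oriented_qual, "", fixed = TRUE)[[1]]), collapse = "")
    } else {
      oriented_qual <- strrep(intToUtf8(default_q + 33L), srcsize)
    }
    oriented_seq <- paste0(strrep("N", rstart0),
                           paste(gread[gread != "-"], collapse = ""),
                           strrep("N", srcsize - max(ppos_all)))

    rows[[length(rows) + 1L]] <- data.table::data.table(
      id = read_id, mate = 0L,
      umi = tryCatch(parse_name_encoded_umi(read_id),
                     error = function(e) NA_character_),
      allele = allele, gene = gene_of_allele(allele), strand = strand,
      score = nmatch - nmismatch, identity = if (sum(both) > 0)
        100 * nmatch / length(gref) else 0,
      aln_len = sum(both),
      sstart = min(spos), send = max(spos),
      pstart = min(ppos), pend = max(ppos),
      ppos = list(ppos), spos = list(spos),
      oriented_seq = oriented_seq, oriented_qual = oriented_qual)
  }
  out <- if (length(rows) > 0) data.table::rbindlist(rows) else empty_hits()
  data.table::setattr(out, "skipped", skipped)
  out[]
}

#' Project an aligned read onto the key polymorphic sites
#'
#' For every key-site MSA column covered by an aligned base pair of the hit
#' (via the hit allele's coordinate map), emits the read base and its phred
#' score. Columns spanned only by a read deletion yield no observation, and
#' non-ACGT read bases are dropped.
#'
#' @param hit one row of a [find_candidates()] table (or a
#'   [overlap_realign()] result augmented with `allele`).
#' @param msa the gene's [align_gene_alleles()] MSA.
#' @param sites the gene's [find_key_sites()] table.
#' @return data.table of site observations: `gene`, `column`, `base`, `q`.
#' @export
project_to_key_sites <- function(hit, msa, sites) {
  if (length(sites$column) == 0) return(empty_observations())
  if (is.data.frame(hit)) hit <- as.list(hit[1, ])
  allele <- hit$allele
  if (is.null(allele) || !allele %in% colnames(sites$pos))
    stop("hit allele absent from the key-site table: ", allele)
  site_pos <- sites$pos[, allele]
  ppos <- if (is.list(hit$ppos)) hit$ppos[[1]] else hit$ppos
  spos <- if (is.list(hit$spos)) hit$spos[[1]] else hit$spos
  ix <- match(site_pos, spos)
  cov <- which(!is.na(ix))
  if (length(cov) == 0) return(empty_observations())
  rpos <- ppos[ix[cov]]
  base <- substring(hit$oriented_seq, rpos, rpos)
  q <- phred_from_chars(substring(hit$oriented_qual, rpos, rpos))
  keep <- base %in% c("A", "C", "G", "T")
  data.table::data.table(gene = sites$gene,
                         column = sites$column[cov][keep],
                         base = base[keep], q = q[keep])
}

empty_observations <- function() {
  data.table::data.table(gene = character(0), column = integer(0),
                         base = character(0), q = integer(0))
}

# vectorized projection: one observation set per (read record, gene),
# using the best-scoring hit of the read in that gene (score ties -> first
# allele in sorted order, which lands on identical MSA columns either way)
project_hits <- function(hits, index) {
  if (nrow(hits) == 0) return(empty_observations()[, id := character(0)][])
  ord <- order(hits$id, hits$mate, hits$gene, -hits$score, hits$allele)
  first <- !duplicated(data.table::data.table(
    hits$id[ord], hits$mate[ord], hits$gene[ord]))
  best <- hits[ord[first]]

  # per gene x allele: key-site coordinates on that allele, and MSA columns
  site_pos <- lapply(index$sites, function(ks) {
    if (length(ks$column) == 0) return(NULL)
    lapply(setNames(ks$alleles, ks$alleles), function(a) ks$pos[, a])
  })
  site_col <- lapply(index$sites, `[[`, "column")

  n <- nrow(best)
  acc <- vector("list", n)
  gene_v <- best$gene; allele_v <- best$allele
  spos_l <- best$spos; ppos_l <- best$ppos
  seq_v <- best$oriented_seq; qual_v <- best$oriented_qual
  id_v <- best$id
  for (r in seq_len(n)) {
    sp <- site_pos[[gene_v[r]]][[allele_v[r]]]
    if (is.null(sp)) next
    ix <- match(sp, spos_l[[r]])
    cov <- which(!is.na(ix))
    if (length(cov) == 0) next
    rpos <- ppos_l[[r]][ix[cov]]
    base <- substring(seq_v[r], rpos, rpos)
    keep <- base %in% c("A", "C", "G", "T")
    if (!any(keep)) next
    qint <- utf8ToInt(qual_v[r]) - 33L
    acc[[r]] <- list(id = id_v[r], gene = gene_v[r],
                     column = site_col[[gene_v[r]]][cov][keep],
                     base = base[keep], q = qint[rpos[keep]])
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (length(acc) == 0)
    return(empty_observations()[, id := character(0)][])
  out <- data.table::data.table(
    id = rep(vapply(acc, `[[`, character(1), "id"),
             vapply(acc, function(x) length(x$column), integer(1))),
    gene = rep(vapply(acc, `[[`, character(1), "gene"),
               vapply(acc, function(x) length(x$column), integer(1))),
    column = unlist(lapply(acc, `[[`, "column")),
    base = unlist(lapply(acc, `[[`, "base")),
    q = unlist(lapply(acc, `[[`, "q")))
  out[]
}
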