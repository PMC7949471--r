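#' Simulation configuration
#'
#' Defines a seeded synthetic study: random gene sequences with 1-2 alleles
#' differing by planted substitutions, per-allele true molecule counts,
#' uniform random UMIs, branching-process PCR amplification with per-copy
#' substitution errors, and phred-scored sequencing with substitution
#' errors at the quality-implied rate. Reads are 5'-anchored (R1 = UMI +
#' template start, emulating STRT-style libraries); the default paired
#' mode adds an R2 starting at a random template offset per sequenced copy
#' (the tagmentation analogue), which is what lets interior polymorphic
#' sites be covered.
#'
#' @param seed integer seed; identical configs are byte-identical.
#' @param genes number of genes.
#' @param seq_len gene sequence length (bases).
#' @param alleles_per_gene 1 or 2.
#' @param divergence substitutions planted between the two alleles of a
#'   gene.
#' @param div_positions optional integer vector of planted positions
#'   (recycled per gene); sampled uniformly when NULL.
#' @param molecules true molecule counts per allele: a numeric vector for
#'   every gene, or a list with one vector per gene.
#' @param umi_len UMI length.
#' @param pcr_cycles PCR cycles.
#' @param pcr_efficiency per-cycle duplication probability in \\[0, 1\\].
#' @param pcr_error per-base substitution rate applied to each new PCR
#'   copy (UMI included).
#' @param q constant phred quality of sequenced bases (or a per-position
#'   vector, recycled); sequencing substitutions occur at rate
#'   `10^(-q/10)`.
#' @param read_len read-1 length including the UMI prefix.
#' @param paired also emit an R2 at a random template offset?
#' @param r2_len read-2 length.
#' @param sample_id sample identifier used in genotype/truth tables.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, genes = 1, seq_len = 1100,
                       alleles_per_gene = 2, divergence = 5,
                       div_positions = NULL,
                       molecules = c(2000, 1000), umi_len = 10,
                       pcr_cycles = 2, pcr_efficiency = 0.5,
                       pcr_error = 1e-4, q = 30, read_len = 100,
                       paired = TRUE, r2_len = 200, sample_id = "SIM1") {
  stopifnot(alleles_per_gene %in% 1:2, pcr_efficiency >= 0,
            pcr_efficiency <= 1, umi_len >= 1, read_len > umi_len,
            all(q >= 0))
  if (divergence >= seq_len) stop("divergence must be < seq_len")
  if (!is.list(molecules)) molecules <- rep(list(molecules), genes)
  if (length(molecules) != genes)
    stop("molecules must give one count vector per gene")
  structure(list(seed = seed, genes = genes, seq_len = seq_len,
                 alleles_per_gene = alleles_per_gene,
                 divergence = divergence, div_positions = div_positions,
                 molecules = molecules, umi_len = umi_len,
                 pcr_cycles = pcr_cycles, pcr_efficiency = pcr_efficiency,
                 pcr_error = pcr_error, q = q, read_len = read_len,
                 paired = paired, r2_len = r2_len, sample_id = sample_id),
            class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

substitute_base <- function(seq, pos) {
  for (p in pos) {
    old <- substr(seq, p, p)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(seq, p, p) <- new
  }
  seq
}

#' Generate the synthetic allele catalog and genotype table
#'
#' Per gene, a uniform random sequence; the second allele (if any) differs
#' from it at exactly `divergence` planted substitution positions. Genes
#' are named `SG1`, `SG2`, ... with alleles `SGk*01:01` / `SGk*02:01`.
#'
#' @param config a [sim_config()].
#' @return list with `catalog` (an `hla_catalog`), `genotypes` (genotype
#'   table for `sample_id`) and `div_positions` (per gene).
#' @export
make_alleles <- function(config) {
  with_seed(config$seed, {
    seqs <- character(0); gt <- list(); divpos <- list()
    for (g in seq_len(config$genes)) {
      gene <- paste0("SG", g)
      a1 <- paste0(gene, "*01:01")
      base <- rand_dna(config$seq_len)
      seqs[a1] <- base
      if (config$alleles_per_gene == 2) {
        a2 <- paste0(gene, "*02:01")
        pos <- if (!is.null(config$div_positions)) {
          as.integer(config$div_positions)
        } else {
          sort(sample(config$seq_len, config$divergence))
        }
        if (anyDuplicated(pos) || any(pos < 1 | pos > config$seq_len))
          stop("invalid planted substitution positions")
        seqs[a2] <- substitute_base(base, pos)
        divpos[[gene]] <- pos
        gt[[gene]] <- data.table::data.table(sample = config$sample_id,
                                             gene = gene, allele1 = a1,
                                             allele2 = a2)
      } else {
        divpos[[gene]] <- integer(0)
        gt[[gene]] <- data.table::data.table(sample = config$sample_id,
                                             gene = gene, allele1 = a1,
                                             allele2 = NA_character_)
      }
    }
    catalog <- structure(seqs, class = "hla_catalog")
    list(catalog = catalog, genotypes = data.table::rbindlist(gt),
         div_positions = divpos)
  })
}

#' Simulate tagged molecules with ground truth
#'
#' Draws the configured number of molecules per allele, each tagged with an
#' independent uniform random UMI. Distinct molecules can collide on a
#' barcode; collisions are recorded in the truth table attribute.
#'
#' @param config a [sim_config()].
#' @param alleles a [make_alleles()] result.
#' @return data.table (the truth table) with one row per molecule:
#'   `molecule_id`, `gene`, `allele`, `umi`; attribute `collisions` counts
#'   molecule pairs sharing a UMI.
#' @export
simulate_molecules <- function(config, alleles) {
  with_seed(config$seed + 1L, {
    gt <- alleles$genotypes
    rows <- list()
    for (g in seq_len(nrow(gt))) {
      als <- stats::na.omit(c(gt$allele1[g], gt$allele2[g]))
      m <- config$molecules[[g]]
      if (length(m) != length(als))
        stop("molecule counts do not match allele count for gene ",
             gt$gene[g])
      for (j in seq_along(als)) {
        if (m[j] == 0) next
        rows[[length(rows) + 1L]] <- data.table::data.table(
          gene = gt$gene[g], allele = als[j],
          umi = vapply(seq_len(m[j]), function(i) rand_dna(config$umi_len),
                       character(1)))
      }
    }
    mols <- data.table::rbindlist(rows)
    mols[, molecule_id := seq_len(.N)]
    data.table::setcolorder(mols, c("molecule_id", "gene", "allele", "umi"))
    tab <- table(mols$umi)
    data.table::setattr(mols, "collisions",
                        sum(choose(as.integer(tab[tab > 1]), 2)))
    mols[]
  })
}

# branching-process PCR: each copy duplicates with probability eff per
# cycle; a new copy inherits its parent's substitutions and may gain more.
# Mutations are tracked as sparse "pos>base" tokens over UMI + template.
pcr_amplify <- function(n_mols, full_len, cycles, eff, error_rate) {
  mol <- seq_len(n_mols)
  muts <- rep("", n_mols)
  for (cy in seq_len(cycles)) {
    if (eff <= 0) break
    dup <- which(rbinom(length(mol), 1, eff) == 1)
    if (length(dup) == 0) next
    newmuts <- muts[dup]
    nmut <- rpois(length(dup), error_rate * full_len)
    hit <- which(nmut > 0)
    for (h in hit) {
      pos <- sample.int(full_len, min(nmut[h], full_len))
      tok <- paste(pos, sample(c("A", "C", "G", "T"), length(pos), TRUE),
                   sep = ">", collapse = ";")
      newmuts[h] <- if (nzchar(newmuts[h])) paste(newmuts[h], tok, sep = ";")
                    else tok
    }
    mol <- c(mol, mol[dup])
    muts <- c(muts, newmuts)
  }
  data.table::data.table(mol = mol, muts = muts)
}

apply_mut_tokens <- function(seqs, muts) {
  hit <- which(nzchar(muts))
  for (h in hit) {
    for (tok in strsplit(muts[h], ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(tok, ">", fixed = TRUE)[[1]]
      p <- as.integer(kv[1])
      if (p <= nchar(seqs[h])) substr(seqs[h], p, p) <- kv[2]
    }
  }
  seqs
}

apply_seq_errors <- function(seqs, e) {
  if (e <= 0 || length(seqs) == 0) return(seqs)
  nerr <- rbinom(length(seqs), nchar(seqs), e)
  hit <- which(nerr > 0)
  for (h in hit) {
    pos <- sample.int(nchar(seqs[h]), nerr[h])
    for (p in pos) {
      old <- substr(seqs[h], p, p)
      substr(seqs[h], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  seqs
}

#' Amplify molecules and sequence them to FASTQ
#'
#' Applies the branching-process PCR (per-copy substitutions, UMI
#' included), then sequences every final copy: R1 = UMI prefix + 5'
#' template bases up to the read length; in paired mode an R2 covering a
#' random template window (reverse-complement orientation) is emitted per
#' copy. Sequencing substitutions occur per base at the quality-implied
#' rate `10^(-q/10)` and qualities are written as phred+33. Read names
#' encode the molecule and copy (`M<molecule>:<copy>`) for auditing.
#'
#' @param molecules a [simulate_molecules()] truth table.
#' @param config the [sim_config()].
#' @param alleles the [make_alleles()] result.
#' @param dir output directory for the FASTQ file(s).
#' @param prefix file-name prefix.
#' @param draw_seed seed for the PCR + sequencing draw; two different
#'   draw seeds give independent sequencing replicates of the same
#'   molecule pool.
#' @return list with `fastq1`, `fastq2` (NULL when single-end), `n_reads`
#'   and the per-molecule `copies` table.
#' @export
pcr_and_sequence <- function(molecules, config, alleles, dir = tempdir(),
                             prefix = "sim", draw_seed = config$seed + 2L) {
  if (nrow(molecules) == 0) stop("no molecules to sequence")
  with_seed(draw_seed, {
    L <- config$umi_len
    tlen1 <- config$read_len - L            # template bases in R1
    catalog <- unclass(alleles$catalog)
    template <- catalog[molecules$allele]
    full_len <- L + config$seq_len

    copies <- pcr_amplify(nrow(molecules), full_len, config$pcr_cycles,
                          config$pcr_efficiency, config$pcr_error)
    mi <- copies$mol
    data.table::setorder(copies, mol)
    copy_no <- copies[, seq_len(.N), by = mol]$V1
    mi <- copies$mol

    full <- paste0(molecules$umi[mi], template[mi])
    full <- apply_mut_tokens(full, copies$muts)

    qv <- rep_len(config$q, max(config$read_len, config$r2_len))
    # constant-quality fast path; per-position profiles fall back to the
    # position-wise rate below
    r1 <- substr(full, 1, L + min(tlen1, config$seq_len))
    e1 <- 10^(-qv[seq_len(nchar(r1[1]))] / 10)
    if (length(unique(config$q)) == 1) {
      r1 <- apply_seq_errors(r1, e1[1])
    } else {
      for (p in seq_len(nchar(r1[1]))) {
        flip <- which(runif(length(r1)) < e1[p])
        for (h in flip) {
          old <- substr(r1[h], p, p)
          substr(r1[h], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
    }
    q1 <- phred_to_string(qv[seq_len(nchar(r1[1]))] )
    ids <- sprintf("M%d:%d", molecules$molecule_id[mi], copy_no)

    fastq1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
    write_fastq(ids, r1, q1, fastq1)
    fastq2 <- NULL
    if (config$paired) {
      tpl <- substring(full, L + 1L)
      r2len <- min(config$r2_len, config$seq_len)
      omax <- config$seq_len - r2len + 1L
      off <- sample.int(omax, length(tpl), replace = TRUE)
      r2 <- substr(tpl, off, off + r2len - 1L)
      r2 <- revcomp(r2)
      if (length(unique(config$q)) == 1) {
        r2 <- apply_seq_errors(r2, 10^(-qv[1] / 10))
      } else {
        e2 <- 10^(-qv[seq_len(r2len)] / 10)
        for (p in seq_len(r2len)) {
          flip <- which(runif(length(r2)) < e2[p])
          for (h in flip) {
            old <- substr(r2[h], p, p)
            substr(r2[h], p, p) <- sample(setdiff(c("A","C","G","T"), old), 1)
          }
        }
      }
      q2 <- phred_to_string(qv[seq_len(r2len)])
      fastq2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
      write_fastq(ids, r2, q2, fastq2)
    }
    list(fastq1 = fastq1, fastq2 = fastq2, n_reads = length(ids),
         copies = copies[, .(copies = .N), by = mol])
  })
}

write_fastq <- function(ids, seqs, qual, path) {
  qv <- if (length(qual) == length(seqs)) qual else rep(qual, length(seqs))
  sr <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(seqs),
    quality = Biostrings::BStringSet(qv),
    id = Biostrings::BStringSet(ids))
  if (file.exists(path)) file.remove(path)
  ShortRead::writeFastq(sr, path, compress = FALSE)
  invisible(path)
}

#' Write a simulation truth table to TSV
#'
#' @param molecules a [simulate_molecules()] table.
#' @param copies per-molecule sequenced-copy counts
#'   (from [pcr_and_sequence()]).
#' @param path output TSV path.
#' @export
write_truth <- function(molecules, copies, path) {
  t <- merge(molecules, copies, by.x = "molecule_id", by.y = "mol",
             all.x = TRUE)
  t[is.na(copies), copies := 0L]
  data.table::fwrite(t[, .(molecule_id, allele, umi, copies)], path,
                     sep = "\t")
  invisible(path)
}

#' One-call simulation: alleles, molecules and FASTQ
#'
#' Convenience wrapper running [make_alleles()], [simulate_molecules()]
#' and [pcr_and_sequence()] under one config.
#'
#' @inheritParams pcr_and_sequence
#' @param config a [sim_config()].
#' @return list with `alleles`, `molecules` (truth) and the
#'   [pcr_and_sequence()] output under `seqrun`.
#' @export
simulate_reads <- function(config, dir = tempdir(), prefix = "sim",
                           draw_seed = config$seed + 2L) {
  alleles <- make_alleles(config)
  molecules <- simulate_molecules(config, alleles)
  seqrun <- pcr_and_sequence(molecules, config, alleles, dir = dir,
                             prefix = prefix, draw_seed = draw_seed)
  list(alleles = alleles, molecules = molecules, seqrun = seqrun)
}
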