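# fixtures are built in code at test time; nothing is stored on disk

write_tmp_fasta <- function(seqs, headers = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", headers, "\n", unname(seqs)), path)
  path
}

write_tmp_genotypes <- function(gt) {
  path <- tempfile(fileext = ".tsv")
  data.table::fwrite(gt, path, sep = "\t", col.names = FALSE)
  path
}

# a tiny two-gene catalog with known polymorphic positions
toy_catalog <- function() {
  set.seed(42)
  base_a <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  a2 <- base_a
  substr(a2, 30, 30) <- switch(substr(a2, 30, 30), A = "C", C = "G",
                               G = "T", T = "A")
  substr(a2, 80, 80) <- switch(substr(a2, 80, 80), A = "G", C = "T",
                               G = "A", T = "C")
  base_b <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  seqs <- c("A*01:01" = base_a, "A*02:01" = a2, "B*07:02" = base_b)
  structure(seqs, class = "hla_catalog")
}

toy_genotypes <- function() {
  data.table::data.table(sample = "S1", gene = c("A", "B"),
                         allele1 = c("A*01:01", "B*07:02"),
                         allele2 = c("A*02:01", NA))
}

# manual tagged reads (already UMI-extracted)
tagged_reads <- function(seqs, umis, ids = NULL,
                         quals = strrep("I", nchar(seqs))) {
  ids <- ids %||% sprintf("r%03d", seq_along(seqs))
  data.table::data.table(id = paste0(ids, "_", umis), mate = 0L,
                         seq = seqs, qual = quals, umi = umis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run the simulator and the full in-memory pipeline in one go
run_sim_pipeline <- function(cfg, draw_seed = cfg$seed + 2L, ...) {
  sim <- simulate_reads(cfg, draw_seed = draw_seed)
  reads <- extract_umis(sim$seqrun$fastq1, sim$seqrun$fastq2)
  res <- quantify_sample(reads, sim$alleles$catalog, sim$alleles$genotypes,
                         cfg$sample_id, ...)
  list(sim = sim, reads = reads, res = res)
}
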