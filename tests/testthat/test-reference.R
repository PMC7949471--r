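test_that("FASTA catalogs parse plain and IMGT-style headers", {
  fa <- write_tmp_fasta(c("ACGTACGT", "ACGTACGA"),
                        headers = c("A*01:01", "A*02:01"))
  cat1 <- read_allele_fasta(fa)
  expect_length(cat1, 2)
  expect_named(cat1, c("A*01:01", "A*02:01"))

  fa2 <- write_tmp_fasta("ACGTACGTACGT",
                         headers = "HLA:HLA00001 A*01:01:01:01 3503 bp")
  cat2 <- read_allele_fasta(fa2)
  expect_named(cat2, "A*01:01")
})

test_that("catalog parsing rejects empty files, empty records and collisions", {
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(read_allele_fasta(empty))
  expect_error(read_allele_fasta(write_tmp_fasta("", "A*01:01")),
               "empty sequence")
  # distinct sequences truncating to the same 2-field name
  fa <- write_tmp_fasta(c("ACGTACGT", "ACGTACGA"),
                        headers = c("A*01:01:01", "A*01:01:02"))
  expect_error(read_allele_fasta(fa), "collision")
  # identical sequences are collapsed
  fa2 <- write_tmp_fasta(c("ACGTACGT", "ACGTACGT"),
                         headers = c("A*01:01:01", "A*01:01:02"))
  expect_length(read_allele_fasta(fa2), 1)
})

test_that("allele name normalization truncates to 2 fields", {
  expect_equal(normalize_allele_name("A*01:01:01:01"), "A*01:01")
  expect_equal(normalize_allele_name("DRB1*15:01"), "DRB1*15:01")
  expect_error(normalize_allele_name("rubbish"))
  expect_equal(gene_of_allele(c("C*06:02", "DQB1*06:02")), c("C", "DQB1"))
})

test_that("personalized references hold the sample's alleles only", {
  catalog <- toy_catalog()
  gt <- data.table::data.table(
    sample = c("S1", "S1", "S2"), gene = c("A", "B", "A"),
    allele1 = c("A*01:01", "B*07:02", "A*99:99"),
    allele2 = c("A*02:01", NA, NA))
  ref <- build_personalized_reference(catalog, gt, "S1")
  expect_length(ref$alleles$A, 2)
  expect_length(ref$alleles$B, 1)
  expect_identical(names(ref$alleles$A), c("A*01:01", "A*02:01"))
  # allele absent from the catalog names sample, gene and allele
  expect_error(build_personalized_reference(catalog, gt, "S2"),
               "S2.*A.*A\\*99:99")
  expect_error(build_personalized_reference(catalog, gt, "nope"),
               "not in genotype table")
})

test_that("a homozygote listed twice contributes one sequence", {
  catalog <- toy_catalog()
  gt <- data.table::data.table(sample = "S1", gene = "A",
                               allele1 = "A*01:01", allele2 = "A*01:01")
  ref <- build_personalized_reference(catalog, gt, "S1")
  expect_length(ref$alleles$A, 1)
})

test_that("single-allele genes give a trivial gapless MSA", {
  catalog <- toy_catalog()
  ref <- build_personalized_reference(catalog, toy_genotypes(), "S1")
  msa <- align_gene_alleles(ref, "B")
  expect_identical(unname(msa$rows), unname(unclass(catalog)["B*07:02"]))
  expect_identical(msa$colmap[["B*07:02"]], seq_len(120))
})

test_that("substitution-only allele pairs align without gaps", {
  catalog <- toy_catalog()
  ref <- build_personalized_reference(catalog, toy_genotypes(), "S1")
  msa <- align_gene_alleles(ref, "A")
  expect_false(any(grepl("-", msa$rows, fixed = TRUE)))
  expect_length(unique(nchar(msa$rows)), 1)
})

test_that("a deletion produces a gap run and the ungapping invariant holds", {
  # periodic sequence: a split gap would shift the register and mismatch,
  # so the optimal alignment must carry one contiguous 3-column gap run
  s1 <- strrep("ACGT", 15)
  s2 <- paste0(substr(s1, 1, 25), substr(s1, 29, 60))  # 3-base deletion
  catalog <- structure(c("A*01:01" = s1, "A*02:01" = s2),
                       class = "hla_catalog")
  gt <- data.table::data.table(sample = "S1", gene = "A",
                               allele1 = "A*01:01", allele2 = "A*02:01")
  ref <- build_personalized_reference(catalog, gt, "S1")
  msa <- align_gene_alleles(ref, "A")
  expect_true(grepl("---", msa$rows[["A*02:01"]], fixed = TRUE))
  expect_identical(gsub("-", "", msa$rows[["A*01:01"]]), s1)
  expect_identical(gsub("-", "", msa$rows[["A*02:01"]]), s2)
  # pairwise global score matches the exhaustive DP oracle (linear gap -2)
  got <- hlaumi:::.align_pairwise_cpp(s2, s1, 1, -1, 0, 2, FALSE, TRUE)[[1]]
  expect_equal(got$score,
               oracle_align_score(s2, s1, open = 0, ext = 2,
                                  free_ends = FALSE))
})

test_that("MSA rows always reproduce their input when ungapped", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(30:60, 1)
    s1 <- random_dna(n)
    # random edit: substitution, deletion or insertion
    kind <- sample(c("sub", "del", "ins"), 1)
    pos <- sample(5:(n - 5), 1)
    s2 <- switch(kind,
      sub = { x <- s1; substr(x, pos, pos) <- "A"; x },
      del = paste0(substr(s1, 1, pos), substr(s1, pos + 3, n)),
      ins = paste0(substr(s1, 1, pos), "ACG", substr(s1, pos + 1, n)))
    catalog <- structure(c("A*01:01" = s1, "A*02:01" = s2),
                         class = "hla_catalog")
    gt <- data.table::data.table(sample = "S1", gene = "A",
                                 allele1 = "A*01:01", allele2 = "A*02:01")
    msa <- align_gene_alleles(
      build_personalized_reference(catalog, gt, "S1"), "A")
    expect_identical(gsub("-", "", msa$rows[["A*01:01"]]), s1)
    expect_identical(gsub("-", "", msa$rows[["A*02:01"]]), s2)
    expect_length(unique(nchar(msa$rows)), 1)
    # column maps strictly increasing
    for (cm in msa$colmap) expect_true(all(diff(cm) > 0))
  }
})

test_that("column entropy has its closed-form values and bounds", {
  # 50/50 biallelic column: H = ln 2
  expect_equal(shannon_entropy(c("A", "C")), log(2))
  # monomorphic column: H = 0
  expect_equal(shannon_entropy(c("G", "G", "G")), 0)
  # 2:1 column, direct evaluation of -(2/3)ln(2/3) - (1/3)ln(1/3)
  expect_equal(shannon_entropy(c("A", "A", "C")),
               -(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3))
  expect_equal(shannon_entropy(c("A", "A", "C")), 0.6365142, tolerance = 1e-6)
  # any two equally frequent symbols give ln 2; bounds 0 <= H <= ln(k)
  set.seed(3)
  for (i in 1:20) {
    pair <- sample(c("A", "C", "G", "T", "-"), 2)
    expect_equal(shannon_entropy(pair), log(2))
    k <- sample(2:6, 1)
    H <- shannon_entropy(sample(c("A", "C", "G", "T"), k, TRUE))
    expect_gte(H, 0)
    expect_lte(H, log(k) + 1e-12)
  }
})

test_that("key sites are the high-entropy gap-free columns", {
  catalog <- toy_catalog()
  ref <- build_personalized_reference(catalog, toy_genotypes(), "S1")
  msa <- align_gene_alleles(ref, "A")
  ks <- find_key_sites(msa)
  expect_identical(ks$column, c(30L, 80L))
  expect_equal(ks$entropy, rep(log(2), 2))
  expect_identical(dim(ks$bases), c(2L, 2L))
  # the per-allele bases disagree at every key site
  expect_true(all(ks$bases[, 1] != ks$bases[, 2]))
  # threshold above ln 2 removes everything
  expect_length(find_key_sites(msa, threshold = 0.7)$column, 0)
  # log base 2 rescales the entropy to 1 per biallelic site
  expect_equal(find_key_sites(msa, log_base = 2)$entropy, rep(1, 2))
})

test_that("identical or single alleles yield an empty key-site table", {
  s <- random_dna(50)
  catalog <- structure(c("A*01:01" = s, "B*07:02" = s),
                       class = "hla_catalog")
  gt <- data.table::data.table(sample = "S1", gene = c("A", "B"),
                               allele1 = c("A*01:01", "B*07:02"),
                               allele2 = NA_character_)
  ref <- build_personalized_reference(catalog, gt, "S1")
  expect_length(find_key_sites(align_gene_alleles(ref, "A"))$column, 0)
  # two *identical sequences* under different names
  catalog2 <- structure(c("A*01:01" = s, "A*02:01" = s),
                        class = "hla_catalog")
  gt2 <- data.table::data.table(sample = "S1", gene = "A",
                                allele1 = "A*01:01", allele2 = "A*02:01")
  ref2 <- build_personalized_reference(catalog2, gt2, "S1")
  expect_length(find_key_sites(align_gene_alleles(ref2, "A"))$column, 0)
})

test_that("gap columns are excluded unless indel sites are requested", {
  s1 <- "ACGTACGTACGTACGTACGT"
  s2 <- "ACGTACGTACGTACGT"        # 4-base deletion somewhere
  catalog <- structure(c("A*01:01" = s1, "A*02:01" = s2),
                       class = "hla_catalog")
  gt <- data.table::data.table(sample = "S1", gene = "A",
                               allele1 = "A*01:01", allele2 = "A*02:01")
  msa <- align_gene_alleles(
    build_personalized_reference(catalog, gt, "S1"), "A")
  expect_length(find_key_sites(msa)$column, 0)
  with_gaps <- find_key_sites(msa, include_indel_sites = TRUE)
  expect_gt(length(with_gaps$column), 0)
  expect_true(anyNA(with_gaps$pos))
})

test_that("key-site tables export to long format", {
  catalog <- toy_catalog()
  ref <- build_personalized_reference(catalog, toy_genotypes(), "S1")
  idx <- build_sample_index(ref)
  long <- key_sites_as_table(idx$sites)
  expect_identical(names(long),
                   c("gene", "msa_column", "entropy", "allele", "base"))
  expect_identical(nrow(long), 4L)  # 2 sites x 2 alleles, gene B empty
})
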