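#' Quantify one sample from tagged reads (in-memory pipeline)
#'
#' Runs the per-sample core of the pipeline: build the personalized
#' reference and its key-site index, align reads (or accept imported
#' hits), cluster UMIs, assign each UMI group and count deduplicated
#' molecules.
#'
#' @param reads tagged-read table ([extract_umis()]).
#' @param catalog allele catalog ([read_allele_fasta()]).
#' @param genotypes genotype table.
#' @param sample sample id.
#' @param hits optional pre-computed hit table (e.g. [read_maf()] imports,
#'   rbind-ed over R1/R2/paired files); computed with [find_candidates()]
#'   when NULL.
#' @param threshold entropy threshold for key sites.
#' @param log_base entropy log base.
#' @param min_identity,min_aln_len alignment filters.
#' @param tie_policy,min_likelihood assignment options ([assign_umi()]).
#' @param seed seed for the `random` tie policy.
#' @return list with `index`, `hits`, `clusters`, `groups`, `assignments`,
#'   `counts` and a `report` list (tallies of reads, groups, routes,
#'   ambiguous/unassigned, dropped reads, parameters).
#' @export
quantify_sample <- function(reads, catalog, genotypes, sample,
                            hits = NULL, threshold = 0.5,
                            log_base = exp(1), min_identity = 90,
                            min_aln_len = 50,
                            tie_policy = "ambiguous", min_likelihood = 0,
                            seed = 1) {
  ref <- build_personalized_reference(catalog, genotypes, sample)
  index <- build_sample_index(ref, threshold = threshold,
                              log_base = log_base)
  if (is.null(hits))
    hits <- find_candidates(reads, ref, min_identity = min_identity,
                            min_aln_len = min_aln_len)
  aligned <- reads[id %in% unique(hits$id)]
  clusters <- cluster_umis(aligned$umi)
  groups <- read_groups(aligned, clusters)
  assignments <- with_seed(seed,
    assign_umis(hits, groups, index, tie_policy = tie_policy,
                min_likelihood = min_likelihood))
  counts <- count_alleles(assignments, sample,
                          alleles = names(ref_sequences(ref)))
  report <- list(
    sample = sample,
    n_reads = nrow(reads),
    n_aligned_reads = nrow(aligned),
    n_dropped_umi = attr(reads, "dropped") %||% 0L,
    n_umi_groups = length(unique(groups$group)),
    n_unique_route = sum(assignments$route == "unique"),
    n_likelihood_route = sum(assignments$route == "likelihood"),
    ambiguous = attr(counts, "ambiguous"),
    unassigned = attr(counts, "unassigned"),
    parameters = list(threshold = threshold, log_base = log_base,
                      min_identity = min_identity,
                      min_aln_len = min_aln_len, tie_policy = tie_policy,
                      min_likelihood = min_likelihood, seed = seed))
  list(index = index, hits = hits, clusters = clusters, groups = groups,
       assignments = assignments, counts = counts, report = report)
}

#' Score assignments against a simulation truth table
#'
#' Maps each UMI group back to its originating molecules through the
#' audit read names (`M<molecule>:<copy>`), flags barcode collisions
#' (groups pooling molecules of more than one origin), and marks a group
#' correct when its decision equals its molecules' true allele.
#'
#' @param result a [quantify_sample()] result.
#' @param reads the tagged reads the result was computed from.
#' @param truth the [simulate_molecules()] truth table.
#' @return data.table per UMI group: `group`, `n_molecules`,
#'   `true_allele` (NA for cross-allele collisions), `decision`,
#'   `correct`.
#' @export
evaluate_against_truth <- function(result, reads, truth) {
  rg <- result$groups
  mol <- as.integer(sub("^M([0-9]+):.*$", "\\1", sub("_[ACGTN]+$", "",
                                                     rg$id)))
  gm <- unique(data.table::data.table(group = rg$group, molecule = mol))
  gm <- merge(gm, truth[, .(molecule = molecule_id, allele)],
              by = "molecule")
  per <- gm[, .(n_molecules = data.table::uniqueN(molecule),
                true_allele = if (data.table::uniqueN(allele) == 1)
                  allele[1] else NA_character_), by = group]
  out <- merge(per, result$assignments[, .(group, decision)], by = "group")
  out[, correct := !is.na(true_allele) & decision == true_allele]
  out[]
}

#' Validate and normalize a pipeline run configuration
#'
#' @param config list or path to a YAML file. Required fields: `fasta`,
#'   `genotypes`, `sample`, and either `fastq1` (with optional `fastq2`)
#'   or `maf` (one or more MAF paths). Optional: `outdir`, `route`
#'   (`cdna` or `amplicon`), `library_sizes` (TSV sample/total, cdna
#'   route), `cdna_norm` (normalized cDNA TSV, amplicon route),
#'   `umi_len`, `umi_mate`, `threshold`, `log_base`, `min_identity`,
#'   `min_aln_len`, `tie_policy`, `min_likelihood`, `seed`.
#' @return validated config list with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(route = "cdna", umi_len = 10, umi_mate = 1,
                   threshold = 0.5, log_base = exp(1), min_identity = 90,
                   min_aln_len = 50, tie_policy = "ambiguous",
                   min_likelihood = 0, seed = 1, outdir = NULL,
                   fastq2 = NULL, maf = NULL, library_sizes = NULL,
                   cdna_norm = NULL)
  config <- modifyList(defaults, config)
  for (f in c("fasta", "genotypes", "sample"))
    if (is.null(config[[f]])) stop("config is missing '", f, "'")
  if (is.null(config$fastq1) && is.null(config$maf))
    stop("config needs 'fastq1' (FASTQ input) or 'maf' (LAST import)")
  for (f in c("fasta", "genotypes", "fastq1", "fastq2", "library_sizes",
              "cdna_norm"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config path does not exist (", f, "): ", config[[f]])
  for (m in config$maf)
    if (!file.exists(m)) stop("config path does not exist (maf): ", m)
  if (!config$route %in% c("cdna", "amplicon"))
    stop("route must be 'cdna' or 'amplicon'")
  if (config$route == "amplicon" && is.null(config$cdna_norm))
    stop("route 'amplicon' requires 'cdna_norm' ",
         "(CPM-normalized cDNA table to scale against)")
  config
}

#' Run the full pipeline from a configuration
#'
#' Executes build-ref, find-sites, extract, align (or MAF import),
#' cluster, assign, count and normalize, writing intermediate TSVs and a
#' JSON run report to `outdir` when given. Identical config and inputs
#' give identical outputs.
#'
#' @param config list or YAML path (see [validate_run_config()]).
#' @return the [quantify_sample()] result list, extended with `normalized`
#'   (when normalization inputs were supplied) and `config`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  catalog <- read_allele_fasta(config$fasta)
  genotypes <- read_genotype_table(config$genotypes)

  hits <- NULL
  if (!is.null(config$maf)) {
    ref <- build_personalized_reference(catalog, genotypes, config$sample)
    hits <- data.table::rbindlist(lapply(config$maf, read_maf, ref = ref))
    reads <- data.table::data.table(
      id = unique(hits$id),
      mate = 0L, seq = "", qual = "",
      umi = parse_name_encoded_umi(unique(hits$id)))
  } else {
    reads <- extract_umis(config$fastq1, config$fastq2,
                          umi_len = config$umi_len,
                          umi_mate = config$umi_mate)
  }
  res <- quantify_sample(reads, catalog, genotypes, config$sample,
                         hits = hits, threshold = config$threshold,
                         log_base = config$log_base,
                         min_identity = config$min_identity,
                         min_aln_len = config$min_aln_len,
                         tie_policy = config$tie_policy,
                         min_likelihood = config$min_likelihood,
                         seed = config$seed)
  res$config <- config

  if (config$route == "cdna" && !is.null(config$library_sizes)) {
    sizes <- data.table::fread(config$library_sizes, header = FALSE)
    res$normalized <- cpm_normalize(res$counts,
                                    setNames(sizes[[2]],
                                             as.character(sizes[[1]])))
  } else if (config$route == "amplicon") {
    cdna <- data.table::fread(config$cdna_norm)
    res$normalized <- amplicon_scale(res$counts, cdna)
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outdir, f)
    data.table::fwrite(key_sites_as_table(res$index$sites),
                       out("key_sites.tsv"), sep = "\t")
    data.table::fwrite(res$assignments, out("assignments.tsv"), sep = "\t")
    data.table::fwrite(res$counts, out("counts.tsv"), sep = "\t")
    if (!is.null(res$normalized))
      data.table::fwrite(res$normalized, out("normalized.tsv"), sep = "\t")
    report <- c(res$report,
                list(route = config$route,
                     package_version =
                       as.character(utils::packageVersion("hlaumi"))))
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  res
}
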