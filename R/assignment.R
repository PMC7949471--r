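#' Probability of an observed base given a reference allele base
#'
#' `p(b | A) = 1 - e` when the read base matches the allele base and
#' `e / 3` otherwise, with the phred error probability `e = 10^(-q/10)`.
#' The four base probabilities at a site sum to one for any q.
#'
#' @param b observed base(s), one of A/C/G/T.
#' @param q phred score(s) of the observed base.
#' @param ref_base reference allele base(s) at the site.
#' @return numeric vector of probabilities.
#' @export
site_probability <- function(b, q, ref_base) {
  if (any(!b %in% c("A", "C", "G", "T")) ||
      any(!ref_base %in% c("A", "C", "G", "T")))
    stop("site_probability is defined over A/C/G/T bases only")
  if (any(q < 0)) stop("negative phred score")
  e <- 10^(-q / 10)
  ifelse(b == ref_base, 1 - e, e / 3)
}

#' Aggregate a UMI group's site observations into evidence
#'
#' Member reads of one UMI group may cover the same key site several times,
#' possibly with conflicting bases; the model needs a single observed base
#' per site. Resolution per (gene, column): keep the highest-quality
#' observations, take the majority base among them, and break remaining
#' ties by the lexicographically smallest base (its maximal q is kept).
#'
#' @param observations data.table of member-read site observations
#'   (`gene`, `column`, `base`, `q`; an `id` column is ignored).
#' @param candidates character vector of candidate allele names (union of
#'   the member reads' hits).
#' @param group_id identifier for the group.
#' @return object of class `umi_evidence`: list with `group_id`,
#'   `candidates`, `obs` (one row per gene x column) and `n` (named
#'   per-gene count of covered key sites).
#' @export
aggregate_group_observations <- function(observations, candidates,
                                         group_id = NA) {
  obs <- data.table::as.data.table(observations)
  if (nrow(obs) == 0) {
    resolved <- empty_observations()
  } else {
    resolved <- obs[, {
      qm <- max(q)
      bb <- base[q == qm]
      tb <- table(bb)
      win <- sort(names(tb)[tb == max(tb)])[1]
      list(base = win, q = qm)
    }, by = .(gene, column)]
  }
  n <- if (nrow(resolved) > 0) {
    tapply(resolved$column, resolved$gene, length)
  } else {
    integer(0)
  }
  structure(list(group_id = group_id, candidates = sort(unique(candidates)),
                 obs = resolved[], n = n),
            class = "umi_evidence")
}

#' Likelihood of a UMI group under one reference allele
#'
#' `P(U | A_i) = (1/n) * sum_k p(b_k | A_ik)` over the `n` key polymorphic
#' sites of the allele's gene covered by the group's reads: the arithmetic
#' mean of the per-site base probabilities, a value in (0, 1] comparable
#' across genes.
#'
#' @param evidence an [aggregate_group_observations()] result.
#' @param allele candidate allele name.
#' @param sites the gene's `key_site_table` (or a per-gene list of tables).
#' @return the likelihood value.
#' @export
umi_likelihood <- function(evidence, allele, sites) {
  gene <- gene_of_allele(allele)
  if (!inherits(sites, "key_site_table")) sites <- sites[[gene]]
  if (is.null(sites) || !identical(sites$gene, gene))
    stop("key-site table does not cover gene ", gene)
  obs <- evidence$obs[which(evidence$obs$gene == gene)]
  if (nrow(obs) == 0)
    stop("no covered key sites for gene ", gene, " (n = 0)")
  ref_base <- sites$bases[match(obs$column, sites$column), allele]
  if (anyNA(ref_base))
    stop("observation at a column absent from the key-site table")
  mean(site_probability(obs$base, obs$q, ref_base))
}

#' Assign one UMI group to an allele
#'
#' A group whose reads hit only one allele takes the `unique` route and is
#' counted to that allele without computing a likelihood. With several
#' candidates, `P(U | A_i)` is evaluated for each (cross-gene candidates
#' are compared directly on this normalized scale) and the strict argmax
#' wins; exact ties follow `tie_policy` (`ambiguous` excludes the group
#' from counts, `random` draws one of the tied alleles, `fractional`
#' splits the count). A multi-candidate group covering no key site is
#' `unassigned`, as is one whose best likelihood falls below
#' `min_likelihood`.
#'
#' @param evidence an [aggregate_group_observations()] result.
#' @param sites per-gene list of `key_site_table`s (or a single table).
#' @param tie_policy one of `"ambiguous"`, `"random"`, `"fractional"`.
#' @param min_likelihood decisions with a smaller best likelihood are
#'   routed to unassigned (0 disables the floor).
#' @return object of class `umi_assignment`: list with `group_id`, `route`
#'   (`unique` or `likelihood`), `likelihoods` (named, empty for the unique
#'   route), `decision` (allele name, `"ambiguous"` or `"unassigned"`) and
#'   `shares` (named fractional counts; used by the `fractional` policy).
#' @export
assign_umi <- function(evidence, sites,
                       tie_policy = c("ambiguous", "random", "fractional"),
                       min_likelihood = 0) {
  tie_policy <- match.arg(tie_policy)
  if (inherits(sites, "key_site_table")) sites <- setNames(list(sites),
                                                           sites$gene)
  cand <- evidence$candidates
  if (length(cand) == 0) stop("empty candidate set")
  if (length(cand) == 1) {
    return(structure(list(group_id = evidence$group_id, route = "unique",
                          likelihoods = numeric(0), decision = cand,
                          shares = setNames(1, cand)),
                     class = "umi_assignment"))
  }
  lik <- setNames(rep(NA_real_, length(cand)), cand)
  for (a in cand) {
    g <- gene_of_allele(a)
    covered <- nrow(evidence$obs[gene == g]) > 0
    lik[a] <- if (covered) umi_likelihood(evidence, a, sites[[g]]) else NA
  }
  res <- list(group_id = evidence$group_id, route = "likelihood",
              likelihoods = lik)
  if (all(is.na(lik)) || max(lik, na.rm = TRUE) < min_likelihood) {
    res$decision <- "unassigned"; res$shares <- numeric(0)
  } else {
    top <- names(lik)[!is.na(lik) & lik == max(lik, na.rm = TRUE)]
    if (length(top) == 1) {
      res$decision <- top; res$shares <- setNames(1, top)
    } else if (tie_policy == "ambiguous") {
      res$decision <- "ambiguous"; res$shares <- numeric(0)
    } else if (tie_policy == "random") {
      res$decision <- sample(top, 1)
      res$shares <- setNames(1, res$decision)
    } else {
      res$decision <- "ambiguous"
      res$shares <- setNames(rep(1 / length(top), length(top)), top)
    }
  }
  structure(res, class = "umi_assignment")
}

#' Assign every UMI group of a sample
#'
#' Builds per-group evidence from the hit table and read-group map, then
#' applies the unique-mapping shortcut or the likelihood model to each
#' group. The candidate set of a group is the union of its member reads'
#' hits.
#'
#' @param hits a [find_candidates()] (or [read_maf()]) hit table.
#' @param groups a [read_groups()] read-to-group map.
#' @param index a [build_sample_index()] result.
#' @inheritParams assign_umi
#' @return data.table with one row per UMI group: `group`, `route`,
#'   `candidates`, `n` (covered key sites, summed over genes),
#'   `likelihoods` (comma-separated `allele=value`), `decision`; attribute
#'   `assignments` holds the full `umi_assignment` list.
#' @export
assign_umis <- function(hits, groups, index,
                        tie_policy = c("ambiguous", "random", "fractional"),
                        min_likelihood = 0) {
  tie_policy <- match.arg(tie_policy)
  empty <- data.table::data.table(group = integer(0), route = character(0),
                                  candidates = character(0), n = integer(0),
                                  likelihoods = character(0),
                                  decision = character(0))
  if (nrow(hits) == 0) {
    data.table::setattr(empty, "shares",
                        data.table::data.table(group = integer(0),
                                               allele = character(0),
                                               share = numeric(0)))
    return(empty[])
  }
  obs <- project_hits(hits, index)
  cand <- unique(merge(unique(hits[, .(id, allele)]), groups,
                       by = "id")[, .(group, allele)])
  cand[, gene := gene_of_allele(allele)]

  # one resolved observation per (group, gene, column):
  # highest q, then majority base, then lexicographically smallest
  gobs <- merge(obs, groups, by = "id", allow.cartesian = TRUE)
  res_obs <- if (nrow(gobs) > 0) {
    gobs[, qm := max(q), by = .(group, gene, column)]
    top <- gobs[q == qm]
    cnt <- top[, .(votes = .N), by = .(group, gene, column, base, qm)]
    data.table::setorder(cnt, group, gene, column, -votes, base)
    res <- cnt[!duplicated(cnt[, .(group, gene, column)])]
    res[, .(group, gene, column, base, q = qm)]
  } else {
    data.table::data.table(group = integer(0), gene = character(0),
                           column = integer(0), base = character(0),
                           q = integer(0))
  }
  n_per_group <- res_obs[, .(n = .N), by = group]

  # per-candidate likelihoods: mean site probability over the covered key
  # sites of the candidate's gene
  site_long <- data.table::rbindlist(lapply(index$sites, function(ks) {
    if (length(ks$column) == 0) return(NULL)
    data.table::data.table(gene = ks$gene,
                           column = rep(ks$column, length(ks$alleles)),
                           allele = rep(ks$alleles, each = length(ks$column)),
                           ref_base = as.vector(ks$bases))
  }))
  lik <- if (nrow(res_obs) > 0 && nrow(site_long) > 0) {
    li <- merge(cand, res_obs, by = c("group", "gene"),
                allow.cartesian = TRUE)
    li <- merge(li, site_long, by = c("gene", "column", "allele"))
    li[, p := site_probability(base, q, ref_base)]
    li[, .(lik = mean(p)), by = .(group, allele)]
  } else {
    data.table::data.table(group = integer(0), allele = character(0),
                           lik = numeric(0))
  }

  full <- merge(cand, lik, by = c("group", "allele"), all.x = TRUE)
  data.table::setorder(full, group, allele)
  dec <- full[, {
    if (.N == 1) {
      list(route = "unique", decision = allele,
           likelihoods = "", shares_allele = list(allele),
           shares_val = list(1))
    } else {
      ls <- lik
      lstr <- paste(sprintf("%s=%.6g", allele, ls), collapse = ",")
      if (all(is.na(ls)) || max(ls, na.rm = TRUE) < min_likelihood) {
        list(route = "likelihood", decision = "unassigned",
             likelihoods = lstr, shares_allele = list(character(0)),
             shares_val = list(numeric(0)))
      } else {
        top <- allele[!is.na(ls) & ls == max(ls, na.rm = TRUE)]
        if (length(top) == 1) {
          list(route = "likelihood", decision = top, likelihoods = lstr,
               shares_allele = list(top), shares_val = list(1))
        } else if (tie_policy == "ambiguous") {
          list(route = "likelihood", decision = "ambiguous",
               likelihoods = lstr, shares_allele = list(character(0)),
               shares_val = list(numeric(0)))
        } else if (tie_policy == "random") {
          pick <- sample(top, 1)
          list(route = "likelihood", decision = pick, likelihoods = lstr,
               shares_allele = list(pick), shares_val = list(1))
        } else {
          list(route = "likelihood", decision = "ambiguous",
               likelihoods = lstr, shares_allele = list(top),
               shares_val = list(rep(1 / length(top), length(top))))
        }
      }
    }
  }, by = group]

  out <- merge(dec, full[, .(candidates = paste(allele, collapse = ",")),
                         by = group], by = "group")
  out <- merge(out, n_per_group, by = "group", all.x = TRUE)
  out[is.na(n), n := 0L]
  shares <- out[, .(allele = unlist(shares_allele),
                    share = unlist(shares_val)), by = group]
  out <- out[, .(group, route, candidates, n, likelihoods, decision)]
  data.table::setorder(out, group)
  data.table::setattr(out, "shares", shares[])
  out[]
}

#' Count deduplicated molecules per allele
#'
#' Each UMI group contributes exactly once: to its decided allele, or to
#' the ambiguous / unassigned side counts. Under the `fractional` tie
#' policy, tied groups contribute equal fractional shares instead (counts
#' are then non-integer).
#'
#' @param assignments an [assign_umis()] table (with its `assignments`
#'   attribute) or a list of `umi_assignment` objects.
#' @param sample sample identifier for the output rows.
#' @param alleles optional character vector fixing the output allele rows
#'   (e.g. all alleles of the personalized reference); alleles with no
#'   assigned group get a zero row.
#' @return data.table `sample`, `allele`, `count` with attributes
#'   `ambiguous` and `unassigned`.
#' @export
count_alleles <- function(assignments, sample, alleles = NULL) {
  if (data.table::is.data.table(assignments)) {
    gids <- assignments$group
    decisions <- assignments$decision
    shares <- attr(assignments, "shares")
    shared_groups <- unique(shares$group)
  } else {
    gids <- vapply(assignments, function(a) a$group_id[1], FUN.VALUE = 1)
    decisions <- vapply(assignments, `[[`, character(1), "decision")
    shares <- data.table::rbindlist(lapply(assignments, function(a) {
      if (length(a$shares) == 0) return(NULL)
      data.table::data.table(group = a$group_id, allele = names(a$shares),
                             share = unname(a$shares))
    }))
    shared_groups <- if (nrow(shares) > 0) unique(shares$group) else c()
  }
  if (anyDuplicated(gids) > 0)
    stop("duplicate UMI group id: ", gids[duplicated(gids)][1])
  unassigned <- sum(decisions == "unassigned")
  ambiguous <- sum(decisions == "ambiguous" & !gids %in% shared_groups)
  counts <- if (nrow(shares) > 0)
    shares[, .(count = sum(share)), by = allele] else
    data.table::data.table(allele = character(0), count = numeric(0))
  nm <- sort(unique(c(counts$allele, alleles)))
  out <- data.table::data.table(sample = sample, allele = nm)
  out <- merge(out, counts, by = "allele", all.x = TRUE)
  out[is.na(count), count := 0]
  out <- out[, .(sample, allele, count)]
  data.table::setorder(out, allele)
  data.table::setattr(out, "ambiguous", ambiguous)
  data.table::setattr(out, "unassigned", unassigned)
  out[]
}
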