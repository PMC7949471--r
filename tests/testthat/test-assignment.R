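test_that("site probabilities follow the phred error model", {
  expect_equal(site_probability("A", 10, "A"), 0.9)
  expect_equal(site_probability("C", 10, "A"), 0.1 / 3)
  expect_equal(site_probability("G", 30, "G"), 0.999)
  expect_error(site_probability("N", 30, "A"), "A/C/G/T")
  expect_error(site_probability("A", -1, "A"))
})

test_that("the four base probabilities at a site always sum to one", {
  for (q in c(0, 2, 10, 13.7, 20, 30, 40, 60, 93)) {
    total <- sum(vapply(c("A", "C", "G", "T"), site_probability,
                        numeric(1), q = q, ref_base = "G"))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

# evidence builder for hand-made cases: one gene "A", sites at columns
# given, two alleles with per-site bases
toy_sites <- function(columns, bases1, bases2) {
  structure(list(
    gene = "A", alleles = c("A*01:01", "A*02:01"),
    column = columns, entropy = rep(log(2), length(columns)),
    bases = matrix(c(bases1, bases2), ncol = 2,
                   dimnames = list(NULL, c("A*01:01", "A*02:01"))),
    pos = matrix(rep(columns, 2), ncol = 2,
                 dimnames = list(NULL, c("A*01:01", "A*02:01"))),
    threshold = 0.5, log_base = exp(1)), class = "key_site_table")
}

toy_evidence <- function(columns, bases, q,
                         candidates = c("A*01:01", "A*02:01")) {
  obs <- data.table::data.table(gene = "A", column = columns, base = bases,
                                q = q)
  aggregate_group_observations(obs, candidates, group_id = 1L)
}

test_that("the UMI likelihood is the mean site probability", {
  sites <- toy_sites(c(10L, 20L), c("A", "C"), c("G", "T"))
  ev <- toy_evidence(c(10L, 20L), c("A", "C"), c(20L, 20L))
  expect_equal(umi_likelihood(ev, "A*01:01", sites), 0.99)
  expect_equal(umi_likelihood(ev, "A*02:01", sites), 0.01 / 3)
  # 1 match + 1 mismatch at q = 20
  ev2 <- toy_evidence(c(10L, 20L), c("A", "T"), c(20L, 20L))
  expect_equal(umi_likelihood(ev2, "A*01:01", sites), (0.99 + 0.01 / 3) / 2)
  expect_equal(umi_likelihood(ev2, "A*01:01", sites), 0.49667, tolerance = 1e-4)
  # no covered site is an error the caller must catch
  ev0 <- toy_evidence(integer(0), character(0), integer(0))
  expect_error(umi_likelihood(ev0, "A*01:01", sites), "n = 0")
})

test_that("likelihood never increases when a site flips to mismatch", {
  sites <- toy_sites(1:4, c("A", "A", "A", "A"), c("C", "C", "C", "C"))
  liks <- vapply(0:4, function(k) {
    bases <- c(rep("C", k), rep("A", 4 - k))
    umi_likelihood(toy_evidence(1:4, bases, rep(25L, 4)), "A*01:01", sites)
  }, numeric(1))
  expect_true(all(diff(liks) < 0))
})

test_that("conflicting group observations resolve by quality then majority", {
  obs <- data.table::data.table(
    gene = "A", column = c(10L, 10L), base = c("A", "A"), q = c(30L, 20L))
  ev <- aggregate_group_observations(obs, "A*01:01")
  expect_identical(ev$obs$base, "A")
  expect_identical(ev$obs$q, 30L)

  obs2 <- data.table::data.table(
    gene = "A", column = rep(10L, 3), base = c("A", "A", "C"),
    q = rep(20L, 3))
  ev2 <- aggregate_group_observations(obs2, "A*01:01")
  expect_identical(ev2$obs$base, "A")   # majority at equal quality

  obs3 <- data.table::data.table(
    gene = "A", column = rep(10L, 2), base = c("T", "G"), q = rep(20L, 2))
  ev3 <- aggregate_group_observations(obs3, "A*01:01")
  expect_identical(ev3$obs$base, "G")   # full tie: lexicographic

  # no coverage: n is empty
  ev4 <- aggregate_group_observations(
    data.table::data.table(gene = character(0), column = integer(0),
                           base = character(0), q = integer(0)), "A*01:01")
  expect_length(ev4$n, 0)
})

test_that("single-candidate groups take the unique route", {
  sites <- toy_sites(10L, "A", "C")
  ev <- toy_evidence(integer(0), character(0), integer(0),
                     candidates = "A*01:01")
  a <- assign_umi(ev, setNames(list(sites), "A"))
  expect_identical(a$route, "unique")
  expect_identical(a$decision, "A*01:01")
  expect_length(a$likelihoods, 0)
})

test_that("multi-candidate groups go to the likelihood argmax", {
  sites <- toy_sites(c(10L, 20L), c("A", "C"), c("G", "T"))
  ev <- toy_evidence(c(10L, 20L), c("A", "C"), c(20L, 20L))
  a <- assign_umi(ev, setNames(list(sites), "A"))
  expect_identical(a$route, "likelihood")
  expect_identical(a$decision, "A*01:01")
  expect_equal(unname(a$likelihoods["A*01:01"]), 0.99)
  expect_equal(unname(a$likelihoods["A*02:01"]), 0.01 / 3, tolerance = 1e-9)

  # symmetric evidence: exact tie -> ambiguous under the default policy
  ev_tie <- toy_evidence(c(10L, 20L), c("A", "T"), c(20L, 20L))
  tie <- assign_umi(ev_tie, setNames(list(sites), "A"))
  expect_equal(unname(tie$likelihoods["A*01:01"]),
               unname(tie$likelihoods["A*02:01"]))
  expect_identical(tie$decision, "ambiguous")

  # fractional policy splits the tie
  frac <- assign_umi(ev_tie, setNames(list(sites), "A"),
                     tie_policy = "fractional")
  expect_equal(unname(frac$shares), c(0.5, 0.5))

  # random policy picks one of the tied alleles
  set.seed(1)
  rnd <- assign_umi(ev_tie, setNames(list(sites), "A"),
                    tie_policy = "random")
  expect_true(rnd$decision %in% c("A*01:01", "A*02:01"))

  # multiple candidates but no covered site -> unassigned
  ev_none <- toy_evidence(integer(0), character(0), integer(0))
  expect_identical(assign_umi(ev_none,
                              setNames(list(sites), "A"))$decision,
                   "unassigned")

  # a likelihood floor reroutes weak argmax decisions
  weak <- assign_umi(ev, setNames(list(sites), "A"), min_likelihood = 0.999)
  expect_identical(weak$decision, "unassigned")
})

test_that("counting conserves every UMI group exactly once", {
  sites <- setNames(list(toy_sites(10L, "A", "C")), "A")
  mk <- function(gid, cols, bases, q, cand = c("A*01:01", "A*02:01")) {
    ev <- aggregate_group_observations(
      data.table::data.table(gene = "A",
                             column = cols, base = bases, q = q),
      cand, group_id = gid)
    assign_umi(ev, sites)
  }
  asn <- list(
    mk(1L, 10L, "A", 30L),                       # -> A*01:01
    mk(2L, 10L, "A", 30L),                       # -> A*01:01
    mk(3L, 10L, "A", 30L, cand = "A*01:01"),     # unique
    mk(4L, integer(0), character(0), integer(0)))  # unassigned
  counts <- count_alleles(asn, "S1")
  expect_identical(counts$count[counts$allele == "A*01:01"], 3)
  expect_identical(attr(counts, "unassigned"), 1L)
  total <- sum(counts$count) + attr(counts, "ambiguous") +
    attr(counts, "unassigned")
  expect_identical(total, 4)
  # duplicate group ids are rejected
  expect_error(count_alleles(c(asn, asn[1]), "S1"), "duplicate")
  # empty assignment set gives an all-zero table
  z <- count_alleles(list(), "S1", alleles = c("A*01:01", "A*02:01"))
  expect_identical(z$count, c(0, 0))
})

test_that("assign and count equal the brute-force oracle on random instances", {
  set.seed(77)
  for (rep in 1:40) {
    n_alleles <- sample(2:3, 1)
    n_sites <- sample(1:5, 1)
    n_umis <- sample(1:20, 1)
    allele_names <- paste0("A*0", seq_len(n_alleles), ":01")
    site_cols <- sort(sample(10:60, n_sites))
    bases_mat <- matrix(sample(c("A", "C", "G", "T"),
                               n_sites * n_alleles, TRUE),
                        nrow = n_sites,
                        dimnames = list(NULL, allele_names))
    sites <- structure(list(
      gene = "A", alleles = allele_names, column = site_cols,
      entropy = rep(log(2), n_sites), bases = bases_mat,
      pos = matrix(rep(site_cols, n_alleles), ncol = n_alleles,
                   dimnames = list(NULL, allele_names)),
      threshold = 0.5, log_base = exp(1)), class = "key_site_table")
    sites_l <- setNames(list(sites), "A")

    instance <- list(
      alleles = setNames(lapply(allele_names,
                                function(a) bases_mat[, a]), allele_names),
      umis = list())
    package_asn <- list()
    for (u in seq_len(n_umis)) {
      cand <- sort(sample(allele_names, sample(seq_len(n_alleles), 1)))
      covered <- sort(sample(seq_len(n_sites), sample(0:n_sites, 1)))
      bases <- sample(c("A", "C", "G", "T"), length(covered), TRUE)
      q <- sample(c(10L, 20L, 30L, 40L), length(covered), TRUE)
      instance$umis[[u]] <- list(
        candidates = cand,
        sites = list(A = covered),
        base = list(A = bases), q = list(A = q))
      ev <- aggregate_group_observations(
        data.table::data.table(gene = rep("A", length(covered)),
                               column = site_cols[covered],
                               base = bases, q = q),
        cand, group_id = u)
      package_asn[[u]] <- assign_umi(ev, sites_l)
    }
    got <- count_alleles(package_asn, "S1", alleles = allele_names)
    want <- oracle_assign_count(instance)
    expect_equal(setNames(got$count, got$allele),
                 want$counts[sort(names(want$counts))])
    expect_identical(attr(got, "ambiguous"), as.integer(want$ambiguous))
    expect_identical(attr(got, "unassigned"), as.integer(want$unassigned))
  }
})
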