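test_that("evolve_genome: rate zero, determinism, planted identity", {
  z <- evolve_genome(evolve_spec(root_length = 2000, substitution_rate = 0,
                                 seed = 1))
  expect_identical(z$ancestor$replicons[[1]], z$derived$replicons[[1]])
  expect_equal(z$true_identity, 100)

  a <- evolve_genome(evolve_spec(root_length = 5000, substitution_rate = 0.05,
                                 seed = 42))
  b <- evolve_genome(evolve_spec(root_length = 5000, substitution_rate = 0.05,
                                 seed = 42))
  expect_identical(a$derived$replicons, b$derived$replicons)
  expect_equal(a$true_identity, 95, tolerance = 0.015)
  # substitutions always change the base: identity == 100 - mutated%
  al <- strsplit(a$alignment$root, "")[[1]]
  dl <- strsplit(a$alignment$derived, "")[[1]]
  expect_equal(100 * mean(al == dl), a$true_identity)
})

test_that("evolve_genome applies indels and gene loss coherently", {
  w <- evolve_genome(evolve_spec(root_length = 20000, substitution_rate = 0.02,
                                 indel_rate = 0.001, indel_mean = 4,
                                 gene_loss_fraction = 0.1, seed = 8))
  expect_equal(nchar(w$alignment$root), nchar(w$alignment$derived))
  expect_lt(genome_length(w$derived), 20000)     # net loss from 10% blocks
  expect_equal(w$true_identity, 98, tolerance = 0.01)
  # gapped alignment reduces to the two sequences
  expect_identical(gsub("-", "", w$alignment$derived),
                   w$derived$replicons[[1]])
})

test_that("simulate_families returns usable truth", {
  tags <- list(f1 = "shikimate", f2 = "shikimate", f3 = "shikimate",
               f4 = "shikimate", f5 = "shikimate")
  sim <- simulate_families(n_strains = 8, n_families = 5, lengths = 150,
                           tags = tags, seed = 3)
  expect_length(sim$proteomes, 8L)
  tab <- cluster_orthologs(sim$proteomes)
  sel <- select_markers(tab, required_tags = "shikimate")
  expect_length(sel, 5L)
  # every family matches a planted truth group exactly
  got <- lapply(tab$families[sel], function(df)
    sort(paste(df$strain, df$protein)))
  want <- lapply(sim$truth, function(x) sort(paste(names(x), x)))
  for (g in got)
    expect_true(any(vapply(want, identical, logical(1), g)))
})

test_that("NJ on ML distances recovers the simulation tree topology", {
  set.seed(10)
  tre <- ape::rtree(5, rooted = FALSE, tip.label = paste0("s", 1:5))
  tre$edge.length <- runif(nrow(tre$edge), 0.05, 0.15)
  sim <- simulate_families(tree = tre, n_families = 5, lengths = 400,
                           seed = 10)
  alns <- lapply(sim$sequences, aln_matrix)
  conc <- concatenate_markers(alns)
  expect_equal(ncol(conc$alignment), 2000L)
  d <- pairwise_distance(conc$alignment, "jtt")
  nj <- neighbor_joining(d)
  expect_setequal(bipartitions(nj), bipartitions(tre))
})

test_that("simulate_profiles: archetypes, noise and ND propagate", {
  arch <- list(
    high_q8 = c(aerobic.Q8 = 70, aerobic.DMK8 = 10, aerobic.MK8 = 20,
                anaerobic.Q8 = 60, anaerobic.DMK8 = 15, anaerobic.MK8 = 25),
    high_mk8 = c(aerobic.Q8 = 15, aerobic.DMK8 = 25, aerobic.MK8 = 60,
                 anaerobic.Q8 = 10, anaerobic.DMK8 = 30, anaerobic.MK8 = 60))
  who <- c(a1 = "high_q8", a2 = "high_q8", b1 = "high_mk8", b2 = "high_mk8")
  exact <- simulate_profiles(who, arch, noise_sd = 0, seed = 5)
  expect_equal(profile_correlation(exact$a1, exact$a2), 1.0)
  noisy <- simulate_profiles(who, arch, noise_sd = 0.1, seed = 5)
  within <- profile_correlation(noisy$a1, noisy$a2)
  between <- profile_correlation(noisy$a1, noisy$b1)
  expect_gt(within, between)
  # compositions renormalize to 100 per condition
  v <- noisy$a1$values
  expect_equal(sum(v[startsWith(names(v), "aerobic")]), 100)
  nd <- simulate_profiles(who, arch, noise_sd = 0,
                          nd_pattern = list(a2 = c("aerobic.DMK8")), seed = 5)
  expect_true(is.na(profile_correlation(nd$a1, nd$a2)))
})

test_that("generators are bit-reproducible and child seeds are stable", {
  expect_identical(child_seed(1, "families"), child_seed(1, "families"))
  expect_false(child_seed(1, "families") == child_seed(1, "profiles"))
  expect_false(child_seed(1, "x") == child_seed(2, "x"))
  s1 <- simulate_families(n_strains = 4, n_families = 2, lengths = 60,
                          seed = 9)
  s2 <- simulate_families(n_strains = 4, n_families = 2, lengths = 60,
                          seed = 9)
  expect_identical(s1$sequences, s2$sequences)
})
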