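test_that("fragment_ani is exactly 100 on self-comparison", {
  g <- genome_record("g", c(chr = random_seq(8000, 4)))
  res <- fragment_ani(g, g)
  expect_equal(res$ani, 100)
  expect_equal(res$n_conserved_fragments, res$n_fragments)
})

test_that("fragment_ani recovers planted identity and is monotone in rate", {
  rates <- c(0.02, 0.05, 0.10)
  got <- truth <- numeric(length(rates))
  for (k in seq_along(rates)) {
    pair <- evolve_genome(evolve_spec(root_length = 20000,
                                      substitution_rate = rates[k],
                                      seed = 100 + k))
    res <- fragment_ani(pair$ancestor, pair$derived)
    got[k] <- res$ani
    truth[k] <- pair$true_identity
    expect_lt(abs(got[k] - truth[k]), 0.5)
  }
  expect_true(all(diff(got) < 0))
  # directional asymmetry below one percentage point without indels
  pair <- evolve_genome(evolve_spec(root_length = 20000,
                                    substitution_rate = 0.05, seed = 321))
  fwd <- fragment_ani(pair$ancestor, pair$derived)$ani
  rev_ <- fragment_ani(pair$derived, pair$ancestor)$ani
  expect_lt(abs(fwd - rev_), 1)
})

test_that("gene loss removes conserved fragments roughly in proportion", {
  base <- evolve_genome(evolve_spec(root_length = 50000,
                                    substitution_rate = 0.20, seed = 55))
  lost <- evolve_genome(evolve_spec(root_length = 50000,
                                    substitution_rate = 0.20,
                                    gene_loss_fraction = 0.10, seed = 55))
  n0 <- fragment_ani(base$ancestor, base$derived)$n_conserved_fragments
  n1 <- fragment_ani(lost$ancestor, lost$derived)$n_conserved_fragments
  drop <- (n0 - n1) / n0
  expect_gt(drop, 0.04)
  expect_lt(drop, 0.18)
})

test_that("fragment_ani warns on sub-fragment genomes and flags no-hit pairs", {
  small <- genome_record("s", c(chr = random_seq(600, 5)))
  expect_warning(res <- fragment_ani(small, small), "single-fragment")
  expect_equal(res$ani, 100)
  other <- genome_record("o", c(chr = random_seq(3000, 99)))
  far <- genome_record("f", c(chr = strrep("AT", 1500)))
  res2 <- fragment_ani(far, other)
  expect_false(res2$defined)
  expect_equal(res2$ani, 0)
})

test_that("rbh_aai: self comparison, duplicates, and planted identity", {
  a <- tiny_proteome("a", n = 6, len = 120, seed = 11)
  self <- rbh_aai(a, a)
  expect_equal(self$aai, 100)
  expect_equal(self$n_orthologs, 6L)

  # a duplicated gene cannot form two reciprocal pairs
  b <- tiny_proteome("b", n = 5, len = 120, seed = 12)
  base_pairs <- rbh_aai(b, b)$n_orthologs
  dup <- protein_set("bdup", c(b$proteins,
                               dup1 = unname(b$proteins[1])))
  res <- rbh_aai(dup, b)
  expect_equal(res$n_orthologs, base_pairs)
  expect_false(anyDuplicated(res$pairs$id_b) > 0)

  # planted mean identity 0.80 recovered within 2 points
  mod <- aa_model("jtt")
  t80 <- identity_to_time(mod, 0.80)
  tre <- ape::read.tree(text = sprintf("(x:%f,y:%f);", t80 / 2, t80 / 2))
  sim <- simulate_families(tree = tre, n_families = 12, lengths = 150,
                           seed = 77)
  res <- rbh_aai(sim$proteomes$x, sim$proteomes$y)
  expect_equal(res$n_orthologs, 12L)
  expect_lt(abs(res$aai - 80), 2)
})

test_that("rbh_aai reports missing (not zero) when no pair passes", {
  a <- protein_set("a", c(p = strrep("AC", 40)))
  b <- protein_set("b", c(q = strrep("WY", 40)))
  res <- rbh_aai(a, b)
  expect_true(is.na(res$aai))
  expect_equal(res$n_orthologs, 0L)
})

test_that("pairwise_16s_identity matches forced arithmetic and simulation", {
  s <- random_seq(800, 21)
  expect_equal(pairwise_16s_identity(s, s), 100)
  # 10 substitutions in 500 bp -> 98.0
  v <- strsplit(random_seq(500, 22), "")[[1]]
  w <- v
  pos <- seq(10, 500, by = 50)
  w[pos] <- chartr("ACGT", "CGTA", w[pos])
  expect_equal(pairwise_16s_identity(paste(v, collapse = ""),
                                     paste(w, collapse = "")), 98.0)
  # simulated divergence 0.0187 ~ 98.13; oracle is the true alignment
  pair <- evolve_genome(evolve_spec(root_length = 3000,
                                    substitution_rate = 0.0187, seed = 87))
  got <- pairwise_16s_identity(pair$ancestor$replicons[[1]],
                               pair$derived$replicons[[1]])
  expect_equal(got, pair$true_identity, tolerance = 0.3 / 98)
  expect_equal(got, 98.13, tolerance = 1 / 98)
})

test_that("ddh_estimate is monotone and consistent with paired cutoffs", {
  expect_equal(ddh_estimate(100), 100)
  expect_gte(ddh_estimate(96), 70)
  expect_lt(ddh_estimate(80), 70)
  x <- seq(0, 100, by = 5)
  expect_true(all(diff(ddh_estimate(x)) > 0))
})

test_that("build_matrix averages directions and orders by divergence", {
  g <- genome_record("g1", c(chr = random_seq(4000, 31)))
  g2 <- g; g2$id <- "g2"
  m <- build_matrix(list(g, g2), function(a, b) fragment_ani(a, b)$ani,
                    kind = "ANI")
  expect_equal(m$values["g1", "g2"], 100)

  pairs <- lapply(c(0.02, 0.08, 0.15), function(r)
    evolve_genome(evolve_spec(root_length = 6000, substitution_rate = r,
                              seed = 500)))
  items <- list(pairs[[1]]$ancestor,
                pairs[[1]]$derived, pairs[[2]]$derived, pairs[[3]]$derived)
  for (i in seq_along(items)) items[[i]]$id <- paste0("s", i)
  m2 <- build_matrix(items, function(a, b) fragment_ani(a, b)$ani,
                     kind = "ANI")
  v <- m2$values["s1", c("s2", "s3", "s4")]
  expect_true(all(diff(v) < 0))          # staggered divergence ordering
  expect_true(all(m2$asymmetry < 1.5))
  expect_error(build_matrix(list(g, g2), function(a, b) stop("boom")),
               "g1.*g2")
})
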