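test_that("pairwise_distance: closed forms and degenerate inputs", {
  aln <- rbind(a = rep("A", 10), b = rep("A", 10))
  for (m in c("p", "poisson", "jtt", "dayhoff"))
    expect_equal(unname(pairwise_distance(aln, m)["a", "b"]), 0)

  x <- c(rep("A", 9), "C")              # p = 0.1
  aln <- rbind(a = rep("A", 10), b = x)
  expect_equal(unname(pairwise_distance(aln, "p")["a", "b"]), 0.1)
  expect_equal(unname(pairwise_distance(aln, "poisson")["a", "b"]),
               -log(0.9), tolerance = 1e-12)

  sat <- rbind(a = rep("A", 5), b = rep("C", 5))
  expect_error(pairwise_distance(sat, "poisson"), "saturated")

  gappy <- rbind(a = c("A", "-", "C"), b = c("A", "A", "C"))
  expect_equal(unname(pairwise_distance(gappy, "p")["a", "b"]), 0)
})

test_that("ML distances agree with the phangorn oracle and order correctly", {
  mod <- aa_model("jtt")
  pair <- simulate_aa_pair(mod, 0.4, 1200, seed = 5)
  aln <- rbind(a = pair$x, b = pair$y)
  for (m in c("jtt", "dayhoff")) {
    mine <- unname(pairwise_distance(aln, m)["a", "b"])
    ph <- phangorn::phyDat(aln, type = "AA")
    oracle <- as.numeric(phangorn::dist.ml(
      ph, model = c(jtt = "JTT", dayhoff = "Dayhoff")[[m]]))
    expect_equal(mine, oracle, tolerance = 1e-4)
  }
  # Jensen ordering p <= poisson <= ML for a divergent pair
  p <- unname(pairwise_distance(aln, "p")["a", "b"])
  po <- unname(pairwise_distance(aln, "poisson")["a", "b"])
  ml <- unname(pairwise_distance(aln, "jtt")["a", "b"])
  expect_true(p <= po && po <= ml)
})

test_that("kimura-nt matches ape's K80 implementation", {
  pair <- evolve_genome(evolve_spec(root_length = 2000,
                                    substitution_rate = 0.1, seed = 44))
  aln <- rbind(a = strsplit(pair$alignment$root, "")[[1]],
               b = strsplit(pair$alignment$derived, "")[[1]])
  mine <- unname(pairwise_distance(aln, "kimura-nt")["a", "b"])
  bin <- ape::as.DNAbin(tolower(aln))
  oracle <- as.numeric(ape::dist.dna(bin, model = "K80"))
  expect_equal(mine, oracle, tolerance = 1e-10)
})

test_that("upgma: heights, exact ultrametric recovery, tie rule", {
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(max(ape::node.depth.edgelength(t2)), 1)   # root height 1

  tru <- ape::read.tree(text = "((a:1,b:1):2,(c:2,d:2):1);")
  rec <- upgma(ape::cophenetic.phylo(tru))
  expect_setequal(bipartitions(rec), bipartitions(tru))
  expect_equal(ape::cophenetic.phylo(rec)[c("a", "b", "c", "d"),
                                          c("a", "b", "c", "d")],
               ape::cophenetic.phylo(tru)[c("a", "b", "c", "d"),
                                          c("a", "b", "c", "d")],
               tolerance = 1e-12)

  # all-ties: lowest label pair (a,b) merges first
  d3 <- matrix(2, 3, 3, dimnames = list(c("c", "a", "b"), c("c", "a", "b")))
  diag(d3) <- 0
  t3 <- upgma(d3)
  expect_true("a|b" %in% paste(bipartitions(t3)) ||
              any(vapply(ape::prop.part(t3), function(p)
                setequal(t3$tip.label[p], c("a", "b")), logical(1))))
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2,
                            dimnames = list(c("a", "b"), c("a", "b")))), "NA")
})

test_that("neighbor_joining inverts additive matrices exactly", {
  tru <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  d <- ape::cophenetic.phylo(tru)
  nj <- neighbor_joining(d)
  expect_setequal(bipartitions(nj), bipartitions(ape::unroot(tru)))
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)

  # 3 taxa: three-point formulas
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  expect_equal(ape::cophenetic.phylo(t3)[rownames(d3), colnames(d3)], d3,
               tolerance = 1e-12)

  # random 8-taxon additive matrix reproduced to 1e-9
  ra <- random_additive(8, 19)
  nj8 <- neighbor_joining(ra$d)
  expect_lt(max(abs(ape::cophenetic.phylo(nj8)[rownames(ra$d),
                                               colnames(ra$d)] - ra$d)),
            1e-9)
})

test_that("me_tree_length: OLS on additive input returns the true lengths", {
  ra <- random_additive(6, 23)
  fit <- me_tree_length(ra$tree, ra$d)
  expect_equal(fit$total, sum(ra$tree$edge.length), tolerance = 1e-9)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  expect_false(fit$negative)

  # 3-taxon star: closed-form three-point lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  star <- ape::read.tree(text = "(a,b,c);")
  fit3 <- me_tree_length(star, d3)
  expect_equal(sort(unname(fit3$lengths)), c(1, 2, 3), tolerance = 1e-12)

  # OLS residual prefers the generating topology under perturbation
  set.seed(9)
  noisy <- ra$d + matrix(runif(36, 0, 0.02), 6)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  rss_true <- me_tree_length(ra$tree, noisy)$rss
  other <- phangorn::allTrees(6, rooted = FALSE,
                              tip.label = rownames(ra$d))[[1]]
  if (setequal(bipartitions(other), bipartitions(ra$tree)))
    other <- phangorn::allTrees(6, rooted = FALSE,
                                tip.label = rownames(ra$d))[[2]]
  expect_lt(rss_true, me_tree_length(other, noisy)$rss)
})

test_that("minimum_evolution equals NJ on additive input and never exceeds NJ", {
  ra <- random_additive(7, 29)
  me <- minimum_evolution(ra$d)
  expect_setequal(bipartitions(me), bipartitions(ra$tree))
  for (s in 1:5) {
    set.seed(s)
    n <- 6
    d <- ra$d[1:n, 1:n] + matrix(runif(n * n, 0, 0.3), n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    nj_len <- me_tree_length(ape::unroot(neighbor_joining(d)), d)$total
    me_len <- attr(minimum_evolution(d), "me_length")
    expect_lte(me_len, nj_len + 1e-12)
  }
})

test_that("bootstrap_support: separable data gives 100 on the central edge", {
  # 8 taxa, two clean 4-taxon clades over 300 columns
  block <- function(ch, n) matrix(ch, nrow = 4, ncol = n)
  set.seed(42)
  noise <- matrix(sample(c("A", "C", "G", "T"), 8 * 60, replace = TRUE),
                  nrow = 8)
  aln <- cbind(rbind(block("A", 240), block("C", 240)), noise)
  rownames(aln) <- paste0("t", 1:8)
  tr <- bootstrap_support(aln, model = "p", builder = "nj",
                          replicates = 100, seed = 7)
  key <- paste(sort(paste0("t", 5:8)), collapse = "|")
  sup <- stats::setNames(as.numeric(tr$node.label),
                         vapply((length(tr$tip.label) + 1):(length(tr$tip.label) + tr$Nnode),
                                function(i) "", character(1)))
  expect_true(any(tr$node.label == "100"))
  # reproducibility for a fixed seed
  tr2 <- bootstrap_support(aln, model = "p", builder = "nj",
                           replicates = 100, seed = 7)
  expect_identical(tr$node.label, tr2$node.label)
  vals <- suppressWarnings(as.numeric(tr$node.label))
  vals <- vals[!is.na(vals)]
  expect_true(all(vals >= 0 & vals <= 100))
  # column order does not change support under the same replicate seeds
  perm <- sample(ncol(aln))
  tr3 <- bootstrap_support(aln[, perm], model = "p", builder = "nj",
                           replicates = 100, seed = 7)
  b3 <- bipartitions(tr3)
  expect_true(key %in% b3 || paste(sort(paste0("t", 1:4)), collapse = "|") %in% b3)
})
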