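# shared in-code fixtures for the suite

# additive distance matrix from a random tree with positive branch lengths
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

random_seq <- function(n, seed, letters = c("A", "C", "G", "T")) {
  set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# proteome of random sequences, deterministic
tiny_proteome <- function(id, n = 5, len = 80, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(polyphasic:::AA_ALPHABET, len, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0(id, "_p", seq_len(n))
  protein_set(id, seqs)
}

# divergence t at which the expected residue identity under `model`
# equals `target` (bisection on sum_i pi_i P_ii(t))
identity_to_time <- function(model, target) {
  f <- function(t) sum(model$pi * diag(aa_transition_prob(model, t))) - target
  stats::uniroot(f, c(1e-6, 8))$root
}
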