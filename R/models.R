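# Empirical amino-acid replacement models (JTT, Dayhoff).
#
# The exchangeability coefficients and stationary frequencies are taken at
# run time from the model data shipped with the 'phangorn' package (the
# same tables every ML phylogenetics program packages). We build the
# normalized instantaneous rate matrix Q ourselves and expose its
# eigendecomposition so that transition probabilities P(t) = exp(Qt) are
# cheap for both ML distance estimation and sequence simulation.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Empirical amino-acid substitution model
#'
#' Builds the normalized rate matrix of an empirical model from its
#' exchangeabilities `S` and stationary frequencies `pi`:
#' `Q[i,j] = S[i,j] * pi[j]`, diagonal set so rows sum to zero, scaled so
#' one unit of time equals one expected substitution per site.
#'
#' @param name `"jtt"` or `"dayhoff"`.
#' @return list with `name`, `pi` (stationary frequencies), `Q` (rate
#'   matrix) and the eigendecomposition used by [aa_transition_prob()].
#' @export
aa_model <- function(name = c("jtt", "dayhoff")) {
  name <- match.arg(name)
  key <- c(jtt = ".JTT", dayhoff = ".Dayhoff")[[name]]
  dat <- get(key, envir = environment(phangorn::dist.ml))
  S <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  S[lower.tri(S)] <- dat$Q          # column-wise lower triangle
  S <- S + t(S)
  pi <- as.numeric(dat$bf)
  names(pi) <- AA_ALPHABET
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = 20L)      # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  # symmetrized eigendecomposition: B = D^{1/2} Q D^{-1/2} is symmetric
  sp <- sqrt(pi)
  B <- Q * outer(sp, 1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(name = name, pi = pi, Q = Q,
                 eval = eig$values,
                 evec = eig$vectors * rep(1 / sp, nrow(B)),    # D^{-1/2} V
                 ivec = t(eig$vectors * rep(sp, nrow(B)))),    # V' D^{1/2}
            class = "aa_model")
}

#' Transition probability matrix P(t) of an empirical model
#'
#' @param model an [aa_model()].
#' @param t evolutionary time in expected substitutions per site.
#' @return 20 x 20 row-stochastic matrix.
#' @export
aa_transition_prob <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$evec %*% (exp(model$eval * t) * model$ivec)
  P[P < 0] <- 0                      # numerical noise near t = 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  P
}

# 20x20 table of aligned residue-pair counts (X and gaps dropped)
aa_pair_counts <- function(x, y) {
  keep <- x %in% AA_ALPHABET & y %in% AA_ALPHABET
  table(factor(x[keep], AA_ALPHABET), factor(y[keep], AA_ALPHABET))
}

#' Maximum-likelihood pairwise distance under an empirical model
#'
#' One-dimensional likelihood maximization of
#' `prod pi[i] * P[i,j](t)` over the observed aligned residue pairs.
#'
#' @param x,y character vectors of aligned residues (equal length).
#' @param model an [aa_model()].
#' @param t_max upper bound of the search interval; hitting it is
#'   reported as non-convergence.
#' @return ML distance in substitutions per site.
#' @export
aa_ml_distance <- function(x, y, model, t_max = 15) {
  N <- aa_pair_counts(x, y)
  if (sum(N) == 0L) stop("no comparable residue pairs")
  if (sum(diag(N)) == sum(N)) return(0)
  lpi <- log(model$pi)
  nll <- function(t) {
    P <- aa_transition_prob(model, t)
    lp <- log(pmax(P, 1e-300))
    -sum(N * (lpi + lp))
  }
  opt <- stats::optimize(nll, c(1e-8, t_max), tol = 1e-8)
  if (opt$minimum > t_max * 0.99)
    stop("ML distance did not converge (saturated pair?)")
  opt$minimum
}

#' Simulate a pair of aligned sequences under an empirical model
#'
#' Draws the ancestral sequence from the stationary distribution and the
#' descendant from `P(t)`; used by distance-recovery oracles.
#'
#' @param model an [aa_model()].
#' @param t divergence time (substitutions per site).
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @return list with character vectors `x` (ancestor) and `y`.
#' @export
simulate_aa_pair <- function(model, t, n_sites, seed) {
  set.seed(seed)
  x <- sample(AA_ALPHABET, n_sites, replace = TRUE, prob = model$pi)
  P <- aa_transition_prob(model, t)
  y <- vapply(x, function(a) sample(AA_ALPHABET, 1L, prob = P[a, ]),
              character(1), USE.NAMES = FALSE)
  list(x = x, y = y)
}

# evolve a residue vector along one branch
evolve_aa <- function(x, model, t) {
  P <- aa_transition_prob(model, t)
  vapply(x, function(a) sample(AA_ALPHABET, 1L, prob = P[a, ]),
         character(1), USE.NAMES = FALSE)
}
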