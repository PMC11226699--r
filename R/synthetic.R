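# Seeded generators with returned truth: genome pairs evolved to a target
# identity, protein families on a known tree, and composition profiles.
# One global seed fans out to per-generator child seeds through
# child_seed(), so adding a generator never shifts existing fixtures.

#' Deterministic child seed
#'
#' Derives a per-generator seed from a global seed and a tag by a fixed
#' polynomial string hash, keeping results below 2^31.
#'
#' @param seed global integer seed.
#' @param tag character tag naming the consumer.
#' @return integer seed.
#' @export
child_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1048576
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% (2^31 - 1))
}

#' Specification for a simulated genome pair
#'
#' @param root_length root genome length in bp (>= 1 kb).
#' @param substitution_rate per-site substitution probability in `[0, 1)`.
#' @param indel_rate per-site indel event rate in `[0, 1)`.
#' @param indel_mean mean indel length (geometric).
#' @param gene_loss_fraction fraction of the derived genome deleted in
#'   gene-sized (1 kb) blocks.
#' @param gc target GC fraction of the root.
#' @param seed integer seed.
#' @return an `evolve_spec` list.
#' @export
evolve_spec <- function(root_length = 100000L, substitution_rate = 0.05,
                        indel_rate = 0, indel_mean = 3,
                        gene_loss_fraction = 0, gc = 0.55, seed = 1L) {
  stopifnot(root_length >= 1000L,
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            gene_loss_fraction >= 0, gene_loss_fraction < 1,
            gc > 0, gc < 1)
  structure(list(root_length = as.integer(root_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate, indel_mean = indel_mean,
                 gene_loss_fraction = gene_loss_fraction,
                 gc = gc, seed = as.integer(seed)),
            class = "evolve_spec")
}

#' Simulate a genome pair with a known site-level alignment
#'
#' Generates (or accepts) a root genome and evolves one descendant:
#' substitutions always change the base, insertions/deletions follow a
#' geometric length model, and gene loss removes 1 kb blocks. The true
#' gapped alignment is returned so that identity oracles are exact.
#' Deterministic for a fixed seed.
#'
#' @param spec an [evolve_spec()].
#' @param root optional [genome_record()] used as the ancestor (first
#'   replicon).
#' @return list with `ancestor` and `derived` ([genome_record()]s),
#'   `alignment` (list of two gapped strings `root`, `derived`) and
#'   `true_identity` (percent identity over aligned non-gap columns).
#' @export
evolve_genome <- function(spec = evolve_spec(), root = NULL) {
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  if (is.null(root)) {
    p <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
    r <- sample(bases, spec$root_length, replace = TRUE, prob = p)
  } else {
    r <- strsplit(paste(root$replicons, collapse = ""), "")[[1]]
  }
  L <- length(r)
  d <- r
  mut <- which(stats::runif(L) < spec$substitution_rate)
  if (length(mut)) {
    shift <- sample.int(3L, length(mut), replace = TRUE)
    d[mut] <- bases[(match(d[mut], bases) - 1L + shift) %% 4L + 1L]
  }
  # alignment columns as parallel vectors; start fully aligned
  ar <- r; ad <- d
  # gene loss: delete whole 1 kb blocks of the derived sequence
  if (spec$gene_loss_fraction > 0) {
    n_genes <- L %/% 1000L
    lost <- sample.int(n_genes, round(spec$gene_loss_fraction * n_genes))
    for (g in lost) ad[((g - 1L) * 1000L + 1L):(g * 1000L)] <- "-"
  }
  # indels: geometric lengths, insertions add columns with a root gap
  n_ev <- stats::rpois(1L, spec$indel_rate * L)
  if (n_ev > 0L) {
    pos <- sort(sample.int(length(ar), n_ev))
    len <- stats::rgeom(n_ev, 1 / spec$indel_mean) + 1L
    ins <- stats::runif(n_ev) < 0.5
    newr <- newd <- vector("list", 2L * n_ev + 1L)
    last <- 0L
    for (k in seq_len(n_ev)) {
      seg <- if (pos[k] > last) (last + 1L):pos[k] else integer(0)
      newr[[2L * k - 1L]] <- ar[seg]; newd[[2L * k - 1L]] <- ad[seg]
      if (ins[k]) {
        newr[[2L * k]] <- rep("-", len[k])
        newd[[2L * k]] <- sample(bases, len[k], replace = TRUE)
      } else {
        del <- (pos[k] + 1L):min(pos[k] + len[k], length(ar))
        newr[[2L * k]] <- ar[del]
        newd[[2L * k]] <- rep("-", length(del))
        pos[k] <- max(del)
      }
      last <- pos[k]
    }
    seg <- if (last < length(ar)) (last + 1L):length(ar) else integer(0)
    newr[[2L * n_ev + 1L]] <- ar[seg]; newd[[2L * n_ev + 1L]] <- ad[seg]
    ar <- unlist(newr); ad <- unlist(newd)
  }
  both <- ar != "-" & ad != "-"
  truth <- 100 * mean(ar[both] == ad[both])
  anc <- genome_record("ancestor", c(chr = paste(r, collapse = "")))
  der <- genome_record("derived",
                       c(chr = paste(ad[ad != "-"], collapse = "")))
  list(ancestor = anc, derived = der,
       alignment = list(root = paste(ar, collapse = ""),
                        derived = paste(ad, collapse = "")),
       true_identity = truth)
}

#' Simulate protein families on a known tree
#'
#' Evolves `n_families` single-copy protein families along a strain tree
#' under an empirical amino-acid model, with optional planted absences
#' and duplications, and returns the truth needed by recovery tests.
#'
#' @param n_strains number of strains (ignored when `tree` given).
#' @param n_families number of families.
#' @param tree optional `phylo` strain tree; defaults to a random seeded
#'   topology with branch lengths uniform in `[0.02, 0.12]`.
#' @param lengths protein lengths per family (recycled).
#' @param tags named list family-name -> character tags.
#' @param absent_in named list family-name -> strains lacking the family.
#' @param duplicate_in named list family-name -> strains with two copies.
#' @param model `"jtt"` or `"dayhoff"`.
#' @param seed integer seed.
#' @return list with `proteomes` (list of [protein_set()]), `truth`
#'   (family -> per-strain protein ids), `tree`, `sequences` (family ->
#'   strain-named ungapped sequence vector, single-copy members only).
#' @export
simulate_families <- function(n_strains = 8L, n_families = 5L, tree = NULL,
                              lengths = 300L, tags = list(),
                              absent_in = list(), duplicate_in = list(),
                              model = "jtt", seed = 1L) {
  set.seed(child_seed(seed, "families"))
  mod <- aa_model(model)
  if (is.null(tree)) {
    tree <- ape::rtree(n_strains, rooted = TRUE,
                       tip.label = sprintf("strain%02d", seq_len(n_strains)))
    tree$edge.length <- stats::runif(nrow(tree$edge), 0.02, 0.12)
  }
  strains <- tree$tip.label
  n_strains <- length(strains)
  fam_names <- if (!is.null(names(tags)) && length(tags) == n_families)
    names(tags) else sprintf("fam%02d", seq_len(n_families))
  lengths <- rep_len(lengths, n_families)
  eo <- ape::reorder.phylo(tree, "cladewise")
  root <- setdiff(eo$edge[, 1], eo$edge[, 2])[1L]
  seqs <- vector("list", n_families)
  names(seqs) <- fam_names
  for (f in seq_len(n_families)) {
    node_seq <- vector("list", n_strains + tree$Nnode)
    node_seq[[root]] <- sample(AA_ALPHABET, lengths[f], replace = TRUE,
                               prob = mod$pi)
    for (e in seq_len(nrow(eo$edge))) {
      p <- eo$edge[e, 1L]; ch <- eo$edge[e, 2L]
      node_seq[[ch]] <- evolve_aa(node_seq[[p]], mod, eo$edge.length[e])
    }
    fam <- vapply(seq_len(n_strains),
                  function(i) paste(node_seq[[i]], collapse = ""),
                  character(1))
    names(fam) <- strains
    seqs[[f]] <- fam
  }
  proteomes <- truth <- list()
  for (s in strains) {
    prot <- character(0); ptags <- list()
    for (f in fam_names) {
      if (s %in% absent_in[[f]]) next
      pid <- paste0(f, "_", s)
      prot[pid] <- seqs[[f]][[s]]
      ptags[[pid]] <- as.character(tags[[f]])
      truth[[f]] <- c(truth[[f]], stats::setNames(pid, s))
      if (s %in% duplicate_in[[f]]) {
        pid2 <- paste0(f, "_", s, "_copy2")
        # a slightly diverged paralog
        prot[pid2] <- paste(evolve_aa(strsplit(seqs[[f]][[s]], "")[[1]],
                                      mod, 0.01), collapse = "")
        ptags[[pid2]] <- as.character(tags[[f]])
        truth[[f]] <- c(truth[[f]], stats::setNames(pid2, s))
      }
    }
    proteomes[[s]] <- protein_set(s, prot, ptags)
  }
  list(proteomes = proteomes, truth = truth, tree = tree, sequences = seqs)
}

#' Simulate chemotaxonomic composition profiles
#'
#' Draws positive compositions around per-archetype condition means
#' (gamma noise, then normalized to percent), with optional ND masking.
#'
#' @param archetype_of named character vector strain -> archetype name.
#' @param archetypes named list archetype -> named numeric vector of mean
#'   percentages, names `condition.component`.
#' @param noise_sd relative noise (gamma shape `1/noise_sd^2`); 0 gives
#'   the archetype means exactly.
#' @param nd_pattern named list strain -> value names set to ND.
#' @param seed integer seed.
#' @return named list of [chem_profile()] objects.
#' @export
simulate_profiles <- function(archetype_of, archetypes, noise_sd = 0.1,
                              nd_pattern = list(), seed = 1L) {
  set.seed(child_seed(seed, "profiles"))
  out <- list()
  for (s in names(archetype_of)) {
    mu <- archetypes[[archetype_of[[s]]]]
    stopifnot(!is.null(mu), !is.null(names(mu)))
    v <- if (noise_sd > 0) {
      shape <- 1 / noise_sd^2
      stats::rgamma(length(mu), shape = shape, rate = shape / mu)
    } else mu
    names(v) <- names(mu)
    v[names(v) %in% nd_pattern[[s]]] <- NA_real_
    conds <- sub("\\..*$", "", names(v))
    for (cn in unique(conds)) {
      idx <- conds == cn
      if (any(!is.na(v[idx]))) v[idx] <- molar_ratio(v[idx])
    }
    out[[s]] <- chem_profile(s, v)
  }
  out
}
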