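# Taxonomic decisions from similarity matrices: species calls by ANI/DDH
# cutoffs, similarity clustering at a threshold, and novel-genus flagging
# combining AAI clustering with tree separation.

#' Delineation policy
#'
#' Threshold bundle for species and genus calls. The defaults are the
#' conventional cutoffs: 95% ANI / 70% DDH for species identity, 96%
#' identity with 90% coverage for type-strain verification, 80% AAI for
#' genus-level clustering and 68% for the AAI tree scale.
#'
#' @param species_ani,species_ddh species-level cutoffs (percent).
#' @param verify_identity,verify_coverage verification cutoffs (percent).
#' @param genus_aai_cluster AAI clustering threshold (percent).
#' @param genus_tree_cutoff AAI tree-scale cutoff (percent); only used
#'   when `tree_rule = "distance"` in [genus_call()].
#' @return a `delineation_policy` list.
#' @export
delineation_policy <- function(species_ani = 95, species_ddh = 70,
                               verify_identity = 96, verify_coverage = 90,
                               genus_aai_cluster = 80,
                               genus_tree_cutoff = 68) {
  vals <- c(species_ani, species_ddh, verify_identity, verify_coverage,
            genus_aai_cluster, genus_tree_cutoff)
  stopifnot(all(vals > 0 & vals <= 100))
  structure(list(species_ani = species_ani, species_ddh = species_ddh,
                 verify_identity = verify_identity,
                 verify_coverage = verify_coverage,
                 genus_aai_cluster = genus_aai_cluster,
                 genus_tree_cutoff = genus_tree_cutoff),
            class = "delineation_policy")
}

#' Cluster strains at a similarity threshold
#'
#' Connected components of the graph whose edges join strains with
#' similarity strictly above `threshold`. With `edges` supplied (a
#' two-column matrix/data frame of label pairs, e.g. the bold-box pairs of
#' a printed matrix), those pairs are used as the graph directly and the
#' numeric threshold is ignored — a clearly separated mode for reproducing
#' a published table's box reading rather than recomputing from values.
#'
#' @param m a [similarity_matrix()].
#' @param threshold percent; edges require `similarity > threshold`.
#' @param edges optional explicit edge list (label pairs).
#' @return list of character vectors (clusters), each sorted; the list is
#'   ordered by first member.
#' @export
threshold_clusters <- function(m, threshold = 80, edges = NULL) {
  labs <- m$labels
  parent <- stats::setNames(seq_along(labs), labs)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  join <- function(a, b) {
    ra <- find(match(a, labs)); rb <- find(match(b, labs))
    if (ra != rb) parent[[max(ra, rb)]] <<- min(ra, rb)
  }
  if (is.null(edges)) {
    v <- m$values
    for (i in seq_along(labs)) for (j in seq_along(labs))
      if (i < j && v[i, j] > threshold) join(labs[i], labs[j])
  } else {
    edges <- as.matrix(edges)
    for (r in seq_len(nrow(edges))) {
      if (!all(edges[r, 1:2] %in% labs))
        stop("edge refers to unknown label: ",
             paste(edges[r, 1:2], collapse = ", "))
      join(edges[r, 1L], edges[r, 2L])
    }
  }
  comp <- vapply(seq_along(labs), find, integer(1))
  cl <- lapply(split(labs, comp), sort)
  unname(cl[order(vapply(cl, `[`, character(1), 1L))])
}

#' Species-level call for one strain
#'
#' Same species as its nearest type strain iff the maximum ANI against any
#' other strain reaches `species_ani` (boundary inclusive) or the maximum
#' DDH reaches `species_ddh`; otherwise a novel species.
#'
#' @param strain strain id.
#' @param m_ani ANI [similarity_matrix()].
#' @param m_ddh DDH matrix; if `NULL`, estimated from ANI via
#'   [ddh_estimate()] and flagged as estimated.
#' @param policy a [delineation_policy()].
#' @return a `taxon_call` list with `strain`, `verdict`
#'   (`"same-species"` or `"novel-species"`), `nearest`, `max_ani`,
#'   `max_ddh`, `ddh_estimated` and `evidence` strings.
#' @export
species_call <- function(strain, m_ani, m_ddh = NULL,
                         policy = delineation_policy()) {
  if (!strain %in% m_ani$labels) stop("strain not in ANI matrix: ", strain)
  others <- setdiff(m_ani$labels, strain)
  ani <- m_ani$values[strain, others]
  est <- is.null(m_ddh)
  ddh <- if (est) ddh_estimate(ani) else m_ddh$values[strain, others]
  i_ani <- which.max(ani); i_ddh <- which.max(ddh)
  same <- ani[i_ani] >= policy$species_ani || ddh[i_ddh] >= policy$species_ddh
  evidence <- c(
    sprintf("max ANI %.2f vs %s (cutoff %g)", ani[i_ani], others[i_ani],
            policy$species_ani),
    sprintf("max DDH%s %.2f vs %s (cutoff %g)",
            if (est) " [estimated from ANI]" else "",
            ddh[i_ddh], others[i_ddh], policy$species_ddh))
  structure(list(strain = strain,
                 verdict = if (same) "same-species" else "novel-species",
                 nearest = others[i_ani],
                 max_ani = unname(ani[i_ani]), max_ddh = unname(ddh[i_ddh]),
                 ddh_estimated = est, evidence = evidence),
            class = "taxon_call")
}

#' Genus-level call for one strain
#'
#' Combines two independent pieces of evidence: (1) the strain is a
#' singleton under [threshold_clusters()] at the policy's AAI clustering
#' threshold (or under an explicit box-edge reading), and (2) the strain
#' forms its own branch in the tree — every multi-member cluster is
#' separated from the strain by a bipartition (`tree_rule = "bipartition"`,
#' the default), or no other leaf lies within the tree path distance
#' implied by `genus_tree_cutoff` (`tree_rule = "distance"`). Agreement of
#' both yields `novel-genus-candidate`; disagreement is reported as
#' `ambiguous` with both facts, never silently resolved.
#'
#' @param strain strain id.
#' @param m_aai AAI [similarity_matrix()].
#' @param tree `phylo` tree whose leaves include the matrix labels.
#' @param policy a [delineation_policy()].
#' @param edges optional explicit cluster edge list (see
#'   [threshold_clusters()]).
#' @param tree_rule `"bipartition"` or `"distance"`.
#' @return a `taxon_call` with verdict `novel-genus-candidate`,
#'   `member-of-cluster` or `ambiguous`.
#' @export
genus_call <- function(strain, m_aai, tree, policy = delineation_policy(),
                       edges = NULL, tree_rule = c("bipartition", "distance")) {
  tree_rule <- match.arg(tree_rule)
  if (!strain %in% m_aai$labels) stop("strain not in AAI matrix: ", strain)
  if (!all(m_aai$labels %in% tree$tip.label))
    stop("tree leaves must cover the matrix labels")
  cl <- threshold_clusters(m_aai, policy$genus_aai_cluster, edges = edges)
  mine <- cl[[which(vapply(cl, function(x) strain %in% x, logical(1)))]]
  singleton <- length(mine) == 1L
  multi <- cl[vapply(cl, length, integer(1)) > 1L]
  if (tree_rule == "bipartition") {
    # the strain is nested inside a cluster's branch when some split
    # groups it with a nonempty PROPER subset of that cluster; sitting
    # sister to a complete cluster clade still counts as an own branch
    sides <- tree_sides(tree)
    nested <- vapply(multi, function(cluster) {
      any(vapply(sides, function(S) {
        if (!(strain %in% S)) return(FALSE)
        rest <- setdiff(S, strain)
        length(rest) >= 1L && all(rest %in% cluster) &&
          length(rest) < length(cluster)
      }, logical(1)))
    }, logical(1))
    in_multi <- any(vapply(multi, function(x) strain %in% x, logical(1)))
    own_branch <- !in_multi && !any(nested)
    tree_evidence <- sprintf(
      "tree: %s is nested inside %d of %d multi-member cluster branches",
      strain, sum(nested), length(multi))
  } else {
    dmat <- ape::cophenetic.phylo(tree)
    dcut <- 100 - policy$genus_tree_cutoff
    others <- setdiff(m_aai$labels, strain)
    nearest <- min(dmat[strain, others])
    own_branch <- nearest > dcut
    tree_evidence <- sprintf(
      "tree: nearest leaf at path distance %.3f (cutoff %.3f)",
      nearest, dcut)
  }
  cluster_evidence <- sprintf("clustering: %s is %s at threshold %g%s",
                              strain,
                              if (singleton) "a singleton"
                              else paste0("grouped with ",
                                          paste(setdiff(mine, strain),
                                                collapse = ", ")),
                              policy$genus_aai_cluster,
                              if (is.null(edges)) "" else " (box-edge mode)")
  verdict <- if (singleton && own_branch) "novel-genus-candidate"
             else if (!singleton && !own_branch) "member-of-cluster"
             else "ambiguous"
  structure(list(strain = strain, verdict = verdict,
                 cluster = mine, singleton = singleton,
                 own_branch = own_branch,
                 evidence = c(cluster_evidence, tree_evidence)),
            class = "taxon_call")
}

#' @export
print.taxon_call <- function(x, ...) {
  cat("<taxon_call> ", x$strain, ": ", x$verdict, "\n", sep = "")
  for (e in x$evidence) cat("  - ", e, "\n", sep = "")
  invisible(x)
}
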