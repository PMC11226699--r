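# Distance-based tree reconstruction: UPGMA, neighbor joining, minimum
# evolution (OLS branch lengths + close-neighbor-interchange search) and
# nonparametric bootstrap support. Trees are 'ape' "phylo" objects.

check_dist <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  if (anyNA(d)) stop("distance matrix contains NA")
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(d < -1e-12)) stop("negative distances")
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; the height of a new node is half the
#' between-cluster distance, so the result is rooted and ultrametric.
#' Merge ties are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its alphabetically first member).
#'
#' @param d symmetric non-negative distance matrix with row names.
#' @return rooted ultrametric `phylo` tree.
#' @export
upgma <- function(d) {
  d <- check_dist(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  lab <- rownames(d)
  nwk <- lab                       # growing newick fragment per cluster
  size <- rep(1L, n)
  height <- rep(0, n)
  first <- lab                     # tie-break label of each cluster
  active <- seq_len(n)
  while (length(active) > 1L) {
    da <- d[active, active, drop = FALSE]
    diag(da) <- Inf
    m <- min(da)
    cand <- which(da - m <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(first[active][cand[, 1]], first[active][cand[, 2]]),
                 pmax(first[active][cand[, 1]], first[active][cand[, 2]]))
    pick <- cand[order(key)[1L], ]
    i <- active[pick[1L]]; j <- active[pick[2L]]
    h <- d[i, j] / 2
    bi <- h - height[i]; bj <- h - height[j]
    new <- length(size) + 1L
    nwk <- c(nwk, sprintf("(%s:%.12g,%s:%.12g)", nwk[i], bi, nwk[j], bj))
    size <- c(size, size[i] + size[j])
    height <- c(height, h)
    first <- c(first, min(first[i], first[j]))
    drow <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    d <- rbind(cbind(d, drow), c(drow, 0))
    active <- c(setdiff(active, c(i, j)), new)
  }
  ape::read.tree(text = paste0(nwk[active], ";"))
}

#' Neighbor-joining tree
#'
#' Studier-Keppler Q-criterion agglomeration with the standard
#' branch-length formulas. Exact on additive matrices. Negative estimated
#' terminal lengths are clamped to zero with the deficit moved to the
#' sister branch. Ties in the Q criterion are broken by the
#' lexicographically smallest label pair.
#'
#' @param d symmetric distance matrix with row names, `n >= 3`.
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- check_dist(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  nwk <- rownames(d)
  first <- rownames(d)
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3L) {
    r <- length(active)
    da <- d[active, active, drop = FALSE]
    R <- rowSums(da)
    Q <- (r - 2) * da - outer(R, R, `+`)
    diag(Q) <- Inf
    m <- min(Q)
    cand <- which(Q - m <= 1e-9 * max(1, abs(m)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(first[active][cand[, 1]], first[active][cand[, 2]]),
                 pmax(first[active][cand[, 1]], first[active][cand[, 2]]))
    pick <- cand[order(key)[1L], ]
    ii <- pick[1L]; jj <- pick[2L]
    i <- active[ii]; j <- active[jj]
    li <- d[i, j] / 2 + (R[ii] - R[jj]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new <- length(first) + 1L
    nwk <- c(nwk, sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj)))
    first <- c(first, min(first[i], first[j]))
    drow <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    d <- rbind(cbind(d, drow), c(drow, 0))
    d[new, new] <- 0
    active <- c(setdiff(active, c(i, j)), new)
  }
  a <- active[1L]; b <- active[2L]; cc <- active[3L]
  la <- (d[a, b] + d[a, cc] - d[b, cc]) / 2
  lb <- (d[a, b] + d[b, cc] - d[a, cc]) / 2
  lc <- (d[a, cc] + d[b, cc] - d[a, b]) / 2
  ln <- c(la, lb, lc)
  for (kk in 1:3) if (ln[kk] < 0) {            # clamp, spread deficit
    ln[-kk] <- ln[-kk] + ln[kk] / 2
    ln[kk] <- 0
  }
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[a], fmt(ln[1]),
                 nwk[b], fmt(ln[2]), nwk[cc], fmt(ln[3]))
  ape::read.tree(text = txt)
}

# edge-path indicator matrix: rows = unordered tip pairs, cols = edges
path_indicator <- function(tree) {
  n <- length(tree$tip.label)
  m <- nrow(tree$edge)
  parent_edge <- integer(n + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(m)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1L]
  up <- function(node) {
    path <- logical(m)
    while (node != root) {
      e <- parent_edge[node]
      path[e] <- TRUE
      node <- tree$edge[e, 1]
    }
    path
  }
  tip_paths <- vapply(seq_len(n), up, logical(m))
  pairs <- utils::combn(n, 2L)
  A <- matrix(0, ncol(pairs), m)
  for (p in seq_len(ncol(pairs)))
    A[p, ] <- xor(tip_paths[, pairs[1L, p]], tip_paths[, pairs[2L, p]])
  list(A = A, pairs = pairs)
}

#' OLS branch lengths and minimum-evolution tree length
#'
#' Fits ordinary-least-squares branch lengths to a fixed topology and
#' returns their sum (the minimum-evolution objective). Negative fitted
#' lengths are kept in the objective but flagged.
#'
#' @param tree `phylo` topology spanning the labels of `d`.
#' @param d distance matrix.
#' @return list with `total` (sum of OLS lengths), `lengths`, `rss`
#'   (residual sum of squares), `negative` flag and `tree` with the OLS
#'   lengths attached (clamped at zero for the tree object only).
#' @export
me_tree_length <- function(tree, d) {
  d <- check_dist(d)
  if (!setequal(tree$tip.label, rownames(d)))
    stop("topology labels do not match the distance matrix")
  pi_ <- path_indicator(tree)
  idx <- match(tree$tip.label, rownames(d))
  dvec <- apply(pi_$pairs, 2L, function(p) d[idx[p[1L]], idx[p[2L]]])
  qr_ <- qr(pi_$A)
  if (qr_$rank < ncol(pi_$A)) stop("singular OLS system for this topology")
  beta <- qr.coef(qr_, dvec)
  fit <- as.vector(pi_$A %*% beta)
  out <- tree
  out$edge.length <- pmax(beta, 0)
  list(total = sum(beta), lengths = beta, rss = sum((dvec - fit)^2),
       negative = any(beta < 0), tree = out)
}

# all NNI neighbors of an unrooted binary tree (via phangorn)
nni_neighbors <- function(tree) {
  nb <- phangorn::nni(tree)
  if (inherits(nb, "phylo")) return(list(nb))
  # use [[ so compressed multiPhylo tip labels are restored per tree
  lapply(seq_along(nb), function(i) nb[[i]])
}

# canonical topology key: sorted non-trivial bipartitions
topo_key <- function(tree) paste(sort(bipartitions(tree)), collapse = ";")

#' Minimum-evolution tree by close-neighbor-interchange search
#'
#' Starts from the neighbor-joining tree and repeatedly moves to the
#' nearest-neighbor-interchange (search level 1) neighbor with the
#' smallest OLS tree length while this improves the objective. Ties are
#' broken by the lexicographically smallest canonical topology key, so the
#' search is deterministic.
#'
#' @param d distance matrix, `n >= 4`.
#' @param max_iter safety cap on accepted moves.
#' @return `phylo` tree with OLS branch lengths (negatives clamped to 0 in
#'   the reported tree); attributes `me_length` (raw objective) and
#'   `negative_lengths`.
#' @export
minimum_evolution <- function(d, max_iter = 100L) {
  d <- check_dist(d)
  if (nrow(d) < 4L) stop("need at least 4 taxa")
  cur <- ape::unroot(neighbor_joining(d))
  cur_fit <- me_tree_length(cur, d)
  for (it in seq_len(max_iter)) {
    nbs <- nni_neighbors(cur)
    fits <- lapply(nbs, me_tree_length, d = d)
    totals <- vapply(fits, `[[`, numeric(1), "total")
    best <- min(totals)
    if (best >= cur_fit$total - 1e-12) break
    cand <- which(totals - best <= 1e-12)
    if (length(cand) > 1L)
      cand <- cand[order(vapply(nbs[cand], topo_key, character(1)))[1L]]
    cur <- nbs[[cand[1L]]]
    cur_fit <- fits[[cand[1L]]]
  }
  out <- cur_fit$tree
  attr(out, "me_length") <- cur_fit$total
  attr(out, "negative_lengths") <- cur_fit$negative
  out
}

#' Exhaustive minimum-evolution search (oracle)
#'
#' Evaluates the OLS tree length of every unrooted binary topology;
#' intended as an independent check of [minimum_evolution()] for small
#' `n` (the number of topologies grows as `(2n-5)!!`).
#'
#' @param d distance matrix with `4 <= n <= 8` taxa.
#' @return as [minimum_evolution()].
#' @export
exhaustive_minimum_evolution <- function(d) {
  d <- check_dist(d)
  n <- nrow(d)
  stopifnot(n >= 4L, n <= 8L)
  all_tr <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(d))
  fits <- lapply(all_tr, me_tree_length, d = d)
  totals <- vapply(fits, `[[`, numeric(1), "total")
  best <- which(totals - min(totals) <= 1e-12)
  if (length(best) > 1L)
    best <- best[order(vapply(all_tr[best], topo_key, character(1)))[1L]]
  out <- fits[[best[1L]]]$tree
  attr(out, "me_length") <- totals[best[1L]]
  attr(out, "negative_lengths") <- fits[[best[1L]]]$negative
  out
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the leaves in two; a bipartition is encoded
#' as the sorted labels of the side not containing the alphabetically
#' first leaf, joined by `|`. Trivial splits (single leaf) are omitted.
#'
#' @param tree `phylo` object.
#' @return character vector of bipartition keys.
#' @export
bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  desc <- clade_sets(tree)
  keys <- character(0)
  for (node in (n + 1L):(n + tree$Nnode)) {
    side <- desc[[node]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2L && length(side) <= n - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# every bipartition side (both orientations) induced by internal edges
tree_sides <- function(tree) {
  n <- length(tree$tip.label)
  desc <- clade_sets(tree)
  sides <- list()
  for (node in (n + 1L):(n + tree$Nnode)) {
    s <- desc[[node]]
    if (length(s) >= 2L && length(s) <= n - 2L) {
      sides[[length(sides) + 1L]] <- s
      sides[[length(sides) + 1L]] <- setdiff(tree$tip.label, s)
    }
  }
  sides
}

# leaf-label sets below every node
clade_sets <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  desc[seq_len(n)] <- as.list(tree$tip.label)
  eo <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1L]; ch <- eo$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Bootstrap bipartition support
#'
#' Builds the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `replicates` times (seeded),
#' rebuilds the tree, and reports for every internal edge of the point
#' tree the percentage of replicate trees containing the same
#' bipartition. Support is stored in `$node.label`.
#'
#' @param aln alignment (character matrix or named gapped strings).
#' @param model distance model name, see [pairwise_distance()].
#' @param builder `"nj"`, `"upgma"` or `"me"`.
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @return the point-estimate `phylo` tree with percent support values in
#'   `$node.label` and attribute `n_effective` (replicates in which a
#'   tree could be built).
#' @export
bootstrap_support <- function(aln, model = "p", builder = c("nj", "upgma", "me"),
                              replicates = 1000L, seed = 1L) {
  builder <- match.arg(builder)
  if (!is.matrix(aln)) aln <- aln_matrix(unlist(aln))
  stopifnot(ncol(aln) >= 1L, replicates >= 1L)
  build <- function(a) {
    d <- pairwise_distance(a, model)
    switch(builder, nj = neighbor_joining(d), upgma = upgma(d),
           me = minimum_evolution(d))
  }
  point <- build(aln)
  keys <- bipartitions(point)
  count <- stats::setNames(numeric(length(keys)), keys)
  set.seed(seed)
  n_ok <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    tr <- tryCatch(build(aln[, cols, drop = FALSE]), error = function(e) NULL)
    if (is.null(tr)) next
    n_ok <- n_ok + 1L
    hit <- keys %in% bipartitions(tr)
    count[hit] <- count[hit] + 1
  }
  if (n_ok == 0L) stop("no bootstrap replicate produced a tree")
  support <- 100 * count / n_ok
  point <- attach_support(point, support)
  attr(point, "n_effective") <- n_ok
  point
}

# write per-bipartition support into node labels of the point tree
attach_support <- function(tree, support) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  desc <- clade_sets(tree)
  lab <- character(tree$Nnode)
  for (node in (n + 1L):(n + tree$Nnode)) {
    side <- desc[[node]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    lab[node - n] <- if (key %in% names(support))
      sprintf("%g", round(support[[key]], 1)) else ""
  }
  tree$node.label <- lab
  tree
}
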