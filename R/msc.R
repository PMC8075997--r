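# Multispecies-coalescent gene-tree simulation on a species tree with
# branch lengths in coalescent units, and per-branch topology (quartet)
# frequencies around focal internal branches.
#
# One lineage enters at each tip; within a species-tree branch of length
# t, the k lineages present coalesce with exponential waiting times at
# rate choose(k, 2); survivors are passed to the parent branch and any
# lineages reaching the root coalesce in an unbounded ancestral branch.
# Gene trees are stored as merge tables (which pair of lineage clusters
# coalesced, in chronological order), which is what both the topology
# classifier and the newick writer need.

#' Set terminal branch lengths of a species tree
#'
#' @param tree An \code{ape::phylo} tree.
#' @param length New length for every terminal (tip) branch (default 1,
#'   the convention when one allele is sampled per species).
#' @return The tree with terminal branches set.
#' @export
set_terminal_branches <- function(tree, length = 1) {
  tip_edges <- tree$edge[, 2] <= ape::Ntip(tree)
  tree$edge.length[tip_edges] <- length
  tree
}

# internal: species tree as traversal tables
sptree_tables <- function(tree) {
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  bl <- rep(Inf, nnode)
  parent <- rep(NA_integer_, nnode)
  bl[tree$edge[, 2]] <- tree$edge.length
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  bl[root] <- Inf
  children <- lapply(seq_len(nnode), function(v)
    tree$edge[tree$edge[, 1] == v, 2])
  # postorder sequence of internal nodes (children before parents)
  post <- integer(0)
  visit <- function(v) {
    for (k in children[[v]]) if (k > ntip) visit(k)
    post <<- c(post, v)
  }
  visit(root)
  list(ntip = ntip, root = root, bl = bl, parent = parent,
       post = post, children = children, labels = tree$tip.label)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' @param tree Rooted binary \code{ape::phylo} species tree with branch
#'   lengths in coalescent units.
#' @param n Number of gene trees.
#' @param seed Integer seed (simulation is deterministic given the seed).
#' @return Object of class \code{gene_tree_set}: \code{tip_labels},
#'   \code{n}, and \code{merges}, a list of (ntip - 1) x 3 matrices
#'   (columns: representative leaf of each merged cluster, in
#'   chronological order; third column the coalescence height).
#' @export
simulate_gene_trees <- function(tree, n, seed = 1) {
  stopifnot(n >= 1)
  tab <- sptree_tables(tree)
  withr::with_seed(seed, {
    merges <- vector("list", n)
    for (g in seq_len(n)) merges[[g]] <- sim_one_gene_tree(tab)
    structure(list(tip_labels = tab$labels, n = n, merges = merges,
                   seed = seed),
              class = "gene_tree_set")
  })
}

sim_one_gene_tree <- function(tab) {
  ntip <- tab$ntip
  # heights: species-tree node entry heights for gene-tree time stamps
  # (local stacking; only relative order within a path matters)
  lineages <- vector("list", length(tab$bl))  # per node: rep leaf ids
  entry_h <- numeric(length(tab$bl))
  for (v in seq_len(ntip)) lineages[[v]] <- v
  merge_mat <- matrix(0, nrow = ntip - 1L, ncol = 3L)
  mi <- 0L
  for (v in tab$post) {
    kids <- tab$children[[v]]
    lin <- c(lineages[[v]], unlist(lapply(kids, function(k)
      lineages[[k]]), use.names = FALSE))
    h0 <- if (length(kids)) {
      max(vapply(kids, function(k) entry_h[k] + tab$bl[k], numeric(1)))
    } else {
      0
    }
    entry_h[v] <- h0
    t_avail <- tab$bl[v]
    t_used <- 0
    k <- length(lin)
    while (k > 1) {
      w <- stats::rexp(1, rate = k * (k - 1) / 2)
      if (t_used + w > t_avail) break
      t_used <- t_used + w
      pr <- sample.int(k, 2)
      i <- lin[pr[1]]
      j <- lin[pr[2]]
      mi <- mi + 1L
      merge_mat[mi, ] <- c(i, j, h0 + t_used)
      lin <- c(lin[-pr], i)
      k <- k - 1L
    }
    lineages[[v]] <- lin
  }
  merge_mat
}

#' Closed-form MSC topology frequencies around an internal branch
#'
#' For an internal branch of length \code{t} coalescent units the
#' species-tree arrangement is expected in \code{q1 = 1 - (2/3) exp(-t)}
#' of gene trees and each alternate in \code{(1/3) exp(-t)}.
#'
#' @param t Internal branch length in coalescent units (>= 0).
#' @return Named numeric vector (q1, q2, q3).
#' @export
expected_topology_freqs <- function(t) {
  if (any(t < 0)) stop("negative branch length")
  c(q1 = 1 - (2 / 3) * exp(-t), q2 = (1 / 3) * exp(-t),
    q3 = (1 / 3) * exp(-t))
}

# Identify the four neighbor groups (leaf label sets) around the
# internal branch subtending `clade` (character vector of tip labels).
# A = child clade containing the alphabetically first label, B = other
# child clade, C = sibling clade, D = everything else.
branch_groups <- function(tree, clade) {
  ntip <- ape::Ntip(tree)
  labs <- tree$tip.label
  node <- ape::getMRCA(tree, clade)
  if (is.null(node) || node <= ntip) {
    stop("focal branch must be internal (clade of >= 2 tips)")
  }
  # tip descendants per node via one traversal
  desc <- vector("list", ntip + tree$Nnode)
  for (v in seq_len(ntip)) desc[[v]] <- labs[v]
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    desc[[edges[i, 1]]] <- c(desc[[edges[i, 1]]], desc[[edges[i, 2]]])
  }
  if (!setequal(desc[[node]], clade)) {
    stop("clade does not correspond to a node: ",
         paste(clade, collapse = ","))
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (length(kids) != 2) stop("species tree must be binary")
  par <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(par) == 0) stop("focal branch has no parent (root)")
  sib <- setdiff(tree$edge[tree$edge[, 1] == par, 2], node)
  g_c <- desc[[sib]]
  g_d <- setdiff(labs, c(desc[[node]], g_c))
  if (length(g_d) == 0) {
    # branch incident to the root: the remaining two neighbor groups are
    # the sibling's child clades (the classification is then around the
    # single unrooted internal edge, whose effective coalescent length is
    # the sum of the two root-incident branches)
    if (sib <= ntip) {
      stop("focal branch is degenerate: only three neighbor groups")
    }
    sk <- tree$edge[tree$edge[, 1] == sib, 2]
    g_c <- desc[[sk[1]]]
    g_d <- desc[[sk[2]]]
  }
  ab <- list(desc[[kids[1]]], desc[[kids[2]]])
  first <- vapply(ab, function(s) sort(s)[1], character(1))
  ab <- ab[order(first)]
  list(A = ab[[1]], B = ab[[2]], C = g_c, D = g_d)
}

#' Topology frequencies around a focal internal branch
#'
#' Classifies gene trees by which of the three arrangements of the
#' branch's four neighbor groups they display, counting every quartet
#' with one leaf per group (the per-branch quartet support of
#' coalescent species-tree methods). q1 is the species-tree arrangement;
#' q2 joins group A with group C, q3 joins A with D (A, B the child
#' clades of the branch, A first alphabetically; C the sibling clade;
#' D the rest).
#'
#' @param genetrees A \code{gene_tree_set}.
#' @param tree The species tree used for the simulation.
#' @param clade Character vector of tip labels spanning the clade below
#'   the focal branch.
#' @return Object of class \code{quartet_freqs}: \code{freqs} (q1, q2,
#'   q3), \code{counts}, \code{n_quartets}, \code{groups} and
#'   \code{branch_id} (the sorted leaf-set bipartition).
#' @export
topology_freqs <- function(genetrees, tree, clade) {
  stopifnot(inherits(genetrees, "gene_tree_set"))
  if (!setequal(genetrees$tip_labels, tree$tip.label)) {
    stop("gene trees and species tree have different leaf sets")
  }
  gr <- branch_groups(tree, clade)
  lab <- genetrees$tip_labels
  gidx <- lapply(gr, function(g) match(g, lab))
  quart <- as.matrix(expand.grid(a = gidx$A, b = gidx$B, c = gidx$C,
                                 d = gidx$D))
  counts <- c(q1 = 0, q2 = 0, q3 = 0)
  ntip <- length(lab)
  pair_cols <- list(q1 = rbind(c("a", "b"), c("c", "d")),
                    q2 = rbind(c("a", "c"), c("b", "d")),
                    q3 = rbind(c("a", "d"), c("b", "c")))
  for (m in genetrees$merges) {
    M <- pair_merge_ranks(m, ntip)
    r1 <- pmin(M[quart[, c("a", "b"), drop = FALSE]],
               M[quart[, c("c", "d"), drop = FALSE]])
    r2 <- pmin(M[quart[, c("a", "c"), drop = FALSE]],
               M[quart[, c("b", "d"), drop = FALSE]])
    r3 <- pmin(M[quart[, c("a", "d"), drop = FALSE]],
               M[quart[, c("b", "c"), drop = FALSE]])
    counts["q1"] <- counts["q1"] + sum(r1 < r2 & r1 < r3)
    counts["q2"] <- counts["q2"] + sum(r2 < r1 & r2 < r3)
    counts["q3"] <- counts["q3"] + sum(r3 < r1 & r3 < r2)
  }
  total <- sum(counts)
  structure(
    list(freqs = counts / total, counts = counts, n_quartets = total,
         groups = gr,
         branch_id = paste(sort(clade), collapse = "|")),
    class = "quartet_freqs")
}

# For one merge table, the 2D lookup M[i, j] = chronological rank of the
# coalescence joining leaves i and j.
pair_merge_ranks <- function(merge_mat, ntip) {
  memb <- as.list(seq_len(ntip))
  M <- matrix(NA_integer_, ntip, ntip)
  for (k in seq_len(nrow(merge_mat))) {
    i <- merge_mat[k, 1]
    j <- merge_mat[k, 2]
    mi <- memb[[i]]
    mj <- memb[[j]]
    M[mi, mj] <- k
    M[mj, mi] <- k
    memb[[i]] <- c(mi, mj)
  }
  M
}

# M[quart[, cols]] needs numeric indices: helper index matrix
#' @export
`[.gene_tree_set` <- function(x, i) {
  structure(list(tip_labels = x$tip_labels, n = length(i),
                 merges = x$merges[i], seed = x$seed),
            class = "gene_tree_set")
}

#' Frequency of the arrangement joining two leaves
#'
#' Picks, from a \code{quartet_freqs} result, the frequency of the
#' arrangement in which the neighbor groups containing the two named
#' leaves are joined.
#'
#' @param tf A \code{quartet_freqs} object.
#' @param leaf_x,leaf_y Tip labels lying in two different neighbor
#'   groups.
#' @return Numeric scalar frequency.
#' @export
freq_joining <- function(tf, leaf_x, leaf_y) {
  gx <- names(Filter(function(g) leaf_x %in% g, tf$groups))
  gy <- names(Filter(function(g) leaf_y %in% g, tf$groups))
  if (length(gx) != 1 || length(gy) != 1 || gx == gy) {
    stop("leaves must lie in two different neighbor groups")
  }
  key <- paste(sort(c(gx, gy)), collapse = "")
  q <- switch(key,
              AB = "q1", CD = "q1",
              AC = "q2", BD = "q2",
              AD = "q3", BC = "q3")
  unname(tf$freqs[[q]])
}

#' @export
print.quartet_freqs <- function(x, ...) {
  cat("Topology frequencies around branch", x$branch_id, "\n")
  cat(sprintf("  q1 = %.4f  q2 = %.4f  q3 = %.4f  (n = %d quartets)\n",
              x$freqs[["q1"]], x$freqs[["q2"]], x$freqs[["q3"]],
              x$n_quartets))
  invisible(x)
}

#' Spearman concordance between empirical and simulated frequencies
#'
#' @param empirical,simulated Numeric vectors of topology proportions
#'   (equal length >= 3).
#' @return List with \code{rho} and \code{p_value} (two-sided Spearman
#'   rank correlation).
#' @export
concordance <- function(empirical, simulated) {
  if (length(empirical) != length(simulated)) {
    stop("length mismatch: ", length(empirical), " vs ",
         length(simulated))
  }
  if (length(empirical) < 3) stop("need at least 3 paired proportions")
  ct <- suppressWarnings(
    stats::cor.test(empirical, simulated, method = "spearman",
                    alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Convert simulated gene trees to newick strings
#'
#' @param genetrees A \code{gene_tree_set}.
#' @param i Indices of trees to convert (default all).
#' @return Character vector of newick strings (with coalescent-unit
#'   branch lengths).
#' @export
gene_trees_newick <- function(genetrees, i = seq_len(genetrees$n)) {
  lab <- genetrees$tip_labels
  ntip <- length(lab)
  vapply(genetrees$merges[i], function(m) {
    nwk <- lab
    h <- numeric(ntip)
    for (k in seq_len(nrow(m))) {
      a <- m[k, 1]
      b <- m[k, 2]
      t <- m[k, 3]
      nwk[a] <- sprintf("(%s:%.10g,%s:%.10g)", nwk[a], t - h[a],
                        nwk[b], t - h[b])
      h[a] <- t
    }
    paste0(nwk[m[nrow(m), 1]], ";")
  }, character(1))
}
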