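# Supermatrix construction and site statistics: gap masking, concatenation,
# site classification, Fitch parsimony with CI/HI, site concordance factors,
# and per-branch putative synapomorphies.

BASES <- c("A", "C", "G", "T")

# IUPAC state-set bitmasks (A=1, C=2, G=4, T=8); gap/N/unknown = 15 (missing)
state_mask <- function(ch) {
  map <- c(A = 1L, C = 2L, G = 4L, T = 8L,
           R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
           B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, "-" = 15L, "?" = 15L)
  out <- unname(map[ch])
  out[is.na(out)] <- 15L
  out
}

#' Remove gap-rich alignment columns
#'
#' Columns in which the gap fraction reaches `max_gap_fraction` are removed
#' (a column with gaps in exactly half of the rows is removed; "less than
#' half" is retained).
#'
#' @param alignment A [dna_alignment()].
#' @param max_gap_fraction Removal threshold on the gap fraction (default 0.5).
#' @return List with `alignment` (filtered) and `mask` (removed original
#'   column indices, 1-based), so original coordinates are recoverable.
#' @export
mask_gap_rich_columns <- function(alignment, max_gap_fraction = 0.5) {
  m <- unclass(alignment)
  gap_frac <- colMeans(m == "-")
  drop <- which(gap_frac >= max_gap_fraction)
  if (length(drop) == ncol(m))
    ps_abort("all columns masked", "ps_empty_matrix_error")
  kept <- if (length(drop)) m[, -drop, drop = FALSE] else m
  list(alignment = dna_alignment(kept), mask = drop)
}

#' Concatenate alignment blocks into a supermatrix
#'
#' @param blocks List of [dna_alignment()] objects sharing a taxon namespace.
#' @param policy `"strict"` (all blocks must contain identical taxon sets) or
#'   `"fill"` (missing taxa padded with gaps).
#' @return List with `alignment` and `partitions`, a tibble mapping each
#'   block to its column interval (1-based inclusive).
#' @export
concatenate_alignments <- function(blocks, policy = c("strict", "fill")) {
  policy <- match.arg(policy)
  stopifnot(length(blocks) >= 1L)
  taxa <- sort(unique(unlist(lapply(blocks, rownames))))
  mats <- list(); parts <- list(); at <- 0L
  for (b in seq_along(blocks)) {
    m <- unclass(blocks[[b]])
    missing <- setdiff(taxa, rownames(m))
    if (length(missing) > 0L) {
      if (policy == "strict")
        ps_abort(sprintf("block %d lacks taxa: %s", b,
                         paste(missing, collapse = ", ")),
                 "ps_taxon_mismatch_error")
      pad <- matrix("-", nrow = length(missing), ncol = ncol(m),
                    dimnames = list(missing, NULL))
      m <- rbind(m, pad)
    }
    m <- m[taxa, , drop = FALSE]
    mats[[b]] <- m
    parts[[b]] <- tibble::tibble(
      block = names(blocks)[b] %||% as.character(b),
      start = at + 1L, end = at + ncol(m))
    at <- at + ncol(m)
  }
  list(alignment = dna_alignment(do.call(cbind, mats)),
       partitions = dplyr::bind_rows(parts))
}

#' Classify alignment sites
#'
#' Per column, gaps, N, and ambiguity codes are excluded from state counting.
#' Constant = at most one distinct state; parsimony-informative = at least
#' two states each with multiplicity at least two; singleton = variable but
#' not informative.
#'
#' @param alignment A [dna_alignment()].
#' @param masked Number of columns removed upstream (recorded, default 0).
#' @return One-row tibble of class `site_classification`: `columns`,
#'   `constant`, `variable`, `parsimony_informative`, `singleton`, `masked`.
#' @export
classify_sites <- function(alignment, masked = 0L) {
  m <- unclass(alignment)
  stats <- apply(m, 2L, function(col) {
    col <- col[col %in% BASES]
    if (length(col) == 0L) return(c(var = FALSE, pi = FALSE))
    tab <- table(col)
    c(var = length(tab) > 1L, pi = sum(tab >= 2L) >= 2L && length(tab) > 1L)
  })
  variable <- sum(stats["var", ])
  pi <- sum(stats["pi", ])
  structure(
    tibble::tibble(columns = ncol(m), constant = ncol(m) - variable,
                   variable = variable, parsimony_informative = pi,
                   singleton = variable - pi, masked = as.integer(masked)),
    class = c("site_classification", class(tibble::tibble())))
}

# ---- Fitch parsimony -----------------------------------------------------

#' Fitch parsimony length with consistency/homoplasy indices
#'
#' Per-site parsimony changes by the Fitch state-set pass (unordered
#' equal-cost states; gaps/N/ambiguity treated as missing = the full state
#' set). The per-site minimum is the number of distinct observed single
#' states minus one. CI = sum(min)/sum(length) and HI = 1 - CI, computed over
#' variable sites by default; invariant data yields CI = 1 with
#' `degenerate = TRUE`.
#'
#' @param tree An `ape::phylo` tree whose tips match the alignment taxa.
#' @param alignment A [dna_alignment()].
#' @param include_invariant Include parsimony-uninformative constant sites in
#'   the CI denominator (default `FALSE`).
#' @return Object of class `parsimony_result`: list with `total_length`,
#'   `per_site_length`, `min_possible`, `ci`, `hi`, `degenerate`.
#' @export
fitch_length <- function(tree, alignment, include_invariant = FALSE) {
  m <- unclass(alignment)
  if (!setequal(tree$tip.label, rownames(m)))
    ps_abort("tree tips and alignment taxa differ", "ps_taxon_error")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nsite <- ncol(m)
  masks <- matrix(15L, nrow = ntip + nnode, ncol = nsite)
  for (i in seq_len(ntip))
    masks[i, ] <- state_mask(m[tree$tip.label[i], ])
  changes <- numeric(nsite)
  visited <- logical(ntip + nnode)
  visited[seq_len(ntip)] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    if (!visited[parent]) {
      masks[parent, ] <- masks[child, ]
      visited[parent] <- TRUE
    } else {
      inter <- bitwAnd(masks[parent, ], masks[child, ])
      disjoint <- inter == 0L
      changes <- changes + disjoint
      masks[parent, ] <- ifelse(disjoint,
                                bitwOr(masks[parent, ], masks[child, ]),
                                inter)
    }
  }
  min_poss <- apply(m, 2L, function(col) {
    max(0L, length(unique(col[col %in% BASES])) - 1L)
  })
  counted <- if (include_invariant) rep(TRUE, nsite) else min_poss >= 1L
  degenerate <- sum(changes[counted]) == 0
  ci <- if (degenerate) 1 else sum(min_poss[counted]) / sum(changes[counted])
  structure(
    list(total_length = as.integer(sum(changes)),
         per_site_length = as.integer(changes),
         min_possible = as.integer(min_poss),
         ci = ci, hi = 1 - ci, degenerate = degenerate,
         include_invariant = include_invariant),
    class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("<parsimony_result> length %d, CI %.3f, HI %.3f%s\n",
              x$total_length, x$ci, x$hi,
              if (x$degenerate) " (degenerate: no variable sites)" else ""))
  invisible(x)
}

#' @method tidy parsimony_result
#' @export
tidy.parsimony_result <- function(x, ...) {
  tibble::tibble(site = seq_along(x$per_site_length),
                 length = x$per_site_length, min_possible = x$min_possible)
}

#' @method glance parsimony_result
#' @export
glance.parsimony_result <- function(x, ...) {
  tibble::tibble(total_length = x$total_length, ci = x$ci, hi = x$hi,
                 degenerate = x$degenerate)
}

# ---- site concordance factors --------------------------------------------

# adjacency list of the tree as an undirected graph
tree_adjacency <- function(tree) {
  nv <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nv)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# leaves reachable from `from` when the edge (block from -> via) is removed
reachable_leaves <- function(adj, ntip, start, blocked) {
  seen <- logical(length(adj))
  seen[blocked] <- TRUE
  stack <- start
  leaves <- integer(0)
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    if (v <= ntip) leaves <- c(leaves, v)
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  leaves
}

# site concordance and synapomorphy counting view the tree as unrooted (a
# degree-2 root would break the four-subtree decomposition)
as_unrooted <- function(tree) {
  if (ape::is.rooted(tree)) ape::unroot(tree) else tree
}

#' Enumerate internal branches of a tree
#'
#' Branch ids are edge row indices of the unrooted tree (`ape::unroot`),
#' which is also how [site_concordance()] and
#' [count_branch_synapomorphies()] interpret their `branch` argument.
#'
#' @param tree An `ape::phylo`.
#' @return Tibble with `branch` (edge row index in the unrooted
#'   `tree$edge`) and the two node ids; only edges joining two internal
#'   nodes are listed.
#' @export
internal_branches <- function(tree) {
  tree <- as_unrooted(tree)
  ntip <- length(tree$tip.label)
  idx <- which(tree$edge[, 1L] > ntip & tree$edge[, 2L] > ntip)
  tibble::tibble(branch = idx, node1 = tree$edge[idx, 1L],
                 node2 = tree$edge[idx, 2L])
}

# the four leaf groups around an internal branch
branch_quartet_groups <- function(tree, branch) {
  ntip <- length(tree$tip.label)
  if (branch < 1L || branch > nrow(tree$edge))
    ps_abort("no such branch", "ps_key_error")
  u <- tree$edge[branch, 1L]; v <- tree$edge[branch, 2L]
  if (u <= ntip || v <= ntip)
    ps_abort("branch is pendant to a leaf, not internal", "ps_not_internal_error")
  adj <- tree_adjacency(tree)
  nb_u <- setdiff(adj[[u]], v)
  nb_v <- setdiff(adj[[v]], u)
  if (length(nb_u) != 2L || length(nb_v) != 2L)
    ps_abort("site concordance requires a binary branch neighbourhood",
             "ps_not_internal_error")
  groups <- c(lapply(nb_u, function(w) reachable_leaves(adj, ntip, w, u)),
              lapply(nb_v, function(w) reachable_leaves(adj, ntip, w, v)))
  lapply(groups, function(g) tree$tip.label[g])
}

#' Site concordance factor for an internal branch
#'
#' For quartets made of one leaf from each of the four subtrees around the
#' branch, a site is decisive when the four leaves carry exactly two states,
#' each twice, so the site supports one of the three quartet topologies. sCF
#' is the mean over quartets of the fraction of decisive sites supporting the
#' tree's own topology (the first two groups together); sDF1/sDF2 are the
#' fractions for the two alternatives. All quartets are enumerated when the
#' quartet universe is at most `n_quartets`, otherwise `n_quartets` distinct
#' quartets are sampled reproducibly from `seed`.
#'
#' @param tree An `ape::phylo` over the alignment taxa.
#' @param alignment A [dna_alignment()].
#' @param branch Edge row index in `tree$edge` (see [internal_branches()]).
#' @param n_quartets Quartet sample size (default 100).
#' @param seed Integer seed for quartet sampling.
#' @return One-row tibble of class `concordance_result`: `branch`, `scf`,
#'   `sdf1`, `sdf2` (percent), `n_quartets`, `n_decisive_mean`,
#'   `synapomorphies`.
#' @export
site_concordance <- function(tree, alignment, branch, n_quartets = 100L,
                             seed = 1L) {
  m <- unclass(alignment)
  if (!setequal(tree$tip.label, rownames(m)))
    ps_abort("tree tips and alignment taxa differ", "ps_taxon_error")
  tree <- as_unrooted(tree)
  groups <- branch_quartet_groups(tree, branch)
  sizes <- vapply(groups, length, integer(1))
  universe <- prod(sizes)
  quartets <- if (universe <= n_quartets) {
    as.matrix(expand.grid(seq_len(sizes[1]), seq_len(sizes[2]),
                          seq_len(sizes[3]), seq_len(sizes[4])))
  } else {
    with_seed(seed, {
      if (universe <= 1e6) {
        picks <- sample.int(universe, n_quartets)
      } else {
        picks <- unique(ceiling(stats::runif(n_quartets * 2L) * universe))
        picks <- picks[seq_len(min(n_quartets, length(picks)))]
      }
      decode_quartets(picks, sizes)
    })
  }
  f1 <- f2 <- f3 <- ndec <- numeric(nrow(quartets))
  used <- logical(nrow(quartets))
  for (q in seq_len(nrow(quartets))) {
    tips <- vapply(1:4, function(g) groups[[g]][quartets[q, g]], character(1))
    a <- m[tips[1], ]; b <- m[tips[2], ]; c_ <- m[tips[3], ]; d <- m[tips[4], ]
    ok <- a %in% BASES & b %in% BASES & c_ %in% BASES & d %in% BASES
    s1 <- ok & a == b & c_ == d & a != c_          # supports tree (AB|CD)
    s2 <- ok & a == c_ & b == d & a != b           # AC|BD
    s3 <- ok & a == d & b == c_ & a != b           # AD|BC
    dec <- sum(s1) + sum(s2) + sum(s3)
    ndec[q] <- dec
    if (dec > 0L) {
      used[q] <- TRUE
      f1[q] <- sum(s1) / dec; f2[q] <- sum(s2) / dec; f3[q] <- sum(s3) / dec
    }
  }
  syn <- count_branch_synapomorphies(tree, alignment, branch)
  structure(
    tibble::tibble(
      branch = branch,
      scf = if (any(used)) 100 * mean(f1[used]) else NA_real_,
      sdf1 = if (any(used)) 100 * mean(f2[used]) else NA_real_,
      sdf2 = if (any(used)) 100 * mean(f3[used]) else NA_real_,
      n_quartets = nrow(quartets),
      n_decisive_mean = mean(ndec),
      synapomorphies = syn),
    class = c("concordance_result", class(tibble::tibble())))
}

decode_quartets <- function(picks, sizes) {
  picks <- picks - 1
  i1 <- picks %% sizes[1]
  r <- picks %/% sizes[1]
  i2 <- r %% sizes[2]
  r <- r %/% sizes[2]
  i3 <- r %% sizes[3]
  i4 <- r %/% sizes[3]
  cbind(i1 + 1L, i2 + 1L, i3 + 1L, i4 + 1L)
}

#' Site concordance for every internal branch
#'
#' @inheritParams site_concordance
#' @return Tibble with one [site_concordance()] row per internal branch.
#' @export
site_concordance_all <- function(tree, alignment, n_quartets = 100L,
                                 seed = 1L) {
  br <- internal_branches(tree)
  out <- purrr::map_dfr(br$branch, function(b)
    site_concordance(tree, alignment, b, n_quartets = n_quartets, seed = seed))
  structure(out, class = c("concordance_result", class(tibble::tibble())))
}

#' Count putative synapomorphies for a branch
#'
#' Columns where every non-missing taxon on one side of the branch's
#' bipartition shares one state, every non-missing taxon on the other side
#' shares a different state, and both sides have at least two non-missing
#' taxa. This strict two-sided reading of "putative synapomorphy" is one
#' defensible operational definition and is labelled as such.
#'
#' @inheritParams site_concordance
#' @return Integer count.
#' @export
count_branch_synapomorphies <- function(tree, alignment, branch) {
  m <- unclass(alignment)
  tree <- as_unrooted(tree)
  ntip <- length(tree$tip.label)
  u <- tree$edge[branch, 1L]; v <- tree$edge[branch, 2L]
  if (u <= ntip || v <= ntip)
    ps_abort("branch is pendant to a leaf, not internal", "ps_not_internal_error")
  adj <- tree_adjacency(tree)
  side <- tree$tip.label[reachable_leaves(adj, ntip, v, u)]
  other <- setdiff(tree$tip.label, side)
  ms <- m[side, , drop = FALSE]; mo <- m[other, , drop = FALSE]
  count <- 0L
  for (j in seq_len(ncol(m))) {
    a <- ms[, j]; a <- a[a %in% BASES]
    b <- mo[, j]; b <- b[b %in% BASES]
    if (length(a) >= 2L && length(b) >= 2L &&
        length(unique(a)) == 1L && length(unique(b)) == 1L && a[1] != b[1])
      count <- count + 1L
  }
  count
}
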