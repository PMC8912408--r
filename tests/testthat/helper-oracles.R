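# Shared fixtures and independent brute-force oracles.

# a small, fast synthetic plastome (mini template)
mini_spec <- function(seed = 1, lsc = 14000, ssc = 4000, ir = 6000, ...) {
  plastome_spec(seed = seed, lsc_length = lsc, ssc_length = ssc,
                ir_length = ir, template = "mini", ...)
}

# brute force: longest pair of disjoint exactly reverse-complementary
# substrings on the circle, by scanning match runs along every anti-diagonal
brute_longest_inverted_repeat <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[s]
  best <- 0L
  x <- 0:(n - 1)
  for (d in 0:(n - 1)) {
    y <- (d - x) %% n
    match_v <- s[x + 1] == comp[y + 1] & s[x + 1] != "N"
    r <- rle(match_v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      len <- r$lengths[i]
      # wrap: a run may continue across x = n-1 -> 0 on the same diagonal;
      # handled approximately by also testing the doubled run below
      a <- starts[i] - 1L                      # block A columns [a, a+len)
      b_lo <- (d - (a + len - 1L)) %% n        # block B columns
      # disjointness: usable length when A and B overlap is halved
      usable <- len
      aset <- (a + seq_len(len) - 1L) %% n
      bset <- (d - aset) %% n
      if (length(intersect(aset, bset)) > 0L) usable <- len %/% 2L
      best <- max(best, usable)
    }
  }
  best
}

# brute force per-site Fitch: minimize substitutions over all internal
# node labelings
brute_fitch_lengths <- function(tree, m) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  states <- c("A", "C", "G", "T")
  labelings <- as.matrix(expand.grid(rep(list(states), nn),
                                     stringsAsFactors = FALSE))
  per <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[tree$tip.label, j]
    missing <- !(col %in% states)
    bestc <- Inf
    for (r in seq_len(nrow(labelings))) {
      lab <- c(col, labelings[r, ])
      ch <- 0L
      for (e in seq_len(nrow(tree$edge))) {
        child <- tree$edge[e, 2L]
        if (child <= ntip && missing[child]) next
        if (lab[tree$edge[e, 1L]] != lab[child]) ch <- ch + 1L
      }
      if (ch < bestc) bestc <- ch
    }
    per[j] <- bestc
  }
  per
}

# naive primer-site scan: every circular placement, both strands
brute_primer_sites <- function(sequence, primer, max_mismatch) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  m <- nchar(primer)
  pc <- strsplit(primer, "")[[1]]
  rc <- rev(strsplit(chartr("ACGT", "TGCA", primer), "")[[1]])
  hits <- list()
  for (start in 0:(n - 1)) {
    win <- s[((start + 0:(m - 1)) %% n) + 1]
    for (strand in c("+", "-")) {
      tpl <- if (strand == "+") pc else rc
      neq <- win != tpl
      anchor <- if (strand == "+") (m - 4):m else 1:5
      if (sum(neq) <= max_mismatch && !any(neq[anchor]))
        hits[[length(hits) + 1L]] <- data.frame(start = start,
                                                strand = strand,
                                                mismatches = sum(neq))
    }
  }
  if (length(hits) == 0L) {
    data.frame(start = integer(), strand = character(),
               mismatches = integer())
  } else do.call(rbind, hits)
}

# overlap-based matching of inversion calls against planted truth
inversion_scores <- function(calls, truth) {
  ov <- function(s1, e1, s2, e2)
    pmin(e1, e2) - pmax(s1, s2) + 1 >= 0.5 * pmax(e1 - s1 + 1, e2 - s2 + 1)
  tp_call <- if (nrow(calls) == 0L) logical(0) else
    vapply(seq_len(nrow(calls)), function(i)
      any(ov(calls$start[i], calls$end[i], truth$start, truth$end)),
      logical(1))
  found <- vapply(seq_len(nrow(truth)), function(i)
    nrow(calls) > 0L &&
      any(pmin(calls$end, truth$end[i]) - pmax(calls$start, truth$start[i]) + 1 >=
            0.5 * (truth$end[i] - truth$start[i] + 1)), logical(1))
  list(tp = sum(tp_call), n_calls = nrow(calls), n_found = sum(found),
       n_truth = nrow(truth))
}

# internal branch whose bipartition equals the given tip set
pick_branch <- function(tree, tips) {
  tree_u <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  br <- internal_branches(tree)
  adj <- plastshift:::tree_adjacency(tree_u)
  ntip <- length(tree_u$tip.label)
  for (b in br$branch) {
    u <- tree_u$edge[b, 1]; v <- tree_u$edge[b, 2]
    side <- tree_u$tip.label[plastshift:::reachable_leaves(adj, ntip, v, u)]
    if (setequal(side, tips) ||
        setequal(setdiff(tree_u$tip.label, side), tips)) return(b)
  }
  stop("no branch with that bipartition")
}
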