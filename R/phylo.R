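#' Pairwise distance matrix from an MSA
#'
#' `p` is the mismatch proportion over columns where both rows are
#' non-gap; `poisson` is the Poisson correction `-log(1 - p)`.
#'
#' @param msa character matrix (rows = sequences), `-` for gaps.
#' @param model `"p"` or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal and row/col names.
#' @export
distance_matrix <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (nrow(msa) < 2) stop("need at least 2 aligned sequences", call. = FALSE)
  n <- nrow(msa)
  labs <- rownames(msa)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- msa[i, ] != "-" & msa[j, ] != "-"
      if (!any(ok)) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     labs[i], labs[j]), call. = FALSE)
      }
      p <- sum(msa[i, ok] != msa[j, ok]) / sum(ok)
      d <- if (model == "p") p else {
        if (p >= 1) stop("p >= 1: Poisson distance undefined", call. = FALSE)
        -log(1 - p)
      }
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion. Ties in Q are broken by
#' the lexicographically smallest label-sorted pair; negative estimated
#' branch lengths are clamped to 0 (the raw value is logged). `n = 2`
#' returns the single edge split `d/2, d/2`. On an additive matrix the
#' topology and all branch lengths are recovered exactly.
#'
#' @param D symmetric distance matrix with labels.
#' @return unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  if (any(is.na(D))) stop("NaN/NA in distance matrix", call. = FALSE)
  if (is.null(rownames(D))) stop("distance matrix must be labelled", call. = FALSE)
  labs <- rownames(D)
  n <- length(labs)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  rep_ <- labs            # newick fragment per active node
  key <- labs             # tie-break label per active node
  d <- D
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  clamp <- function(x, what) {
    if (x < 0) {
      log_msg("INFO", "nj", sprintf("negative branch length %.6g at %s clamped to 0", x, what))
      return(0)
    }
    x
  }
  while (length(rep_) > 3) {
    m <- length(rep_)
    r <- rowSums(d)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        pk <- paste(sort(c(key[i], key[j])), collapse = "\r")
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 && pk < best$pk)) {
          best <- list(q = q, i = i, j = j, pk = pk)
        }
      }
    }
    i <- best$i; j <- best$j
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    vi <- clamp(vi, key[i]); vj <- clamp(vj, key[j])
    newrep <- sprintf("(%s:%s,%s:%s)", rep_[i], fmt(vi), rep_[j], fmt(vj))
    newkey <- min(key[i], key[j])
    duk <- (d[i, -c(i, j), drop = TRUE] + d[j, -c(i, j), drop = TRUE] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- matrix(0, m - 1, m - 1)
    d2[seq_along(keep), seq_along(keep)] <- d[keep, keep]
    d2[m - 1, seq_along(keep)] <- duk
    d2[seq_along(keep), m - 1] <- duk
    d <- d2
    rep_ <- c(rep_[keep], newrep)
    key <- c(key[keep], newkey)
  }
  nwk <- if (length(rep_) == 2) {
    sprintf("(%s:%s,%s:%s);", rep_[1], fmt(d[1, 2] / 2), rep_[2], fmt(d[1, 2] / 2))
  } else {
    a <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2, key[1])
    b <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2, key[2])
    c_ <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2, key[3])
    sprintf("(%s:%s,%s:%s,%s:%s);",
            rep_[1], fmt(a), rep_[2], fmt(b), rep_[3], fmt(c_))
  }
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge induces a split of the leaf set; the split is
#' canonicalized as the sorted side containing the alphabetically first
#' tip, serialized as a single string. Trivial (single-leaf) splits are
#' dropped.
#'
#' @param tree [ape::phylo].
#' @return character vector of canonical split strings.
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  first <- all_tips[1]
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  root <- ntip + 1L
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  splits <- character(0)
  for (node in internal_children) {
    side <- sort(desc(node))
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (!(first %in% side)) side <- setdiff(all_tips, side)
    splits <- c(splits, paste(side, collapse = "|"))
  }
  unique(splits)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Columns of the MSA are resampled with replacement `n_reps` times, a
#' tree is rebuilt per replicate, and the support of each internal edge of
#' the full-data tree is `100 * (replicates containing that bipartition) /
#' n_reps`, rounded to integer. Replicates whose distance matrix is
#' undefined (an all-gap pair, or a saturated Poisson distance) are
#' discarded and logged; more than 50% discarded is an error.
#'
#' @param msa character matrix (rows = sequences, >= 4).
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param model distance model, see [distance_matrix].
#' @return the full-data NJ tree with `node.label` holding integer
#'   supports ("" at the root) and attribute `n_discarded`.
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L, model = "p") {
  if (nrow(msa) < 4) stop("need >= 4 sequences for bootstrap", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  full <- neighbor_joining(distance_matrix(msa, model))
  target <- tree_bipartitions(full)
  counts <- setNames(numeric(length(target)), target)
  set.seed(as.integer(seed))
  discarded <- 0
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
    rep_tree <- tryCatch(
      neighbor_joining(distance_matrix(msa[, cols, drop = FALSE], model)),
      error = function(e) NULL
    )
    if (is.null(rep_tree)) {
      discarded <- discarded + 1
      log_msg("WARN", "bootstrap", sprintf("replicate %d discarded", r))
      next
    }
    got <- tree_bipartitions(rep_tree)
    hit <- target %in% got
    counts[hit] <- counts[hit] + 1
  }
  if (discarded > n_reps / 2) {
    stop("more than 50% of bootstrap replicates discarded", call. = FALSE)
  }
  supports <- setNames(as.integer(round(100 * counts / n_reps)), names(counts))
  ntip <- length(full$tip.label)
  labels <- character(full$Nnode)
  # map each internal node (except the root) to its split's support
  desc <- function(node) {
    if (node <= ntip) return(full$tip.label[node])
    kids <- full$edge[full$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  all_tips <- sort(full$tip.label)
  first <- all_tips[1]
  non_root <- if (full$Nnode >= 2) (ntip + 2L):(ntip + full$Nnode) else integer(0)
  for (node in non_root) {
    side <- sort(desc(node))
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (!(first %in% side)) side <- setdiff(all_tips, side)
    kkey <- paste(side, collapse = "|")
    if (kkey %in% names(counts)) {
      labels[node - ntip] <- as.character(supports[kkey])
    }
  }
  full$node.label <- labels
  attr(full, "n_discarded") <- discarded
  full
}

#' Two-group split of a tree at its longest internal edge
#'
#' The survey's main-group/subgroup dichotomy has no printed criterion;
#' as a declared heuristic, leaves are partitioned by the two sides of
#' the longest internal edge.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @return named character vector, `"main"` for the larger side and
#'   `"sub"` for the smaller.
#' @export
group_by_longest_edge <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  if (length(internal) == 0) {
    return(setNames(rep("main", ntip), tree$tip.label))
  }
  e <- internal[which.max(tree$edge.length[internal])]
  node <- tree$edge[e, 2]
  desc <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    unlist(lapply(kids, desc))
  }
  side <- desc(node)
  other <- setdiff(tree$tip.label, side)
  big <- if (length(side) >= length(other)) side else other
  out <- setNames(ifelse(tree$tip.label %in% big, "main", "sub"),
                  tree$tip.label)
  out
}
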