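## Neighbor-joining trees, bootstrap supports, and Retand lineage
## assignment by clade membership under midpoint rooting.

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining with the Q criterion. Ties in Q
#' are broken lexicographically on the joined pair's representative labels
#' (the alphabetically smallest leaf of each cluster), so the result does
#' not depend on input order. Negative branch-length estimates are clamped
#' to zero. Additive distance matrices are recovered exactly.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("non-symmetric distance matrix")
  if (any(d < 0)) stop("negative distances")
  labels <- rownames(d)
  n <- nrow(d)
  ## active clusters: tree node id + representative (min leaf label)
  node_id <- seq_len(n)
  rep_lab <- labels
  D <- unname(d)
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  next_internal <- n + 1L
  clamp <- function(x) max(0, x)
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    u <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, node_id[i]), c(u, node_id[j]))
    lens <- c(lens, clamp(vi), clamp(vj))
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    node_id <- c(node_id[keep], u)
    rep_lab <- c(rep_lab[keep], min(rep_lab[i], rep_lab[j]))
    D <- D2
  }
  va <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  vb <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  vc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  center <- next_internal
  edges <- rbind(edges, c(center, node_id[1]), c(center, node_id[2]),
                 c(center, node_id[3]))
  lens <- c(lens, clamp(va), clamp(vb), clamp(vc))
  ## ape convention: the (root) center node is numbered n + 1
  remap <- function(x) ifelse(x <= n, x,
                              ifelse(x == center, n + 1L, x + 1L))
  edges <- matrix(remap(edges), ncol = 2)
  phy <- structure(list(edge = edges, edge.length = lens,
                        tip.label = labels, Nnode = n - 2L),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

## canonical key of the bipartition induced by a clade's tip set
.bipart_key <- function(tips, all_tips) {
  ref <- sort(all_tips)[1]
  side <- if (ref %in% tips) sort(setdiff(all_tips, tips)) else sort(tips)
  paste(side, collapse = "\r")
}

## keys of all non-trivial bipartitions of an unrooted tree
.tree_biparts <- function(tree) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    if (length(p) >= 2 && length(p) <= n - 2) {
      keys <- c(keys, .bipart_key(tree$tip.label[p], tree$tip.label))
    }
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' p-distances for each replicate, and reports for every internal edge of
#' the full-alignment tree the number of replicates containing the same
#' bipartition (0..replicates). Bipartitions absent from every replicate
#' get support 0. Deterministic for a fixed seed.
#'
#' @param alignment Aligned sequences (see [p_distance()]), >= 2 columns.
#' @param replicates Number of bootstrap replicates (mining used 100;
#'   published cluster trees 1,000).
#' @param rng_seed Integer seed.
#' @return A list: `tree` (the full-alignment NJ tree with `node.label`
#'   set to supports, `NA` for trivial splits) and `supports` (named
#'   integer vector keyed by bipartition).
#' @export
bootstrap_support <- function(alignment, replicates = 100, rng_seed = 1) {
  stopifnot(replicates >= 1)
  if (methods::is(alignment, "AAStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  L <- unique(nchar(alignment))
  stopifnot(length(L) == 1)
  if (L < 2) stop("alignment must have at least 2 columns")
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  main <- nj_tree(p_distance(alignment))
  counts <- stats::setNames(integer(0), character(0))
  with_seed(rng_seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
      keys <- .tree_biparts(nj_tree(p_distance(res)))
      for (k in keys) {
        counts[k] <- if (k %in% names(counts)) counts[k] + 1L else 1L
      }
    }
  })
  ## attach supports to the main tree's internal nodes
  n <- length(main$tip.label)
  nnode <- main$Nnode
  node_support <- rep(NA_integer_, nnode)
  for (node in (n + 1):(n + nnode)) {
    tips <- main$tip.label[.tips_under(main, node)]
    if (length(tips) >= 2 && length(tips) <= n - 2) {
      k <- .bipart_key(tips, main$tip.label)
      node_support[node - n] <- if (k %in% names(counts)) counts[[k]] else 0L
    }
  }
  main$node.label <- node_support
  own <- .tree_biparts(main)
  sup <- stats::setNames(integer(length(own)), own)
  for (k in own) sup[k] <- if (k %in% names(counts)) counts[[k]] else 0L
  list(tree = main, supports = sup)
}

## tip indices under a node (the node itself if a tip)
.tips_under <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- kids[kids <= n]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > n])
  }
  out
}

#' Assign candidate RT domains to lineages by clade membership
#'
#' Builds an NJ tree (p-distances on a progressive alignment) over the
#' candidates plus the model panel, roots it at the midpoint, and labels a
#' candidate `Retand` iff it falls inside the smallest clade containing
#' all Retand references and no panel member of another lineage.
#' Candidates inside another lineage's analogous clade get that lineage's
#' label; candidates outside every pure lineage clade are `unassigned`.
#'
#' @param candidates Named character vector of candidate RT proteins, or a
#'   [find_rt_hits()] table (ids are built from genome and position).
#' @param panel Model panel ([Biostrings::AAStringSet], `lineage|name`
#'   headers).
#' @param retand_lineage Panel lineage treated as the target (default
#'   `"Retand"`).
#' @return A data.frame with `id`, `lineage`, plus the hit columns when a
#'   hit table was supplied.
#' @export
assign_lineage <- function(candidates, panel = synthetic_rt_panel(),
                           retand_lineage = "Retand") {
  hit_table <- NULL
  if (is.data.frame(candidates)) {
    hit_table <- candidates
    if (!nrow(hit_table)) {
      return(cbind(hit_table, data.frame(lineage = character(0))))
    }
    ids <- sprintf("cand_%s_%d", hit_table$genome_id, hit_table$start)
    candidates <- stats::setNames(hit_table$protein, ids)
  }
  if (!length(candidates)) {
    return(data.frame(id = character(0), lineage = character(0)))
  }
  pan_lin <- sub("\\|.*$", "", names(panel))
  if (!retand_lineage %in% pan_lin) {
    stop("panel contains no ", retand_lineage, " references")
  }
  pan <- stats::setNames(as.character(panel), names(panel))
  if (any(names(candidates) %in% names(pan))) {
    stop("candidate ids collide with panel names")
  }
  aln <- align_panel(c(candidates, pan))
  tree <- nj_tree(p_distance(aln))
  rooted <- .midpoint_root(tree)
  lineages <- unique(pan_lin)
  clade_tips <- list()
  for (lg in lineages) {
    members <- names(pan)[pan_lin == lg]
    tips <- if (length(members) == 1) members else {
      node <- ape::getMRCA(rooted, members)
      rooted$tip.label[.tips_under(rooted, node)]
    }
    other_panel <- intersect(tips, names(pan)[pan_lin != lg])
    if (length(other_panel) == 0) clade_tips[[lg]] <- tips
  }
  lab <- vapply(names(candidates), function(id) {
    containing <- names(clade_tips)[vapply(clade_tips, function(tp)
      id %in% tp, logical(1))]
    if (!length(containing)) return("unassigned")
    sizes <- vapply(containing, function(lg) length(clade_tips[[lg]]),
                    numeric(1))
    containing[order(sizes)][1]
  }, character(1))
  out <- data.frame(id = names(candidates), lineage = unname(lab),
                    stringsAsFactors = FALSE)
  if (!is.null(hit_table)) out <- cbind(hit_table, lineage = out$lineage)
  out
}

## midpoint rooting (longest tip-to-tip path, root at its middle)
.midpoint_root <- function(tree) {
  if (requireNamespace("phangorn", quietly = TRUE)) {
    return(phangorn::midpoint(tree))
  }
  ## fallback: root on the longest-path edge via ape
  d <- ape::dist.nodes(tree)
  n <- length(tree$tip.label)
  tipd <- d[seq_len(n), seq_len(n)]
  far <- which(tipd == max(tipd), arr.ind = TRUE)[1, ]
  ape::root(tree, outgroup = far[1], resolve.root = TRUE)
}
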