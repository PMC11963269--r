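## Independent oracles used by unit and acceptance tests. These are
## deliberately naive re-derivations that share no code with the package
## paths they check.

## --- full Smith-Waterman (affine gaps) in plain R -------------------------
## Returns the best local score and the subject span achieving it.
oracle_sw <- function(query, subject, mat, open = 11, ext = 1) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (left moves)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (up moves)
  best <- 0; best_ij <- c(0L, 0L)
  ## BLAST gap convention: a length-k gap costs open + k * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[q[i - 1], s[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) {
        best <- H[i, j]
        best_ij <- c(i, j)
      }
    }
  }
  ## recover the subject start by traceback on values
  list(score = best, end_j = best_ij[2] - 1L)
}

## --- brute-force six-frame ORF scan ---------------------------------------
## Walks codons directly on the nucleotide sequence; for each (strand,
## frame) keeps the first-ATG-to-stop ORF per stop codon.
oracle_orfs <- function(seq, min_len) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") chars else rev(unname(comp[chars]))
    for (off in 0:2) {
      starts <- seq(off + 1, n - 2, by = 3)
      codons <- vapply(starts, function(p)
        paste(sc[p:(p + 2)], collapse = ""), character(1))
      aas <- unname(code[codons])
      aas[is.na(aas)] <- "X"
      open_at <- NA_integer_
      for (k in seq_along(aas)) {
        if (aas[k] == "*") {
          if (!is.na(open_at)) {
            a <- starts[open_at]; b <- starts[k] + 2L
            len <- b - a + 1L
            if (len >= min_len) {
              sp <- if (strand == "+") c(a, b) else c(n - b + 1L, n - a + 1L)
              out[[length(out) + 1]] <- data.frame(
                start = as.integer(sp[1]), end = as.integer(sp[2]),
                strand = strand, length = as.integer(len))
            }
          }
          open_at <- NA_integer_
        } else if (is.na(open_at) && aas[k] == "M") {
          open_at <- k
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0)))
  }
  o <- do.call(rbind, out)
  o <- o[order(o$start, o$end, o$strand), ]
  rownames(o) <- NULL
  o
}

## --- exhaustive (start, period) tandem-array scan -------------------------
oracle_tandems <- function(seq, min_copies = 3, max_period = 20,
                           min_span = 24) {
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  cand <- list()
  for (p in seq_len(max_period)) {
    for (s in seq_len(L - min_copies * p + 1)) {
      unit <- x[s:(s + p - 1)]
      k <- 1L
      while (s + (k + 1) * p - 1 <= L &&
             all(x[(s + k * p):(s + (k + 1) * p - 1)] == unit)) {
        k <- k + 1L
      }
      if (k >= min_copies && k * p >= min_span) {
        cand[[length(cand) + 1]] <- data.frame(
          start = s, end = s + k * p - 1L, period = p, copies = k)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copies = integer(0)))
  }
  cand <- do.call(rbind, cand)
  ## drop arrays contained in a longer array of the same period
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    same <- cand$period == cand$period[i]
    inside <- same & cand$start <= cand$start[i] & cand$end >= cand$end[i] &
      (cand$start != cand$start[i] | cand$end != cand$end[i])
    if (any(inside)) keep[i] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- unique(cand)
  ## same resolution rule, re-derived: copies*period desc, period asc,
  ## start asc, greedy non-overlapping
  cand <- cand[order(-(cand$copies * cand$period), cand$period, cand$start),
               , drop = FALSE]
  occupied <- logical(L)
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(occupied[span])) {
      sel[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

## --- least-squares fit of a distance matrix on a fixed topology -----------
## residual ~ 0 iff the topology is consistent with the (additive) matrix
oracle_ls_fit <- function(phy, D) {
  n <- length(phy$tip.label)
  ne <- nrow(phy$edge)
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), ne)
  y <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    path <- ape::nodepath(phy, i, j)
    for (e in seq_len(ne)) {
      u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
      hit <- FALSE
      for (q in seq_len(length(path) - 1)) {
        if ((path[q] == u && path[q + 1] == v) ||
            (path[q] == v && path[q + 1] == u)) hit <- TRUE
      }
      if (hit) A[k, e] <- 1
    }
    y[k] <- D[phy$tip.label[i], phy$tip.label[j]]
  }
  fit <- stats::lm.fit(A, y)
  list(residual = sqrt(sum(fit$residuals^2)),
       lengths = fit$coefficients)
}

## random unrooted binary tree with positive branch lengths, plus its
## additive tip distance matrix
random_additive_case <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  phy <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(phy)
  list(tree = phy, D = D[sort(rownames(D)), sort(colnames(D))])
}
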