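## Progressive multiple alignment of protein panels.
##
## Guide tree from pairwise global-alignment distances (UPGMA), then
## profile-profile merges with BLOSUM62 sum-of-pairs column scores and
## affine gaps (open 11, extend 1). Small panels only (tens of sequences,
## a few hundred columns) - exactness over speed.

.blosum62_aa <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())[AA_ORDER, AA_ORDER]
}

## column frequency matrix (20 x L) of an alignment block (character matrix)
.profile_freq <- function(block) {
  L <- ncol(block)
  f <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA_ORDER, NULL))
  nr <- nrow(block)
  for (j in seq_len(L)) {
    tb <- table(factor(block[, j], levels = AA_ORDER))
    f[, j] <- as.numeric(tb) / nr
  }
  f
}

## Affine-gap global alignment of two profile blocks; returns the merged
## character matrix (rows of A then rows of B).
.profile_merge <- function(A, B, S, open = 11, ext = 1) {
  fa <- .profile_freq(A)
  fb <- .profile_freq(B)
  sc <- t(fa) %*% S %*% fb
  n <- ncol(A); m <- ncol(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  ## BLAST gap convention: a length-k gap costs open + k * ext
  Y[1, 2:(m + 1)] <- -open - (1:m) * ext
  jj <- seq_len(m)
  ## row-wise DP: M and X depend only on the previous row; the left-gap
  ## state Y is a running maximum over the current M row (cummax trick)
  for (i in 2:(n + 1)) {
    prevM <- M[i - 1, ]; prevX <- X[i - 1, ]; prevY <- Y[i - 1, ]
    best_prev <- pmax(prevM, prevX, prevY)
    M[i, jj + 1] <- sc[i - 1, ] + best_prev[jj]
    X[i, ] <- pmax(prevM - open - ext, prevX - ext)
    W <- M[i, jj] - open + jj * ext
    Y[i, jj + 1] <- cummax(W) - (jj + 1) * ext
  }
  ## traceback by value recomputation (ties prefer the match state, as in
  ## the forward pass)
  eps <- 1e-9
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  colsA <- integer(0); colsB <- integer(0)  # 0 = gap column
  while (i > 1 || j > 1) {
    if (i == 1) {
      colsA <- c(0L, colsA); colsB <- c(j - 1, colsB); j <- j - 1
    } else if (j == 1) {
      colsA <- c(i - 1, colsA); colsB <- c(0L, colsB); i <- i - 1
    } else if (state == 1L) {
      colsA <- c(i - 1, colsA); colsB <- c(j - 1, colsB)
      state <- which.max(c(M[i - 1, j - 1], X[i - 1, j - 1],
                           Y[i - 1, j - 1]))
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      colsA <- c(i - 1, colsA); colsB <- c(0L, colsB)
      state <- if (X[i, j] >= M[i - 1, j] - open - ext - eps) 1L else 2L
      i <- i - 1
    } else {
      colsA <- c(0L, colsA); colsB <- c(j - 1, colsB)
      state <- if (Y[i, j] >= M[i, j - 1] - open - ext - eps) 1L else 3L
      j <- j - 1
    }
  }
  take <- function(block, cols) {
    out <- matrix("-", nrow(block), length(cols))
    nz <- cols > 0
    out[, nz] <- block[, cols[nz], drop = FALSE]
    out
  }
  rbind(take(A, colsA), take(B, colsB))
}

#' Progressive multiple alignment
#'
#' Aligns protein sequences progressively: pairwise global-alignment
#' distances feed a UPGMA guide tree, and profiles are merged bottom-up
#' with BLOSUM62 column scores and affine gap penalties (11/1). Removing
#' all-gap characters from any output row recovers the input sequence.
#'
#' @param sequences Named character vector or [Biostrings::AAStringSet]
#'   (at least one sequence; alignment needs two or more).
#' @return An [Biostrings::AAStringSet] of equal-length aligned rows, in
#'   input order.
#' @export
align_panel <- function(sequences) {
  if (methods::is(sequences, "AAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  n <- length(sequences)
  if (n == 0) stop("empty input")
  if (is.null(names(sequences))) names(sequences) <- paste0("s", seq_len(n))
  if (n == 1) return(Biostrings::AAStringSet(sequences))
  S <- .blosum62_aa()
  ## guide distances; one vectorized pairwiseAlignment call per subject
  D <- matrix(0, n, n)
  mat_full <- {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    get("BLOSUM62", envir = environment())
  }
  aaset <- Biostrings::AAStringSet(sequences)
  for (i in 1:(n - 1)) {
    js <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      aaset[js], Biostrings::AAString(sequences[[i]]),
      type = "global", substitutionMatrix = mat_full,
      gapOpening = 11, gapExtension = 1)
    alen <- nchar(as.character(Biostrings::pattern(aln)))
    d <- 1 - Biostrings::nmatch(aln) / alen
    D[i, js] <- D[js, i] <- d
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  blocks <- lapply(sequences, function(s) {
    matrix(strsplit(s, "")[[1]], nrow = 1)
  })
  rows_of <- as.list(seq_len(n))
  merged_blocks <- vector("list", n - 1)
  merged_rows <- vector("list", n - 1)
  get_block <- function(k) if (k < 0) blocks[[-k]] else merged_blocks[[k]]
  get_rows <- function(k) if (k < 0) rows_of[[-k]] else merged_rows[[k]]
  for (s in seq_len(n - 1)) {
    a <- hc$merge[s, 1]; b <- hc$merge[s, 2]
    merged_blocks[[s]] <- .profile_merge(get_block(a), get_block(b), S)
    merged_rows[[s]] <- c(get_rows(a), get_rows(b))
  }
  final <- merged_blocks[[n - 1]]
  ord <- order(merged_rows[[n - 1]])
  final <- final[ord, , drop = FALSE]
  out <- apply(final, 1, paste, collapse = "")
  Biostrings::AAStringSet(stats::setNames(out, names(sequences)))
}

#' Pairwise p-distance matrix from an alignment
#'
#' p-distance over shared ungapped columns: the fraction of differing
#' residues among columns where neither sequence has a gap. Pairs with no
#' shared columns get distance 1.
#'
#' @param alignment Aligned sequences ([Biostrings::AAStringSet] or named
#'   character vector, equal lengths).
#' @return A symmetric numeric matrix with taxon dimnames.
#' @export
p_distance <- function(alignment) {
  if (methods::is(alignment, "AAStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  stopifnot(length(unique(nchar(alignment))) == 1)
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  gap <- m == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !gap[i, ] & !gap[j, ]
      ns <- sum(shared)
      D[i, j] <- D[j, i] <- if (ns == 0) 1 else
        sum(m[i, shared] != m[j, shared]) / ns
    }
  }
  D
}
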