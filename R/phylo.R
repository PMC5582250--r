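#' Optimal global pairwise alignment with identity
#'
#' Needleman-Wunsch global alignment under a simple linear scheme
#' (match +1, mismatch -1, gap -2 by default), delegated to
#' `Biostrings::pairwiseAlignment`.  Identity is the number of matched
#' columns divided by the total number of alignment columns (gaps
#' included).
#'
#' @param a,b nucleotide strings (RNA or DNA).
#' @param match,mismatch,gap scoring parameters.
#' @return list with `score`, `identity`, `aligned_a`, `aligned_b`.
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(nzchar(a), nzchar(b))
  a_dna <- chartr("U", "T", toupper(a))
  b_dna <- chartr("U", "T", toupper(b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(a_dna, b_dna, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = -gap)
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  av <- strsplit(pa, "")[[1]]; bv <- strsplit(pb, "")[[1]]
  matches <- sum(av == bv & av != "-")
  list(score = Biostrings::score(al),
       identity = matches / length(av),
       aligned_a = chartr("T", "U", pa),
       aligned_b = chartr("T", "U", pb))
}

#' Identity-based distance matrix
#'
#' All-pairs global alignment identity (via [pairwise_align()]) turned into
#' distances `d(i,j) = 1 - identity(i,j)`.
#'
#' @param records `seq_set` of at least 3 sequences.
#' @param ... scoring parameters passed to [pairwise_align()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
identity_distance <- function(records, ...) {
  n <- nrow(records)
  if (n < 3) stop("identity_distance needs at least 3 records")
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- pairwise_align(records$seq[i], records$seq[j], ...)
      d[i, j] <- d[j, i] <- 1 - al$identity
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion; ties in Q are
#' broken towards the smallest (i, j) index pair, so the tree is
#' deterministic for any input.  Negative branch-length estimates are
#' clamped to zero (with a message).  Exact on additive matrices: path
#' lengths on the returned tree reproduce the input distances to machine
#' precision.
#'
#' @param dm symmetric distance matrix with dimnames (taxa), n >= 3.
#' @return an `ape::phylo` unrooted tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbour joining needs at least 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(dm < -1e-12)) stop("distances must be non-negative")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
  labels <- rownames(dm)
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.12g", x)
  }
  nodes <- as.list(labels)  # newick fragments
  d <- dm
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(d)
    # Q(i,j) = (m - 2) d(i,j) - r_i - r_j ; smallest index pair wins ties
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    merged <- paste0("(", nodes[[i]], ":", fmt(li), ",",
                     nodes[[j]], ":", fmt(lj), ")")
    dk <- vapply(seq_len(m), function(k) {
      0.5 * (d[i, k] + d[j, k] - d[i, j])
    }, numeric(1))
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], merged)
    d <- d2
  }
  # terminal star: analytic branch lengths
  x <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  y <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  z <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  nwk <- paste0("(", nodes[[1]], ":", fmt(x), ",", nodes[[2]], ":", fmt(y),
                ",", nodes[[3]], ":", fmt(z), ");")
  if (clamped) message("negative NJ branch length(s) clamped to zero")
  ape::read.tree(text = nwk)
}

#' Build a per-family neighbour-joining tree of precursor sequences
#'
#' @param records `seq_set` of precursor sequences (>= 3).
#' @param ... passed to [identity_distance()].
#' @return an `ape::phylo` tree.
#' @export
family_tree <- function(records, ...) {
  neighbor_joining(identity_distance(records, ...))
}
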