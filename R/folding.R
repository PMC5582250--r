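#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' Runs the package's nearest-neighbour dynamic program (Zuker-style V/WM
#' recursions) over the embedded 37 C energy table: stacking for the six
#' canonical pair types (Watson-Crick plus G:U), tabulated hairpin, bulge
#' and interior loop initiation with Jacobson-Stockmayer logarithmic
#' extrapolation, an interior-loop asymmetry penalty, and an affine
#' multibranch penalty.  Pseudoknots are excluded by construction, hairpin
#' loops are at least 3 nt, interior/bulge loops are capped at
#' `max_loop_size`, and `N` never pairs.  Among equal-energy structures the
#' one with fewer pairs is preferred and traceback choices are made in a
#' fixed order, so folding is deterministic.
#'
#' @param sequence RNA string, 10-1000 nt, alphabet `A,C,G,U,N` (`T`
#'   accepted and read as `U`).
#' @param max_loop_size largest interior/bulge loop size, nt (default 30).
#' @return an object of class `rna_structure`: list with `sequence`,
#'   `dotbracket`, `mfe` (kcal/mol, 0.1 resolution), `pairs` (two-column
#'   matrix of 1-based partners, i < j) and `length`.
#' @examples
#' st <- fold_rna("GGGGGAAAAACCCCC")
#' st$mfe
#' st$dotbracket
#' @export
fold_rna <- function(sequence, max_loop_size = 30) {
  sequence <- normalize_residues(sequence, "RNA")
  if (nchar(sequence) < 10) stop("sequence shorter than 10 nt cannot be folded")
  res <- c_fold(sequence, as.integer(max_loop_size))
  structure(list(sequence = sequence,
                 dotbracket = res$dotbracket,
                 mfe = res$energy10 / 10,
                 pairs = res$pairs,
                 length = nchar(sequence)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", sep = "")
  cat(sprintf("%s (%.1f)\n", x$dotbracket, x$mfe))
  invisible(x)
}

#' Free energy of an explicit secondary structure
#'
#' Evaluates an arbitrary non-crossing pair set under the same energy model
#' as [fold_rna()] by loop decomposition.  Structures violating a hard
#' constraint (non-canonical pair, hairpin loop < 3 nt, crossing pairs,
#' interior/bulge loop above `max_loop_size`) evaluate to `Inf`.
#'
#' @param sequence RNA string.
#' @param pairs two-column matrix of 1-based pair coordinates (i < j); a
#'   zero-row matrix is the open structure with energy 0.
#' @param max_loop_size largest interior/bulge loop size, nt.
#' @return energy in kcal/mol, or `Inf` for a forbidden structure.
#' @export
structure_energy <- function(sequence, pairs, max_loop_size = 30) {
  sequence <- normalize_residues(sequence, "RNA")
  if (is.null(pairs) || length(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  e <- c_eval_structure(sequence, pairs, as.integer(max_loop_size))
  if (is.na(e[1])) Inf else e[1] / 10
}

#' Maximum number of non-crossing canonical base pairs
#'
#' Nussinov-style pairing-count dynamic program over Watson-Crick and G:U
#' pairs with hairpin loops of at least 3 nt; used as a structural oracle
#' for generated hairpins.
#'
#' @param sequence RNA string (any length; exhaustive cross-checks in the
#'   test-suite are limited to short sequences).
#' @return integer pair count.
#' @examples
#' max_pairing("GGGAAACCC")  # 3
#' @export
max_pairing <- function(sequence) {
  c_max_pairing(normalize_residues(sequence, "RNA"))
}

#' Exhaustive minimum free energy by structure enumeration
#'
#' Enumerates every valid non-crossing set of canonical pairs (hairpin
#' loops >= 3 nt) and scores each with [structure_energy()], returning the
#' minimum.  Exponential in sequence length; intended as an independent
#' check of the dynamic program on short sequences.
#'
#' @param sequence RNA string (<= ~16 nt is practical).
#' @param max_loop_size largest interior/bulge loop size, nt.
#' @return list with `mfe` (kcal/mol) and `n_structures` examined.
#' @export
brute_force_mfe <- function(sequence, max_loop_size = 30) {
  sequence <- normalize_residues(sequence, "RNA")
  n <- nchar(sequence)
  s <- strsplit(sequence, "")[[1]]
  ok_pair <- function(a, b) {
    paste0(a, b) %in% c("CG", "GC", "GU", "UG", "AU", "UA")
  }
  cand <- list()
  for (i in seq_len(n)) {
    j <- i + 4
    while (j <= n) {
      if (ok_pair(s[i], s[j])) cand[[length(cand) + 1]] <- c(i, j)
      j <- j + 1
    }
  }
  best <- 0  # open structure
  count <- 1L
  m <- length(cand)
  if (m > 0) {
    # depth-first over compatible pair subsets
    rec <- function(start, chosen) {
      for (k in start:m) {
        if (k > m) break
        p <- cand[[k]]
        compatible <- TRUE
        for (q in chosen) {
          # no shared bases, no crossing
          if (p[1] == q[1] || p[1] == q[2] || p[2] == q[1] || p[2] == q[2] ||
              (q[1] < p[1] && p[1] < q[2] && q[2] < p[2]) ||
              (p[1] < q[1] && q[1] < p[2] && p[2] < q[2])) {
            compatible <- FALSE
            break
          }
        }
        if (!compatible) next
        chosen2 <- c(chosen, list(p))
        e <- structure_energy(sequence, do.call(rbind, chosen2), max_loop_size)
        count <<- count + 1L
        if (e < best) best <<- e
        if (k < m) rec(k + 1, chosen2)
      }
    }
    rec(1, list())
  }
  list(mfe = best, n_structures = count)
}

#' Locate the hairpin around a mature region and derive its features
#'
#' Given a folded structure and the 1-based inclusive coordinates of the
#' mature miRNA within it, determines which arm the mature sits on (`5p`
#' when its partners lie downstream, `3p` when upstream, `loop` when it is
#' unpaired inside a hairpin loop or its pairing is ambiguous, `outside`
#' when unpaired outside any stem), counts the mature positions left
#' unpaired against the star arm (duplex mismatches), and measures the
#' largest unpaired run inside the mature region on its own strand.
#'
#' @param struct an `rna_structure` from [fold_rna()].
#' @param mature_range integer vector `c(start, end)`, 1-based inclusive.
#' @return list of class `hairpin_features`: `arm`, `duplex_mismatches`,
#'   `largest_mature_gap`, `mature_paired`, `loop_start`, `loop_end`,
#'   `stem5`, `stem3`.
#' @export
extract_hairpin <- function(struct, mature_range) {
  stopifnot(inherits(struct, "rna_structure"), length(mature_range) == 2)
  n <- struct$length
  ms <- mature_range[1]; me <- mature_range[2]
  if (ms < 1 || me > n || ms > me) stop("mature_range outside the structure")
  partner <- integer(n)
  if (nrow(struct$pairs) > 0) {
    partner[struct$pairs[, 1]] <- struct$pairs[, 2]
    partner[struct$pairs[, 2]] <- struct$pairs[, 1]
  }
  idx <- ms:me
  p <- partner[idx]
  right <- sum(p > me)          # partners downstream of the mature
  left <- sum(p >= 1 & p < ms)  # partners upstream
  paired_star <- sum(p > me | (p >= 1 & p < ms))
  arm <- if (right == 0 && left == 0) {
    if (any(enclosing_pair_exists(partner, ms, me))) "loop" else "outside"
  } else if (right > left) "5p" else if (left > right) "3p" else "loop"
  duplex_mm <- length(idx) - paired_star
  # largest unpaired run on the mature's own strand
  runs <- rle(p == 0)
  largest_gap <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  # innermost hairpin loop associated with the mature's stem
  loop <- find_hairpin_loop(partner, ms, me, arm)
  structure(list(arm = arm,
                 duplex_mismatches = as.integer(duplex_mm),
                 largest_mature_gap = as.integer(largest_gap),
                 mature_paired = as.integer(paired_star),
                 loop_start = loop$start, loop_end = loop$end,
                 stem5 = loop$stem5, stem3 = loop$stem3),
            class = "hairpin_features")
}

enclosing_pair_exists <- function(partner, ms, me) {
  n <- length(partner)
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j > i && i < ms && j > me) return(TRUE)
  }
  FALSE
}

find_hairpin_loop <- function(partner, ms, me, arm) {
  n <- length(partner)
  # hairpin loops: closing pairs with no pair strictly inside
  closings <- NULL
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j > i) {
      inside <- if (j - i > 1) any(partner[(i + 1):(j - 1)] != 0) else FALSE
      if (!inside) closings <- rbind(closings, c(i, j))
    }
  }
  empty <- list(start = NA_integer_, end = NA_integer_,
                stem5 = c(NA_integer_, NA_integer_),
                stem3 = c(NA_integer_, NA_integer_))
  if (is.null(closings)) return(empty)
  # pick the hairpin whose closing pair is reached from the mature's pairing
  span_lo <- min(ms, partner[ms:me][partner[ms:me] > 0], me)
  span_hi <- max(me, partner[ms:me][partner[ms:me] > 0], ms)
  sel <- which(closings[, 1] >= span_lo - 1 & closings[, 2] <= span_hi + 1)
  if (!length(sel)) sel <- which.min(abs((closings[, 1] + closings[, 2]) / 2 -
                                           (ms + me) / 2))
  a <- closings[sel[1], 1]; b <- closings[sel[1], 2]
  # stem: pairs enclosing (a,b) with no other hairpin loop inside
  enc <- which(vapply(seq_len(n), function(i) {
    j <- partner[i]
    j > i && i <= a && j >= b
  }, logical(1)))
  list(start = a + 1L, end = b - 1L,
       stem5 = c(min(enc), a), stem3 = c(b, max(partner[enc])))
}
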