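#' Build a sequence collection
#'
#' A `seq_set` is the package's light-weight sequence container: a
#' `data.frame` with columns `id`, `desc` and `seq` plus a `moltype`
#' attribute (`"RNA"` or `"DNA"`).  Residues are stored uppercase with the
#' alphabet normalised to the molecule type (`T` for DNA, `U` for RNA);
#' `N` is allowed and treated as an ambiguous residue throughout the
#' pipeline (it never matches a probe and is excluded from GC counts).
#'
#' @param id character vector of unique record identifiers.
#' @param seq character vector of sequences over `A,C,G,U,T,N`.
#' @param desc optional description line remainders (default `""`).
#' @param moltype `"RNA"` or `"DNA"`; sequences are normalised to it.
#' @return a `seq_set` data.frame.
#' @examples
#' qs <- seq_set("q1", "UGACAGAAGAGAGUGAGCAC")
#' nchar(qs$seq)
#' @export
seq_set <- function(id, seq, desc = "", moltype = c("RNA", "DNA")) {
  moltype <- match.arg(moltype)
  id <- as.character(id)
  seq <- normalize_residues(as.character(seq), moltype, ids = id)
  if (length(id) != length(seq)) {
    stop("id and seq must have the same length")
  }
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(seq))) {
    stop("empty sequence for id(s): ", paste(id[!nzchar(seq)], collapse = ", "))
  }
  out <- data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
                    seq = seq, stringsAsFactors = FALSE)
  attr(out, "moltype") <- moltype
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Normalise residues to a canonical uppercase alphabet
#'
#' Uppercases, converts `T`/`U` according to `moltype`, and rejects any
#' character outside `A,C,G,U,T,N` with the offending position.
#' Normalisation is idempotent.
#'
#' @param seq character vector of sequences.
#' @param moltype `"RNA"` (T -> U) or `"DNA"` (U -> T).
#' @param ids optional ids used in error messages.
#' @return normalised character vector.
#' @export
normalize_residues <- function(seq, moltype = c("RNA", "DNA"), ids = NULL) {
  moltype <- match.arg(moltype)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGUTN]", seq)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1]
    lab <- if (!is.null(ids)) ids[k] else paste0("sequence ", k)
    stop("illegal residue '", substr(seq[k], bad[k], bad[k]), "' at position ",
         bad[k], " in ", lab)
  }
  if (moltype == "RNA") chartr("T", "U", seq) else chartr("U", "T", seq)
}

#' Read a FASTA file into a `seq_set`
#'
#' Accepts multi-line (wrap-agnostic) FASTA in either the miRBase mature
#' dialect (`>spe-miR156a ...`) or dbEST-style headers; the id is the first
#' whitespace-delimited token, the rest of the header is kept as `desc`.
#'
#' @param path FASTA file path.
#' @param moltype `"RNA"` or `"DNA"`; `T`/`U` are interconverted to match.
#' @return a `seq_set`; record order follows the file.
#' @export
read_fasta <- function(path, moltype = c("RNA", "DNA")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  xs <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("cannot parse FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(xs) == 0) stop("empty FASTA file: ", path)
  headers <- names(xs)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_set(id = id, seq = as.character(xs), desc = desc, moltype = moltype)
}

#' Write a `seq_set` (or id/seq vectors) to FASTA
#'
#' @param x a `seq_set` data.frame.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(x$desc[i])) paste(x$id[i], x$desc[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' `N` maps to `N`; the output alphabet follows `moltype`.
#'
#' @param seq character vector of sequences.
#' @param moltype `"RNA"` (default) or `"DNA"`.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(seq, moltype = c("RNA", "DNA")) {
  moltype <- match.arg(moltype)
  out <- vapply(seq, function(s) {
    comp <- chartr("ACGUTN", "UGCAAN", toupper(s))
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (moltype == "DNA") out <- chartr("U", "T", out)
  out
}

#' Extract the miRNA family name from a miRBase-style identifier
#'
#' Strips the species prefix and trailing paralog/arm suffixes:
#' `bra-miR156h-5p` -> `miR156`.  Identifiers that do not contain a
#' `miR<digits>` core are returned with the species prefix removed.
#'
#' @param id character vector of miRNA identifiers.
#' @return character vector of family names.
#' @examples
#' mirna_family(c("bra-miR156h-5p", "ath-MIR838a", "osa-miR5021"))
#' @export
mirna_family <- function(id) {
  core <- sub("^[A-Za-z]{2,4}-", "", id)
  m <- regmatches(core, regexpr("^[Mm][Ii][Rr][0-9]+", core))
  out <- core
  has <- grepl("^[Mm][Ii][Rr][0-9]+", core)
  out[has] <- paste0("miR", sub("^[Mm][Ii][Rr]", "", m))
  out
}

#' Write a screening report table
#'
#' Writes one row per candidate in a fixed, deterministic column order:
#' candidate id, source EST, family, strand, mature start/end, arm,
#' precursor length, MFE, AMFE, MFEI, GC%, the per-criterion pass flags and
#' the overall verdict.  Repeats are serialised as a `;`-separated
#' annotation column.
#'
#' @param reports a data.frame of screening reports as returned by
#'   [screen_candidate()] (rows may be bound together), or an empty
#'   data.frame / NULL for a header-only file.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(reports, path) {
  cols <- screen_report_columns()
  if (is.null(reports) || nrow(as.data.frame(reports)) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    df <- as.data.frame(reports)[, cols]
    num <- c("mfe", "amfe", "mfei", "gc_percent")
    for (cc in num) df[[cc]] <- formatC(df[[cc]], format = "f", digits = 2)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

screen_report_columns <- function() {
  c("candidate_id", "est_id", "family", "strand", "mature_start", "mature_end",
    "arm", "precursor_length", "mfe", "amfe", "mfei", "gc_percent",
    "starts_with_U", "crit_arm", "crit_mature_contiguity", "crit_duplex",
    "crit_mfe", "crit_mfei", "crit_gc", "crit_length", "high_confidence",
    "repeat_annotations", "verdict")
}

#' Write folded structures in dot-bracket format
#'
#' MFOLD-like plain-text layout: an id line, the sequence, and the
#' dot-bracket string with the energy appended as ` (-12.3)`.
#'
#' @param structures a named list of [fold_rna()] results (names are ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dot_bracket <- function(structures, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(structures)) {
    st <- structures[[nm]]
    writeLines(c(paste0(">", nm), st$sequence,
                 sprintf("%s (%.1f)", st$dotbracket, st$mfe)), con)
  }
  invisible(path)
}

#' Read a dot-bracket structure file written by [write_dot_bracket()]
#'
#' @param path input path.
#' @return named list with elements `sequence`, `dotbracket`, `mfe`.
#' @export
read_dot_bracket <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (length(ln) %% 3 != 0) stop("malformed dot-bracket file: ", path)
  out <- list()
  for (k in seq(1, length(ln), by = 3)) {
    id <- sub("^>", "", ln[k])
    m <- regmatches(ln[k + 2], regexec("^(\\S+) \\((-?[0-9.]+)\\)$", ln[k + 2]))[[1]]
    if (length(m) != 3) stop("malformed structure line for ", id)
    out[[id]] <- list(sequence = ln[k + 1], dotbracket = m[2],
                      mfe = as.numeric(m[3]))
  }
  out
}
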