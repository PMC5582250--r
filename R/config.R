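#' Pipeline run configuration
#'
#' Collects every tunable threshold of the discovery pipeline, with defaults
#' matching the screening regime the package implements: a 4-substitution
#' homology budget over ~21-nt probes, precursors of 50-350 nt folded at
#' 37 degrees C with interior/bulge loops capped at 30 nt, and candidates
#' retained when MFE <= -15 kcal/mol, MFEI <= -0.7, and GC between 20 and
#' 70 percent.  `mfei_high_confidence` marks the stricter MFEI <= -0.85
#' band that is strongly indicative of genuine miRNA precursors; it flags,
#' never filters.
#'
#' @param max_mismatches homology budget, substitutions per probe (default 4).
#' @param mfe_cutoff keep candidates with MFE at or below this, kcal/mol
#'   (default -15).
#' @param mfei_cutoff keep candidates with MFEI at or below this (default
#'   -0.7, kcal/mol per 100 nt per GC percent).
#' @param mfei_high_confidence MFEI at or below this sets the
#'   `high_confidence` flag (default -0.85).
#' @param gc_min,gc_max GC-content window, percent (defaults 20 and 70).
#' @param precursor_min,precursor_max allowed precursor lengths, nt
#'   (defaults 50 and 350).
#' @param fold_temperature folding temperature, degrees C; informational -
#'   the embedded energy table is the 37 C / 1 M NaCl regime.
#' @param max_loop_size largest interior/bulge loop allowed in a predicted
#'   structure, nt (default 30).
#' @param duplex_max_mismatches mature positions allowed unpaired against
#'   the star arm (default 6).
#' @param max_mature_gap largest unpaired run tolerated inside the mature
#'   region on its own strand, nt (default 3).
#' @param min_orf_aa ORF length (amino acids) at or above which an EST is
#'   called protein-coding (default 80).
#' @param identity_threshold redundancy-collapse identity fraction
#'   (default 0.95).
#' @param max_expectation target-site expectation cutoff (default 3.0).
#' @param max_gaps gaps allowed in a miRNA-target duplex (default 1).
#' @param seed integer seed controlling every stochastic step.
#' @return a validated list of class `mir_config`.
#' @export
run_config <- function(max_mismatches = 4,
                       mfe_cutoff = -15,
                       mfei_cutoff = -0.7,
                       mfei_high_confidence = -0.85,
                       gc_min = 20, gc_max = 70,
                       precursor_min = 50, precursor_max = 350,
                       fold_temperature = 37,
                       max_loop_size = 30,
                       duplex_max_mismatches = 6,
                       max_mature_gap = 3,
                       min_orf_aa = 80,
                       identity_threshold = 0.95,
                       max_expectation = 3.0,
                       max_gaps = 1,
                       seed = 1L) {
  cfg <- list(max_mismatches = as.integer(max_mismatches),
              mfe_cutoff = mfe_cutoff,
              mfei_cutoff = mfei_cutoff,
              mfei_high_confidence = mfei_high_confidence,
              gc_min = gc_min, gc_max = gc_max,
              precursor_min = as.integer(precursor_min),
              precursor_max = as.integer(precursor_max),
              fold_temperature = fold_temperature,
              max_loop_size = as.integer(max_loop_size),
              duplex_max_mismatches = as.integer(duplex_max_mismatches),
              max_mature_gap = as.integer(max_mature_gap),
              min_orf_aa = as.integer(min_orf_aa),
              identity_threshold = identity_threshold,
              max_expectation = max_expectation,
              max_gaps = as.integer(max_gaps),
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "mir_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.finite(unlist(cfg[c("mfe_cutoff", "mfei_cutoff", "gc_min",
                                   "gc_max", "max_expectation")])))
  if (cfg$max_mismatches < 0) stop("max_mismatches must be >= 0")
  if (cfg$mfe_cutoff >= 0) stop("mfe_cutoff must be negative")
  if (cfg$gc_min >= cfg$gc_max) stop("gc_min must be below gc_max")
  if (cfg$precursor_min < 40) stop("precursor_min must be >= 40 nt")
  if (cfg$precursor_min >= cfg$precursor_max)
    stop("precursor_min must be below precursor_max")
  if (cfg$max_loop_size < 1) stop("max_loop_size must be positive")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirroring the arguments of [run_config()]; keys absent from the
#' file keep their defaults, unknown keys are an error, and `overrides`
#' (e.g. parsed command-line flags) win over the file.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return a `mir_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.mir_config <- function(x, ...) {
  cat("mirEST run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
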