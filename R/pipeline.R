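#' Run the full miRNA discovery pipeline
#'
#' Executes the fixed stage order: probe dereplication, homology scan on
#' both EST strands, redundancy collapse, protein-coding filtration,
#' precursor excision and folding, criteria screening, candidate-level
#' deduplication, optional target prediction, and a neighbour-joining tree
#' for every family with at least three passing precursors.  All artifacts
#' are written eagerly when `outdir` is given (hit tables, exclusion
#' evidence, the screening report, dot-bracket structures, target tables,
#' Newick trees and a plain-text run log echoing the configuration), so a
#' rerun with identical inputs and configuration reproduces them
#' byte-for-byte.
#'
#' @param config a [run_config()] list.
#' @param queries `seq_set` of mature miRNA probes.
#' @param ests `seq_set` of EST sequences.
#' @param transcripts optional `seq_set` of candidate target transcripts;
#'   when supplied, targets are predicted for every passing mature.
#' @param outdir optional output directory (created if missing).
#' @return a `pipeline_summary`: stage counts (`n_queries_unique`,
#'   `n_hits`, `n_after_redundancy`, `n_after_coding_filter`,
#'   `n_candidates_folded`, `n_pass`, `n_families`,
#'   `n_starting_with_U`), the screening report (`reports`), per-criterion
#'   rejection tallies, summary statistics over the passing set, target
#'   sites (`targets`) and the family trees (`trees`).
#' @export
run_pipeline <- function(config, queries, ests, transcripts = NULL,
                         outdir = NULL) {
  stopifnot(inherits(config, "mir_config"))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  save_tsv <- function(df, name) {
    if (!is.null(outdir)) {
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  log_lines <- c("mirEST pipeline run",
                 paste0("seed: ", config$seed),
                 "configuration:",
                 vapply(names(unclass(config)), function(nm) {
                   sprintf("  %s = %s", nm, format(config[[nm]]))
                 }, character(1)))

  uq <- dereplicate_queries(queries)
  hits <- scan_homology(uq, ests, config$max_mismatches)
  save_tsv(hits, "hits.tsv")
  collapsed <- collapse_redundant(hits, ests, config$identity_threshold)
  save_tsv(collapsed, "hits_collapsed.tsv")

  # coding filter applied to the hit-bearing ESTs
  hit_ests <- ests[ests$id %in% unique(collapsed$est_id), , drop = FALSE]
  cf <- if (nrow(hit_ests) > 0) {
    filter_coding(hit_ests, config$min_orf_aa)
  } else {
    list(ests = hit_ests,
         excluded = data.frame(est_id = character(0)))
  }
  save_tsv(cf$excluded, "coding_excluded.tsv")
  noncoding_hits <- collapsed[!collapsed$est_id %in% cf$excluded$est_id, ,
                              drop = FALSE]

  est_by_id <- setNames(seq_len(nrow(ests)), ests$id)
  candidates <- list()
  for (k in seq_len(nrow(noncoding_hits))) {
    hit <- noncoding_hits[k, ]
    cand <- excise_candidates(hit, ests[est_by_id[[hit$est_id]], ], config)
    candidates <- c(candidates, cand)
  }

  reports <- lapply(candidates, screen_candidate, config = config)
  reports_df <- if (length(reports)) do.call(rbind, reports) else NULL
  # candidate-level deduplication: overlapping windows on the same EST are
  # the same hairpin (e.g. a probe hitting both the mature and the star
  # region); keep the best-MFEI passing representative
  if (!is.null(reports_df) && nrow(reports_df) > 1) {
    windows <- t(vapply(candidates, function(cc) cc$window, numeric(2)))
    ord <- order(!reports_df$verdict, reports_df$mfei,
                 reports_df$candidate_id)
    keep <- rep(FALSE, nrow(reports_df))
    for (k in ord) {
      same <- keep & reports_df$est_id == reports_df$est_id[k] &
        windows[, 1] <= windows[k, 2] & windows[, 2] >= windows[k, 1]
      if (!any(same)) keep[k] <- TRUE
    }
    candidates <- candidates[keep]
    reports_df <- reports_df[keep, , drop = FALSE]
    reports_df <- reports_df[order(reports_df$candidate_id), , drop = FALSE]
    candidates <- candidates[order(vapply(candidates, `[[`, "",
                                          "candidate_id"))]
    rownames(reports_df) <- NULL
  }
  if (!is.null(outdir)) {
    write_screen_report(reports_df, file.path(outdir, "screen_report.tsv"))
    sts <- lapply(candidates, function(cc) cc$structure)
    names(sts) <- vapply(candidates, `[[`, "", "candidate_id")
    write_dot_bracket(sts, file.path(outdir, "structures.txt"))
  }

  pass <- if (!is.null(reports_df)) reports_df[reports_df$verdict, ,
                                               drop = FALSE] else NULL
  n_pass <- if (is.null(pass)) 0L else nrow(pass)
  fams <- if (n_pass > 0) unique(pass$family) else character(0)

  # per-criterion rejection tallies ("why was X dropped" audit)
  crit_cols <- grep("^crit_", screen_report_columns(), value = TRUE)
  rejections <- if (is.null(reports_df)) {
    setNames(integer(length(crit_cols)), crit_cols)
  } else {
    vapply(crit_cols, function(cc) sum(!reports_df[[cc]]), integer(1))
  }

  # targets for passing matures
  targets <- NULL
  if (!is.null(transcripts) && n_pass > 0) {
    tl <- lapply(seq_len(n_pass), function(k) {
      cand <- candidates[[which(vapply(candidates, `[[`, "",
                                       "candidate_id") ==
                                  pass$candidate_id[k])]]
      mat_seq <- substr(cand$structure$sequence, cand$mature_offset,
                        cand$mature_offset + cand$mature_len - 1)
      ts <- find_sites(seq_set(pass$candidate_id[k], mat_seq),
                       transcripts, config$max_expectation, config$max_gaps)
      ts
    })
    targets <- do.call(rbind, tl)
    save_tsv(as.data.frame(targets), "targets.tsv")
  }

  # per-family trees over passing precursors
  trees <- list()
  if (n_pass > 0) {
    for (fam in sort(fams)) {
      members <- pass$candidate_id[pass$family == fam]
      if (length(members) < 3) next
      idx <- match(members, vapply(candidates, `[[`, "", "candidate_id"))
      recs <- seq_set(id = members,
                      seq = vapply(candidates[idx],
                                   function(cc) cc$structure$sequence, ""))
      tr <- family_tree(recs)
      trees[[fam]] <- tr
      if (!is.null(outdir)) {
        ape::write.tree(tr, file.path(outdir, paste0("tree_", fam, ".nwk")))
      }
    }
  }

  stats_over <- function(x) {
    if (!length(x)) return(c(min = NA, max = NA, mean = NA))
    c(min = min(x), max = max(x), mean = mean(x))
  }
  summary <- structure(list(
    n_queries_unique = nrow(uq),
    n_hits = nrow(hits),
    n_after_redundancy = nrow(collapsed),
    n_after_coding_filter = nrow(noncoding_hits),
    n_candidates_folded = length(candidates),
    n_pass = n_pass,
    n_families = length(fams),
    families = fams,
    n_starting_with_U = if (n_pass > 0) sum(pass$starts_with_U) else 0L,
    length_stats = stats_over(if (n_pass > 0) pass$precursor_length),
    mfe_stats = stats_over(if (n_pass > 0) pass$mfe),
    mfei_stats = stats_over(if (n_pass > 0) pass$mfei),
    gc_stats = stats_over(if (n_pass > 0) pass$gc_percent),
    rejections = rejections,
    reports = reports_df,
    candidates = candidates,
    targets = targets,
    trees = trees,
    config = config), class = "pipeline_summary")

  # filter-chain monotonicity is a structural invariant of the pipeline
  stopifnot(summary$n_hits >= summary$n_after_redundancy,
            summary$n_after_redundancy >= summary$n_after_coding_filter,
            summary$n_after_coding_filter >= summary$n_candidates_folded ||
              summary$n_candidates_folded <= summary$n_after_coding_filter,
            summary$n_candidates_folded >= summary$n_pass)

  if (!is.null(outdir)) {
    log_lines <- c(log_lines, "",
                   sprintf("unique queries: %d", summary$n_queries_unique),
                   sprintf("hits: %d", summary$n_hits),
                   sprintf("after redundancy collapse: %d",
                           summary$n_after_redundancy),
                   sprintf("after coding filter: %d",
                           summary$n_after_coding_filter),
                   sprintf("candidates folded: %d",
                           summary$n_candidates_folded),
                   sprintf("passing: %d in %d families", summary$n_pass,
                           summary$n_families),
                   "rejection tallies:",
                   vapply(names(rejections), function(nm) {
                     sprintf("  %s: %d", nm, rejections[[nm]])
                   }, character(1)))
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  if (nrow(ests) == 0 || summary$n_hits == 0) {
    warning("no homology hits; all downstream counts are zero")
  }
  summary
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("mirEST pipeline summary\n")
  cat(sprintf("  unique queries        %d\n", x$n_queries_unique))
  cat(sprintf("  homology hits         %d\n", x$n_hits))
  cat(sprintf("  after redundancy      %d\n", x$n_after_redundancy))
  cat(sprintf("  after coding filter   %d\n", x$n_after_coding_filter))
  cat(sprintf("  candidates folded     %d\n", x$n_candidates_folded))
  cat(sprintf("  passing candidates    %d (%d famil%s)\n", x$n_pass,
              x$n_families, if (x$n_families == 1) "y" else "ies"))
  if (x$n_pass > 0) {
    cat(sprintf("  mature starting U     %d\n", x$n_starting_with_U))
    cat(sprintf("  length nt             %.0f-%.0f (mean %.1f)\n",
                x$length_stats["min"], x$length_stats["max"],
                x$length_stats["mean"]))
    cat(sprintf("  MFE kcal/mol          %.1f..%.1f (mean %.2f)\n",
                x$mfe_stats["min"], x$mfe_stats["max"], x$mfe_stats["mean"]))
    cat(sprintf("  MFEI                  %.2f..%.2f (mean %.3f)\n",
                x$mfei_stats["min"], x$mfei_stats["max"],
                x$mfei_stats["mean"]))
    cat(sprintf("  GC%%                   %.1f-%.1f (mean %.1f)\n",
                x$gc_stats["min"], x$gc_stats["max"], x$gc_stats["mean"]))
  }
  invisible(x)
}

#' Default synthetic benchmark collection
#'
#' The package's reference study condition: 30 planted compliant
#' precursors (random arms, strands, 0-4 probe mutations, 0-4 duplex
#' mismatches, loops of 6-12 nt, flanks of 80-150 nt), 100 background ESTs
#' at 40 percent GC, 10 protein-coding decoys and 5 tandem-repeat decoys.
#' Probes are random matures of 20-22 nt drawn at 45-60 percent GC so the
#' planted hairpins sit inside the screening thresholds.
#'
#' @param seed integer seed (default 17).
#' @param n_plants,n_background,n_coding,n_repeat collection composition.
#' @return list with `queries` (`seq_set`), `ests` (`seq_set`), `truth`
#'   (data.frame), `plants` (list of [plant_spec()]).
#' @export
benchmark_collection <- function(seed = 17, n_plants = 30, n_background = 100,
                                 n_coding = 10, n_repeat = 5) {
  local_seed(seed, {
    qids <- sprintf("syn-miR%03d", seq_len(n_plants))
    qseqs <- vapply(seq_len(n_plants), function(i) {
      random_sequence(sample(20:22, 1), gc = runif(1, 45, 60))
    }, character(1))
    queries <- seq_set(id = qids, seq = qseqs, moltype = "RNA")
    plants <- lapply(seq_len(n_plants), function(i) {
      plant_spec(query_id = qids[i],
                 n_mutations = sample(0:4, 1),
                 arm = sample(c("5p", "3p"), 1),
                 loop_len = sample(6:12, 1),
                 duplex_mismatches = sample(0:4, 1),
                 flank_len_5 = sample(80:150, 1),
                 flank_len_3 = sample(80:150, 1),
                 target_gc = 40,
                 strand = sample(c("+", "-"), 1))
    })
    coll <- make_est_collection(queries, plants, n_background = n_background,
                                n_coding_decoys = n_coding,
                                n_repeat_decoys = n_repeat,
                                rng_seed = sample.int(2^31 - 1, 1),
                                background_gc = 40,
                                config = run_config(seed = seed))
    list(queries = queries, ests = coll$ests, truth = coll$truth,
         plants = plants)
  })
}

#' Score pipeline output against a generator truth table
#'
#' A passing candidate is a true positive when its precursor window
#' overlaps the planted precursor region of its source EST; a planted
#' hairpin is recovered when at least one passing candidate does so.
#'
#' @param summary a `pipeline_summary`.
#' @param truth the truth table from [make_est_collection()] /
#'   [benchmark_collection()].
#' @return list with `recall`, `precision`, `n_true_positive`,
#'   `n_false_positive`, `n_planted`, `n_recovered`,
#'   `starts_with_U_fraction` (over passing candidates).
#' @export
evaluate_benchmark <- function(summary, truth) {
  planted <- truth[truth$kind == "planted", , drop = FALSE]
  pass <- summary$reports
  pass <- if (is.null(pass)) NULL else pass[pass$verdict, , drop = FALSE]
  windows <- if (length(summary$candidates)) {
    ids <- vapply(summary$candidates, `[[`, "", "candidate_id")
    w <- t(vapply(summary$candidates, function(cc) cc$window, numeric(2)))
    rownames(w) <- ids
    w
  } else NULL
  tp <- 0L
  recovered <- rep(FALSE, nrow(planted))
  n_pass <- if (is.null(pass)) 0L else nrow(pass)
  if (n_pass > 0) {
    for (k in seq_len(n_pass)) {
      w <- windows[pass$candidate_id[k], ]
      match_rows <- which(planted$est_id == pass$est_id[k] &
                            planted$precursor_start <= w[2] &
                            planted$precursor_end >= w[1])
      if (length(match_rows)) {
        tp <- tp + 1L
        recovered[match_rows] <- TRUE
      }
    }
  }
  list(recall = if (nrow(planted)) sum(recovered) / nrow(planted) else NA,
       precision = if (n_pass > 0) tp / n_pass else NA,
       n_true_positive = tp,
       n_false_positive = n_pass - tp,
       n_planted = nrow(planted),
       n_recovered = sum(recovered),
       starts_with_U_fraction = if (n_pass > 0)
         mean(pass$starts_with_U) else NA)
}
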