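#' Run code under a transient RNG seed
#'
#' Evaluates `code` with the global RNG seeded at `seed`, restoring the
#' caller's RNG state afterwards, so generator calls are reproducible
#' without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

#' Random nucleotide sequence at a target GC content
#'
#' Residues are i.i.d. with `P(G) = P(C) = gc/200` and
#' `P(A) = P(U) = (100 - gc)/200`.
#'
#' @param n length in nt.
#' @param gc target GC, percent (default 40).
#' @return RNA string.
#' @export
random_sequence <- function(n, gc = 40) {
  p <- c(A = (100 - gc) / 200, C = gc / 200, G = gc / 200, U = (100 - gc) / 200)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Specification of one planted precursor
#'
#' Describes how a known mature miRNA is turned into a synthetic pre-miRNA
#' hairpin planted in an EST: the number of substitutions separating the
#' planted mature from the probe (the homology signal), the arm carrying
#' the mature, the loop length, the number of non-complementary positions
#' planted in the mature/star duplex, the 2-nt overhang mimicking the
#' staggered DCL1 cuts, the background flanks, and the embedding strand.
#'
#' @param query_id id of the probe the mature is derived from.
#' @param n_mutations substitutions between planted mature and probe (0-4).
#' @param arm `"5p"` or `"3p"`.
#' @param loop_len hairpin loop length, nt (>= 3).
#' @param duplex_mismatches non-complementary positions planted in the
#'   mature/star duplex (0-6).
#' @param overhang unpaired 3' overhang, nt (default 2).
#' @param flank_len_5,flank_len_3 background flanks around the precursor in
#'   the host EST, nt.
#' @param target_gc GC content of loop/flank background, percent.
#' @param strand embedding strand of the precursor in the host EST.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(query_id, n_mutations = 0, arm = c("5p", "3p"),
                       loop_len = 8, duplex_mismatches = 0, overhang = 2,
                       flank_len_5 = 100, flank_len_3 = 100, target_gc = 40,
                       strand = c("+", "-")) {
  arm <- match.arg(arm)
  strand <- match.arg(strand)
  if (n_mutations < 0 || n_mutations > 4)
    stop("n_mutations must be within 0..4")
  if (duplex_mismatches < 0 || duplex_mismatches > 6)
    stop("duplex_mismatches must be within 0..6")
  if (loop_len < 3) stop("loop_len must be >= 3")
  structure(list(query_id = query_id, n_mutations = as.integer(n_mutations),
                 arm = arm, loop_len = as.integer(loop_len),
                 duplex_mismatches = as.integer(duplex_mismatches),
                 overhang = as.integer(overhang),
                 flank_len_5 = as.integer(flank_len_5),
                 flank_len_3 = as.integer(flank_len_3),
                 target_gc = target_gc, strand = strand),
            class = "plant_spec")
}

substitute_base <- function(base, forbidden) {
  sample(setdiff(c("A", "C", "G", "U"), forbidden), 1)
}

# bases that pair (WC or wobble) with `base`
pairing_partners <- function(base) {
  switch(base, A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
}

#' Construct a synthetic pre-miRNA hairpin from a mature probe
#'
#' The planted mature is the probe with `n_mutations` random substitutions.
#' For a 5p-arm spec the precursor is `mature + loop + star + overhang`
#' where the star is the reverse complement of the mature with
#' `duplex_mismatches` planted non-pairing substitutions (kept out of the
#' two loop-adjacent and two overhang-adjacent star positions so the duplex
#' stays well defined); the 3p arrangement mirrors it
#' (`star + loop + mature + overhang`).  With zero duplex mismatches every
#' mature position can pair with the star.
#'
#' @param mature a single-row `seq_set` (or list with `id`, `seq`) holding
#'   the probe; length 18-26 nt.
#' @param spec a [plant_spec()].
#' @param rng_seed integer seed; the same seed reproduces the sequence.
#' @return list with `record` (single-row `seq_set` of the precursor) and
#'   `truth` (one-row data.frame: query, family, arm, mature coordinates
#'   inside the precursor, planted mature sequence, mutation and duplex
#'   mismatch counts).
#' @export
make_precursor <- function(mature, spec, rng_seed) {
  q <- normalize_residues(mature$seq[1], "RNA")
  L <- nchar(q)
  if (L < 18 || L > 26) stop("mature length must be 18-26 nt")
  local_seed(rng_seed, {
    mbases <- strsplit(q, "")[[1]]
    if (spec$n_mutations > 0) {
      pos <- sample(L, spec$n_mutations)
      for (p in pos) mbases[p] <- substitute_base(mbases[p], mbases[p])
    }
    planted <- paste(mbases, collapse = "")
    star <- strsplit(revcomp(planted), "")[[1]]
    if (spec$duplex_mismatches > 0) {
      allowed <- 3:(L - 2)  # keep loop- and overhang-adjacent ends intact
      if (length(allowed) < spec$duplex_mismatches)
        stop("mature too short for the requested duplex mismatches")
      pos <- sample(allowed, spec$duplex_mismatches)
      for (p in pos) {
        # star position p pairs mature position L - p + 1
        mate <- mbases[L - p + 1]
        star[p] <- substitute_base(star[p],
                                   c(star[p], pairing_partners(mate)))
      }
    }
    star <- paste(star, collapse = "")
    loop <- random_sequence(spec$loop_len, spec$target_gc)
    over <- random_sequence(spec$overhang, spec$target_gc)
    if (spec$arm == "5p") {
      seqs <- paste0(planted, loop, star, over)
      m_start <- 1L
    } else {
      seqs <- paste0(star, loop, planted, over)
      m_start <- nchar(star) + spec$loop_len + 1L
    }
    m_end <- m_start + L - 1L
    plen <- nchar(seqs)
    rec <- seq_set(id = paste0(spec$query_id, "_hairpin"), seq = seqs,
                   moltype = "RNA")
    truth <- data.frame(query_id = spec$query_id,
                        family = mirna_family(spec$query_id),
                        arm = spec$arm, precursor_length = plen,
                        mature_start = m_start, mature_end = m_end,
                        mature_seq = planted,
                        n_mutations = spec$n_mutations,
                        duplex_mismatches = spec$duplex_mismatches,
                        stringsAsFactors = FALSE)
    list(record = rec, truth = truth)
  })
}

#' Generate a synthetic EST collection with planted precursors and decoys
#'
#' Emulates the statistical structure of a dbEST-style input: background
#' ESTs are i.i.d. residues at `background_gc` with lengths uniform in
#' `len_range`; each [plant_spec()] contributes one EST carrying its
#' hairpin between background flanks (reverse-complemented for minus-strand
#' specs); coding decoys contain an open reading frame of at least 100
#' codons; repeat decoys contain an exact tandem run of at least 24 nt.
#' The returned truth table records every planted item with plus-strand
#' coordinates, so pipeline recall and precision are computable without
#' re-inspecting sequences.
#'
#' @param queries `seq_set` of mature probes referenced by the specs.
#' @param plants list of [plant_spec()] objects.
#' @param n_background number of background ESTs.
#' @param n_coding_decoys number of protein-coding decoys.
#' @param n_repeat_decoys number of tandem-repeat decoys.
#' @param rng_seed integer seed.
#' @param background_gc background GC, percent (default 40, the average GC
#'   of the Brassica rapa precursors the screening thresholds were
#'   calibrated on).
#' @param len_range background EST length range, nt (default 200-800).
#' @param config optional [run_config()].  When supplied, every planted
#'   EST is verified to yield a screening-compliant candidate (the planted
#'   hairpin is excised, folded and screened); the stochastic components
#'   of a failing plant (mutation/mismatch placement, loop, flanks) are
#'   redrawn up to `max_tries` times so the planted precursors really are
#'   compliant under the configured thresholds.  Plants that stay
#'   non-compliant (e.g. a hopelessly AU-rich probe) are kept as drawn,
#'   with a warning.
#' @param max_tries redraw budget per plant when `config` is given.
#' @return list with `ests` (a `seq_set`) and `truth` (data.frame: est_id,
#'   kind, strand, precursor/mature plus-strand coordinates, planted mature
#'   sequence, family, counts).
#' @export
make_est_collection <- function(queries, plants = list(), n_background = 0,
                                n_coding_decoys = 0, n_repeat_decoys = 0,
                                rng_seed = 1, background_gc = 40,
                                len_range = c(200, 800), config = NULL,
                                max_tries = 25) {
  stopifnot(n_background >= 0, n_coding_decoys >= 0, n_repeat_decoys >= 0)
  qmap <- setNames(seq_len(nrow(queries)), queries$id)
  local_seed(rng_seed, {
    ids <- character(0); seqs <- character(0)
    truth <- list()
    k <- 0
    for (pi in seq_along(plants)) {
      sp <- plants[[pi]]
      if (is.null(qmap[[sp$query_id]]))
        stop("plant spec references unknown query: ", sp$query_id)
      id <- sprintf("EST_P%04d", pi)
      compliant <- FALSE
      for (try in seq_len(if (is.null(config)) 1L else max_tries)) {
        prec <- make_precursor(queries[qmap[[sp$query_id]], ], sp,
                               rng_seed = sample.int(2^31 - 1, 1))
        f5 <- random_sequence(sp$flank_len_5, sp$target_gc)
        f3 <- random_sequence(sp$flank_len_3, sp$target_gc)
        insert <- paste0(f5, prec$record$seq, f3)
        est <- if (sp$strand == "+") insert else revcomp(insert)
        Lp <- nchar(prec$record$seq)
        Lt <- nchar(insert)
        p_start <- sp$flank_len_5 + 1L
        p_end <- sp$flank_len_5 + Lp
        m_start <- sp$flank_len_5 + prec$truth$mature_start
        m_end <- sp$flank_len_5 + prec$truth$mature_end
        if (sp$strand == "-") {
          tmp <- Lt - p_end + 1L; p_end <- Lt - p_start + 1L; p_start <- tmp
          tmp <- Lt - m_end + 1L; m_end <- Lt - m_start + 1L; m_start <- tmp
        }
        if (is.null(config)) break
        hit <- data.frame(query_id = sp$query_id,
                          family = prec$truth$family, est_id = id,
                          strand = sp$strand, est_start = m_start,
                          est_end = m_end, mismatches = sp$n_mutations,
                          stringsAsFactors = FALSE)
        cand <- excise_candidates(hit, list(id = id, seq = est), config)
        compliant <- length(cand) > 0 &&
          screen_candidate(cand[[1]], config)$verdict
        if (compliant) break
      }
      if (!is.null(config) && !compliant) {
        warning("planted precursor for ", sp$query_id,
                " stayed non-compliant after ", max_tries, " redraws")
      }
      k <- k + 1
      ids <- c(ids, id); seqs <- c(seqs, est)
      truth[[k]] <- data.frame(est_id = id, kind = "planted",
                               query_id = sp$query_id,
                               family = prec$truth$family,
                               strand = sp$strand,
                               precursor_start = p_start,
                               precursor_end = p_end,
                               mature_start = m_start, mature_end = m_end,
                               mature_seq = prec$truth$mature_seq,
                               arm = sp$arm,
                               n_mutations = sp$n_mutations,
                               duplex_mismatches = sp$duplex_mismatches,
                               stringsAsFactors = FALSE)
    }
    empty_cols <- function(id, kind) {
      data.frame(est_id = id, kind = kind, query_id = NA_character_,
                 family = NA_character_, strand = NA_character_,
                 precursor_start = NA_integer_, precursor_end = NA_integer_,
                 mature_start = NA_integer_, mature_end = NA_integer_,
                 mature_seq = NA_character_, arm = NA_character_,
                 n_mutations = NA_integer_, duplex_mismatches = NA_integer_,
                 stringsAsFactors = FALSE)
    }
    for (bi in seq_len(n_background)) {
      id <- sprintf("EST_B%04d", bi)
      n <- sample(len_range[1]:len_range[2], 1)
      ids <- c(ids, id); seqs <- c(seqs, random_sequence(n, background_gc))
      k <- k + 1; truth[[k]] <- empty_cols(id, "background")
    }
    stops <- c("UAA", "UAG", "UGA")
    codon_pool <- apply(expand.grid(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                                    c("A", "C", "G", "U")), 1, paste,
                        collapse = "")
    codon_pool <- setdiff(codon_pool, stops)
    for (ci in seq_len(n_coding_decoys)) {
      id <- sprintf("EST_C%04d", ci)
      ncod <- sample(100:160, 1)
      orf <- paste0("AUG", paste(sample(codon_pool, ncod - 1, replace = TRUE),
                                 collapse = ""), sample(stops, 1))
      est <- paste0(random_sequence(sample(20:60, 1), background_gc), orf,
                    random_sequence(sample(20:60, 1), background_gc))
      ids <- c(ids, id); seqs <- c(seqs, est)
      k <- k + 1; truth[[k]] <- empty_cols(id, "coding_decoy")
    }
    for (ri in seq_len(n_repeat_decoys)) {
      id <- sprintf("EST_R%04d", ri)
      ulen <- sample(2:4, 1)
      unit <- random_sequence(ulen, 50)
      while (!is_primitive_unit(unit)) unit <- random_sequence(ulen, 50)
      ncopies <- ceiling(24 / ulen) + sample(0:6, 1)
      run <- paste(rep(unit, ncopies), collapse = "")
      est <- paste0(random_sequence(sample(80:200, 1), background_gc), run,
                    random_sequence(sample(80:200, 1), background_gc))
      ids <- c(ids, id); seqs <- c(seqs, est)
      k <- k + 1; truth[[k]] <- empty_cols(id, "repeat_decoy")
    }
    list(ests = seq_set(id = ids, seq = seqs, moltype = "RNA"),
         truth = do.call(rbind, truth))
  })
}

#' Generate transcripts carrying planted miRNA target sites
#'
#' Each site specification plants one complementary site whose true
#' expectation score is known by construction: `mismatches` non-pairing
#' substitutions (1.0 each), `gu_pairs` wobble positions (0.5 each) and
#' `gaps` deleted target bases (2.0 each), every penalty doubled when
#' `seed_region` places the deviations in miRNA positions 2-13.
#'
#' For gap-free compositions the planted composition is also the optimal
#' alignment, so [find_sites()] reports exactly the truth expectation.  A
#' gap-bearing site can occasionally be explained more cheaply by an
#' alternative alignment, in which case the reported expectation is below
#' the planted-composition value.
#'
#' @param mature single-row `seq_set` (or list with `id`, `seq`), 18-26 nt.
#' @param site_specs data.frame with columns `mismatches`, `gu_pairs`,
#'   `gaps`, `seed_region` (logical), one row per transcript.
#' @param rng_seed integer seed.
#' @param flank background flank length around each site, nt (default 80).
#' @return list with `transcripts` (a `seq_set`) and `truth` (data.frame:
#'   transcript id, site coordinates, planted composition, the true
#'   expectation, and the true inhibition mode under the positions-10/11
#'   rule).
#' @export
make_target_transcripts <- function(mature, site_specs, rng_seed, flank = 80) {
  m <- normalize_residues(mature$seq[1], "RNA")
  L <- nchar(m)
  if (L < 18 || L > 26) stop("mature length must be 18-26 nt")
  mb <- strsplit(m, "")[[1]]
  local_seed(rng_seed, {
    ids <- character(0); seqs <- character(0)
    truth <- list()
    for (i in seq_len(nrow(site_specs))) {
      sp <- site_specs[i, ]
      ndev <- sp$mismatches + sp$gu_pairs + sp$gaps
      # candidate miRNA positions for deviations; mode stays 'cleavage'
      # unless a deviation lands on positions 10-11
      region <- if (isTRUE(sp$seed_region)) 2:13 else c(14:(L - 1))
      gu_ok <- region[mb[region] %in% c("G", "U")]
      if (sp$gu_pairs > length(gu_ok))
        stop("not enough G/U mature positions in the chosen region for ",
             sp$gu_pairs, " wobble pairs")
      gu_pos <- if (sp$gu_pairs > 0) sample(gu_ok, sp$gu_pairs) else integer(0)
      rest <- setdiff(region, gu_pos)
      other <- if (ndev - sp$gu_pairs > 0)
        sample(rest, sp$mismatches + sp$gaps) else integer(0)
      mm_pos <- head(other, sp$mismatches)
      gap_pos <- tail(other, sp$gaps)
      # site on the transcript 5'->3'; site column S - k + 1 pairs miRNA k
      site <- strsplit(revcomp(m), "")[[1]]  # length L, perfect WC
      S <- L
      for (p in mm_pos) {
        col <- S - p + 1
        site[col] <- substitute_base(site[col],
                                     c(site[col], pairing_partners(mb[p])))
      }
      for (p in gu_pos) {
        col <- S - p + 1
        site[col] <- if (mb[p] == "G") "U" else "G"
      }
      drop_cols <- sort(S - gap_pos + 1)
      if (length(drop_cols)) site <- site[-drop_cols]
      site <- paste(site, collapse = "")
      f5 <- random_sequence(flank, 45)
      f3 <- random_sequence(flank, 45)
      tx <- paste0(f5, site, f3)
      mult <- if (isTRUE(sp$seed_region)) 2 else 1
      expectation <- mult * (sp$mismatches * 1.0 + sp$gu_pairs * 0.5 +
                               sp$gaps * 2.0)
      central <- any(c(mm_pos, gu_pos, gap_pos) %in% c(10, 11))
      id <- sprintf("TX%04d", i)
      ids <- c(ids, id); seqs <- c(seqs, tx)
      truth[[i]] <- data.frame(transcript_id = id,
                               site_start = flank + 1L,
                               site_end = flank + nchar(site),
                               mismatches = sp$mismatches,
                               gu_pairs = sp$gu_pairs, gaps = sp$gaps,
                               seed_region = isTRUE(sp$seed_region),
                               expectation = expectation,
                               mode = if (central) "translation" else "cleavage",
                               stringsAsFactors = FALSE)
    }
    list(transcripts = seq_set(id = ids, seq = seqs, moltype = "RNA"),
         truth = do.call(rbind, truth))
  })
}
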