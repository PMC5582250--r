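test_that("a mismatch-free spec builds a fully pairable 52-nt hairpin", {
  set.seed(71)
  q <- seq_set("tst-miR001", rand_rna(21))
  sp <- plant_spec("tst-miR001", n_mutations = 0, duplex_mismatches = 0,
                   loop_len = 8)
  pr <- make_precursor(q, sp, rng_seed = 1)
  expect_equal(nchar(pr$record$seq), 21 + 8 + 21 + 2)
  # all 21 mature positions can pair with the star by construction
  st <- fold_rna(pr$record$seq)
  f <- extract_hairpin(st, c(pr$truth$mature_start, pr$truth$mature_end))
  expect_equal(f$duplex_mismatches, 0L)
  expect_gte(max_pairing(pr$record$seq), 21)
})

test_that("planted mature is at the stated Hamming distance from the probe", {
  set.seed(72)
  for (nm in 0:4) {
    q <- seq_set("tst-miR001", rand_rna(22))
    sp <- plant_spec("tst-miR001", n_mutations = nm)
    pr <- make_precursor(q, sp, rng_seed = 40 + nm)
    expect_equal(hamming(pr$truth$mature_seq, q$seq), nm)
  }
})

test_that("generators are deterministic in their seed", {
  q <- seq_set("tst-miR001", "UGACAGAAGAGAGUGAGCACA")
  sp <- plant_spec("tst-miR001", n_mutations = 2, duplex_mismatches = 1)
  a <- make_precursor(q, sp, rng_seed = 5)
  b <- make_precursor(q, sp, rng_seed = 5)
  expect_identical(a, b)
  c1 <- make_est_collection(q, list(sp), n_background = 5, rng_seed = 6)
  c2 <- make_est_collection(q, list(sp), n_background = 5, rng_seed = 6)
  expect_identical(c1, c2)
  t1 <- make_target_transcripts(q, data.frame(mismatches = 1, gu_pairs = 0,
                                              gaps = 0, seed_region = FALSE),
                                rng_seed = 7)
  t2 <- make_target_transcripts(q, data.frame(mismatches = 1, gu_pairs = 0,
                                              gaps = 0, seed_region = FALSE),
                                rng_seed = 7)
  expect_identical(t1, t2)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(plant_spec("q", n_mutations = 5), "0..4")
  expect_error(plant_spec("q", duplex_mismatches = 7), "0..6")
  expect_error(plant_spec("q", loop_len = 2), ">= 3")
  q_short <- seq_set("q", "ACGUACGUACGU")
  expect_error(make_precursor(q_short, plant_spec("q"), 1), "18-26")
})

test_that("background ESTs hit their target GC within binomial bounds", {
  q <- seq_set("tst-miR001", "UGACAGAAGAGAGUGAGCACA")
  coll <- make_est_collection(q, n_background = 100, rng_seed = 73,
                              background_gc = 40, len_range = c(400, 600))
  gc_obs <- mean(vapply(coll$ests$seq, gc_percent, numeric(1)))
  expect_lt(abs(gc_obs - 40), 3)
  lens <- nchar(coll$ests$seq)
  expect_true(all(lens >= 400 & lens <= 600))
})

test_that("minus-strand plants carry the reverse complement at truth coords", {
  set.seed(74)
  q <- seq_set("tst-miR001", rand_rna(21))
  sp <- plant_spec("tst-miR001", strand = "-", flank_len_5 = 50,
                   flank_len_3 = 60)
  coll <- make_est_collection(q, list(sp), rng_seed = 75)
  tr <- coll$truth[1, ]
  expect_equal(tr$strand, "-")
  window <- substr(coll$ests$seq[1], tr$mature_start, tr$mature_end)
  expect_equal(revcomp(window), tr$mature_seq)
})

test_that("truth tables are complete for every planted item", {
  q <- random_query_set(3)
  plants <- lapply(q$id, function(id) plant_spec(id, n_mutations = 1))
  coll <- make_est_collection(q, plants, n_background = 2,
                              n_coding_decoys = 1, n_repeat_decoys = 1,
                              rng_seed = 76)
  expect_equal(nrow(coll$truth), 3 + 2 + 1 + 1)
  expect_equal(sum(coll$truth$kind == "planted"), 3)
  expect_equal(nrow(coll$ests), nrow(coll$truth))
  expect_setequal(coll$truth$est_id, coll$ests$id)
  # n_background = 0 with one plant -> a single EST and a 1-row truth core
  solo <- make_est_collection(q[1, ], plants[1], rng_seed = 77)
  expect_equal(nrow(solo$ests), 1)
  expect_equal(sum(solo$truth$kind == "planted"), 1)
})

test_that("compliance-verified plants pass the screen across random specs", {
  set.seed(78)
  cfg <- run_config()
  n_checked <- 0
  for (k in 1:50) {
    q <- seq_set("tst-miR001", rand_rna(sample(20:22, 1)))
    if (gc_percent(q$seq) < 40) next  # give the verifier workable probes
    sp <- plant_spec("tst-miR001",
                     n_mutations = sample(0:4, 1),
                     arm = sample(c("5p", "3p"), 1),
                     loop_len = sample(6:12, 1),
                     duplex_mismatches = sample(0:4, 1),
                     flank_len_5 = sample(80:120, 1),
                     flank_len_3 = sample(80:120, 1),
                     strand = sample(c("+", "-"), 1))
    coll <- suppressWarnings(
      make_est_collection(q, list(sp), rng_seed = 1000 + k, config = cfg))
    tr <- coll$truth[1, ]
    hit <- data.frame(query_id = tr$query_id, family = tr$family,
                      est_id = tr$est_id, strand = tr$strand,
                      est_start = tr$mature_start, est_end = tr$mature_end,
                      mismatches = tr$n_mutations)
    cand <- excise_candidates(hit, coll$ests[1, ], cfg)
    expect_length(cand, 1)
    rep <- screen_candidate(cand[[1]], cfg)
    n_checked <- n_checked + 1
    expect_true(rep$verdict, info = paste("spec", k))
  }
  expect_gte(n_checked, 30)
})
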