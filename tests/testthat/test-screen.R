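test_that("GC, AMFE and MFEI follow their closed forms", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("AUAU"), 0)
  expect_equal(gc_percent("GCAU"), 50)
  expect_equal(gc_percent("GCAUNN"), 50)  # N excluded from both counts

  expect_equal(amfe(-30, 100), -30)
  expect_equal(mfei(-30, 100, 50), -0.6)
  expect_equal(mfei(-58.6, 100, 58.6), -1.0)
  expect_equal(amfe(0, 77), 0)
  expect_equal(mfei(0, 77, 33), 0)
  expect_true(is.na(mfei(-30, 100, 0)))  # degenerate GC, no crash

  # identity mfei == amfe / gc over a grid
  for (m in c(-58.6, -30, -15, -0.1)) {
    for (len in c(50, 77, 100, 350)) {
      for (gc in c(20, 40.33, 58.6, 70)) {
        expect_equal(mfei(m, len, gc), amfe(m, len) / gc, tolerance = 1e-12)
      }
    }
  }
})

test_that("threshold criteria flip exactly at the boundaries", {
  cfg <- run_config()
  base <- list(arm = "5p", largest_mature_gap = 0, duplex_mismatches = 0,
               mfe = -30, mfei = -1, gc = 45, length = 80)
  at <- function(field, value) {
    s <- base; s[[field]] <- value
    apply_screen_criteria(s, cfg)
  }
  expect_true(at("mfe", -15.0)[["mfe"]])
  expect_false(at("mfe", -14.9)[["mfe"]])
  expect_true(at("mfei", -0.70)[["mfei"]])
  expect_false(at("mfei", -0.69)[["mfei"]])
  expect_true(at("gc", 20)[["gc"]])
  expect_false(at("gc", 19.9)[["gc"]])
  expect_true(at("gc", 70)[["gc"]])
  expect_false(at("gc", 70.1)[["gc"]])
  expect_true(at("length", 50)[["length"]])
  expect_false(at("length", 49)[["length"]])
  expect_true(at("duplex_mismatches", 6)[["duplex"]])
  expect_false(at("duplex_mismatches", 7)[["duplex"]])
  expect_true(at("largest_mature_gap", 3)[["mature_contiguity"]])
  expect_false(at("largest_mature_gap", 4)[["mature_contiguity"]])
  expect_false(at("arm", "loop")[["arm"]])
  expect_true(all(apply_screen_criteria(base, cfg)))

  expect_true(is_high_confidence(-0.85, cfg))
  expect_false(is_high_confidence(-0.849, cfg))
})

test_that("tightening thresholds never enlarges the pass set", {
  set.seed(41)
  cfg <- run_config()
  stats <- lapply(1:200, function(i) {
    list(arm = sample(c("5p", "3p", "loop"), 1, prob = c(.45, .45, .1)),
         largest_mature_gap = sample(0:6, 1),
         duplex_mismatches = sample(0:9, 1),
         mfe = runif(1, -60, -5), mfei = runif(1, -1.6, -0.2),
         gc = runif(1, 10, 80), length = sample(45:360, 1))
  })
  n_pass <- function(cfg) {
    sum(vapply(stats, function(s) all(apply_screen_criteria(s, cfg)),
               logical(1)))
  }
  base_n <- n_pass(cfg)
  expect_lte(n_pass(run_config(mfe_cutoff = -20)), base_n)
  expect_lte(n_pass(run_config(mfei_cutoff = -0.9)), base_n)
  expect_lte(n_pass(run_config(gc_min = 30, gc_max = 60)), base_n)
  expect_lte(n_pass(run_config(duplex_max_mismatches = 4)), base_n)
  expect_lte(n_pass(run_config(precursor_min = 60, precursor_max = 200)),
             base_n)
})

test_that("excision keeps the planted hairpin and maps mature coordinates", {
  set.seed(42)
  cfg <- run_config()
  q <- seq_set("tst-miR001", rand_rna(21))
  sp <- plant_spec("tst-miR001", loop_len = 8, flank_len_5 = 100,
                   flank_len_3 = 100)
  coll <- make_est_collection(q, list(sp), rng_seed = 7, config = cfg)
  tr <- coll$truth[1, ]
  hit <- data.frame(query_id = "tst-miR001", family = "miR001",
                    est_id = tr$est_id, strand = tr$strand,
                    est_start = tr$mature_start, est_end = tr$mature_end,
                    mismatches = 0)
  cands <- excise_candidates(hit, coll$ests[1, ], cfg)
  expect_length(cands, 1)
  cand <- cands[[1]]
  # the retained window overlaps the planted precursor core
  expect_lte(cand$window[1], tr$precursor_end)
  expect_gte(cand$window[2], tr$precursor_start)
  # the excised mature is the planted one
  mat <- substr(cand$structure$sequence, cand$mature_offset,
                cand$mature_offset + cand$mature_len - 1)
  expect_equal(mat, tr$mature_seq)
  rep <- screen_candidate(cand, cfg)
  expect_true(rep$verdict)
  expect_equal(rep$arm, sp$arm)
})

test_that("a hit at the EST edge with no room yields no candidate", {
  cfg <- run_config()
  q <- rand_rna(21)
  est <- list(id = "e1", seq = paste0(q, rand_rna(10)))  # 31 nt total
  hit <- data.frame(query_id = "q", family = "f", est_id = "e1",
                    strand = "+", est_start = 1, est_end = 21,
                    mismatches = 0)
  expect_length(excise_candidates(hit, est, cfg), 0)
})

test_that("tandem repeat detection matches brute-force expectations", {
  r <- find_tandem_repeats("AGAAGAAGAAGA")
  expect_equal(nrow(r), 1)
  expect_equal(r$unit, "AAG")  # canonical smallest rotation of AGA
  expect_equal(r$copies, 4)
  expect_equal(r$span, 12)
  expect_equal(c(r$begin, r$end), c(1L, 12L))

  r2 <- find_tandem_repeats("CTCTCTCTCTCTCT")
  expect_equal(nrow(r2), 1)
  expect_equal(r2$unit, "CT")
  expect_equal(r2$copies, 7)

  set.seed(43)
  # runs embedded mid-sequence keep their coordinates
  s <- paste0(rand_rna(30), "ACGACGACGACGACG", rand_rna(30))
  r3 <- find_tandem_repeats(s, min_span = 12)
  expect_true(any(r3$begin == 31 & r3$end == 45))

  # random sequences without a 3+ copy run give nothing
  hits <- vapply(1:20, function(i) {
    nrow(find_tandem_repeats(rand_rna(100)))
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.2)
  # invariant: every reported run really is a tandem of its unit
  for (i in 1:20) {
    s <- paste0(rand_rna(20), strrep("AU", 9), rand_rna(20))
    rr <- find_tandem_repeats(s)
    for (k in seq_len(nrow(rr))) {
      expect_equal(rr$span[k], rr$end[k] - rr$begin[k] + 1)
      expect_gte(rr$copies[k], 3)
    }
  }
})

test_that("repeat decoys from the generator are annotated by the screen", {
  q <- seq_set("tst-miR001", "UGACAGAAGAGAGUGAGCAC")
  coll <- make_est_collection(q, n_repeat_decoys = 2, rng_seed = 44)
  for (i in 1:2) {
    rr <- find_tandem_repeats(coll$ests$seq[i])
    expect_gte(max(rr$span), 24)
  }
})
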