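test_that("duplex scoring follows the penalty table", {
  m <- "UGACAGAAGAGAGUGAGCACA"  # 21 nt
  perfect <- chartr("ACGU", "UGCA", m)  # site 3'->5', column i pairs pos i
  expect_equal(score_duplex(m, perfect)$expectation, 0)

  # one G:U at position 15 (outside seed): 0.5
  s <- strsplit(perfect, "")[[1]]
  stopifnot(substr(m, 15, 15) == "G")
  s[15] <- "U"
  expect_equal(score_duplex(m, paste(s, collapse = ""))$expectation, 0.5)

  # one mismatch at position 5 (seed): doubled to 2.0
  s <- strsplit(perfect, "")[[1]]
  s[5] <- setdiff(c("A", "C", "G", "U"),
                  c(s[5], pairing_partners_for_test(substr(m, 5, 5))))[1]
  expect_equal(score_duplex(m, paste(s, collapse = ""))$expectation, 2.0)

  # a gap costs 2 (4 in seed)
  expect_equal(score_duplex(paste0(m, "-"), paste0(perfect, "A"))$expectation,
               2.0)
  expect_error(score_duplex("ACGU", "ACG"), "equal length")
  expect_error(score_duplex("ACXU", "ACGU"), "illegal")
})

test_that("expectation is additive and context-independent", {
  set.seed(51)
  m <- rand_rna(21)
  site <- chartr("ACGU", "UGCA", m)
  base <- score_duplex(m, site)$expectation
  expect_equal(base, 0)
  # flipping independent positions adds their penalties
  sv <- strsplit(site, "")[[1]]
  p1 <- 15; p2 <- 18
  sv[p1] <- setdiff(c("A", "C", "G", "U"),
                    c(sv[p1], pairing_partners_for_test(substr(m, p1, p1))))[1]
  one <- score_duplex(m, paste(sv, collapse = ""))$expectation
  sv2 <- sv
  sv2[p2] <- setdiff(c("A", "C", "G", "U"),
                     c(sv2[p2], pairing_partners_for_test(substr(m, p2, p2))))[1]
  two <- score_duplex(m, paste(sv2, collapse = ""))$expectation
  expect_equal(two - one, one - base)
})

test_that("planted sites are recovered at their truth expectations", {
  set.seed(52)
  m <- seq_set("tst-miR001", rand_rna(21))
  specs <- data.frame(mismatches = c(0, 0, 1, 1, 2),
                      gu_pairs = c(0, 1, 1, 0, 0),
                      gaps = 0,
                      seed_region = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  tt <- make_target_transcripts(m, specs, rng_seed = 9)
  expect_equal(tt$truth$expectation, c(0, 0.5, 1.5, 2, 2))
  sites <- find_sites(m, tt$transcripts, max_expectation = 3, max_gaps = 1)
  expect_equal(nrow(sites), nrow(specs))
  found <- sites[match(tt$truth$transcript_id, sites$transcript_id), ]
  expect_equal(found$expectation, tt$truth$expectation)
  expect_equal(found$site_start, tt$truth$site_start)
  expect_equal(found$site_end, tt$truth$site_end)
  expect_equal(found$mode, tt$truth$mode)
})

test_that("sites above the cutoff are not reported and monotonicity holds", {
  set.seed(53)
  m <- seq_set("tst-miR001", rand_rna(21))
  specs <- data.frame(mismatches = c(2, 0), gu_pairs = c(0, 0), gaps = 0,
                      seed_region = c(TRUE, FALSE))  # expectations 4 and 0
  tt <- make_target_transcripts(m, specs, rng_seed = 10)
  s3 <- find_sites(m, tt$transcripts, max_expectation = 3)
  expect_false("TX0001" %in% s3$transcript_id)
  expect_true("TX0002" %in% s3$transcript_id)
  s5 <- find_sites(m, tt$transcripts, max_expectation = 5)
  # raising the cutoff never removes sites
  expect_true(all(paste(s3$transcript_id, s3$site_start) %in%
                    paste(s5$transcript_id, s5$site_start)))

  # cutoff 0 reports exactly perfect complements
  s0 <- find_sites(m, tt$transcripts, max_expectation = 0)
  expect_equal(s0$transcript_id, "TX0002")
  expect_equal(s0$expectation, 0)
})

test_that("mode calls follow the centre positions 10-11 rule", {
  m <- "UGACAGAAGAGAGUGAGCACA"
  perfect <- chartr("ACGU", "UGCA", m)
  mk <- function(site) {
    sd <- score_duplex(m, site)
    call_mode(list(mirna_aln = m, annotation = sd$annotation))
  }
  expect_equal(mk(perfect), "cleavage")
  s <- strsplit(perfect, "")[[1]]
  s10 <- s; s10[10] <- setdiff(c("A", "C", "G", "U"),
                               c(s[10], pairing_partners_for_test(substr(m, 10, 10))))[1]
  expect_equal(mk(paste(s10, collapse = "")), "translation")
  s15 <- s; s15[15] <- setdiff(c("A", "C", "G", "U"),
                               c(s[15], pairing_partners_for_test(substr(m, 15, 15))))[1]
  expect_equal(mk(paste(s15, collapse = "")), "cleavage")
  # wobble at 11 also redirects to translation
  s11 <- s
  stopifnot(substr(m, 11, 11) %in% c("G", "U"))
  s11[11] <- if (substr(m, 11, 11) == "G") "U" else "G"
  expect_equal(mk(paste(s11, collapse = "")), "translation")
})

test_that("planted central deviations are called translation end-to-end", {
  set.seed(54)
  found_translation <- FALSE
  for (trial in 1:20) {
    m <- seq_set("tst-miR001", rand_rna(21))
    specs <- data.frame(mismatches = 1, gu_pairs = 0, gaps = 0,
                        seed_region = TRUE)
    tt <- make_target_transcripts(m, specs, rng_seed = 500 + trial)
    sites <- find_sites(m, tt$transcripts, max_expectation = 3)
    expect_equal(sites$mode, tt$truth$mode)
    if (tt$truth$mode == "translation") found_translation <- TRUE
  }
  expect_true(found_translation)
})
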