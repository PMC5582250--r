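test_that("dereplication collapses identical matures with aliases", {
  qs <- seq_set(c("bra-miR156a", "ath-miR156a", "osa-miR160"),
                c("UGACAGAAGAGAGUGAGCAC", "UGACAGAAGAGAGUGAGCAC",
                  "UGCCUGGCUCCCUGUAUGCC"))
  dq <- dereplicate_queries(qs)
  expect_equal(nrow(dq), 2)
  expect_equal(dq$id[1], "ath-miR156a")  # lexicographically smallest wins
  expect_equal(dq$aliases[1], "ath-miR156a,bra-miR156a")

  all_unique <- random_query_set(5)
  expect_equal(nrow(dereplicate_queries(all_unique)), 5)

  # k duplicates out of n leave n - k
  set.seed(21)
  base <- random_query_set(40)
  dup_idx <- sample(40, 7)
  dup <- seq_set(paste0("dup-miR", 1:7), base$seq[dup_idx])
  pool <- seq_set(c(base$id, dup$id), c(base$seq, dup$seq))
  expect_equal(nrow(dereplicate_queries(pool)), 40)
})

test_that("verbatim and boundary-mismatch plants are found; 5 substitutions are not", {
  set.seed(22)
  q <- seq_set("tst-miR001", rand_rna(21))
  flank <- rand_rna(50)
  for (k in c(0, 4, 5)) {
    planted <- mutate_seq(q$seq, if (k > 0) sample(21, k) else integer(0))
    est <- seq_set("e1", paste0(flank, planted, rand_rna(50)))
    hits <- scan_homology(q, est, max_mismatches = 4)
    exact <- hits[hits$est_start == 51 & hits$strand == "+", ]
    if (k <= 4) {
      expect_equal(nrow(exact), 1)
      expect_equal(exact$mismatches, k)
      expect_equal(exact$est_end, 71)
      expect_equal(exact$matched_subsequence, planted)
    } else {
      expect_equal(nrow(exact), 0)
    }
  }
})

test_that("scan equals the brute-force double loop over windows and strands", {
  set.seed(23)
  queries <- random_query_set(8)
  ests <- planted_est_set(queries, 20)
  brute4 <- brute_scan(queries, ests, 4)
  for (m in 0:4) {
    hits <- scan_homology(queries, ests, m)
    expect_identical(hit_keys(hits), brute_scan(queries, ests, m),
                     info = paste("budget", m))
  }
  expect_identical(hit_keys(scan_homology(queries, ests, 4)), brute4)
})

test_that("scan is strand-symmetric and monotone in the budget", {
  set.seed(24)
  queries <- random_query_set(5)
  ests <- planted_est_set(queries, 12)
  hits <- scan_homology(queries, ests, 4)
  rc <- seq_set(ests$id, revcomp(ests$seq))
  hits_rc <- scan_homology(queries, rc, 4)
  # reverse-complementing every EST swaps strand labels, keeps the multiset
  L <- setNames(nchar(ests$seq), ests$id)
  remapped <- sort(paste(hits_rc$query_id, hits_rc$est_id,
                         ifelse(hits_rc$strand == "+", "-", "+"),
                         L[hits_rc$est_id] - hits_rc$est_end + 1,
                         hits_rc$mismatches))
  original <- sort(paste(hits$query_id, hits$est_id, hits$strand,
                         hits$est_start, hits$mismatches))
  expect_identical(remapped, original)

  prev <- 0
  for (m in 0:4) {
    n <- nrow(scan_homology(queries, ests, m))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("N positions never count as matches", {
  q <- seq_set("q", "GGGGGGGGGGGGGGGGGGGG")
  est <- seq_set("e", paste0("AAAAA", "GGGGGGGGGGGGGGGGNNNN", "AAAAA"))
  hits <- scan_homology(q, est, 4)
  expect_equal(nrow(hits[hits$strand == "+" & hits$est_start == 6, ]), 1)
  expect_equal(hits$mismatches[hits$est_start == 6 & hits$strand == "+"], 4)
  expect_equal(nrow(scan_homology(q, est, 3)), 0)
})

test_that("redundant ESTs collapse to one representative", {
  set.seed(25)
  base <- rand_rna(400)
  q <- seq_set("tst-miR001", substr(base, 101, 121))
  near <- function(rate) {
    v <- strsplit(base, "")[[1]]
    idx <- setdiff(which(runif(400) < rate), 101:121)
    for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "U"), v[i]), 1)
    paste(v, collapse = "")
  }
  # same sequence under two accessions -> one representative
  ests <- seq_set(c("acc1", "acc2"), c(base, base))
  hits <- scan_homology(dereplicate_queries(q), ests, 4)
  col <- collapse_redundant(hits, ests, 0.95)
  expect_equal(nrow(col), 1)
  expect_equal(col$est_id, "acc1")

  # 3 copies at ~96% identity plus one distant relative -> 2 clusters
  ests <- seq_set(c("c1", "c2", "c3", "far"),
                  c(base, near(0.03), near(0.03), near(0.35)))
  hits <- scan_homology(dereplicate_queries(q), ests, 4)
  col <- collapse_redundant(hits, ests, 0.95)
  expect_equal(sort(unique(col$est_id)), c("c1", "far"))

  # unrelated ESTs stay apart
  q2 <- seq_set(c("tst-miR101", "tst-miR102"), c(rand_rna(21), rand_rna(21)))
  e2 <- seq_set(c("u1", "u2"),
                c(paste0(rand_rna(40), q2$seq[1], rand_rna(40)),
                  paste0(rand_rna(40), q2$seq[2], rand_rna(40))))
  h2 <- scan_homology(dereplicate_queries(q2), e2, 0)
  expect_equal(nrow(collapse_redundant(h2, e2)), 2)
})
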