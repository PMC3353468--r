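test_that("continuous Tanimoto matches hand evaluation and reduces to binary", {
  k <- fp(c(`3` = 2))
  expect_equal(tanimoto_continuous(k, k), 1.0)

  a <- fp(c(`0` = 1, `1` = 2))
  b <- fp(c(`0` = 2, `1` = 1))
  expect_equal(tanimoto_continuous(a, b), 4 / (5 + 5 - 4), tolerance = 1e-12)
  expect_equal(tanimoto_continuous(b, a), tanimoto_continuous(a, b))

  expect_equal(tanimoto_continuous(fp(c(`1` = 1)), fp(c(`2` = 3))), 0.0)
  expect_error(tanimoto_continuous(fp(), fp()), "empty")
  expect_error(tanimoto_continuous(a, fp(c(`1` = 1), width = 32)), "width")

  # all-count-1 fingerprints: continuous == binary, over random cases
  set.seed(11)
  for (i in 1:20) {
    x <- fp(stats::setNames(rep(1, 5), sample(0:15, 5)))
    y <- fp(stats::setNames(rep(1, 3), sample(0:15, 3)))
    expect_equal(tanimoto_continuous(x, y), tanimoto_binary(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Okapi belief reproduces direct evaluations of the formula", {
  # ff = 0 collapses to the baseline alpha regardless of the rest
  expect_equal(okapi_belief(0, 5, 3, 10, 4, alpha = 0.4), 0.4)

  # ff = 1, |c_j| = |C_avg|: tf term is exactly 1/3
  expect_equal(okapi_belief(1, 1, 2, 10, 1, alpha = 0.4),
               0.4 + 0.6 * (1 / 3) * log(10.5 / 2) / log(11),
               tolerance = 1e-12)
  expect_equal(okapi_belief(1, 1, 2, 10, 1, alpha = 0.4), 0.5383070,
               tolerance = 1e-6)
  expect_equal(okapi_belief(1, 1, 10, 10, 1, alpha = 0.4), 0.4040694,
               tolerance = 1e-6)

  # base-of-logarithm invariance of the idf ratio
  idf_e <- log((10 + 0.5) / 2) / log(10 + 1)
  idf_10 <- log10((10 + 0.5) / 2) / log10(10 + 1)
  idf_2 <- log2((10 + 0.5) / 2) / log2(10 + 1)
  expect_equal(idf_e, idf_10, tolerance = 1e-12)
  expect_equal(idf_e, idf_2, tolerance = 1e-12)

  expect_error(okapi_belief(1, 1, 0, 10, 1), "cf")
  expect_error(okapi_belief(1, 1, 1, 10, 0), "c_avg")
  expect_error(okapi_belief(1, 1, 1, 10, 1, alpha = 1), "alpha")
})

test_that("Okapi belief is bounded and monotone in ff and cf", {
  m <- 50
  c_avg <- 20
  for (cf in c(1, 5, 50)) {
    bel <- okapi_belief(0:10, 20, cf, m, c_avg)
    expect_true(all(diff(bel) >= 0))        # non-decreasing in ff
    expect_true(all(bel >= 0.4 & bel < 1))  # within [alpha, 1)
  }
  bel_cf <- okapi_belief(3, 20, c(1, 2, 10, 50), m, c_avg)
  expect_true(all(diff(bel_cf) <= 0))       # non-increasing in cf
})

test_that("belief combination operators behave as stated", {
  expect_equal(belief_sum(c(0.4, 0.6)), 0.5)
  expect_equal(belief_sum(0.77), 0.77)
  expect_equal(belief_sum(rep(0.4, 3)), 0.4)
  expect_error(belief_sum(numeric()), "empty")

  expect_equal(belief_wsum(c(0.6, 0.3), c(2, 1)), 0.5)
  expect_equal(belief_wsum(c(0.8, 0.2), c(1, 1e-4)), 0.8, tolerance = 1e-3)
  expect_error(belief_wsum(c(0.1, 0.2), 1), "length")
  expect_error(belief_wsum(c(0.1, 0.2), c(0, 0)), "positive sum")

  # exact reduction to belief_sum under equal weights, random cases
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:6, 1))
    expect_identical(belief_wsum(p, rep(2, length(p))), belief_sum(p))
  }
})

test_that("reweighting factors follow the relative-frequency formula", {
  rs <- reference_set(list(fp(c(`1` = 2)), fp(c(`1` = 1, `2` = 1))))
  rwf <- reweight_factors(rs)
  expect_equal(rwf$idx, c(1L, 2L))
  expect_equal(rwf$rwf, c(1.0, 1 / 3), tolerance = 1e-12)

  # single reference, all counts equal -> every factor 1
  rwf1 <- reweight_factors(reference_set(list(fp(c(`3` = 2, `5` = 2)))))
  expect_equal(rwf1$rwf, c(1, 1))

  # reference-count mode counts references, not occurrences
  rs2 <- reference_set(list(fp(c(`1` = 9)), fp(c(`1` = 1, `2` = 1))),
                       frequency_mode = "reference-count")
  rwf2 <- reweight_factors(rs2)
  expect_equal(rwf2$rwf[rwf2$idx == 1L], 1.0)
  expect_equal(rwf2$rwf[rwf2$idx == 2L], 0.5)

  expect_error(reference_set(list()), "empty")
  expect_true(any(reweight_factors(rs)$rwf == 1))  # max always present
})

test_that("new weights add the factor to the original frequency", {
  rs <- reference_set(list(fp(c(`1` = 2)), fp(c(`1` = 1, `2` = 1))))
  f <- reweight_factors(rs)
  q <- fp(c(`1` = 3, `2` = 1, `7` = 2))
  rq <- apply_reweighting(q, f)
  expect_equal(rq$new_weights, c(3 + 1, 1 + 1 / 3, 2), tolerance = 1e-12)
  # every reweighted fragment present in the set strictly exceeds w
  in_set <- q$idx %in% f$idx
  expect_true(all(rq$new_weights[in_set] > q$count[in_set]))
  expect_equal(rq$new_weights[!in_set], q$count[!in_set])
})

test_that("database scoring agrees with the literal per-compound evaluation", {
  d <- tiny_dataset()
  st <- corpus_stats(d)
  q <- get_fingerprint(d, "M1")

  # TAN against the pairwise function
  tan <- score_database(d, st, "M1", "tan")
  expect_equal(unname(tan),
               vapply(d$ids, function(id)
                 tanimoto_continuous(q, get_fingerprint(d, id)), numeric(1)),
               ignore_attr = TRUE, tolerance = 1e-12)

  # BIN against the okapi_belief + belief_sum loop
  bin <- score_database(d, st, "M1", "bin")
  expect_equal(bin, naive_bin_scores(d, st, q), tolerance = 1e-12)

  # BINRF against the okapi_belief + belief_wsum loop
  rs <- reference_set(list(get_fingerprint(d, "M1"),
                           get_fingerprint(d, "M2")))
  rq <- apply_reweighting(q, reweight_factors(rs))
  binrf <- score_database(d, st, "M1", "binrf", refset = rs)
  expect_equal(binrf, naive_bin_scores(d, st, q, weights = rq$new_weights),
               tolerance = 1e-12)
})

test_that("model scores satisfy the documented identities", {
  d <- tiny_dataset()
  st <- corpus_stats(d)

  # TAN: an exact copy of the query scores 1 and ranks first
  tan <- score_database(d, st, "M1", "tan")
  expect_equal(unname(tan[c("M1", "M3")]), c(1, 1))
  expect_equal(rank_scores(tan)$molecule_id[1], "M1")

  # BIN: a compound sharing no fragment with the query scores exactly alpha
  bin <- score_database(d, st, "M1", "bin", alpha = 0.4)
  expect_equal(unname(bin[["M4"]]), 0.4, tolerance = 1e-12)

  # BINRF with itself as the only reference and count-uniform query
  # fragments: rwf is uniformly 1, the new weights are uniform, and the
  # weighted SUM collapses to the SUM -> identical to BIN
  qu <- fp(c(`1` = 2, `2` = 2, `8` = 2))
  rs1 <- reference_set(list(qu))
  expect_equal(score_database(d, st, qu, "binrf", refset = rs1),
               score_database(d, st, qu, "bin"), tolerance = 1e-14)

  expect_error(score_database(d, st, "M1", "binrf"), "reference set")

  # scores invariant under permutation of database order
  perm_ids <- c("M4", "M1", "M5", "M3", "M2")
  dp <- fp_dataset(lapply(perm_ids, get_fingerprint, dataset = d), perm_ids)
  bp <- score_database(dp, corpus_stats(dp), "M1", "bin", alpha = 0.4)
  expect_equal(bp[d$ids], bin, tolerance = 1e-14)
})

test_that("query fragments absent from the corpus are dropped for BIN", {
  d <- tiny_dataset()
  st <- corpus_stats(d)
  q_out <- fp(c(`1` = 2, `15` = 1))  # fragment 15 occurs nowhere
  q_in <- fp(c(`1` = 2))
  expect_equal(score_database(d, st, q_out, "bin"),
               score_database(d, st, q_in, "bin"), tolerance = 1e-14)
})

test_that("vs_model objects print, summarize and predict", {
  d <- tiny_dataset()
  m <- vs_model(d, "binrf")
  expect_s3_class(m, "vs_model")
  expect_output(print(m), "BINRF")
  expect_output(print(summary(m)), "compounds \\(m\\):\\s+5")
  sc <- predict(m, "M1", references = c("M1", "M2"))
  expect_equal(sc, score_database(d, m$stats, "M1", "binrf",
                                  refset = reference_set(
                                    list(get_fingerprint(d, "M1"),
                                         get_fingerprint(d, "M2")))))
  rk <- predict(vs_model(d, "tan"), "M1", type = "rank")
  expect_s3_class(rk, "ranked_list")
  expect_equal(nrow(rk), 5L)
})
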