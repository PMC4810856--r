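test_that("Good's u matches direct evaluation of the coverage formula", {
  expect_equal(goods_u(c(3, 2, 1, 1)), 5 / 7, tolerance = 1e-12)
  expect_equal(goods_u(c(5, 4, 3)), 1)
  expect_equal(goods_u(c(1, 1, 1, 1)), 0)
  # dominant-corrected form: 1 - s1/(O - n_dominant)
  expect_equal(goods_u(c(6, 2, 1, 1), correct_dominant = TRUE), 1 - 2 / 4)
  # degenerate inputs: empty bin undefined, single-singleton bin zero
  expect_true(is.na(goods_u(numeric(0))))
  expect_equal(goods_u(1, correct_dominant = TRUE), 0)
  expect_error(goods_u(c(0, 2)), ">= 1")
})

test_that("single-taxon and two-taxon bins behave as enumeration predicts", {
  # one taxon spread over many collections: richness 1 regardless of order
  occs <- make_bin_occs(list(list(pub = "p1", taxa = rep("A", 4)),
                             list(pub = "p1", taxa = rep("A", 3))))
  cfg <- sqs_config(quorum = 0.4, trials = 1)
  for (ord in all_perms(unique(occs$collection_id))) {
    expect_equal(sqs_trial(occs, cfg, order = ord), 1L)
  }
  # two equal-count taxa {5,5}, one collection each, dominant share counted:
  # the first collection's 0.5 share reaches q = 0.4, so richness is 1
  occs2 <- make_bin_occs(list(list(pub = "p1", taxa = rep("A", 5)),
                              list(pub = "p2", taxa = rep("B", 5))))
  cfg2 <- sqs_config(quorum = 0.4, trials = 1, dominant_share = TRUE,
                     correct_dominant = FALSE)
  for (ord in all_perms(c("c01", "c02"))) {
    expect_equal(sqs_trial(occs2, cfg2, order = ord), 1L)
  }
  # quorum high enough to require every taxon: richness 2 in every order
  cfg3 <- sqs_config(quorum = 0.99, trials = 1, dominant_share = TRUE,
                     correct_dominant = FALSE)
  for (ord in all_perms(c("c01", "c02"))) {
    expect_equal(sqs_trial(occs2, cfg3, order = ord), 2L)
  }
})

test_that("trials match the independent enumeration oracle over all draw orders", {
  # 4 collections over 2 publications, 5 taxa incl. a singleton and a dominant
  spec <- list(
    list(pub = "p1", taxa = c("A", "A", "B")),
    list(pub = "p1", taxa = c("A", "C", "C")),
    list(pub = "p2", taxa = c("B", "D")),
    list(pub = "p2", taxa = c("A", "E", "C"))
  )
  occs <- make_bin_occs(spec)
  colls <- unique(occs$collection_id)
  for (dialect in c("throttled", "plain")) {
    for (q in c(0.4, 0.7)) {
      for (flags in list(list(es = TRUE, id = TRUE, ds = FALSE, cd = TRUE),
                         list(es = FALSE, id = TRUE, ds = TRUE, cd = FALSE),
                         list(es = TRUE, id = FALSE, ds = FALSE, cd = TRUE))) {
        cfg <- sqs_config(quorum = q, trials = 1, dialect = dialect,
                          pubs_cap = 2L,
                          exclude_singletons = flags$es,
                          include_dominant = flags$id,
                          dominant_share = flags$ds,
                          correct_dominant = flags$cd)
        for (ord in all_perms(colls)) {
          got <- sqs_trial(occs, cfg, order = ord)
          want <- oracle_sqs(occs, ord, q, dialect = dialect, pubs_cap = 2L,
                             exclude_singletons = flags$es,
                             include_dominant = flags$id,
                             dominant_share = flags$ds,
                             correct_dominant = flags$cd)
          expect_identical(got, want)
        }
      }
    }
  }
})

test_that("plain and throttled dialects agree when no publication exceeds the cap", {
  spec <- list(
    list(pub = "p1", taxa = c("A", "B")),
    list(pub = "p2", taxa = c("A", "C", "C")),
    list(pub = "p3", taxa = c("B", "D", "D"))
  )
  occs <- make_bin_occs(spec)
  for (ord in all_perms(unique(occs$collection_id))) {
    a <- sqs_trial(occs, sqs_config(trials = 1, dialect = "plain"), order = ord)
    b <- sqs_trial(occs, sqs_config(trials = 1, dialect = "throttled", pubs_cap = 3),
                   order = ord)
    expect_identical(a, b)
  }
})

test_that("richness is monotone in quorum for a fixed draw order", {
  set.seed(42)
  spec <- lapply(1:6, function(i) {
    list(pub = sample(c("p1", "p2", "p3"), 1),
         taxa = sample(LETTERS[1:8], sample(2:4, 1), replace = TRUE))
  })
  occs <- make_bin_occs(spec)
  ord <- sample(unique(occs$collection_id))
  qs <- c(0.1, 0.3, 0.5, 0.7)
  rich <- vapply(qs, function(q) {
    sqs_trial(occs, sqs_config(quorum = q, trials = 1), order = ord)
  }, integer(1L))
  expect_true(all(diff(rich) >= 0))
})

test_that("seeded estimates are reproducible and bounded by observed richness", {
  sim <- simulate_scenario(jk_scenario(n0 = 60), seed = 4)
  b <- assign_to_bins(sim$occurrences, sim$truth$scheme, "constrained")
  cfg <- sqs_config(trials = 40, seed = 11)
  e1 <- sqs_estimate(b, cfg)
  e2 <- sqs_estimate(b, cfg)
  expect_identical(e1$mean, e2$mean)
  ok <- !is.na(e1$mean)
  expect_true(any(ok))
  expect_true(all(e1$mean[ok] <= e1$observed[ok]))
  expect_true(all(e1$u >= 0 & e1$u <= 1, na.rm = TRUE))
})

test_that("zero-coverage and below-quorum bins are undefined, not biased", {
  s <- toy_scheme()
  # all-singleton bin: u = 0 under the uncorrected form
  df <- data.frame(
    occurrence_id = paste0("o", 1:4), genus = paste0("G", 1:4), species = "",
    collection_id = paste0("c", 1:4), publication_id = "p1",
    age_max = 148, age_min = 146, realm = "marine", continent = "Europe",
    stringsAsFactors = FALSE
  )
  b <- assign_to_bins(occurrence_table(df), s, "constrained")
  e <- sqs_estimate(b, sqs_config(trials = 5, seed = 1, correct_dominant = FALSE))
  expect_equal(e$u[2], 0)
  expect_true(is.na(e$mean[2]))
  expect_true(all(is.na(e$mean[c(1, 3)]))) # empty bins undefined too
})

test_that("subsampled means scale with richness under equal sampling", {
  # two bins, identical sampling intensity, true richness ratio 2
  sch <- bin_scheme(c("x", "y"), older = c(160, 150), younger = c(150, 140))
  set.seed(31)
  mk <- function(bin_i, S, amax, amin) {
    a <- stats::rlnorm(S, -0.5, 1)
    counts <- stats::rpois(S, 3 * a) + 1L
    tot <- sum(counts)
    ci <- sample.int(ceiling(tot / 2.5), tot, replace = TRUE)
    data.frame(occurrence_id = sprintf("%d_%04d", bin_i, seq_len(tot)),
               genus = rep(sprintf("g%d_%03d", bin_i, seq_len(S)), counts),
               species = "",
               collection_id = sprintf("c%d_%03d", bin_i, ci),
               publication_id = sprintf("p%d_%02d", bin_i, ci %% 7L),
               age_max = stats::runif(tot, amin, amax),
               age_min = NA, realm = "marine", continent = "Europe",
               stringsAsFactors = FALSE)
  }
  df <- rbind(mk(1, 50, 159, 151), mk(2, 100, 149, 141))
  df$age_min <- df$age_max
  b <- assign_to_bins(occurrence_table(df), sch, "constrained")
  e <- sqs_estimate(b, sqs_config(trials = 300, seed = 5))
  expect_false(any(is.na(e$mean)))
  ratio <- e$mean[2] / e$mean[1]
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})

test_that("unconstrained trials resolve multi-bin occurrences without double counting", {
  sc <- tenmyr_bins()
  tr <- simulate_ranges(50, sc, 0.2, 0.2, seed = 21)
  occ <- simulate_occurrences(tr, 4, age_smear = 2, seed = 22)
  bu <- assign_to_bins(occ, sc, "unconstrained")
  bc <- assign_to_bins(occ, sc, "constrained")
  expect_gt(bc$n_multibin_dropped, 0)
  expect_equal(nrow(bu$table), nrow(occ))
  # every constrained assignment appears in the unconstrained candidate set
  idx <- match(bc$table$occurrence_id, bu$table$occurrence_id)
  expect_true(all(mapply(function(b_i, cand) b_i %in% cand,
                         bc$table$bin, bu$candidates[idx])))
  e <- sqs_estimate(bu, sqs_config(trials = 20, seed = 23))
  e2 <- sqs_estimate(bu, sqs_config(trials = 20, seed = 23))
  expect_identical(e$mean, e2$mean)
  expect_true(any(!is.na(e$mean)))
})

test_that("a true diversity drop is detected at every quorum level", {
  # a genuine two-fold richness drop between equally-sampled bins should be
  # visible at any quorum, not an artefact of one subsampling depth
  sch <- bin_scheme(c("x", "y"), older = c(160, 150), younger = c(150, 140))
  set.seed(77)
  mk <- function(bin_i, S, amax, amin) {
    a <- stats::rlnorm(S, -0.5, 1)
    counts <- stats::rpois(S, 4 * a) + 1L
    tot <- sum(counts)
    ci <- sample.int(ceiling(tot / 2.5), tot, replace = TRUE)
    data.frame(occurrence_id = sprintf("%d_%04d", bin_i, seq_len(tot)),
               genus = rep(sprintf("g%d_%03d", bin_i, seq_len(S)), counts),
               species = "", collection_id = sprintf("c%d_%03d", bin_i, ci),
               publication_id = sprintf("p%d_%02d", bin_i, ci %% 7L),
               age_max = stats::runif(tot, amin, amax), age_min = NA,
               realm = "marine", continent = "Europe", stringsAsFactors = FALSE)
  }
  df <- rbind(mk(1, 80, 159, 151), mk(2, 40, 149, 141))
  df$age_min <- df$age_max
  b <- assign_to_bins(occurrence_table(df), sch, "constrained")
  drops <- vapply(c(0.4, 0.6, 0.8), function(q) {
    e <- sqs_estimate(b, sqs_config(quorum = q, trials = 300, seed = 13))
    1 - e$mean[2] / e$mean[1]
  }, numeric(1L))
  expect_true(all(drops > 0.2))
  expect_true(all(drops < 0.8))
})
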