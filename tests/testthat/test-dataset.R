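test_that("label_sites applies the distance-50 negative rule", {
  # S at 60 (distance 40 -> excluded), annotated S at 100, S at 160
  # (distance 60 -> negative)
  chars <- rep("A", 200)
  chars[c(60, 100, 160)] <- "S"
  prof <- pssm_profile("P1", paste(chars, collapse = ""),
                       matrix(0L, 200, 20))
  lab <- label_sites(prof, 100)
  expect_identical(lab$label[lab$position == 60], "excluded")
  expect_identical(lab$label[lab$position == 100], "positive")
  expect_identical(lab$label[lab$position == 160], "negative")
})

test_that("short proteins yield no negatives when everything is in range", {
  chars <- rep(c("A", "S", "T", "Y", "K"), 6)  # 30 residues, site at 10
  chars[10] <- "S"
  prof <- pssm_profile("P1", paste(chars, collapse = ""),
                       matrix(0L, 30, 20))
  a <- 10
  lab <- label_sites(prof, a)
  expect_false(any(lab$label == "negative"))
  expect_identical(lab$label[lab$position == a], "positive")
})

test_that("positives on non-S/T/Y residues are rejected", {
  prof <- pssm_profile("P1", "MASTY", matrix(0L, 5, 20))
  expect_error(label_sites(prof, 1), class = "pssmphos_data_error")
  expect_error(label_sites(prof, 99), class = "pssmphos_data_error")
})

test_that("labeling trichotomy matches a brute-force oracle (property)", {
  for (i in 1:30) {
    prof <- rand_profile(sample(80:300, 1), seed = 300 + i)
    chars <- strsplit(prof$sequence, "")[[1]]
    sty <- which(chars %in% c("S", "T", "Y"))
    if (length(sty) < 2) next
    positives <- sort(sample(sty, min(length(sty), sample(1:3, 1))))
    lab <- label_sites(prof, positives)
    expect_identical(lab$position, sty)
    expect_identical(lab$label, oracle_labels(prof$sequence, positives))
    expect_true(all(lab$label %in% c("positive", "negative", "excluded")))
  }
})

test_that("extract_window flattens rows in ascending order with zero padding", {
  prof <- counting_profile(30)
  # interior, W=11: rows 6..16 concatenated, length 220
  v <- extract_window(prof, 11, 11)
  expect_length(v, 220)
  expect_identical(v, as.numeric(t(prof$scores[6:16, ])))

  # W=7 at position 1: first 3 row-slots all zeros, length 140
  v1 <- extract_window(prof, 1, 7)
  expect_length(v1, 140)
  expect_identical(v1[1:60], rep(0, 60))
  expect_identical(v1[61:140], as.numeric(t(prof$scores[1:4, ])))

  # 5x20 profile, W=3 at position 2: hand-flattened rows 1..3
  p5 <- counting_profile(5)
  expect_identical(extract_window(p5, 2, 3),
                   as.numeric(t(p5$scores[1:3, ])))

  expect_error(extract_window(prof, 5, 8), class = "pssmphos_config_error")
  expect_error(extract_window(prof, 5, -3), class = "pssmphos_config_error")
  expect_error(extract_window(prof, 31, 7), class = "pssmphos_data_error")
})

test_that("extract_window only sees rows inside the window (locality)", {
  prof <- rand_profile(40, seed = 17)
  v <- extract_window(prof, 20, 9)
  edited <- prof
  outside <- c(1:15, 25:40)
  edited$scores[outside, ] <- edited$scores[outside, ] + 7
  expect_identical(extract_window(edited, 20, 9), v)
})

test_that("build_instances counts, order and features are consistent", {
  # two proteins engineered to give 3 S positives and 4 S negatives
  mk <- function(id, seed) rand_profile(250, id = id, seed = seed)
  strip_sty <- function(prof) {
    chars <- strsplit(prof$sequence, "")[[1]]
    chars[chars %in% c("S", "T", "Y")] <- "A"
    chars
  }
  c1 <- strip_sty(mk("P1", 41)); c2 <- strip_sty(mk("P2", 42))
  # P1: positive S at 30, negative S at 120, 200; excluded S at 60
  c1[c(30, 60, 120, 200)] <- "S"
  # P2: positives S at 40 and 150 (101 apart -> both clear), negatives at
  # 241, 245 (within 50 of 150? 241-150=91 -> negative), plus a T negative
  c2[c(40, 150, 241, 245)] <- "S"
  c2[249] <- "T"
  p1 <- pssm_profile("P1", paste(c1, collapse = ""),
                     matrix(sample(-5:5, 250 * 20, TRUE), 250, 20))
  p2 <- pssm_profile("P2", paste(c2, collapse = ""),
                     matrix(sample(-5:5, 250 * 20, TRUE), 250, 20))
  profiles <- list(P1 = p1, P2 = p2)
  ann <- data.frame(protein_id = c("P1", "P2", "P2"),
                    position = c(30, 40, 150),
                    residue = "S", stringsAsFactors = FALSE)
  built <- build_instances(profiles, ann, "S", 9)
  expect_equal(n_instances(built$positives), 3L)
  expect_equal(n_instances(built$negatives), 4L)
  expect_true(all(built$positives$provenance$residue == "S"))
  expect_true(all(built$negatives$provenance$residue == "S"))
  # deterministic ordering: protein order then ascending position
  expect_identical(built$negatives$provenance$position, c(120L, 200L, 241L, 245L))
  # compositional consistency with extract_window
  i <- 2L
  pr <- built$negatives$provenance
  expect_identical(built$negatives$features[i, ],
                   extract_window(profiles[[pr$protein_id[i]]],
                                  pr$position[i], 9))
  # residue=T request never yields S/Y-centered instances
  builtT <- build_instances(profiles, ann, "T", 9)
  expect_true(all(builtT$negatives$provenance$residue == "T"))
  expect_equal(n_instances(builtT$positives), 0L)

  ann_bad <- rbind(ann, data.frame(protein_id = "MISSING", position = 1,
                                   residue = "S"))
  expect_error(build_instances(profiles, ann_bad, "S", 9),
               "MISSING", class = "pssmphos_data_error")
})

test_that("balance_plan and balance implement stride-r selection", {
  # p=100, n=1000, factor=2 -> r=5 -> 200 kept
  plan <- balance_plan(100, 1000, 2)
  expect_equal(plan$r, 5L)
  neg <- make_feature_instances(0, 1000, W = 7, seed = 3)
  kept <- balance(neg, plan)
  expect_equal(n_instances(kept), 200L)
  expect_identical(kept$provenance$position, seq(1L, 1000L, by = 5L))

  # n = factor * p exactly -> r = 1, all kept
  plan1 <- balance_plan(50, 100, 2)
  expect_equal(plan1$r, 1L)

  # p=10, n=35, factor=1 -> r=3 -> 12 kept at 0-based indices 0,3,...,33
  plan2 <- balance_plan(10, 35, 1)
  expect_equal(plan2$r, 3L)
  neg35 <- make_feature_instances(0, 35, W = 7, seed = 4)
  kept2 <- balance(neg35, plan2)
  expect_equal(n_instances(kept2), 12L)
  expect_identical(kept2$provenance$position, seq(1L, 34L, by = 3L))

  expect_error(balance_plan(10, 35, 0), class = "pssmphos_config_error")
  expect_error(balance(neg35, plan1), class = "pssmphos_data_error")
})

test_that("split_folds stratifies, partitions and is seed-reproducible", {
  inst <- make_feature_instances(9, 9, W = 7, seed = 5)
  folds <- split_folds(inst, folds = 3, seed = 1)
  for (f in folds) {
    expect_equal(sum(inst$target[f$test] > 0), 3L)
    expect_equal(sum(inst$target[f$test] < 0), 3L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, seq_len(18L))

  expect_identical(split_folds(inst, 3, seed = 1), folds)
  expect_false(identical(split_folds(inst, 3, seed = 2), folds))

  tiny <- make_feature_instances(2, 9, W = 7, seed = 6)
  expect_error(split_folds(tiny, 3), class = "pssmphos_data_error")
})

test_that("libsvm round-trip preserves instances and provenance", {
  inst <- make_feature_instances(5, 8, W = 7, delta = 4, seed = 7)
  tmp <- withr::local_tempfile(fileext = ".libsvm")
  write_libsvm(inst, tmp)
  back <- read_libsvm(tmp)
  expect_equal(back$features, inst$features)
  expect_identical(back$target, inst$target)
  expect_identical(back$provenance$protein_id, inst$provenance$protein_id)
  expect_identical(back$W, inst$W)
  # zero features are omitted from the sparse lines
  expect_false(any(grepl(":0( |$)", readLines(tmp))))
})

test_that("dataset lineage bookkeeping reproduces the A/A'/A'' chain", {
  # synthetic stand-in corpus: 6 proteins, one with a histidine site,
  # two overlapping the benchmark
  ann <- data.frame(
    protein_id = c("P1", "P1", "P2", "P3", "P3", "P4", "P5", "P6"),
    position = c(10, 20, 5, 7, 9, 3, 4, 8),
    residue = c("S", "T", "H", "S", "Y", "S", "T", "S"),
    stringsAsFactors = FALSE)
  lin <- dataset_lineage(ann, benchmark_proteins = c("P4", "P6"))
  expect_equal(lin$A$proteins, 6L)
  expect_equal(lin$A$annotations, 8L)
  expect_equal(lin$A$by_residue[["other"]], 1L)
  # A': drop P2 entirely
  expect_equal(lin$A_prime$proteins, 5L)
  expect_equal(lin$A_prime$annotations, 7L)
  # A'': additionally drop benchmark-overlapping P4, P6
  expect_equal(lin$A_double_prime$proteins, 3L)
  expect_equal(lin$A_double_prime$annotations, 5L)
  expect_identical(lin$A_double_prime$by_residue[c("S", "T", "Y")],
                   c(S = 2L, T = 2L, Y = 1L))
})
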