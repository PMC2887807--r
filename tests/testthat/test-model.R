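test_that("model_config encodes the standard hyperparameters", {
  cfg <- model_config("S", 11)
  expect_equal(cfg$k, 220L)
  expect_equal(cfg$gamma, 1 / 220)
  expect_equal(cfg$C, 1)
  expect_identical(cfg$kernel, "rbf")
  expect_error(model_config("S", 10), class = "pssmphos_config_error")
  expect_error(model_config("S", 11, C = -1), class = "pssmphos_config_error")
})

test_that("well-separated clusters are learned to >= 99% training accuracy", {
  inst <- make_feature_instances(80, 80, W = 9, delta = 10, seed = 21)
  bundle <- train_model(inst, model_config("S", 9))
  pred <- predict(bundle, inst)
  expect_gte(mean(pred == inst$target), 0.99)
})

test_that("training is deterministic and rejects degenerate input", {
  inst <- make_feature_instances(40, 40, W = 7, delta = 2, seed = 22)
  probe <- make_feature_instances(30, 30, W = 7, delta = 2, seed = 23)
  b1 <- train_model(inst, model_config("S", 7), seed = 1)
  b2 <- train_model(inst, model_config("S", 7), seed = 1)
  expect_identical(predict(b1, probe), predict(b2, probe))

  onecls <- make_feature_instances(10, 0, W = 7, seed = 24)
  expect_error(train_model(onecls, model_config("S", 7)),
               class = "pssmphos_model_error")
  expect_error(train_model(inst, model_config("S", 9)),
               class = "pssmphos_model_error")
})

test_that("predict is order-preserving, pure and dimension-checked", {
  inst <- make_feature_instances(40, 40, W = 7, delta = 3, seed = 25)
  bundle <- train_model(inst, model_config("S", 7))
  probe <- make_feature_instances(25, 25, W = 7, delta = 3, seed = 26)
  p <- predict(bundle, probe)
  expect_length(p, 50L)
  expect_true(all(p %in% c(-1, 1)))

  perm <- pssmphos:::with_local_seed(1, sample(50))
  expect_identical(predict(bundle, probe$features[perm, ]), p[perm])
  expect_identical(predict(bundle, probe$features[0, , drop = FALSE]),
                   numeric(0))
  expect_error(predict(bundle, matrix(0, 2, 10)),
               class = "pssmphos_model_error")
})

test_that("save/load round-trips predictions and enforces metadata", {
  inst <- make_feature_instances(40, 40, W = 11, delta = 3, seed = 27)
  bundle <- train_model(inst, model_config("S", 11))
  probe <- make_feature_instances(20, 20, W = 11, delta = 3, seed = 28)
  tmp <- withr::local_tempfile(fileext = ".svm.json")
  save_bundle(bundle, tmp)
  back <- load_bundle(tmp)
  expect_identical(predict(back, probe), predict(bundle, probe))
  expect_equal(back$config$gamma, bundle$config$gamma)

  expect_error(load_bundle(tmp, residue = "T", W = 11),
               class = "pssmphos_model_error")
  expect_error(load_bundle(tmp, residue = "S", W = 15),
               class = "pssmphos_model_error")
  expect_silent(load_bundle(tmp, residue = "S", W = 11))

  junk <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), junk)
  expect_error(load_bundle(junk), class = "pssmphos_model_error")
})

test_that("decision values agree with an independent SVM implementation", {
  # scikit-learn's libsvm-backed SVC is the oracle: same C, same gamma,
  # hard labels must agree except at numerically borderline points
  inst <- make_feature_instances(75, 75, W = 7, delta = 2, seed = 29)
  probe <- make_feature_instances(50, 50, W = 7, delta = 2, seed = 30)
  # pre-scale identically for both implementations and disable the
  # model's own scaling so the two SVMs see byte-identical data
  inst$features <- inst$features / 5
  probe$features <- probe$features / 5
  bundle <- train_model(inst, model_config("S", 7, scale = FALSE))
  mine <- predict(bundle, probe, decision_values = TRUE)

  tmp <- withr::local_tempdir()
  utils::write.table(cbind(inst$target, inst$features),
                     file.path(tmp, "train.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(probe$features, file.path(tmp, "probe.txt"),
                     row.names = FALSE, col.names = FALSE)
  script <- file.path(tmp, "oracle.py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.svm import SVC",
    "d = sys.argv[1]",
    "tr = np.loadtxt(d + '/train.txt'); pr = np.loadtxt(d + '/probe.txt')",
    "y, X = tr[:, 0], tr[:, 1:]",
    "m = SVC(C=1.0, kernel='rbf', gamma=1.0/X.shape[1]).fit(X, y)",
    "np.savetxt(d + '/dv.txt', m.decision_function(pr))"), script)
  status <- system2("python", c(script, tmp))
  expect_equal(status, 0L)
  dv_oracle <- scan(file.path(tmp, "dv.txt"), quiet = TRUE)
  dv_mine <- attr(mine, "decision_values")
  expect_lt(max(abs(dv_mine - dv_oracle)), 0.01)
  clear <- abs(dv_oracle) > 0.01
  expect_gt(sum(clear), 50)  # the comparison must not be vacuous
  expect_identical(as.numeric(mine)[clear],
                   as.numeric(ifelse(dv_oracle[clear] > 0, 1, -1)))
})

test_that("no signal means no skill: held-out |Mcc| stays near 0", {
  train <- make_feature_instances(1000, 1000, W = 9, delta = 0, seed = 31)
  test <- make_feature_instances(1000, 1000, W = 9, delta = 0, seed = 32)
  bundle <- train_model(train, model_config("S", 9))
  pred <- predict(bundle, test)
  rep <- compute_metrics(score_labels(test$target, pred))
  expect_lt(abs(rep$Mcc), 0.1)
})

test_that("held-out accuracy is monotone in planted effect size", {
  acc <- vapply(c(0, 2, 5), function(delta) {
    train <- make_feature_instances(150, 150, W = 9, delta = delta,
                                    seed = 33)
    test <- make_feature_instances(150, 150, W = 9, delta = delta,
                                   seed = 34)
    bundle <- train_model(train, model_config("S", 9))
    mean(predict(bundle, test) == test$target)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], acc[1])
})

test_that("the raw-feature mode round-trips through save/load", {
  inst <- make_feature_instances(40, 40, W = 7, delta = 3, seed = 35)
  cfg <- model_config("S", 7, scale = FALSE)
  bundle <- train_model(inst, cfg)
  probe <- make_feature_instances(20, 20, W = 7, delta = 3, seed = 36)
  p <- predict(bundle, probe)
  tmp <- withr::local_tempfile()
  save_bundle(bundle, tmp)
  expect_identical(predict(load_bundle(tmp), probe), p)
})
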