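test_that("the learning-rate schedule decays tenfold every ten epochs", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(0, cfg), 0.001)
  expect_equal(lr_at_epoch(9, cfg), 0.001)
  expect_equal(lr_at_epoch(10, cfg), 0.0001)
  expect_equal(lr_at_epoch(49, cfg), 1e-7)
  expect_error(lr_at_epoch(-1, cfg))
})

test_that("confusion matrices count what they should", {
  y <- factor(c("N", "F"), levels = aami_classes)
  p <- factor(c("F", "N"), levels = aami_classes)
  m <- confusion_matrix(y, p)
  expect_equal(m["N", "F"], 1L)
  expect_equal(m["F", "N"], 1L)
  expect_equal(sum(m), 2L)

  expect_equal(unclass(confusion_matrix(rep(aami_classes, 2),
                                        rep(aami_classes, 2))),
               diag(2L, 4), ignore_attr = TRUE)

  set.seed(8)
  yt <- sample(aami_classes, 1000, replace = TRUE)
  yp <- sample(aami_classes, 1000, replace = TRUE)
  expect_equal(sum(confusion_matrix(yt, yp)), 1000L)
  expect_error(confusion_matrix(yt, yp[-1]), "elements")
})

test_that("a perfect classifier scores 100 everywhere", {
  m <- confusion_matrix(rep(aami_classes, c(50, 5, 10, 2)),
                        rep(aami_classes, c(50, 5, 10, 2)))
  met <- per_class_metrics(m)
  expect_true(all(abs(as.matrix(met$per_class[, -1]) - 100) < 1e-12))
  expect_equal(met$overall_accuracy_pct, 100)
})

test_that("published reference matrices reproduce the published metrics", {
  met <- per_class_metrics(reference_confusion_matrices()$focal)
  expect_equal(met$per_class$ppv_pct[2], 68.34, tolerance = 0.005)
  expect_equal(met$per_class$se_pct[2], 81.37, tolerance = 0.005)
  expect_equal(met$macro$f1_pct, 66.09, tolerance = 0.005)
  expect_equal(met$overall_accuracy_pct, 92.53, tolerance = 0.005)
})

test_that("metrics are equivariant under joint row/column permutation", {
  m <- unclass(reference_confusion_matrices()$focal)
  base <- per_class_metrics(m)
  perm <- c(3, 1, 4, 2)
  m2 <- m[perm, perm]
  permuted <- per_class_metrics(m2)
  cols <- c("ppv_pct", "se_pct", "f1_pct", "acc_pct")
  expect_equal(as.matrix(permuted$per_class[, cols]),
               as.matrix(base$per_class[perm, cols]), ignore_attr = TRUE)
  expect_equal(permuted$macro, base$macro)
  expect_equal(permuted$overall_accuracy_pct, base$overall_accuracy_pct)
  # conservation: TP + FN sums to the grand total
  tp <- diag(m); fn <- rowSums(m) - tp
  expect_equal(sum(tp + fn), sum(m))
  expect_error(per_class_metrics(matrix(0L, 4, 4)), "zero total")
})

test_that("training is reproducible and the l2 penalty verifiably applies", {
  beats <- smoke_beats()[1:256, ]
  cfg <- function(l2) train_config(batch_size = 128, max_epochs = 2,
                                   l2_penalty = l2, seed = 31)
  m1 <- hb_train(beats, config = cfg(1e-3))
  m2 <- hb_train(beats, config = cfg(1e-3))
  expect_equal(m1$history$loss[2], m2$history$loss[2], tolerance = 1e-6)
  expect_identical(m1$params, m2$params)
  m0 <- hb_train(beats, config = cfg(0))
  expect_false(identical(m0$params[["L16_W"]], m1$params[["L16_W"]]))
})

test_that("a separable synthetic set is learned within a few epochs", {
  beats <- smoke_beats()
  model <- hb_train(beats, loss = loss_config("focal", gamma = 2),
                    config = train_config(batch_size = 64, max_epochs = 5,
                                          seed = 2))
  pred <- predict(model, beats, type = "class")
  expect_gte(mean(pred == beats$label), 0.95)
  # training loss decreased
  expect_lt(model$history$loss[5], model$history$loss[1])
})

test_that("evaluation enforces the inter-patient guarantee", {
  beats <- smoke_beats()
  model <- hb_train(beats[beats$record_id %in% c("smk01", "smk02"), ],
                    config = train_config(batch_size = 128, max_epochs = 1,
                                          seed = 4))
  expect_error(evaluate(model, beats), "smk01")
  held <- smoke_test_beats()
  ev <- evaluate(model, held)
  # accounting identities
  expect_equal(sum(ev$confusion), nrow(held))
  expect_equal(ev$metrics$n_correct, sum(diag(ev$confusion)))
  expect_equal(ev$metrics$macro$f1_pct, mean(ev$metrics$per_class$f1_pct),
               tolerance = 0.005)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(tidy(ev)), 4)
  expect_equal(glance(ev)$n_beats, nrow(held))
})

test_that("model summaries expose the architecture accounting", {
  m <- build_model(seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 18)
  expect_equal(sum(td$trainable), 30276)
  gl <- glance(m)
  expect_equal(gl$n_trainable, 30276)
  expect_equal(gl$epochs_trained, 0L)
})
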