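test_that("well-separated classes are classified perfectly", {
  tab <- synth_table(shift = c(posterior = 8, middle = 8, anterior = 8),
                     seed = 2)
  cv <- loocv_accuracy(tab, "middle", kernel_spec("linear"))
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$n_total, 23)
})

test_that("each subject is held out exactly once, independent of row order", {
  tab <- synth_table(shift = c(posterior = 0, middle = 2, anterior = 0),
                     seed = 3)
  cv <- loocv_accuracy(tab, "middle", kernel_spec("rbf"))
  expect_length(cv$predicted, 23)
  expect_setequal(cv$subjects, unique(tab$subject))

  shuf <- tab[sample(nrow(tab)), ]
  cv2 <- loocv_accuracy(shuf, "middle", kernel_spec("rbf"))
  expect_equal(cv2$accuracy, cv$accuracy)
})

test_that("permuted labels fall back to the imbalance baseline", {
  tab <- synth_table(shift = c(posterior = 0, middle = 3, anterior = 0),
                     seed = 4)
  set.seed(9)
  accs <- replicate(200, {
    perm <- tab
    subs <- unique(tab$subject)
    newlab <- sample(perm$label[match(subs, perm$subject)])
    perm$label <- newlab[match(perm$subject, subs)]
    loocv_accuracy(perm, "middle", kernel_spec("linear"))$accuracy
  })
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.75)
})

test_that("the experiment grid covers four kernels by four region sets", {
  tab <- synth_table(shift = c(posterior = 1, middle = 4, anterior = 1),
                     seed = 5)
  ex <- run_experiment(tab)
  expect_equal(nrow(ex$results), 16)
  expect_setequal(unique(ex$results$kernel),
                  c("linear", "polynomial", "rbf", "sigmoid"))
  expect_setequal(unique(ex$results$region_set),
                  c("posterior", "middle", "anterior", "all"))
  expect_true(all(ex$results$accuracy >= 0 & ex$results$accuracy <= 1))

  # combined region set concatenates the three regions' features
  expect_equal(ncol(rgfbreast:::region_matrix(tab, "all")$x), 39)
  expect_equal(ncol(rgfbreast:::region_matrix(tab, "middle")$x), 13)
})

test_that("a region carrying the only signal dominates the grid", {
  tab <- synth_table(shift = c(posterior = 0, middle = 6, anterior = 0),
                     seed = 6)
  res <- run_experiment(tab)$results
  lin <- res[res$kernel == "linear", ]
  acc <- setNames(lin$accuracy, lin$region_set)
  expect_gte(acc[["middle"]], acc[["posterior"]])
  expect_gte(acc[["middle"]], acc[["anterior"]])
})

test_that("standardization uses training folds only", {
  tab <- synth_table(shift = c(posterior = 5, middle = 5, anterior = 5),
                     seed = 7)
  # blow up the held-out subject's features along its own class side:
  # the fold that holds it out trains on unchanged data, so the subject
  # must still be classified by the unchanged model
  extreme <- tab
  f <- paste0("f", 1:13)
  extreme[extreme$subject == "S23", f] <-
    extreme[extreme$subject == "S23", f] + 1e3
  # with leaked (all-subject) standardization the extreme point would be
  # crushed towards the majority class; fold-wise standardization keeps
  # the held-out model untouched and classifies it decisively
  cv <- loocv_accuracy(extreme, "middle", kernel_spec("linear"))
  expect_equal(as.character(cv$predicted[cv$subjects == "S23"]), "sparse")
})

test_that("kernel specifications resolve to the study's hyper-parameters", {
  ks <- kernel_spec("rbf", sigma = 1)
  expect_equal(rgfbreast:::svm_args(ks, 13)$gamma, 0.5)      # 1 / (2 sigma^2)
  ks2 <- kernel_spec("rbf", sigma = 1, rbf_form = "plain")
  expect_equal(rgfbreast:::svm_args(ks2, 13)$gamma, 1)
  kp <- kernel_spec("polynomial")
  a <- rgfbreast:::svm_args(kp, 13)
  expect_equal(a$degree, 3); expect_equal(a$coef0, 1)
  expect_equal(a$gamma, 1 / 13)
  expect_equal(a$cost, 1)
})
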