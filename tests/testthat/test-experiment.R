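test_that("the annotator fits on training data only and predicts schemes", {
  res <- micro_dataset()
  labels <- res$labels
  tr <- labels[labels$split == "train", ]
  te <- labels[labels$split == "test", ]
  cfg <- micro_config()

  model <- fit_annotator(tr, res$dir, "original", cfg)
  expect_s3_class(model, "irma_annotator")
  # provenance: codebook and PCA saw training images only
  expect_setequal(model$train_ids, tr$image_id)
  expect_equal(nrow(model$train_features), nrow(tr))
  expect_equal(model$codebook$k, cfg$k)
  expect_lte(ncol(model$train_features), cfg$pca_dim)

  pred <- predict(model, te, res$dir)
  expect_equal(names(pred$labels), c("T", "IRMA"))
  expect_equal(nrow(pred$labels), nrow(te))
  expect_true(all(pred$labels$T %in% c("1121", "1124")))
})

test_that("the experiment report covers every requested cell", {
  res <- micro_dataset()
  labels <- res$labels
  tr <- labels[labels$split == "train", ]
  te <- labels[labels$split == "test", ]
  rep <- run_experiment(tr, res$dir, te, res$dir, micro_config())

  expect_s3_class(rep, "annotation_report")
  expect_equal(dim(rep$accuracy), c(1, 2))
  expect_equal(rownames(rep$accuracy), "Original Image")
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  expect_equal(rep$n_train, nrow(tr))
  expect_match(rep$config_hash, "^[0-9a-f]{8}$")

  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_report(rep, csv_path = f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(back$input_image, "Original Image")
  expect_equal(back$T, unname(rep$accuracy[1, "T"]))

  # report rows follow the canonical mode order when all modes are requested
  expect_equal(input_mode_labels(input_modes()),
               c("Image Padding", "Image Padding/Layered", "Image Layered",
                 "CLAHE Image", "NLMEANS Image", "Original Image"))
})

test_that("a degenerate single-class training table scores all or nothing", {
  dir <- tempfile("degenerate")
  cfg_gen <- generator_config(n_images = 10, t_vocab = "1121", d_vocab = "127",
                              a_vocab = "732", b_vocab = "500",
                              height_range = c(64, 80), width_range = c(64, 80),
                              seed = 13)
  res <- generate_dataset(cfg_gen, dir)
  tab <- res$labels
  cfg <- micro_config(schemes = "IRMA")
  rep_same <- run_experiment(tab[1:8, ], dir, tab[9:10, ], dir, cfg)
  expect_equal(unname(rep_same$accuracy["Original Image", "IRMA"]), 1.0)

  # test labels the model has never seen score zero
  te_other <- data.frame(image_id = tab$image_id[9:10],
                         irma_code = rep("1124-410-620-625", 2))
  rep_diff <- run_experiment(tab[1:8, ], dir, te_other, dir, cfg)
  expect_equal(unname(rep_diff$accuracy["Original Image", "IRMA"]), 0.0)
  expect_equal(rep_diff$unseen_test_classes[["original IRMA"]],
               "1124-410-620-625")
})

test_that("missing inputs abort with the failing stage named", {
  res <- micro_dataset()
  labels <- res$labels
  bad <- labels[labels$split == "train", ]
  bad$image_id[1] <- "does-not-exist.png"
  expect_error(
    run_experiment(bad, res$dir, labels[labels$split == "test", ], res$dir,
                   micro_config()),
    "stage 'fit'")
})

test_that("the benchmark carries the anatomical scheme through enhancement", {
  acc <- benchmark_run(1)$report$accuracy
  # shape classes are learnable end-to-end from the enhanced (layered) input
  expect_gte(acc["Image Layered", "A"], 0.9)
  # every cell of the matrix is populated and usable
  expect_true(all(is.finite(acc)))
})

test_that("accuracy is stable between 100 and 1,000 trees", {
  run <- benchmark_run(1)
  f <- run$report$features[["original"]]
  acc_small <- run$report$accuracy["Original Image", "T"]
  truth <- substr(f$test_labels, 1, 4)
  m <- train_random_forest(
    f$train, substr(f$train_labels, 1, 4),
    rf_config(n_trees = 1000,
              seed = derive_seed(run$report$seed, "rf original T")))
  acc_big <- evaluate_accuracy(predict(m, f$test)$labels, truth)
  expect_lt(abs(acc_big - acc_small), 0.05)
})
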