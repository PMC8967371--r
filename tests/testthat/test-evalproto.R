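test_that("metrics match hand computations and reconcile internally", {
  perfect <- compute_metrics(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$weighted_f1, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))

  m <- compute_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(m$accuracy, 75)
  expect_equal(m$per_class$f1, c(2 / 3, 4 / 5))
  expect_equal(m$weighted_f1, 11 / 15)
  ## confusion marginals reconcile with accuracy and support
  expect_equal(unname(rowSums(m$confusion)), c(2, 2))
  expect_equal(100 * sum(diag(m$confusion)) / sum(m$confusion), m$accuracy)
  expect_error(compute_metrics(character(0), character(0)), "empty")
  expect_error(compute_metrics("A", c("A", "B")), "mismatch")
})

test_that("weighted F1 equals brute force on random label vectors", {
  set.seed(31)
  classes <- c("neg", "neu", "pos")
  for (i in 1:100) {
    n <- sample(5:60, 1)
    yt <- sample(classes, n, replace = TRUE)
    yp <- sample(classes, n, replace = TRUE)
    m <- compute_metrics(yt, yp, class_order = classes)
    expect_equal(m$weighted_f1, brute_force_f1(yt, yp, classes),
                 tolerance = 1e-12)
    expect_equal(m$accuracy, 100 * mean(yt == yp), tolerance = 1e-12)
    expect_equal(unname(rowSums(m$confusion)),
                 unname(as.vector(table(factor(yt, classes)))))
  }
})

test_that("label harmonisation maps the competition vocabulary", {
  recs <- list(recording(matrix(0, 1, 10), "CZ", 10, label = "happy"),
               recording(matrix(0, 1, 10), "CZ", 10, label = "sad"),
               recording(matrix(0, 1, 10), "CZ", 10, label = "neutral"))
  labs <- vapply(harmonize_labels(recs), `[[`, character(1), "label")
  expect_identical(labs, c("positive", "negative", "neutral"))
})

test_that("subject k-fold is a stratified partition with the 24+29 sizes", {
  ids <- paste0("S", 1:53)
  diag <- c(rep("MDD", 24), rep("HC", 29))
  f <- subject_kfold(ids, diag, k = 5, seed = 2)
  expect_setequal(f$subject_id, ids)                     # exact partition
  expect_equal(anyDuplicated(f$subject_id), 0)
  sizes <- as.vector(table(f$fold))
  expect_equal(sizes, c(11, 11, 11, 11, 9))
  tab <- table(f$stratum, f$fold)
  expect_equal(as.vector(tab["MDD", ]), c(5, 5, 5, 5, 4))
  expect_equal(as.vector(tab["HC", ]), c(6, 6, 6, 6, 5))
  ## per-fold stratum proportions within one subject of global
  for (k in 1:5)
    expect_lte(abs(tab["MDD", k] - 24 / 5), 1)
  expect_error(subject_kfold(ids, diag, k = 60), "exceeds")
  expect_error(subject_kfold(c("a", "a"), k = 1), "unique")
})

fast_cfg <- function(...) {
  pipeline_config(
    synth = list(n_subjects = 3, n_trials_per_class = 2, trial_duration = 8),
    model = list(conv_widths = c(4, 4, 4, 4, 4), embed_dim = 16,
                 lstm_hidden = 8),
    train = list(epochs = 12, frame_length = 4, batch_size = 8),
    ...)
}

make_db <- function(seed, n_subjects = 2, prefix = NULL) {
  sp <- synth_spec(n_subjects = n_subjects, n_trials_per_class = 2,
                   trial_duration = 8, noise_sd = 0.5, seed = seed)
  recs <- generate_dataset(sp)
  if (!is.null(prefix))
    recs <- lapply(recs, function(r) {
      r$subject_id <- paste0(prefix, r$subject_id); r
    })
  recs
}

test_that("the cross-database protocol trains on one set and scores the other", {
  cfg <- fast_cfg()
  rep <- cross_database_protocol(make_db(101, prefix = "A_"),
                                 make_db(202, prefix = "B_"), cfg)
  expect_s3_class(rep, "eval_report")
  expect_identical(rep$protocol, "cross_database")
  expect_identical(rep$alignment, "with EA")
  expect_gt(rep$accuracy, 100 / 3)              # transfers above chance
  expect_true(all(startsWith(rep$per_subject$subject_id, "B_")))
  expect_warning(cross_database_protocol(make_db(101), make_db(101), cfg),
                 "overlap")
})

test_that("LOSO builds one fold per subject with disjoint training sets", {
  cfg <- fast_cfg()
  rep <- loso_protocol(make_db(77, n_subjects = 3), cfg)
  expect_identical(rep$protocol, "loso")
  expect_equal(nrow(rep$per_subject), 3)
  expect_setequal(rep$per_subject$subject_id, paste0("sub0", 1:3))
  expect_equal(rep$mean_accuracy, mean(rep$per_subject$accuracy))
  expect_equal(rep$sd_accuracy, sd(rep$per_subject$accuracy))
  expect_equal(sum(rep$per_subject$n), rep$n)
  expect_error(loso_protocol(make_db(5, n_subjects = 1), cfg), "2 subjects")
})

test_that("the frame-length sweep covers its default grid and trims trials", {
  expect_equal(eval(formals(frame_length_sweep)$lengths),
               c(8, 12, 16, 20, 24, 28, 32))
  cfg <- fast_cfg()
  tab <- frame_length_sweep(make_db(55, n_subjects = 3),
                            lengths = c(2, 4), cfg)
  expect_equal(tab$frame_length, c(2, 4))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
  ## longer frames -> no more sequences than shorter ones
  expect_lte(tab$n_train[2], tab$n_train[1])
  expect_warning(frame_length_sweep(make_db(55, n_subjects = 3),
                                    lengths = 50, cfg),
                 "skipped|exceeds")
})
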