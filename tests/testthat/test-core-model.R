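test_that("dataset invariants: unique names, shape, version counting", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  ds <- expression_dataset(m * 1.0)
  expect_equal(dim(ds), c(2L, 3L))
  expect_equal(dataset_version(ds), 1L)

  bad <- m; rownames(bad) <- c("a", "a")
  expect_error(expression_dataset(bad * 1.0), "duplicate probe")
  expect_error(expression_dataset(matrix(1.0, 2, 2)), "rownames")

  ds2 <- set_probe_values(ds, "a", c(9, 9, 9))
  expect_gt(dataset_version(ds2), dataset_version(ds))
  expect_equal(dataset_version(ds), 1L)  # original untouched
})

test_that("z-scoring: rows to mean 0 / sd 1, constant rows to zero", {
  ds <- tiny_ds()
  z <- zscore_dataset(ds)
  expect_equal(unname(dataset_values(z)["SCO0001", ]), c(-1, 0, 1))
  expect_equal(unname(dataset_values(z)["SCO0002", ]), c(0, 0, 0))
  v <- dataset_values(z)
  expect_lt(max(abs(rowMeans(v))), 1e-12)
  sds <- apply(v, 1, sd)
  expect_equal(unname(sds[c(1, 3)]), c(1, 1), tolerance = 1e-12)
  expect_gt(dataset_version(z), dataset_version(ds))
  # idempotence on non-constant rows
  z2 <- zscore_dataset(z)
  expect_equal(dataset_values(z2), dataset_values(z), tolerance = 1e-9)
  one <- expression_dataset(matrix(1.0, 2, 1, dimnames = list(c("a", "b"), "e")))
  expect_error(zscore_dataset(one), "2 experiments")
})

test_that("centering by mean and median", {
  ds <- expression_dataset(matrix(c(1, 2, 9), 1, 3,
                                  dimnames = list("p", c("a", "b", "c"))))
  expect_equal(unname(dataset_values(center_dataset(ds, "mean"))[1, ]),
               c(-3, -2, 5))
  expect_equal(unname(dataset_values(center_dataset(ds, "median"))[1, ]),
               c(-1, 0, 7))
  centered <- center_dataset(ds, "mean")
  again <- center_dataset(centered, "mean")
  expect_equal(dataset_values(again), dataset_values(centered))
})

test_that("smoothing: moving average with shrinking edge windows", {
  ds <- expression_dataset(matrix(c(0, 0, 3, 0, 0), 1, 5,
                                  dimnames = list("p", paste0("e", 1:5))))
  expect_equal(unname(dataset_values(smooth_dataset(ds, 3))[1, ]),
               c(0, 1, 1, 1, 0))
  expect_equal(dataset_values(smooth_dataset(ds, 1)), dataset_values(ds))
  const <- expression_dataset(matrix(2.5, 1, 5,
                                     dimnames = list("p", paste0("e", 1:5))))
  expect_equal(dataset_values(smooth_dataset(const, 5)), dataset_values(const))
  expect_error(smooth_dataset(ds, 2), "odd")
  expect_error(smooth_dataset(ds, -1), "odd")
})

test_that("transforms never change shape or ordering", {
  set.seed(11)
  syn <- quiet_synth(n_probes = 30, seed = 11)
  for (f in list(zscore_dataset, center_dataset,
                 function(d) smooth_dataset(d, 5))) {
    out <- f(syn$dataset)
    expect_identical(dimnames(dataset_values(out)),
                     dimnames(dataset_values(syn$dataset)))
  }
})

test_that("regularized variance: bounded, monotone, rank-preserving", {
  set.seed(4)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("p", 1:20), paste0("e", 1:10)))
  m[1, ] <- 7  # constant probe
  ds <- expression_dataset(m)
  rv <- regularized_variance(ds)
  expect_s3_class(rv, "MetaInfoGroup")
  expect_equal(unname(rv$values["p1"]), 0)
  expect_true(all(rv$values >= 0 & rv$values < 1))
  raw <- apply(m, 1, var)
  expect_equal(order(rv$values), order(raw))

  # equal positive variances -> all 0.5
  eq <- expression_dataset(matrix(rep(c(0, 1), 12), 4, 6, byrow = TRUE,
                                  dimnames = list(paste0("q", 1:4),
                                                  paste0("e", 1:6))))
  expect_equal(unname(regularized_variance(eq)$values), rep(0.5, 4))
  expect_error(regularized_variance(
    expression_dataset(matrix(1.0, 2, 1,
                              dimnames = list(c("a", "b"), "e")))),
    "2 experiments")
})

test_that("merge and split are lossless and validated", {
  set.seed(5)
  syn <- quiet_synth(n_probes = 12, n_timepoints = 5, seed = 5)
  ds <- syn$dataset
  halves <- split_dataset(ds, experiments(ds)[1:3])
  expect_equal(ncol(dataset_values(halves$selected)), 3)
  expect_equal(ncol(dataset_values(halves$rest)), 2)
  back <- merge_datasets(halves$selected, halves$rest)
  expect_equal(dataset_values(back)[, experiments(ds)], dataset_values(ds))

  full <- split_dataset(ds, probe_list("all", probes(ds)))
  expect_equal(nrow(dataset_values(full$selected)), nrow(dataset_values(ds)))
  expect_equal(nrow(dataset_values(full$rest)), 0)

  expect_error(merge_datasets(ds, ds), "collision")
  other <- expression_dataset(matrix(1.0, 2, 2,
                                     dimnames = list(c("zz1", "zz2"),
                                                     c("n1", "n2"))))
  expect_error(merge_datasets(ds, other), "identical probe sets")
})

test_that("annotation records validate coordinates and strand", {
  ann <- annotation_records("SCO5071", "chr", 5529301, 5530200, "+")
  expect_equal(ann$start, 5529301L)
  expect_error(annotation_records("x", "chr", 10, 5, "+"), "start > end")
  expect_error(annotation_records("x", "chr", 1, 5, "x"), "strand")
  expect_error(annotation_records("x", "chr", 0, 5, "+"), ">= 1")
  # unicode minus accepted
  ann2 <- annotation_records("x", "chr", 1, 5, "−")
  expect_equal(ann2$strand, "-")
  groups <- annotation_to_meta(ann)
  expect_setequal(names(groups), c("start", "end", "strand", "replicon"))
  expect_equal(groups$strand$kind, "category")
})
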