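# Readers/writers and cohort alignment.

test_that("time-series TSV round-trips and validates", {
  d <- withr::local_tempdir()
  m <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  ts <- parcellated_ts("s1", m, tr = 0.645)
  p <- file.path(d, "s1.tsv")
  write_timeseries(ts, p)
  back <- read_timeseries(p, tr = 0.645)
  expect_equal(back$data, ts$data, tolerance = 1e-8)
  expect_identical(back$node_ids, c("a", "b", "c", "d"))
  expect_identical(back$subject_id, "s1")

  # malformed inputs
  writeLines(c("a\tb", "1\t2", "3\tNaN"), file.path(d, "bad.tsv"))
  err <- expect_error(read_timeseries(file.path(d, "bad.tsv")),
                      class = "dynmod_parse_error")
  expect_match(conditionMessage(err), "row 2.*column 2")
  writeLines(c("a\tb", "1\t2", "3"), file.path(d, "ragged.tsv"))
  expect_error(read_timeseries(file.path(d, "ragged.tsv")),
               class = "dynmod_parse_error")
  expect_error(read_timeseries(file.path(d, "missing.tsv")),
               class = "dynmod_parse_error")
})

test_that("parcellated_ts enforces its invariants", {
  m <- matrix(1:6, 3, 2)
  expect_error(parcellated_ts("s", m[1, , drop = FALSE], 0.6),
               class = "dynmod_parse_error") # < 2 time points
  expect_error(parcellated_ts("s", m, 0), class = "dynmod_parse_error")
  expect_error(parcellated_ts("s", m, 0.6, node_ids = c("x", "x")),
               class = "dynmod_parse_error")
  m[2, 1] <- NA
  expect_error(parcellated_ts("s", m, 0.6), class = "dynmod_parse_error")
})

test_that("node labeling is structured and validated", {
  lab <- make_node_labeling(114)
  expect_identical(nrow(lab), 114L)
  expect_setequal(unique(lab$network_7), yeo7_networks())
  expect_identical(length(unique(lab$network_17)), 17L) # merged hemispheres
  expect_identical(as.vector(table(lab$hemisphere)), c(57L, 57L))

  bad <- lab
  bad$network_7[1] <- "XXX"
  expect_error(write_node_labeling(bad, tempfile()), class = "dynmod_parse_error")
  expect_error(make_node_labeling(7), class = "dynmod_parse_error")
})

test_that("phenotype CSV round-trips with its coding header", {
  d <- withr::local_tempdir()
  ph <- data.frame(subject_id = c("s1", "s2", "s3"), fsiq = c(95, 110, 100),
                   age = c(30, 40, 50), sex = c(0, 1, 0),
                   handedness = c(1, 1, 0), mean_fd = c(0.1, 0.2, 0.15))
  p <- file.path(d, "ph.csv")
  write_phenotype(ph, p)
  expect_match(readLines(p, n = 1), "^# sex")
  back <- read_phenotype(p)
  expect_equal(back, ph, tolerance = 1e-12)
  ph$mean_fd[2] <- NA
  expect_error(write_phenotype(ph, p), class = "dynmod_parse_error")
})

test_that("matrix TSV writer/reader round-trips at 9 significant digits", {
  m <- matrix(rnorm(25), 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, p)
  back <- read_matrix_tsv(p)
  expect_equal(back, m, tolerance = 1e-8)
  expect_identical(rownames(back), letters[1:5])
})

test_that("partitions round-trip through TSV with q recomputation", {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1
  w[4:6, 4:6] <- 1
  diag(w) <- 0
  rownames(w) <- colnames(w) <- sprintf("n%03d", 1:6)
  p <- best_partition(w, gamma = 1, n_runs = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(p, f)
  back <- read_partition(f, matrix = w, gamma = 1)
  expect_identical(back$assignment, p$assignment)
  expect_equal(back$q, p$q, tolerance = 1e-12)
  expect_identical(back$n_modules, p$n_modules)
})

test_that("align_cohort detects mismatches and drops extra phenotype rows", {
  coh <- generate_cohort(toy_sim_config())
  ok <- align_cohort(coh$series, coh$labeling, coh$phenotype)
  expect_s3_class(ok, "dynmod_cohort")
  expect_identical(ok$phenotype$subject_id,
                   vapply(coh$series, `[[`, character(1), "subject_id"))

  # permuted columns in one subject
  perm <- coh$series
  p2 <- perm[[2]]
  p2$data <- p2$data[, rev(seq_len(ncol(p2$data)))]
  p2$node_ids <- rev(p2$node_ids)
  perm[[2]] <- p2
  err <- expect_error(align_cohort(perm, coh$labeling, coh$phenotype),
                      class = "dynmod_alignment_error")
  expect_match(conditionMessage(err), "sub0002")

  # extra phenotype rows are dropped with a warning
  extra <- rbind(coh$phenotype,
                 data.frame(subject_id = "ghost", fsiq = 100, age = 30,
                            sex = 0, handedness = 1, mean_fd = 0.1))
  expect_warning(al <- align_cohort(coh$series, coh$labeling, extra),
                 "ghost")
  expect_identical(nrow(al$phenotype), length(coh$series))

  # missing subject and empty cohort
  expect_error(align_cohort(coh$series, coh$labeling, coh$phenotype[-1, ]),
               class = "dynmod_alignment_error")
  expect_error(align_cohort(list(), coh$labeling, coh$phenotype),
               class = "dynmod_alignment_error")
})
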