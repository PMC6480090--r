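test_that("read_accel_csv parses valid files and rejects malformed ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,0.1,0.2,0.9", "1,0.2,0.1,1.0", "2,0.0,0.3,0.8"),
             path)
  trace <- read_accel_csv(path)
  expect_equal(nrow(trace), 3L)
  expect_equal(trace$az, c(0.9, 1.0, 0.8))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("t,x,y,z", empty)
  expect_error(read_accel_csv(empty), class = "fallcnn_empty_trace")
  expect_error(read_accel_csv(file.path(tempdir(), "nope.csv")),
               class = "fallcnn_missing_file")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y", "0,1,2"), nocol)
  expect_error(read_accel_csv(nocol), class = "fallcnn_missing_column")

  badnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,oops,2,3"), badnum)
  expect_error(read_accel_csv(badnum), class = "fallcnn_non_numeric")
})

test_that("write then read round-trips a trace field by field", {
  trace <- make_trace(50, seed = 7)
  trace$label <- rep(c(0L, 1L), 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_accel_csv(trace, path)
  back <- read_accel_csv(path)
  expect_equal(back$t, trace$t)
  expect_equal(back$ax, trace$ax)
  expect_equal(back$ay, trace$ay)
  expect_equal(back$az, trace$az)
  expect_equal(back$label, trace$label)
})

test_that("segment_windows slices at the documented offsets", {
  expect_length(segment_windows(make_trace(100), 25, 25), 4L)
  expect_length(segment_windows(make_trace(24), 25), 0L)
  w <- segment_windows(make_trace(500), 500, 500)
  expect_length(w, 1L)
  expect_equal(dim(w[[1]]), c(500L, 3L))
})

test_that("segment_windows count matches exhaustive offset enumeration", {
  set.seed(11)
  for (i in 1:40) {
    T_ <- sample(1:200, 1); L <- sample(1:60, 1); s <- sample(1:30, 1)
    trace <- make_trace(T_, seed = i)
    got <- length(segment_windows(trace, L, s))
    offsets <- 0L
    n_brute <- 0L
    off <- 0L
    while (off + L <= T_) { n_brute <- n_brute + 1L; off <- off + s }
    expect_identical(got, n_brute)
    expect_equal(got, if (T_ >= L) (T_ - L) %/% s + 1L else 0L)
  }
})

test_that("windows inherit labels from a labeled trace", {
  trace <- make_trace(50)
  trace$label <- c(rep(0L, 25), rep(1L, 25))
  ws <- segment_windows(trace, 25, 25)
  expect_equal(vapply(ws, attr, "", "label"), c("adl", "fall"))
})

test_that("fit_min_max finds per-channel extrema", {
  w <- accel_window(cbind(c(-2, 0, 2), c(1, 1, 1), c(0, 5, -5)), "adl")
  p <- fit_min_max(accel_dataset(list(w)))
  expect_equal(p$min, c(-2, 1, -5))
  expect_equal(p$max, c(2, 1, 5))
  expect_equal(p$degenerate, c(FALSE, TRUE, FALSE))

  d <- make_dataset(c("fall", "adl"), L = 16L, seed = 3)
  p2 <- fit_min_max(d)
  all_vals <- do.call(rbind, lapply(d$windows, unclass))  # exhaustive scan
  expect_equal(p2$min, apply(all_vals, 2, min))
  expect_equal(p2$max, apply(all_vals, 2, max))
  expect_error(fit_min_max(accel_dataset(list())),
               class = "fallcnn_empty_dataset")
})

test_that("apply_min_max maps the fit set into [0,1] and inverts exactly", {
  d <- make_dataset(rep(c("fall", "adl"), 5), L = 12L, seed = 5)
  p <- fit_min_max(d)
  nd <- apply_min_max(d, p)
  vals <- unlist(lapply(nd$windows, unclass))
  expect_true(all(vals >= 0 & vals <= 1))
  back <- invert_min_max(nd, p)
  for (i in seq_along(d$windows))
    expect_equal(unclass(back$windows[[i]]), unclass(d$windows[[i]]),
                 tolerance = 1e-9)
  # labels and origins survive
  expect_identical(attr(nd$windows[[1]], "label"), attr(d$windows[[1]], "label"))
})

test_that("apply_min_max endpoints, degenerate channels, and no clipping", {
  w <- accel_window(cbind(c(0, 2), c(3, 3), c(-1, 1)), "adl")
  p <- fit_min_max(accel_dataset(list(w)))
  nw <- apply_min_max(accel_dataset(list(w)), p)$windows[[1]]
  expect_equal(nw[, 1], c(0, 1))     # min -> 0, max -> 1
  expect_equal(nw[, 2], c(0, 0))     # constant channel -> all zeros
  # out-of-range test values are not clipped
  w2 <- accel_window(cbind(c(-1, 4), c(3, 3), c(0, 0)), "adl")
  nw2 <- apply_min_max(accel_dataset(list(w2)), p)$windows[[1]]
  expect_lt(nw2[1, 1], 0)
  expect_gt(nw2[2, 1], 1)
})

test_that("split_dataset sizes, determinism and class-count conservation", {
  d <- make_dataset(rep(c("fall", "adl"), c(4, 6)), seed = 2)
  sp <- split_dataset(d, 0.8, seed = 9)
  expect_length(sp$train$windows, 8L)
  expect_length(sp$test$windows, 2L)
  origins <- function(ds) sort(vapply(ds$windows, attr, "", "origin"))
  expect_identical(sort(c(origins(sp$train), origins(sp$test))), origins(d))
  expect_equal(sp$train$class_counts + sp$test$class_counts, d$class_counts)

  sp2 <- split_dataset(d, 0.8, seed = 9)
  expect_identical(origins(sp2$train), origins(sp$train))
})

test_that("an 80/20 split of 5000 windows gives 4000 and 1000", {
  d <- make_dataset(rep(c("fall", "adl"), c(2000, 3000)), L = 8L)
  sp <- split_dataset(d, 0.8, seed = 1)
  expect_length(sp$train$windows, 4000L)
  expect_length(sp$test$windows, 1000L)
})

test_that("dataset manifest round-trips windows, labels and origins", {
  d <- make_dataset(c("fall", "adl", "adl"), L = 10L, seed = 4)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  back <- read_dataset(dir)
  expect_equal(back$window_length, d$window_length)
  expect_equal(back$class_counts, d$class_counts)
  for (i in seq_along(d$windows)) {
    expect_equal(unclass(back$windows[[i]]), unclass(d$windows[[i]]),
                 tolerance = 1e-12)
    expect_identical(attr(back$windows[[i]], "label"),
                     attr(d$windows[[i]], "label"))
  }
})
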