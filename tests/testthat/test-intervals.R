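test_that("interval validation enforces the half-open convention", {
  expect_error(intervals("c", 10, 10), "start < end")
  expect_error(intervals("c", -1, 10), "start < end")
  expect_error(intervals("", 0, 10), "non-empty")
  x <- intervals("c", 0, 10)
  expect_equal(x$strand, "*")
  expect_equal(interval_width(x), 10L)
})

test_that("interval_subtract returns maximal uncovered sub-intervals", {
  a <- intervals("c", 0, 1000)
  expect_equal(interval_subtract(a, intervals("c", 400, 600))[, c("start", "end")],
               tibble::tibble(start = c(0L, 600L), end = c(400L, 1000L)))
  expect_equal(nrow(interval_subtract(a, intervals("c", 0, 1000))), 0)
  expect_equal(interval_subtract(a, intervals("c", 900, 1200))[, c("start", "end")],
               tibble::tibble(start = 0L, end = 900L))
  expect_error(interval_subtract(a, intervals("other", 0, 10)), "single chromosome")
})

test_that("overlap_bp handles disjoint, abutting and nested pairs", {
  expect_equal(overlap_bp(intervals("c", 0, 100), intervals("c", 50, 150)), 50L)
  expect_equal(overlap_bp(intervals("c", 0, 100), intervals("c", 100, 200)), 0L)
  expect_equal(overlap_bp(intervals("c", 0, 100), intervals("c", 0, 100)), 100L)
  expect_equal(overlap_bp(intervals("c1", 0, 100), intervals("c2", 0, 100)), 0L)
})

test_that("subtracted length plus merged overlap equals the original length", {
  set.seed(42)
  for (rep in 1:50) {
    a <- sort(sample.int(2000, 2))
    x <- intervals("c", a[1], a[2])
    nb <- sample.int(6, 1)
    s <- sample.int(2200, nb)
    y <- intervals("c", s, s + sample.int(300, nb))
    kept <- interval_subtract(x, y)
    kept_len <- if (nrow(kept)) sum(kept$end - kept$start) else 0L
    merged <- interval_reduce(y)
    ov <- sum(overlap_bp(x[rep(1, nrow(merged)), ], merged))
    expect_equal(kept_len + ov, a[2] - a[1])
  }
})
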