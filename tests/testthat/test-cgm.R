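test_that("sample classification covers the whole glucose range once", {
  expect_equal(as.character(classify_sample(144)), "eu")
  expect_equal(as.character(classify_sample(72)), "eu")
  expect_equal(as.character(classify_sample(200)), "S_hyper")
  expect_equal(as.character(classify_sample(100)), "eu")
  expect_equal(as.character(classify_sample(46)), "S_hypo")
  expect_equal(as.character(classify_sample(47)), "m_hypo")
  expect_equal(as.character(classify_sample(180)), "m_hyper")
  expect_equal(as.character(classify_sample(180.5)), "S_hyper")
  expect_equal(as.character(classify_sample(NA)), "unknown")
  # total and single-valued over the physiologic range
  x <- seq(0.5, 1000, by = 0.25)
  cls <- classify_sample(x)
  expect_false(any(is.na(cls)))
  expect_false(any(cls == "unknown"))
})

test_that("event detection needs four consecutive same-class samples", {
  expect_equal(nrow(classify_events(make_trace(rep(100, 12)))), 0)
  ev <- classify_events(make_trace(c(100, 150, 150, 150, 150, 100)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$klass, "m_hyper")
  expect_equal(ev$start_idx, 2)
  expect_equal(ev$end_idx, 5)
  expect_equal(ev$duration_min, 20)
  expect_equal(ev$span_min, 15)
  # 3-sample excursion is not an event
  expect_equal(nrow(classify_events(make_trace(c(100, 190, 190, 190, 100)))),
               0)
  # missing samples break runs
  tr <- make_trace(c(150, 150, NA, 150, 150, 150, 100))
  expect_equal(nrow(classify_events(tr)), 0)
  # mixed severities are separate runs unless merged
  v <- c(150, 150, 150, 190, 190, 190, 100)
  expect_equal(nrow(classify_events(make_trace(v))), 0)
  expect_equal(nrow(classify_events(make_trace(v), merge_severity = TRUE)), 1)
})

test_that("event detection matches a brute-force scanner on random traces", {
  set.seed(42)
  for (i in 1:100) {
    tr <- random_trace()
    got <- classify_events(tr)[, c("klass", "start_idx", "end_idx")]
    want <- oracle_events(tr)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("critical gap is the first quartile under both conventions", {
  expect_equal(critical_gap(c(30, 30, 30, 30)), 30)
  expect_equal(critical_gap(45), 45)
  # hand order-statistic computation (type-7: 15 + 0.75 * (20 - 15))
  expect_equal(critical_gap(c(15, 20, 30, 60)), 18.75)
  expect_equal(critical_gap(c(15, 20, 30, 60), "nearest_rank"), 15)
  expect_error(critical_gap(numeric()), "no event")
})

test_that("inclusion rules flag the documented failure modes", {
  eu_block <- rep(100, 120)
  ev_block <- rep(200, 12)
  good <- make_trace(c(eu_block, ev_block, eu_block))
  span_total <- 5 * length(good$sgc)
  full <- matrix(c(0, span_total), 1)
  starts_high <- make_trace(c(rep(150, 6), eu_block, ev_block, eu_block))
  gap60 <- c(eu_block, ev_block, eu_block)
  gap60[30:41] <- NA
  gappy <- make_trace(gap60)
  res <- apply_inclusion_rules(
    list(list(trace = good, dot_intervals = full),
         list(trace = starts_high, dot_intervals = full),
         list(trace = gappy, dot_intervals = full),
         list(trace = good, dot_intervals = matrix(c(0, 2), 1))),
    gap_min = 45, min_gap = 200)
  expect_equal(res$rule1, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(res$rule2, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(res$included, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("euglycemic spans are delimited and separated by the minimum gap", {
  eu120 <- rep(100, 120)  # 600 min
  ev12 <- rep(200, 12)    # 60 min
  tr <- make_trace(c(eu120, ev12, eu120))
  sp <- euglycemic_spans(tr, classify_events(tr), min_gap = 60)
  expect_equal(unname(sp$first), c(0, 600))
  expect_equal(unname(sp$last), c(660, 1255))
  expect_false(sp$adjusted)
  # same layout under the default 510-min separation: anticipated
  sp510 <- euglycemic_spans(tr, classify_events(tr))
  expect_true(sp510$adjusted)
  expect_equal(unname(sp510$first), c(0, 150))
  expect_gte(sp510$last[1] - sp510$first[2], 510)
  # event in the middle of a short trace forces anticipation
  tr2 <- make_trace(c(rep(100, 120), ev12, rep(100, 108)))
  sp2 <- euglycemic_spans(tr2, classify_events(tr2))
  expect_true(sp2$adjusted)
  expect_gte(sp2$last[1] - sp2$first[2], 510)
  expect_true(sp2$first[2] > sp2$first[1])
  # trace ending out of range: last span ends at last euglycemic sample
  tr3 <- make_trace(c(eu120, ev12, eu120, rep(200, 3)))
  sp3 <- euglycemic_spans(tr3, classify_events(tr3))
  expect_equal(unname(sp3$last[2]), 1255)
  expect_error(euglycemic_spans(make_trace(eu120), data.frame()),
               "no glycemic event")
})

test_that("spans never overlap events and respect the gap when feasible", {
  set.seed(7)
  for (i in 1:30) {
    n_eu <- sample(110:140, 2)
    ev_len <- sample(4:10, 1)
    v <- c(rep(100, n_eu[1]), rep(160, ev_len), rep(100, n_eu[2]))
    tr <- make_trace(v)
    ev <- classify_events(tr)
    sp <- euglycemic_spans(tr, ev)
    ev_start_min <- tr$t[ev$start_idx[1]]
    ev_end_min <- tr$t[ev$end_idx[nrow(ev)]]
    expect_lte(sp$first[2], ev_start_min)
    expect_gte(sp$last[1], ev_end_min + 5)
    if (!sp$adjusted) expect_gte(sp$last[1] - sp$first[2], 510)
  }
})

test_that("glucose metrics satisfy their closed forms and identities", {
  m <- glucose_metrics(make_trace(rep(100, 10)))
  expect_equal(unname(m[c("mean", "sd", "min", "max")]), c(100, 0, 100, 100))
  expect_equal(unname(m[c("tir", "tor", "tbr", "tar")]), c(100, 0, 0, 0))
  m2 <- glucose_metrics(make_trace(c(100, 100, 160, 160)))
  expect_equal(unname(m2[c("tir", "tar", "tbr", "mean")]), c(50, 50, 0, 130))
  # missing samples leave metrics unchanged
  v <- c(100, 100, 160, 160)
  m3 <- glucose_metrics(make_trace(c(v[1:2], NA, v[3:4], NA)))
  expect_equal(m3, m2)
  # identities on random traces
  set.seed(1)
  for (i in 1:50) {
    tr <- random_trace(60)
    if (sum(!tr$missing) < 2) next
    mm <- glucose_metrics(tr)
    expect_equal(unname(mm["tir"] + mm["tor"]), 100)
    expect_equal(unname(mm["tor"]), unname(mm["tbr"] + mm["tar"]))
    expect_lte(mm["min"], mm["mean"])
    expect_lte(mm["mean"], mm["max"])
  }
  expect_error(glucose_metrics(make_trace(c(NA, NA, NA, NA))), "present")
})
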