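test_that("default instrument loads, validates, and covers every section", {
  spec <- default_instrument()
  expect_s3_class(spec, "mhq_instrument")
  expect_setequal(unique(spec$items$section), mhq_sections())
  expect_gt(length(spec$rules), 0)
  # bundled YAML equals the in-code constructor
  path <- system.file("extdata", "mhq_default.yaml", package = "mhqtools")
  expect_equal(read_instrument(path), spec)
})

test_that("instrument validation rejects malformed specifications", {
  yn <- c(no = 0L, yes = 1L)
  items <- dplyr::bind_rows(
    mhq_item("a", "depression", "a", "single_choice", coding = yn),
    mhq_item("b", "depression", "b", "single_choice", coding = yn)
  )
  # linear questionnaire: zero rules is valid
  expect_s3_class(mhq_instrument(items, list()), "mhq_instrument")
  # dangling reference names the missing item
  expect_error(
    mhq_instrument(items, list(skip_rule("a", 1L, "X99"))),
    "X99"
  )
  # backward skipping violates instrument order
  expect_error(
    mhq_instrument(items, list(skip_rule("b", 1L, "a"))),
    "instrument order"
  )
  # self-trigger
  expect_error(
    mhq_instrument(items, list(skip_rule("a", 1L, c("a", "b")))),
    "triggers itself"
  )
  # duplicate ids
  expect_error(mhq_instrument(dplyr::bind_rows(items, items[1, ]), list()),
               "duplicate")
  # reserved codes cannot be substantive
  expect_error(
    mhq_item("c", "depression", "c", "single_choice",
             coding = c(no = 0L, pna = -818L)),
    "reserved"
  )
})

test_that("instrument files round-trip through write and read", {
  spec <- mini_instrument()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_instrument(spec, path)
  expect_equal(read_instrument(path), spec)
})

test_that("negative screens exclude detail items; positive screens include them", {
  spec <- default_instrument()
  detail <- c("dep_sym_anh", "dep_most_day", "dep_dur_weeks", "dep_impair")
  # both depression screens negative: detail excluded
  p <- presented_items(resp(dep_screen_mood = 0L, dep_screen_anh = 0L), spec)
  shown <- p$item_id[p$presented]
  expect_false(any(detail %in% shown))
  # first screen positive: second screen skipped, detail shown
  p2 <- presented_items(resp(dep_screen_mood = 1L), spec)
  shown2 <- p2$item_id[p2$presented]
  expect_true(all(detail %in% shown2))
  expect_false("dep_screen_anh" %in% shown2)
  # second screen positive after negative first: detail shown
  p3 <- presented_items(resp(dep_screen_mood = 0L, dep_screen_anh = 1L), spec)
  expect_true(all(detail %in% p3$item_id[p3$presented]))
  # never drinks: remaining alcohol items skipped
  p4 <- presented_items(resp(audit_1 = 0L), spec)
  expect_false(any(sprintf("audit_%d", 2:10) %in% p4$item_id[p4$presented]))
})

test_that("adding a triggering answer never enlarges the presented set", {
  spec <- mini_instrument()
  base <- presented_items(resp(g1 = 1L), spec)
  shown_base <- base$item_id[base$presented]
  for (ans in list(resp(g1 = 1L, s1 = 1L), resp(g1 = 0L),
                   resp(g1 = 2L, s1 = 0L, s2 = 0L))) {
    p <- presented_items(ans, spec)
    extra <- setdiff(p$item_id[p$presented], shown_base)
    expect_length(extra, 0)
  }
})

test_that("presented set agrees with exhaustive questionnaire-walk enumeration", {
  spec <- mini_instrument()
  walks <- enumerate_walks(spec)
  expect_gt(length(walks), 50)
  for (answers in walks) {
    responses <- answers_to_responses(spec, answers)
    p <- presented_items(responses, spec)
    expect_setequal(p$item_id[p$presented], oracle_walk(spec, answers))
  }
})

test_that("response validation flags illegal codes and answers inside skips", {
  spec <- mini_instrument()
  # clean record
  expect_identical(nrow(validate_responses(
    resp(s1 = 1L, d1 = 1L, d2 = 0L, g1 = 1L, e1 = 0L, z1 = 1L), spec)), 0L)
  # answered despite triggered skip
  v <- validate_responses(resp(s1 = 1L, s2 = 1L), spec)
  expect_identical(v$problem, "answered_in_skip")
  expect_identical(v$item_id, "s2")
  # out-of-range code names item and code
  v2 <- validate_responses(resp(z1 = 99L), spec)
  expect_identical(v2$problem, "illegal_code")
  expect_match(v2$detail, "99")
  expect_match(v2$detail, "z1")
  # generator output is always skip-consistent
  co <- default_cohort()
  expect_identical(nrow(validate_responses(co$responses, default_instrument())),
                   0L)
})

test_that("completion status distinguishes complete, partial and not started", {
  spec <- mini_instrument()
  all_ans <- resp(s1 = 0L, s2 = 0L, g1 = 1L, e1 = 1L, z1 = 0L)
  expect_identical(
    as.character(completion_status(all_ans, spec)$completion), "complete")
  # declining still counts as responding; a declined gate re-exposes its
  # detail block, which must then be answered for completeness
  with_decline <- resp(s1 = 0L, s2 = -818L, d1 = 0L, d2 = 0L, g1 = 1L,
                       e1 = -818L, z1 = 0L)
  expect_identical(
    as.character(completion_status(with_decline, spec)$completion), "complete")
  expect_identical(
    as.character(completion_status(resp(s1 = 1L), spec)$completion), "partial")
  empty <- resp(s1 = NA_integer_)
  expect_identical(
    as.character(completion_status(empty, spec)$completion), "not_started")
})

test_that("data dictionary lists every item plus the reserved sentinels", {
  dd <- data_dictionary(default_instrument())
  expect_true(all(default_instrument()$items$item_id %in% dd$item_id))
  expect_true(all(c(-818L, -121L) %in% dd$code))
})
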