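test_that("facet and design constructors validate their inputs", {
  expect_s3_class(gt_facet("trial"), "gt_facet")
  expect_error(gt_facet(""), "nzchar")
  expect_error(gt_design(), "at least one facet")
  expect_error(gt_design(gt_facet("trial", "fixed")), "at least one random facet")
  expect_error(gt_design(gt_facet("trial"), gt_facet("trial")), "duplicate facet")
  expect_error(gt_design(gt_facet("person")), "cannot also be a facet")
  expect_error(gt_design(gt_facet("trial", nested_in = "block")),
               "undeclared facet")
  expect_error(gt_design(gt_facet("trial", nested_in = "split"),
                         gt_facet("split", nested_in = "trial")),
               "cyclic nesting")
})

test_that("design layouts are classified from the facet structure", {
  expect_identical(one_facet_design()$layout, "one_facet")
  expect_identical(two_facet_design()$layout, "two_facet")
  expect_identical(splits_design()$layout, "splits")
  d4 <- gt_design(gt_facet("trial", "random", nested_in = "split"),
                  gt_facet("split", "random"), gt_facet("occasion", "random"))
  expect_identical(d4$layout, "splits_occasion")
  # a fixed facet does not change the random-structure layout
  dft <- gt_design(gt_facet("trial", "random"), gt_facet("task", "fixed"))
  expect_identical(dft$layout, "one_facet")
  expect_error(gt_design(gt_facet("occasion", "random")), "random 'trial' facet")
  expect_error(gt_design(gt_facet("trial", "random", nested_in = "occasion"),
                         gt_facet("occasion", "random")),
               "unsupported nesting")
})

test_that("ingest maps schemas, sniffs delimiters, and counts dropped rows", {
  for (sep in c(",", "\t")) {
    tab <- read_long_table(write_toy_csv(sep = sep))
    expect_s3_class(tab, "gt_table")
    expect_identical(nrow(tab), 6L)
    expect_identical(attr(tab, "dropped"), 0L)
  }
  # schema renaming
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(subj = c("A", "A", "B", "B"), trialnr = c(1, 2, 1, 2),
                       amp = c(1.5, 2.5, 3.5, NA)), path, row.names = FALSE)
  expect_message(
    tab <- read_long_table(path, schema = list(person = "subj", score = "amp",
                                               trial = "trialnr")),
    "1 row")
  expect_identical(names(tab), c("person", "score", "trial"))
  expect_identical(attr(tab, "dropped"), 1L)
  expect_identical(attr(tab, "n_read"), 4L)
  expect_error(read_long_table(path, schema = list(person = "nope", score = "amp")),
               "not present in file")
  expect_error(read_long_table(tempfile(), schema = list(person = "a", score = "b")),
               "file not found")
})

test_that("as_gt_table enforces structural invariants", {
  expect_error(as_gt_table(data.frame(person = "A", trial = 1)), "'person' and 'score'")
  expect_error(as_gt_table(data.frame(person = c("A", "A"), trial = c(1, 1),
                                      score = c(1, 2))),
               "duplicate")
  expect_error(as_gt_table(data.frame(person = "A", trial = 0, score = 1)),
               "positive integer")
  expect_error(as_gt_table(data.frame(person = "A", trial = 1, score = NA)),
               "no usable rows")
  # a trial index appearing in two splits of the same person is rejected
  bad <- data.frame(person = "A", trial = c(1, 1), split = c(1, 2), score = c(1, 2))
  expect_error(as_gt_table(bad), "nested within exactly one split")
})

test_that("round trip through write_long_table preserves the data", {
  tab <- toy_table()
  path <- tempfile(fileext = ".csv")
  write_long_table(tab, path)
  back <- read_long_table(path)
  expect_equal(as.data.frame(back)[c("person", "trial", "score")],
               as.data.frame(tab)[c("person", "trial", "score")])
})

test_that("validation flags identifiability, hidden facets, and unbalance", {
  tab <- toy_table()
  val <- validate_design(tab, one_facet_design())
  expect_true(val$balanced)
  expect_length(val$persons_missing_cells, 0)

  # single observed condition on a modeled facet is an error, not a warning
  one_cond <- as_gt_table(data.frame(person = c("A", "B"), trial = 1L,
                                     score = c(1, 2)))
  expect_error(validate_design(one_cond, one_facet_design()),
               "identifiability error")

  # declared hidden facets yield conditional-reliability warnings
  val_h <- validate_design(tab, one_facet_design(hidden = "session"))
  expect_match(val_h$hidden$session, "conditional")

  # unbalance: drop one observation
  unb <- as_gt_table(as.data.frame(tab)[-1, ])
  val_u <- validate_design(unb, one_facet_design())
  expect_false(val_u$balanced)
  expect_identical(val_u$persons_missing_cells, "A")
  # validation is pure: the table is not modified
  expect_identical(nrow(unb), 5L)

  expect_error(validate_design(tab, two_facet_design()), "not present in table")
})

test_that("crossed and nested balanced designs are both recognized as balanced", {
  # persons x trials x occasions, complete
  g <- expand.grid(person = c("A", "B"), trial = 1:3, occasion = c("o1", "o2"))
  g$score <- rnorm(nrow(g))
  expect_true(validate_design(as_gt_table(g), two_facet_design())$balanced)
  # trials nested in splits: the full trial x split cross never exists
  s <- expand.grid(person = c("A", "B"), trial = 1:4)
  s$split <- ifelse(s$trial <= 2, 1L, 2L)
  s$score <- rnorm(nrow(s))
  expect_true(validate_design(as_gt_table(s), splits_design())$balanced)
})

test_that("split convention groups consecutive trials identically across persons", {
  g <- expand.grid(person = c("A", "B"), trial = 1:10)
  g$score <- rnorm(nrow(g))
  tab <- as_gt_table(g)
  out <- enforce_split_convention(tab, 5)
  expect_identical(sort(unique(out$split)), c(1L, 2L))
  expect_identical(attr(out, "split_dropped"), 0L)
  # same trial -> same split for every person
  m <- tapply(out$split, list(out$person, out$trial), unique)
  expect_true(all(m["A", ] == m["B", ]))
  # trials 1..5 -> split 1
  expect_true(all(out$split[out$trial <= 5] == 1L))

  # 11 trials with splits of 5: the trailing trial is dropped and logged
  g2 <- data.frame(person = "A", trial = 1:11, score = rnorm(11))
  expect_message(out2 <- enforce_split_convention(as_gt_table(g2), 5),
                 "1 trailing trial")
  expect_identical(nrow(out2), 10L)
  expect_identical(attr(out2, "split_dropped"), 1L)

  # size 1 degenerates to one trial per split
  out3 <- enforce_split_convention(as_gt_table(g2), 1)
  expect_identical(out3$split, out3$trial)

  # split size exceeding a person's trial count names the person
  short <- as_gt_table(data.frame(person = c("A", "A", "B"), trial = c(1, 2, 1),
                                  score = 1:3))
  expect_error(enforce_split_convention(short, 2), "person B")

  expect_error(enforce_split_convention(as_gt_table(
    data.frame(person = "A", occasion = "o1", score = 1)), 2), "no 'trial' column")
})
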