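three_class_data <- function(fst = 0.15, n = 120, seed = 51) {
  simulate_structured_populations(
    rep(0.5, 43), fst = fst,
    sizes = c(afr = n, eas = n, oth = n),
    continents = c("Africa", "East Asia", "Other"),
    seed = seed
  )
}

test_that("stratified split partitions each class at the stated fraction", {
  ds <- three_class_data(n = 100)
  sp <- stratified_split(ds, 0.75, seed = 3)
  expect_equal(nrow(sp$train), 225L)
  expect_equal(nrow(sp$test), 75L)
  expect_equal(as.integer(table(sp$train$continent)), rep(75L, 3))

  # disjoint and exhaustive
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0L)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), ds$sample_id)

  # seeded determinism
  sp2 <- stratified_split(ds, 0.75, seed = 3)
  expect_identical(sp$train$sample_id, sp2$train$sample_id)

  solo <- ds[c(1, 121, 241), ]
  expect_error(stratified_split(solo, 0.75, seed = 1), "fewer than 2")
})

test_that("frequency classifier learns pseudocounted frequencies", {
  ds <- counts_genotypes(25, 50, 25, population = "p")
  ds$continent <- rep(c("A", "B"), length.out = nrow(ds))
  model <- train_frequency_classifier(ds)
  fr <- model$frequencies
  expect_true(all(fr$p_del > 0 & fr$p_del < 1))

  # symmetric counts: p near 0.5 with the half-count pseudocount
  ds2 <- counts_genotypes(25, 50, 25, population = "p")
  ds2$continent <- "A"
  ds2 <- dplyr::bind_rows(ds2, {
    x <- counts_genotypes(100, 0, 0, population = "p")
    x$continent <- "B"
    x
  })
  model2 <- train_frequency_classifier(ds2)
  fa <- model2$frequencies[model2$frequencies$class == "A", ]
  fb <- model2$frequencies[model2$frequencies$class == "B", ]
  expect_equal(fa$p_del, 100.5 / 201)
  expect_equal(fb$p_del, 200.5 / 201)  # fixation kept strictly below 1

  # learned frequencies track the generating subpopulation frequencies
  ds3 <- three_class_data(seed = 77)
  truth <- attr(ds3, "true_frequencies")
  model3 <- train_frequency_classifier(ds3)
  fr3 <- dplyr::inner_join(
    model3$frequencies,
    dplyr::mutate(truth, class = c(afr = "Africa", eas = "East Asia",
                                   oth = "Other")[population]),
    by = c("class", "locus"), suffix = c("_hat", "_true")
  )
  se <- sqrt(fr3$p_del_true * (1 - fr3$p_del_true) / (2 * 120))
  frac_in <- mean(abs(fr3$p_del_hat - fr3$p_del_true) < 3 * pmax(se, 0.01))
  expect_gt(frac_in, 0.95)
})

test_that("classifier decisions follow the likelihood", {
  # mirrored class frequencies: an all-DD individual goes to the high-p class
  train <- dplyr::bind_rows(
    {
      x <- counts_genotypes(90, 9, 1, locus = "l1", population = "hi")
      x$continent <- "hi"; x
    },
    {
      x <- counts_genotypes(1, 9, 90, locus = "l1", population = "lo")
      x$continent <- "lo"; x
    }
  )
  model <- train_frequency_classifier(train)
  probe <- tibble::tibble(
    sample_id = "q", population = "q", continent = NA_character_, l1 = "DD"
  )
  pred <- predict(model, probe)
  expect_equal(pred$predicted, "hi")
  expect_gt(pred$post_hi, 0.5)

  # identical class frequencies: uniform posteriors
  train_eq <- dplyr::bind_rows(
    {
      x <- counts_genotypes(25, 50, 25, locus = "l1", population = "a")
      x$continent <- "a"; x
    },
    {
      x <- counts_genotypes(25, 50, 25, locus = "l1", population = "b")
      x$continent <- "b"; x
    }
  )
  m_eq <- train_frequency_classifier(train_eq)
  pr_eq <- predict(m_eq, probe)
  expect_equal(pr_eq$post_a, 0.5, tolerance = 1e-12)

  # all-missing individual yields a flagged no-call
  probe_na <- probe
  probe_na$l1 <- NA_character_
  pr_na <- predict(m_eq, probe_na)
  expect_true(is.na(pr_na$predicted))
  expect_equal(pr_na$n_loci_used, 0L)
})

test_that("synthetic three-class benchmark reaches field-typical accuracy", {
  ds <- three_class_data(fst = 0.15, n = 120, seed = 91)
  sp <- stratified_split(ds, 0.75, seed = 92)
  model <- train_frequency_classifier(sp$train)
  pred <- predict(model, sp$test)
  ev <- evaluate_assignments(sp$test$continent, pred$predicted,
                             labels = model$classes)
  expect_gt(ev$accuracy, 0.80)
  expect_true(ev$ci_low <= ev$accuracy && ev$accuracy <= ev$ci_high)
})

test_that("accuracy rises with divergence and collapses to the prior at F = 0", {
  accs <- vapply(c(0.01, 0.05, 0.15), function(f) {
    ds <- three_class_data(fst = f, n = 120, seed = 101)
    sp <- stratified_split(ds, 0.75, seed = 102)
    model <- train_frequency_classifier(sp$train)
    pred <- predict(model, sp$test)
    evaluate_assignments(sp$test$continent, pred$predicted,
                         labels = model$classes)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) > 0))

  # (near) zero divergence: accuracy near the largest class prior (1/3)
  ds0 <- three_class_data(fst = 1e-4, n = 350, seed = 103)
  sp0 <- stratified_split(ds0, 0.75, seed = 104)
  m0 <- train_frequency_classifier(sp0$train)
  p0 <- predict(m0, sp0$test)
  acc0 <- evaluate_assignments(sp0$test$continent, p0$predicted,
                               labels = m0$classes)$accuracy
  expect_lt(abs(acc0 - 1 / 3), 0.05 + 2 * sqrt(1 / 3 * 2 / 3 / nrow(sp0$test)))
})

test_that("evaluation reproduces published confusion-matrix summaries", {
  # three-class ancestry test-set matrices of a 43-locus DIP panel study
  xgb <- matrix(
    c(152, 12, 6,
      9, 402, 82,
      4, 58, 246),
    nrow = 3, byrow = TRUE,
    dimnames = list(
      prediction = c("Africa", "East Asia", "Other"),
      truth = c("Africa", "East Asia", "Other")
    )
  )
  ev <- confusion_eval(xgb)
  expect_equal(round_half_up(ev$accuracy), 0.8239)
  expect_equal(round_half_up(ev$ci_low), 0.7984)
  expect_equal(round_half_up(ev$ci_high), 0.8474)
  expect_equal(ev$n, 971L)

  rf <- matrix(
    c(145, 4, 3,
      16, 416, 103,
      4, 52, 228),
    nrow = 3, byrow = TRUE
  )
  expect_equal(round_half_up(confusion_eval(rf)$accuracy), 0.8126)

  # accuracy = trace/total and degenerate all-correct case
  ev_perfect <- evaluate_assignments(c("a", "b"), c("a", "b"))
  expect_equal(ev_perfect$accuracy, 1)
  expect_equal(ev_perfect$ci_high, 1)

  expect_error(
    evaluate_assignments(c("a", "b"), c("a", "z"), labels = c("a", "b")),
    "label"
  )
})

test_that("Clopper-Pearson bounds satisfy the exact binomial definitions", {
  for (case in list(c(8, 10), c(800, 971), c(1, 50), c(49, 50))) {
    x <- case[1]; n <- case[2]
    tab <- matrix(c(x, 0, n - x, 0), 2)
    ev <- confusion_eval(tab)
    # inversion: at the bounds the tail probabilities equal alpha/2
    expect_equal(1 - stats::pbinom(x - 1, n, ev$ci_low), 0.025, tolerance = 1e-6)
    expect_equal(stats::pbinom(x, n, ev$ci_high), 0.025, tolerance = 1e-6)
  }
})

test_that("tidiers and plots expose the evaluation surface", {
  ev <- evaluate_assignments(
    c("a", "a", "b", "b"), c("a", "b", "b", "b")
  )
  td <- tidy(ev)
  expect_equal(sum(td$count), 4L)
  gl <- glance(ev)
  expect_equal(gl$accuracy, 0.75)
  expect_s3_class(autoplot(ev), "ggplot")

  st <- run_lr_study(rep(0.5, 10), n_pairs = 50, seed = 2)
  expect_s3_class(autoplot(st), "ggplot")
})
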