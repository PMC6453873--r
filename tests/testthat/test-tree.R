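test_that("a pool of one marker is returned as-is", {
  set.seed(51)
  df <- two_class_frame(list(a = rnorm(60)), rep(c(TRUE, FALSE), 30))
  df$a <- df$a + (df$group == "T1D")
  sel <- forward_select_markers(df, "T1D", "a")
  expect_equal(sel$markers, "a")
})

test_that("a perfectly separating marker is selected alone; noise markers are not added", {
  set.seed(52)
  y <- rep(c(TRUE, FALSE), c(40, 60))
  df <- two_class_frame(list(
    a = ifelse(y, rnorm(100, 10), rnorm(100, 0)),  # perfect separation
    b = rnorm(100), c = rnorm(100)
  ), y)
  sel <- suppressWarnings(forward_select_markers(df, "T1D", c("a", "b", "c")))
  expect_equal(sel$markers, "a")
  expect_equal(sel$auc$auc, 1.0)
})

test_that("two complementary informative markers are both selected, strongest first", {
  set.seed(53)
  n <- 400
  y <- rep(c(TRUE, FALSE), each = n / 2)
  ## negatively correlated noise makes the pair much stronger than either alone
  z1 <- rnorm(n); z2 <- -0.5 * z1 + sqrt(0.75) * rnorm(n)
  df <- two_class_frame(list(a = 1.05 * y + z1, b = 0.95 * y + z2,
                             junk = rnorm(n)), y)
  sel <- forward_select_markers(df, "T1D", c("a", "b", "junk"))
  expect_true(all(c("a", "b") %in% sel$markers))
  expect_equal(sel$markers[1], "a")
  expect_false("junk" %in% sel$markers)
  auc_single <- c_statistic(df$a[y], df$a[!y])$auc
  expect_gt(sel$auc$auc, auc_single)
})

test_that("a perfectly separable group becomes step 1 with C-statistic 1", {
  set.seed(54)
  n <- 36
  df <- data.frame(
    id = sprintf("r%02d", 1:n),
    group = rep(c("T1D", "HNF1A", "GCK"), each = 12),
    m1 = c(rnorm(12, 20), rnorm(12, 0), rnorm(12, 1)),
    m2 = rnorm(n)
  )
  tr <- suppressWarnings(build_tree(df, pool = c("m1", "m2")))
  expect_equal(tr$steps[[1]]$target_group, "T1D")
  expect_equal(tr$steps[[1]]$auc$auc, 1.0)
})

test_that("tree building is invariant to record order and pool order", {
  co <- simulate_cohort(simulation_config(
    group_sizes = c(HNF1A = 40, GCK = 40, T1D = 40, T2D = 40), seed = 55
  ))
  tr1 <- suppressWarnings(build_tree(co))
  set.seed(1)
  shuffled <- co[sample(nrow(co)), ]
  tr2 <- suppressWarnings(build_tree(shuffled, pool = rev(default_marker_pool())))
  for (k in seq_along(tr1$steps)) {
    expect_equal(tr1$steps[[k]]$target_group, tr2$steps[[k]]$target_group)
    expect_equal(tr1$steps[[k]]$index$markers, tr2$steps[[k]]$index$markers)
    expect_equal(tr1$steps[[k]]$index$weights, tr2$steps[[k]]$index$weights)
    expect_equal(tr1$steps[[k]]$threshold, tr2$steps[[k]]$threshold)
  }
})

test_that("group peeling: a targeted group's records do not influence later steps", {
  co <- simulate_cohort(simulation_config(
    group_sizes = c(HNF1A = 50, GCK = 50, T1D = 50, T2D = 50), seed = 56
  ))
  full <- suppressWarnings(build_tree(co))
  peeled_group <- full$steps[[1]]$target_group
  rest <- co[co$group != peeled_group, ]
  rederived <- suppressWarnings(build_tree(rest))
  expect_equal(length(rederived$steps), length(full$steps) - 1)
  for (k in seq_along(rederived$steps)) {
    expect_equal(rederived$steps[[k]]$target_group, full$steps[[k + 1]]$target_group)
    expect_equal(rederived$steps[[k]]$index$weights, full$steps[[k + 1]]$index$weights)
    expect_equal(rederived$steps[[k]]$threshold, full$steps[[k + 1]]$threshold)
  }
})

test_that("default synthetic cohort recovers the published tree structure", {
  co <- simulate_cohort(simulation_config(seed = 57))
  tr <- suppressWarnings(build_tree(co))
  expect_equal(tr$steps[[1]]$target_group, "T1D")
  expect_equal(tr$steps[[1]]$index$markers, "c_peptide")
  expect_equal(tr$steps[[2]]$target_group, "T2D")
  expect_true(all(c("c_peptide", "bmi") %in% tr$steps[[2]]$index$markers))
  expect_setequal(tr$terminal_pair, c("HNF1A", "GCK"))
  expect_true("ag15" %in% tr$steps[[3]]$index$markers)
})

test_that("fewer than 10 records in a live group aborts the build", {
  co <- simulate_cohort(simulation_config(
    group_sizes = c(HNF1A = 30, GCK = 5, T1D = 30, T2D = 30), seed = 58
  ))
  expect_error(suppressWarnings(build_tree(co)), "small-sample.*GCK")
})

test_that("every retained addition strictly increases the step C-statistic", {
  co <- simulate_cohort(simulation_config(seed = 59))
  df <- as.data.frame(co)
  df <- df[df$group %in% c("HNF1A", "GCK", "T2D"), ]
  sel <- suppressWarnings(forward_select_markers(df, "T2D", default_marker_pool()))
  if (length(sel$markers) > 1) {
    lead <- sel$markers[1]
    y <- df$group == "T2D"
    single <- max(c_statistic(df[[lead]][y], df[[lead]][!y])$auc,
                  1 - c_statistic(df[[lead]][y], df[[lead]][!y])$auc)
    expect_gt(sel$auc$auc, single)
  }
  expect_gt(length(sel$markers), 1)  # bmi + c_peptide are jointly informative here
})

test_that("trees round-trip through JSON and the shipped published tree matches", {
  co <- simulate_cohort(simulation_config(
    group_sizes = c(HNF1A = 40, GCK = 40, T1D = 40, T2D = 40), seed = 60
  ))
  tr <- suppressWarnings(build_tree(co))
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tr, path)
  back <- read_tree(path)
  for (k in seq_along(tr$steps)) {
    expect_equal(back$steps[[k]]$target_group, tr$steps[[k]]$target_group)
    expect_equal(back$steps[[k]]$index$markers, tr$steps[[k]]$index$markers)
    expect_equal(back$steps[[k]]$index$weights, tr$steps[[k]]$index$weights)
    expect_equal(back$steps[[k]]$threshold, tr$steps[[k]]$threshold)
    expect_equal(back$steps[[k]]$auc$auc, tr$steps[[k]]$auc$auc)
  }
  expect_equal(back$terminal_pair, tr$terminal_pair)

  shipped <- read_tree(system.file("extdata", "published_tree.json",
                                   package = "modytree"))
  ref <- published_tree()
  for (k in 1:3) {
    expect_equal(shipped$steps[[k]]$index$markers, ref$steps[[k]]$index$markers)
    expect_equal(shipped$steps[[k]]$index$weights, ref$steps[[k]]$index$weights)
    expect_equal(shipped$steps[[k]]$threshold, ref$steps[[k]]$threshold)
    expect_equal(shipped$steps[[k]]$direction, ref$steps[[k]]$direction)
  }
})
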