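test_that("Spearman matrix is symmetric with unit diagonal and exact limits", {
  x <- c(1, 3, 5, 7, 11)
  m <- spearman_matrix(tibble::tibble(a = x, b = x^2, c = rev(x)))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], 1)    # monotone increasing
  expect_equal(m["a", "c"], -1)   # rank reversal
  expect_equal(unclass(m)[lower.tri(m)], t(unclass(m))[lower.tri(m)])
})

test_that("equicorrelated outcomes show the planted correlation", {
  gn <- generate_global_null(n = 250, k = 5, correlation = 0.64, seed = 99)
  m <- spearman_matrix(gn[, -(1:2)])
  off <- unclass(m)[upper.tri(m)]
  # Spearman of a bivariate normal with rho = 0.64 is (6/pi) asin(rho/2)
  expect_lt(abs(mean(off) - 6 / pi * asin(0.64 / 2)), 0.06)
})

test_that("sparse outcome pairs are flagged as missing", {
  d <- tibble::tibble(a = c(1, 2, 3, 4, NA, NA, NA, NA),
                      b = c(NA, NA, NA, NA, 4, 3, 2, 1),
                      c = 1:8)
  expect_warning(m <- spearman_matrix(d), "fewer than 3")
  expect_true(is.na(m["a", "b"]))
  expect_false(is.na(m["a", "c"]))
})

test_that("complete-linkage ordering groups separated clouds and matches hand agglomeration", {
  pts <- rbind(matrix(rnorm(8, 0, 0.1), 4), matrix(rnorm(8, 10, 0.1), 4))
  ord <- hierarchical_order(pts)$leaf_order
  expect_true(all(diff(match(1:4, ord)) %in% c(-1, 1)) ||
                all(sort(match(1:4, ord)) %in% 1:4 |
                      sort(match(1:4, ord)) %in% 5:8))
  first_cloud <- sort(match(1:4, ord))
  expect_true(identical(first_cloud, 1:4) || identical(first_cloud, 5:8))

  # three 1-d points: merge (0,1) at height 1, then with 10 at height 10
  hc <- hierarchical_order(matrix(c(0, 1, 10), ncol = 1))$hclust
  expect_equal(hc$height, c(1, 10))
  expect_equal(sort(abs(hc$merge[1, ])), c(1, 2))

  same <- hierarchical_order(matrix(1, nrow = 3, ncol = 2))
  expect_equal(same$hclust$height, c(0, 0))

  one <- hierarchical_order(matrix(1:2, nrow = 1))
  expect_equal(one$leaf_order, 1)
})

test_that("clustering mean-imputes missing cells and records the count", {
  m <- matrix(rnorm(20), 5, 4)
  m[2, 3] <- NA
  ord <- hierarchical_order(m)
  expect_equal(ord$n_imputed, 1L)
  expect_equal(length(ord$leaf_order), 5)
})

test_that("lasagna plots expose cell structure and honour the cluster flag", {
  g <- small_cohort(n = 10, q = 2, seed = 60, dropout_probs = rep(0, 4))
  d <- as_tibble(g)
  d$symptom_01[3] <- NA
  d <- validate_roles(d, roles_of(g))
  p <- plot_lasagna(d, "symptom_01", cluster_subjects = FALSE)
  cells <- ggplot2::layer_data(p)
  expect_equal(nrow(cells), 10 * 4)
  expect_gte(sum(is.na(ggplot2::layer_data(p)$fill)) +
               sum(ggplot2::layer_data(p)$fill == "white"), 1)
  expect_equal(attr(p, "subject_order"), sprintf("S%03d", 1:10))

  pc <- plot_lasagna(d, "symptom_01", cluster_subjects = TRUE)
  wide <- tidyr::pivot_wider(as_tibble(d)[c("subject", "occasion", "symptom_01")],
                             names_from = "occasion",
                             values_from = "symptom_01")
  ord <- hierarchical_order(as.matrix(wide[-1]),
                            labels = wide$subject)$leaf_order
  expect_equal(attr(pc, "subject_order"), wide$subject[ord])
})

test_that("spaghetti subsetting is seeded and bounded", {
  g <- small_cohort(n = 25, q = 1, seed = 8)
  p1 <- plot_spaghetti(g, "symptom_01", subset_size = 10, seed = 5)
  p2 <- plot_spaghetti(g, "symptom_01", subset_size = 10, seed = 5)
  expect_length(attr(p1, "subjects"), 10)
  expect_identical(attr(p1, "subjects"), attr(p2, "subjects"))
  expect_message(plot_spaghetti(g, "symptom_01", subset_size = 100),
                 "showing all")
  one <- generate_em_like(sim_config(n_subjects = 1, n_outcomes = 1),
                          seed = 1)
  expect_s3_class(plot_spaghetti(one, "symptom_01"), "ggplot")
})

test_that("boxplot facet modes transpose the layout", {
  g <- small_cohort(n = 12, q = 3, seed = 71)
  p1 <- plot_boxplots(g, facet_mode = "outcome_by_occasion")
  p2 <- plot_boxplots(g, facet_mode = "occasion_by_outcome")
  b1 <- ggplot2::ggplot_build(p1)
  b2 <- ggplot2::ggplot_build(p2)
  expect_equal(length(unique(b1$layout$layout$PANEL)), 3)
  expect_equal(length(unique(b2$layout$layout$PANEL)), 4)
})

test_that("timeline bubbles sit at the scheduled days and skip zero values", {
  g <- small_cohort(n = 8, q = 2, seed = 90, dropout_probs = rep(0, 4))
  p <- plot_timeline(g, x_axis = "days_since_first")
  dat <- ggplot2::layer_data(p)
  expect_true(all(dat$x %in% c(0, 14, 180, 365)))
  d <- as_tibble(add_days_since_first(g))
  n_positive <- sum(d$symptom_01 > 0, na.rm = TRUE) +
    sum(d$symptom_02 > 0, na.rm = TRUE)
  expect_equal(nrow(dat), n_positive)
})

test_that("the clustered heat map pulls a planted severe block together", {
  base <- matrix(rnorm(40, 1, 0.3), 10, 4)
  base[4:6, ] <- base[4:6, ] + 8   # planted block of severe subjects
  d <- tibble::tibble(
    subject = sprintf("P%02d", 1:10),
    date = as.Date("2020-01-01"),
    occasion = "0")
  d <- cbind(d, stats::setNames(as.data.frame(base), paste0("s", 1:4)))
  v <- validate_roles(d, var_roles(id = "subject", date = "date",
                                   occasion = "occasion",
                                   outcomes = paste0("s", 1:4)))
  p <- plot_heatmap(v, "0")
  ord <- attr(p, "subject_order")
  pos <- sort(match(sprintf("P%02d", 4:6), ord))
  expect_equal(diff(pos), c(1, 1))
  expect_length(attr(p, "outcome_order"), 4)
})

test_that("every plot kind renders to raster and vector files", {
  g <- small_cohort(n = 8, q = 3, seed = 33)
  plots <- list(
    box = plot_boxplots(g),
    spaghetti = plot_spaghetti(g, "symptom_01"),
    lasagna = plot_lasagna(g, "symptom_01"),
    timeline = plot_timeline(g),
    corr = autoplot(spearman_matrix(g, occasion = "0")),
    heatmap = plot_heatmap(g, "0"),
    dendrogram = {
      d0 <- as_tibble(at_occasion(g, "0"))
      autoplot(hierarchical_order(t(as.matrix(d0[roles_of(g)$outcomes])),
                                  labels = roles_of(g)$outcomes))
    },
    bar = plot_bars(g),
    summary = autoplot(summarize_outcomes(g, binary = TRUE)))
  dir <- withr::local_tempdir()
  for (nm in names(plots)) {
    files <- write_figure(plots[[nm]], file.path(dir, nm),
                          formats = c("png", "eps"))
    expect_true(all(file.exists(files)), info = nm)
    expect_true(all(file.size(files) > 0), info = nm)
  }
  expect_error(write_figure(plots$box, file.path(dir, "x"), formats = "bmp"),
               class = "longmed_usage_error")
})
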