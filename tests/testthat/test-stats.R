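make_neuron_table <- function(rates_by_rat, group = "vehicle", day = 2) {
  dplyr::bind_rows(lapply(names(rates_by_rat), function(r) {
    tibble::tibble(rat_id = r, group = group, day = day,
                   firing_rate = rates_by_rat[[r]])
  }))
}

rat_values_table <- function(values_by_group, day = 2) {
  # one neuron per rat: per-rat mean equals the supplied value
  out <- dplyr::bind_rows(lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    tibble::tibble(rat_id = paste0(g, "_", seq_along(v)), group = g,
                   day = day, firing_rate = v)
  }))
  aggregate_to_rats(out)
}

test_that("aggregation averages a rat's neurons and is one row per cell", {
  tab <- aggregate_to_rats(make_neuron_table(list(r1 = c(2, 4, 6), r2 = 5)))
  expect_s3_class(tab, "rat_table")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$firing_rate[tab$rat_id == "r1"], 4)
  expect_equal(tab$firing_rate[tab$rat_id == "r2"], 5)
  expect_equal(tab$n_neurons, c(3L, 1L))
  expect_error(aggregate_to_rats(tibble::tibble(rat_id = NA, group = "g",
                                                day = 2, firing_rate = 1)),
               "rat_id")
})

test_that("two-stage group means equal a brute-force nested mean", {
  withr::with_seed(13, {
    rats <- paste0("r", 1:8)
    tabs <- lapply(rats, function(r) {
      tibble::tibble(rat_id = r, group = "combination", day = 14,
                     firing_rate = rnorm(sample(3:10, 1), 4, 1))
    })
    per_neuron <- dplyr::bind_rows(tabs)
    agg <- aggregate_to_rats(per_neuron)
    brute <- mean(vapply(split(per_neuron$firing_rate, per_neuron$rat_id), mean,
                         numeric(1)))
    expect_equal(mean(agg$firing_rate), brute)
  })
})

test_that("within-rat factors survive aggregation for repeated measures", {
  per_obs <- tibble::tibble(
    rat_id = rep(c("r1", "r2"), each = 4),
    group = "vehicle", day = 2,
    freq = rep(c(1, 1, 5, 5), 2),
    dos_ms = c(50, 54, 36, 38, 48, 52, 34, 36))
  tab <- aggregate_to_rats(per_obs, within = "freq")
  expect_equal(nrow(tab), 4)  # 2 rats x 2 frequencies
  expect_equal(tab$dos_ms[tab$rat_id == "r1" & tab$freq == 1], 52)
  expect_equal(tab$dos_ms[tab$rat_id == "r2" & tab$freq == 5], 35)
})

test_that("tests refuse disaggregated per-neuron data", {
  per_neuron <- make_neuron_table(list(r1 = c(2, 4), r2 = c(3, 5)))
  expect_error(compare_groups(per_neuron, "firing_rate", "two_sample_t"),
               "aggregate")
})

test_that("degenerate inputs give the expected null statistics", {
  tab <- rat_values_table(list(vehicle = c(3, 4, 5), combination = c(3, 4, 5)))
  tt <- compare_groups(tab, "firing_rate", "two_sample_t")
  expect_equal(tt$statistic, 0)
  expect_gt(tt$p_value, 0.99)

  # identical group distributions: between-group sum of squares is zero
  tab0 <- rat_values_table(list(a = c(3, 4, 5), b = c(3, 4, 5), c = c(3, 4, 5)))
  an <- compare_groups(tab0, "firing_rate", "oneway_anova_bonferroni")
  expect_equal(an$statistic, 0, tolerance = 1e-10)
})

test_that("cells with fewer than two rats are refused by name", {
  tab <- rat_values_table(list(vehicle = c(3, 4, 5), combination = 4))
  expect_error(compare_groups(tab, "firing_rate", "two_sample_t"), "combination")
})

test_that("Holm-Sidak step-down adjustment has the textbook form", {
  p <- c(0.01, 0.04, 0.03)
  adj <- ephystat:::holm_sidak_adjust(p)
  # sorted: 0.01, 0.03, 0.04 with multipliers 3, 2, 1 -> 1-(1-p)^m, cummax
  expect_equal(adj[1], 1 - (1 - 0.01)^3)
  expect_equal(adj[3], max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2))
  expect_equal(adj[2], max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2, 0.04))
  withr::with_seed(4, {
    p5 <- runif(5)
    adj5 <- ephystat:::holm_sidak_adjust(p5)
    expect_true(all(diff(adj5[order(p5)]) >= 0))  # step-down monotonicity
    expect_true(all(adj5 >= p5 & adj5 <= 1))
  })
})

test_that("one-way ANOVA through the pipeline matches stats::aov directly", {
  withr::with_seed(31, {
    tab <- rat_values_table(list(vehicle = rnorm(6, 4), venlafaxine = rnorm(6, 3),
                                 combination = rnorm(6, 4.5)))
  })
  res <- compare_groups(tab, "firing_rate", "oneway_anova_bonferroni")
  ref <- anova(aov(firing_rate ~ group, data = as.data.frame(tab)))
  expect_equal(res$statistic, ref[["F value"]][1])
  expect_equal(res$p_value, ref[["Pr(>F)"]][1])
  expect_equal(res$df, ref$Df)
  expect_equal(nrow(res$posthoc), 3)
})

test_that("two-way repeated-measures design reports all three terms", {
  withr::with_seed(77, {
    rats <- expand.grid(rat = paste0("r", 1:12), day = c(2, 14))
    rats$group <- ifelse(as.integer(sub("r", "", rats$rat)) <= 6,
                         "vehicle", "combination")
    per_neuron <- tibble::tibble(rat_id = as.character(rats$rat),
                                 group = rats$group, day = rats$day,
                                 firing_rate = rnorm(nrow(rats), 4) +
                                   ifelse(rats$group == "combination", 1, 0))
  })
  tab <- aggregate_to_rats(per_neuron)
  res <- compare_groups(tab, "firing_rate", "twoway_rm_anova_holm_sidak",
                        factor2 = "day")
  expect_equal(res$terms$term, c("group", "day", "group:day"))
  expect_true(all(is.finite(res$terms$F)))
  expect_equal(res$posthoc$method[1], "holm_sidak")
})

test_that("vehicle-day pooling is explicit and collapses the control cells", {
  withr::with_seed(8, {
    per_neuron <- dplyr::bind_rows(
      tibble::tibble(rat_id = paste0("v2_", 1:4), group = "vehicle", day = 2,
                     firing_rate = rnorm(4, 4)),
      tibble::tibble(rat_id = paste0("v14_", 1:4), group = "vehicle", day = 14,
                     firing_rate = rnorm(4, 4)),
      tibble::tibble(rat_id = paste0("c_", 1:4), group = "combination", day = 14,
                     firing_rate = rnorm(4, 5))
    )
  })
  tab <- aggregate_to_rats(per_neuron)
  res <- compare_groups(tab, "firing_rate", "two_sample_t",
                        pool_vehicle_days = TRUE)
  expect_equal(sum(res$n_per_cell$Freq), 12)
  expect_equal(res$n_per_cell$Freq[res$n_per_cell$group == "vehicle"], 8)
})

test_that("type-I error of the pipeline ANOVA is calibrated at alpha", {
  # moderate replicate count here; the full calibration lives in acceptance
  withr::with_seed(202, {
    rej <- mean(vapply(1:400, function(i) {
      tab <- rat_values_table(list(a = rnorm(6), b = rnorm(6), c = rnorm(6)))
      compare_groups(tab, "firing_rate", "oneway_anova_bonferroni")$p_value < 0.05
    }, logical(1)))
  })
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("pipeline power matches the closed-form noncentral-F oracle", {
  withr::with_seed(303, {
    rej <- mean(vapply(1:400, function(i) {
      tab <- rat_values_table(list(a = rnorm(6), b = rnorm(6), c = rnorm(6, 2)))
      compare_groups(tab, "firing_rate", "oneway_anova_bonferroni")$p_value < 0.05
    }, logical(1)))
  })
  expect_lt(abs(rej - anova_power_exact(c(0, 0, 2), 6, 1)), 0.05)
})
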