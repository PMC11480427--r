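#' Aggregate per-neuron metrics to one row per rat
#'
#' The unit of statistical analysis is the rat, never the neuron: all metric
#' columns are averaged within each `(rat_id, group, day)` cell before any
#' test is run, mirroring standard practice for nested electrophysiology
#' designs. The returned table carries class `rat_table`; [compare_groups()]
#' only accepts that class, so running a test on disaggregated per-neuron
#' data is structurally impossible through the public interface.
#'
#' @param per_neuron A data frame with columns `rat_id`, `group`, `day`
#'   (and optionally `neuron_id`) plus one or more numeric metric columns.
#' @param within Optional extra grouping columns kept as within-rat factors
#'   (e.g. stimulation frequency or cumulative dose for repeated-measures
#'   designs); per-rat averaging then happens inside each level.
#' @return A tibble of class `rat_table` with one row per `(rat_id, group,
#'   day)` (times any `within` levels), per-rat means of every metric, and
#'   an `n_neurons` column. Neuron and rat counts are reported via
#'   `attr(, "counts")`.
#' @export
aggregate_to_rats <- function(per_neuron, within = character()) {
  per_neuron <- tibble::as_tibble(per_neuron)
  for (col in c("rat_id", "group", "day", within)) {
    if (!col %in% names(per_neuron)) stop("missing column: ", col, call. = FALSE)
  }
  if (anyNA(per_neuron$rat_id)) stop("neuron rows with missing rat_id", call. = FALSE)
  metric_cols <- setdiff(names(per_neuron)[vapply(per_neuron, is.numeric, logical(1))],
                         c("day", "neuron_id", within))
  out <- dplyr::summarise(
    dplyr::group_by(per_neuron,
                    dplyr::across(dplyr::all_of(c("rat_id", "group", "day", within)))),
    n_neurons = dplyr::n(),
    dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  attr(out, "counts") <- dplyr::count(out, .data$group, .data$day, name = "n_rats")
  class(out) <- c("rat_table", class(out))
  out
}

# Holm-Sidak step-down adjustment: order p ascending, adjust the i-th as
# 1 - (1 - p_(i))^(m - i + 1), then enforce monotonicity by running max.
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

pairwise_posthoc <- function(values, groups, method = c("bonferroni", "holm_sidak")) {
  method <- match.arg(method)
  lev <- unique(as.character(groups))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  raw <- vapply(pairs, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    # degenerate cells (zero variance in both groups): p = 1 if means equal
    tryCatch(stats::t.test(a, b)$p.value,
             error = function(e) if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_)
  }, numeric(1))
  adj <- switch(method,
                bonferroni = stats::p.adjust(raw, "bonferroni"),
                holm_sidak = holm_sidak_adjust(raw))
  tibble::tibble(
    comparison = vapply(pairs, paste, character(1), collapse = " vs "),
    p_raw = raw, p_adj = adj, method = method
  )
}

check_cells <- function(df, cells) {
  counts <- base::table(cells)
  bad <- names(counts)[counts < 2]
  if (length(bad)) {
    stop("fewer than 2 rats in cell(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Group comparisons on per-rat values
#'
#' The statistical comparison layer of the pipeline. All designs operate on
#' per-rat means only (the input must be an [aggregate_to_rats()] table);
#' the underlying tests are delegated to the standard routines
#' (`t.test`, `wilcox.test`, `aov`), while this layer owns design dispatch,
#' the Bonferroni and Holm-Sidak post-hoc families and cell-size checks.
#'
#' Designs: `two_sample_t` (Welch), `mann_whitney`,
#' `oneway_anova_bonferroni` (one-way ANOVA on `group`, Bonferroni-adjusted
#' pairwise t post hoc), `twoway_anova` (crossed fixed factors `group` x
#' `factor2`), and `twoway_rm_anova_holm_sidak` (repeated measures on
#' `factor2` within rat, treatment as the between factor, Holm-Sidak
#' post hoc on group).
#'
#' @param table A `rat_table` from [aggregate_to_rats()].
#' @param metric Name of the metric column to analyse.
#' @param design One of the designs above.
#' @param factor2 Second factor column for the two-way designs
#'   (default `"day"`).
#' @param pool_vehicle_days If `TRUE`, vehicle rows from both days are
#'   relabelled to a single pooled control cell before testing (an explicit
#'   analysis choice, applied only when a pre-test shows the two vehicle
#'   groups do not differ; never automatic).
#' @param alpha Significance level recorded in the report (default 0.05).
#' @return A list of class `group_comparison`: `design`, `metric`,
#'   `statistic`, `df`, `p_value`, `terms` (for ANOVA designs, a tibble of
#'   all terms), `posthoc` (tibble or `NULL`), `n_per_cell`.
#' @export
compare_groups <- function(table, metric,
                           design = c("two_sample_t", "mann_whitney",
                                      "oneway_anova_bonferroni", "twoway_anova",
                                      "twoway_rm_anova_holm_sidak"),
                           factor2 = "day", pool_vehicle_days = FALSE,
                           alpha = 0.05) {
  design <- match.arg(design)
  if (!inherits(table, "rat_table")) {
    stop("compare_groups() requires a rat-aggregated table from aggregate_to_rats(); ",
         "per-neuron data must be aggregated first", call. = FALSE)
  }
  if (!metric %in% names(table)) stop("unknown metric: ", metric, call. = FALSE)
  df <- as.data.frame(table)
  if (pool_vehicle_days) {
    df$day[df$group == "vehicle"] <- df$day[df$group == "vehicle"][1]
  }
  y <- df[[metric]]
  g <- factor(df$group)
  keep <- !is.na(y)
  df <- df[keep, , drop = FALSE]; y <- y[keep]; g <- droplevels(g[keep])

  out <- switch(
    design,
    two_sample_t = {
      if (nlevels(g) != 2) stop("two_sample_t needs exactly 2 groups", call. = FALSE)
      check_cells(df, df$group)
      tt <- stats::t.test(y ~ g)
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, terms = NULL, posthoc = NULL)
    },
    mann_whitney = {
      if (nlevels(g) != 2) stop("mann_whitney needs exactly 2 groups", call. = FALSE)
      check_cells(df, df$group)
      wt <- stats::wilcox.test(y ~ g, exact = FALSE)
      list(statistic = unname(wt$statistic), df = NA_real_,
           p_value = wt$p.value, terms = NULL, posthoc = NULL)
    },
    oneway_anova_bonferroni = {
      check_cells(df, df$group)
      fit <- stats::aov(y ~ g)
      an <- stats::anova(fit)
      list(statistic = an[["F value"]][1],
           df = c(an$Df[1], an$Df[2]),
           p_value = an[["Pr(>F)"]][1],
           terms = anova_terms(an),
           posthoc = pairwise_posthoc(y, g, "bonferroni"))
    },
    twoway_anova = {
      f2 <- factor(df[[factor2]])
      check_cells(df, interaction(df$group, df[[factor2]], drop = TRUE))
      fit <- stats::aov(y ~ g * f2)
      an <- stats::anova(fit)
      rownames(an)[1:3] <- c("group", factor2, paste0("group:", factor2))
      list(statistic = an[["F value"]][1],
           df = c(an$Df[1], an$Df[4]),
           p_value = an[["Pr(>F)"]][1],
           terms = anova_terms(an),
           posthoc = pairwise_posthoc(y, g, "holm_sidak"))
    },
    twoway_rm_anova_holm_sidak = {
      f2 <- factor(df[[factor2]])
      rat <- factor(df$rat_id)
      check_cells(df, interaction(df$group, df[[factor2]], drop = TRUE))
      d2 <- data.frame(y = y, g = g, f2 = f2, rat = rat)
      fit <- stats::aov(y ~ g * f2 + Error(rat / f2), data = d2)
      sm <- summary(fit)
      # between-rat stratum: treatment main effect
      betw <- sm[["Error: rat"]][[1]]
      with <- sm[["Error: rat:f2"]][[1]]
      terms <- rbind(
        data.frame(term = "group", df = betw$Df[1], F = betw$`F value`[1],
                   p = betw$`Pr(>F)`[1]),
        data.frame(term = factor2, df = with$Df[1], F = with$`F value`[1],
                   p = with$`Pr(>F)`[1]),
        data.frame(term = paste0("group:", factor2), df = with$Df[2],
                   F = with$`F value`[2], p = with$`Pr(>F)`[2])
      )
      list(statistic = betw$`F value`[1],
           df = c(betw$Df[1], betw$Df[nrow(betw)]),
           p_value = betw$`Pr(>F)`[1],
           terms = tibble::as_tibble(terms),
           posthoc = pairwise_posthoc(y, g, "holm_sidak"))
    }
  )
  out$design <- design
  out$metric <- metric
  out$alpha <- alpha
  out$n_per_cell <- as.data.frame(base::table(group = df$group))
  structure(out, class = "group_comparison")
}

anova_terms <- function(an) {
  tibble::tibble(term = rownames(an), df = an$Df, F = an[["F value"]],
                 p = an[["Pr(>F)"]])
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s on %s: statistic = %.3g, p = %.3g\n",
              x$design, x$metric, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post hoc (", x$posthoc$method[1], "):\n", sep = "")
    print(as.data.frame(x$posthoc[, c("comparison", "p_adj")]))
  }
  invisible(x)
}
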