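## Group reporting layer: mean +/- SD summaries, normality screening,
## one/two-way ANOVA with the usual post hoc procedures, and osmotic
## mini-pump dose arithmetic.
##
## The ANOVA decomposition is delegated to the classical fixed-effects
## machinery in stats::aov; post hoc family-wise adjustment goes through
## emmeans (Tukey on all pairs, Sidak on all pairs, Dunnett-style
## comparisons against a control). Normality is screened per cell with
## Shapiro-Wilk and reported, never used to auto-switch tests.

#' Assemble a tidy per-animal measurement table
#'
#' @param animal_id,group,day,measure,value Parallel vectors, one entry per
#'   animal x time-point x measure.
#' @return A validated `group_table` data frame.
#' @export
group_table <- function(animal_id, group, day, measure, value) {
  df <- data.frame(animal_id = as.character(animal_id),
                   group = as.character(group),
                   day = day, measure = as.character(measure),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("animal_id", "day", "measure")]))
    stop("duplicate (animal, day, measure) rows", call. = FALSE)
  if (any(!is.finite(df$value))) stop("values must be finite", call. = FALSE)
  class(df) <- c("group_table", "data.frame")
  df
}

#' Group summaries as n / mean / SD
#'
#' Sample mean and sample SD (n - 1 denominator) per group x day x measure
#' cell over the full cell grid; cells with no data are reported as missing
#' (`n = 0`, `NA` statistics) and single-observation cells carry a defined
#' mean but an `NA` SD.
#'
#' @param table A `group_table` (or any data frame with columns `group`,
#'   `day`, `measure`, `value`).
#' @return Data frame with columns `group`, `day`, `measure`, `n`, `mean`,
#'   `sd`.
#' @export
summarize_groups <- function(table) {
  stopifnot(all(c("group", "day", "measure", "value") %in% names(table)))
  grid <- expand.grid(group = unique(table$group), day = unique(table$day),
                      measure = unique(table$measure),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- function(g, d, m) paste(g, d, m, sep = "\r")
  split_vals <- split(table$value, key(table$group, table$day, table$measure))
  k <- key(grid$group, grid$day, grid$measure)
  grid$n <- vapply(k, function(x) length(split_vals[[x]]), integer(1),
                   USE.NAMES = FALSE)
  grid$mean <- vapply(k, function(x) {
    v <- split_vals[[x]]; if (length(v)) mean(v) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  grid$sd <- vapply(k, function(x) {
    v <- split_vals[[x]]; if (length(v) >= 2L) sd(v) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  grid[order(grid$measure, grid$day, grid$group), , drop = FALSE]
}

#' Fixed-effects ANOVA with post hoc multiple comparisons
#'
#' One-way (`value ~ group`) or two-way (`value ~ group * day`, both factors
#' crossed) ANOVA per measure, followed by the requested family-wise
#' post hoc procedure: all pairwise comparisons with Tukey or Sidak
#' adjustment, or comparisons of every group against a control with a
#' Dunnett-style adjustment. For the two-way design post hoc comparisons are
#' made between groups within each day. A Shapiro-Wilk statistic per group
#' cell is attached as a normality screening column (requires 3 or more
#' observations; otherwise `NA`).
#'
#' @param table A `group_table`, ideally one measure (several measures are
#'   analysed independently and stacked).
#' @param design `"one_way"` or `"two_way"`.
#' @param posthoc `"tukey"`, `"dunnett"`, `"sidak"`, or `"none"` to report
#'   the omnibus test only (useful for large simulation studies).
#' @param alpha Nominal significance level (annotates the output).
#' @param control Control group label for Dunnett (defaults to the first
#'   group level).
#' @return List of class `anova_report` with elements `omnibus` (effect, df,
#'   sum_sq, F, p per measure), `posthoc` (comparison, estimate, p_adjusted),
#'   `shapiro` (cell, W, p) and `alpha`.
#' @export
run_anova <- function(table, design = c("one_way", "two_way"),
                      posthoc = c("tukey", "dunnett", "sidak", "none"),
                      alpha = 0.05, control = NULL) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  stopifnot(all(c("group", "value") %in% names(table)))
  if (design == "two_way" && !"day" %in% names(table))
    stop("two-way design needs a `day` column", call. = FALSE)
  measures <- if ("measure" %in% names(table)) unique(table$measure) else "value"

  omnibus <- posthoc_tab <- shapiro_tab <- list()
  for (ms in measures) {
    dat <- if ("measure" %in% names(table)) table[table$measure == ms, ] else table
    dat$group <- factor(dat$group)
    if (nlevels(dat$group) < 2L)
      stop("need at least two groups", call. = FALSE)
    cell_sizes <- table(dat$group)
    if (any(cell_sizes == 0L))
      stop("singular design: empty group", call. = FALSE)
    if (any(cell_sizes < 2L))
      stop("each group needs n >= 2 for the omnibus test", call. = FALSE)

    if (design == "one_way") {
      fit <- aov(value ~ group, data = dat)
      em_spec <- ~group
    } else {
      dat$day <- factor(dat$day)
      fit <- aov(value ~ group * day, data = dat)
      em_spec <- ~group | day
    }
    at <- summary(fit)[[1]]
    eff <- trimws(rownames(at))
    keep <- eff != "Residuals"
    omnibus[[ms]] <- data.frame(
      measure = ms, effect = eff[keep], df = at$Df[keep],
      sum_sq = at$`Sum Sq`[keep], F = at$`F value`[keep],
      p = at$`Pr(>F)`[keep], stringsAsFactors = FALSE)

    if (posthoc == "none") {
      posthoc_tab[[ms]] <- NULL
      cells <- split(dat$value, if (design == "two_way")
        interaction(dat$group, dat$day, drop = TRUE) else dat$group)
      shapiro_tab[[ms]] <- data.frame(
        measure = ms, cell = names(cells),
        n = vapply(cells, length, integer(1)),
        shapiro_W = vapply(cells, function(v)
          if (length(v) >= 3L && sd(v) > 0) shapiro.test(v)$statistic else NA_real_,
          numeric(1)),
        shapiro_p = vapply(cells, function(v)
          if (length(v) >= 3L && sd(v) > 0) shapiro.test(v)$p.value else NA_real_,
          numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
      next
    }
    em <- emmeans::emmeans(fit, em_spec)
    cmp <- switch(posthoc,
      tukey = emmeans::contrast(em, method = "pairwise", adjust = "tukey"),
      sidak = emmeans::contrast(em, method = "pairwise", adjust = "sidak"),
      dunnett = {
        ref <- if (is.null(control)) 1L else match(control, levels(dat$group))
        if (is.na(ref)) stop("unknown control group", call. = FALSE)
        emmeans::contrast(em, method = "trt.vs.ctrl", ref = ref)
      })
    cs <- as.data.frame(summary(cmp))
    unadj <- as.data.frame(summary(
      switch(posthoc,
             dunnett = {
               ref <- if (is.null(control)) 1L else match(control, levels(dat$group))
               emmeans::contrast(em, method = "trt.vs.ctrl", ref = ref,
                                 adjust = "none")
             },
             emmeans::contrast(em, method = "pairwise", adjust = "none"))))
    posthoc_tab[[ms]] <- data.frame(
      measure = ms, comparison = as.character(cs$contrast),
      day = if ("day" %in% names(cs)) as.character(cs$day) else NA_character_,
      estimate = cs$estimate, se = cs$SE, t = cs$t.ratio,
      p_unadjusted = unadj$p.value, p_adjusted = cs$p.value,
      significant = cs$p.value < alpha, stringsAsFactors = FALSE)

    cells <- split(dat$value, if (design == "two_way")
      interaction(dat$group, dat$day, drop = TRUE) else dat$group)
    shapiro_tab[[ms]] <- data.frame(
      measure = ms, cell = names(cells),
      n = vapply(cells, length, integer(1)),
      shapiro_W = vapply(cells, function(v)
        if (length(v) >= 3L && sd(v) > 0) shapiro.test(v)$statistic else NA_real_,
        numeric(1)),
      shapiro_p = vapply(cells, function(v)
        if (length(v) >= 3L && sd(v) > 0) shapiro.test(v)$p.value else NA_real_,
        numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(omnibus = do.call(rbind, omnibus),
                 posthoc = do.call(rbind, posthoc_tab),
                 shapiro = do.call(rbind, shapiro_tab),
                 design = design, posthoc_method = posthoc, alpha = alpha),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("<anova_report> %s ANOVA, %s post hoc, alpha = %g\n",
              x$design, x$posthoc_method, x$alpha))
  print(x$omnibus, row.names = FALSE)
  invisible(x)
}

#' Osmotic mini-pump dose specification
#'
#' @param fill_volume Pump fill volume (microlitres).
#' @param concentration Drug concentration (mg/mL).
#' @param body_weight Animal body weight (kg).
#' @param pump_rate Delivery rate (microlitres/hour).
#' @param duration Delivery duration (hours).
#' @return A validated `dose_spec`.
#' @export
dose_spec <- function(fill_volume, concentration, body_weight,
                      pump_rate = 0.5, duration = 168) {
  vals <- c(fill_volume, concentration, body_weight, pump_rate, duration)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dose parameters must be strictly positive", call. = FALSE)
  structure(list(fill_volume = fill_volume, concentration = concentration,
                 body_weight = body_weight, pump_rate = pump_rate,
                 duration = duration),
            class = "dose_spec")
}

#' Nominal pump dose and delivered volume
#'
#' The nominal dose is computed on the fill-volume basis:
#' `concentration (mg/mL) x fill_volume (uL) / 1000 / body_weight (kg)`,
#' in mg/kg. The actually delivered volume, `min(fill_volume,
#' pump_rate x duration)`, is reported alongside so that the difference
#' between the nominal fill and what the pump can physically expel over the
#' delivery window stays visible.
#'
#' @param spec A [dose_spec()].
#' @return List with `nominal_dose_mg_per_kg` and `delivered_volume_ul`.
#' @export
#' @examples
#' pump_dose(dose_spec(100, 20, 0.020))  # 100 mg/kg, 84 uL delivered
pump_dose <- function(spec) {
  stopifnot(inherits(spec, "dose_spec"))
  list(
    nominal_dose_mg_per_kg =
      spec$concentration * spec$fill_volume / 1000 / spec$body_weight,
    delivered_volume_ul = min(spec$fill_volume, spec$pump_rate * spec$duration))
}
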