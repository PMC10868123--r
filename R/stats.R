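# Group-comparison layer on per-cell metrics: Student's t, one-way ANOVA
# with Tukey's HSD, one-sample t, and mean +/- SEM summaries. The unit of
# analysis is the cell; per-organelle observations are summarized per cell
# upstream to avoid pseudo-replication.

groupStats <- function(values) {
  c(mean = mean(values), sem = sd(values) / sqrt(length(values)),
    n = length(values))
}

#' Unpaired two-tailed Student's t test
#'
#' Classic equal-variance two-sample t test (a Welch option is provided for
#' robustness checks).
#'
#' @param valuesA,valuesB numeric vectors, each of length >= 2.
#' @param labels group labels for reporting.
#' @param welch use Welch's unequal-variance form instead.
#' @return a \linkS4class{GroupResult}.
#' @examples
#' ttestUnpaired(c(1, 2, 3), c(4, 5, 6))
#' @export
ttestUnpaired <- function(valuesA, valuesB, labels = c("A", "B"),
                          welch = FALSE) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("each group needs at least two cells")
  if (sd(valuesA) == 0 && sd(valuesB) == 0)
    stop("degenerate comparison: both groups have zero variance")
  tt <- t.test(valuesA, valuesB, var.equal = !welch)
  ga <- groupStats(valuesA); gb <- groupStats(valuesB)
  new("GroupResult", groups = labels,
      means = unname(c(ga["mean"], gb["mean"])),
      sems = unname(c(ga["sem"], gb["sem"])),
      n = c(as.integer(ga["n"]), as.integer(gb["n"])),
      test = if (welch) "Welch two-sample t" else "unpaired two-tailed Student's t",
      statistic = unname(tt$statistic), pValue = tt$p.value,
      pairwise = NULL)
}

#' One-way ANOVA with Tukey's multiple comparisons
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 2).
#' @return a \linkS4class{GroupResult} whose \code{pairwise} slot holds the
#'   all-pairs Tukey HSD table (pair, diff, lwr, upr, p_adj).
#' @export
anovaTukey <- function(groups) {
  if (length(groups) < 3L)
    stop("fewer than 3 groups: use ttestUnpaired() for two-group comparisons")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least two cells")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL)
  gs <- vapply(groups, groupStats, numeric(3))
  Fv <- an["group", "F value"]
  pv <- an["group", "Pr(>F)"]
  if (is.na(Fv)) { Fv <- 0; pv <- 1 }  # zero between- and within-group SS
  new("GroupResult", groups = names(groups),
      means = unname(gs["mean", ]), sems = unname(gs["sem", ]),
      n = as.integer(gs["n", ]),
      test = "one-way ANOVA + Tukey HSD",
      statistic = Fv, pValue = min(max(pv, 0), 1), pairwise = pw)
}

#' One-sample two-tailed t test
#'
#' @param values numeric vector (n >= 2) of per-cell values.
#' @param mu0 null-hypothesis mean (e.g. 1 for fold changes).
#' @return a \linkS4class{GroupResult}.
#' @export
oneSampleTtest <- function(values, mu0) {
  if (length(values) < 2L) stop("need at least two cells")
  if (sd(values) == 0)
    stop("degenerate one-sample test: zero variance")
  tt <- t.test(values, mu = mu0)
  g <- groupStats(values)
  new("GroupResult", groups = "sample",
      means = unname(g["mean"]), sems = unname(g["sem"]),
      n = as.integer(g["n"]),
      test = sprintf("one-sample t vs mu0 = %g", mu0),
      statistic = unname(tt$statistic), pValue = tt$p.value,
      pairwise = NULL)
}

#' Per-group mean +/- SEM publication summary
#'
#' Summarizes a per-cell metric table the way figure legends report it:
#' per-group mean and SEM over cells (n), with the number of biological
#' replicates (N) carried alongside when a replicate label is present.
#'
#' @param metricTable data.frame with one row per cell.
#' @param value name of the metric column.
#' @param group name of the condition column.
#' @param replicate optional name of the replicate column.
#' @return data.frame (group, mean, sem, n_cells, N_replicates).
#' @export
summarizePerCell <- function(metricTable, value, group, replicate = NULL) {
  for (col in c(value, group, replicate))
    if (!col %in% names(metricTable)) stop("missing column: ", col)
  if (anyNA(metricTable[[group]])) stop("missing group labels")
  sp <- split(metricTable, metricTable[[group]])
  out <- lapply(names(sp), function(g) {
    v <- sp[[g]][[value]]
    if (length(v) < 2L)
      warning("group '", g, "' has a single cell: SEM undefined")
    data.frame(group = g, mean = mean(v),
               sem = if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_,
               n_cells = length(v),
               N_replicates = if (is.null(replicate)) NA_integer_ else
                 length(unique(sp[[g]][[replicate]])))
  })
  do.call(rbind, out)
}

#' Significance stars
#'
#' Maps p-values to the star convention used in figure legends:
#' * p < 0.05, ** p < 0.01, *** p < 0.001, **** p < 0.0001; "ns" otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star labels.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}
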