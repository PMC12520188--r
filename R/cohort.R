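# Pearson r with a two-sided p from the t transform, pairwise-complete.
# p values below `p_floor` (numerically zero, e.g. exact collinearity) are
# reported at the floor so downstream log-scale handling never sees 0.
pearson_test <- function(x, y, p_floor = 1e-300) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop_input("insufficient data: %d complete pairs (need >= 3)", n)
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  }
  r <- sum(dx * dy) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) {
    p_floor
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    max(2 * stats::pt(-abs(tt), df = n - 2), p_floor)
  }
  list(r = r, p = p, n = n, undefined = FALSE)
}

#' Stratify a cohort by nucleus pulposus T2
#'
#' Adds a `degeneration_grade` column binned on `np_t2_ms`: `healthy`
#' (T2 > 60 ms), `mild-moderate` (40 < T2 <= 60 ms) and `severe`
#' (T2 <= 40 ms). The published bins leave the boundary values unassigned;
#' here ties go to the more degenerative bin (60 ms is mild-moderate, 40 ms
#' is severe), which is conservative for claims of health. Missing T2 yields
#' a missing grade.
#'
#' @param table data.frame with an `np_t2_ms` column.
#' @param breaks_ms `c(severe_upper, healthy_lower)` bin edges, ms.
#' @return `table` with `degeneration_grade` added (ordered factor
#'   healthy < mild-moderate < severe).
#' @export
stratify_by_t2 <- function(table, breaks_ms = c(40, 60)) {
  if (!"np_t2_ms" %in% names(table)) {
    stop_input("`table` must have an `np_t2_ms` column")
  }
  t2 <- table$np_t2_ms
  grade <- ifelse(t2 > breaks_ms[2], "healthy",
                  ifelse(t2 > breaks_ms[1], "mild-moderate", "severe"))
  table$degeneration_grade <- factor(grade,
    levels = c("healthy", "mild-moderate", "severe"), ordered = TRUE)
  table
}

#' T2 versus trans-endplate diffusion correlation, with the exclusion rule
#'
#' Correlates NP T2 with the percent-T1-reduction diffusion metric twice:
#' over all records, and over the subset excluding discs with endplate
#' resorption or severe degeneration (NP T2 < `severe_t2_ms`) — in those
#' discs transport is enhanced through breached boundaries, masking the
#' positive T2-diffusion relationship of intact discs. The least-squares
#' line of the excluded-subset relationship is also reported.
#'
#' @param table data.frame with `np_t2_ms`, `pct_t1_reduction`,
#'   `endplate_resorption` columns (and optionally `specimen_id` used to
#'   label exclusions).
#' @param severe_t2_ms severity threshold for exclusion, ms.
#' @return list with elements `all` and `excluded_subset` (each `r`, `p`,
#'   `n`, `undefined`), `excluded_ids`, and `subset_line`
#'   (`c(intercept, slope)`).
#' @export
diffusion_correlation <- function(table, severe_t2_ms = 40) {
  need <- c("np_t2_ms", "pct_t1_reduction", "endplate_resorption")
  if (!all(need %in% names(table))) {
    stop_input("`table` must have columns: %s", paste(need, collapse = ", "))
  }
  ids <- if ("specimen_id" %in% names(table)) table$specimen_id else
    seq_len(nrow(table))
  drop <- table$endplate_resorption %in% TRUE |
    (is.finite(table$np_t2_ms) & table$np_t2_ms < severe_t2_ms)
  keep <- !drop
  all_res <- pearson_test(table$np_t2_ms, table$pct_t1_reduction)
  sub <- table[keep, , drop = FALSE]
  sub_res <- pearson_test(sub$np_t2_ms, sub$pct_t1_reduction)
  line <- stats::coef(stats::lm(pct_t1_reduction ~ np_t2_ms, data = sub))
  list(all = all_res, excluded_subset = sub_res,
       excluded_ids = ids[drop],
       subset_line = c(intercept = unname(line[1]), slope = unname(line[2])))
}

#' Disc-facet Pearson correlation matrix
#'
#' Pearson correlation of every disc variable against every facet variable
#' over pairwise-complete observations, with the two-sided p from the t
#' transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom. No
#' multiplicity correction is applied by default (Benjamini-Hochberg is
#' available via `adjust = "BH"`). Zero-variance columns yield a row flagged
#' `undefined`.
#'
#' @param table cohort data.frame.
#' @param disc_vars,facet_vars column names to pair.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with `disc_var`, `facet_var`, `r`, `p`, `n`,
#'   `undefined`.
#' @export
correlation_matrix <- function(table, disc_vars, facet_vars,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  missing_vars <- setdiff(c(disc_vars, facet_vars), names(table))
  if (length(missing_vars)) {
    stop_input("variables not in table: %s", paste(missing_vars, collapse = ", "))
  }
  grid <- expand.grid(disc_var = disc_vars, facet_var = facet_vars,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- pearson_test(table[[grid$disc_var[i]]], table[[grid$facet_var[i]]])
    data.frame(disc_var = grid$disc_var[i], facet_var = grid$facet_var[i],
               r = res$r, p = res$p, n = res$n, undefined = res$undefined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-group summary with percent difference versus a reference group
#'
#' Mean, SD and n of `value_var` within each level of `group_var`, plus the
#' percent difference of each group mean from the reference group mean:
#' `100 * (mean_group - mean_ref) / mean_ref`.
#'
#' @param table data.frame.
#' @param value_var,group_var column names.
#' @param reference reference group label (default: first factor level /
#'   first unique value).
#' @return data.frame with `group`, `mean`, `sd`, `n`, `pct_diff_vs_ref`,
#'   and a `reference` attribute naming the reference group.
#' @export
group_summary <- function(table, value_var, group_var,
                          reference = NULL) {
  if (!all(c(value_var, group_var) %in% names(table))) {
    stop_input("`value_var`/`group_var` not found in table")
  }
  g <- table[[group_var]]
  v <- table[[value_var]]
  groups <- if (is.factor(g)) levels(g)[levels(g) %in% unique(as.character(g))]
    else unique(as.character(g))
  if (is.null(reference)) reference <- groups[1]
  ref_vals <- v[as.character(g) == reference & is.finite(v)]
  if (!length(ref_vals)) {
    stop_input("empty reference group '%s'", reference)
  }
  ref_mean <- mean(ref_vals)
  rows <- lapply(groups, function(gr) {
    vals <- v[as.character(g) == gr & is.finite(v)]
    m <- if (length(vals)) mean(vals) else NA_real_
    data.frame(group = gr, mean = m,
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
               n = length(vals),
               pct_diff_vs_ref = 100 * (m - ref_mean) / ref_mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  out
}

#' The six disc-facet variable pairs of the headline correlation analysis
#'
#' Pairs, in reporting order: NP T2 vs facet tensile modulus, NP T2 vs facet
#' permeability, disc histology score vs facet permeability, disc histology
#' score vs facet compressive modulus, disc linear modulus vs facet
#' permeability, disc toe modulus vs facet permeability. Their expected signs
#' under the degeneration model are (+, -, +, -, +, +).
#'
#' @return data.frame with `disc_var`, `facet_var`, `expected_sign`.
#' @export
headline_correlation_pairs <- function() {
  data.frame(
    disc_var = c("np_t2_ms", "np_t2_ms", "disc_histology_score",
                 "disc_histology_score", "linear_modulus_MPa",
                 "toe_modulus_MPa"),
    facet_var = c("facet_Et", "facet_k", "facet_k", "facet_Ec",
                  "facet_k", "facet_k"),
    expected_sign = c(1, -1, 1, -1, 1, 1),
    stringsAsFactors = FALSE
  )
}
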