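#' Read a Ct-value table
#'
#' CSV with columns `sample_id,group,gene,replicate,ct`. Gene symbols are
#' uppercased; Ct values must lie in (0, 45) cycles (the usual qPCR
#' instrument range).
#'
#' @param path file path.
#' @return data.frame of Ct measurements.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df$gene <- toupper(df$gene)
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct) | df$ct <= 0 | df$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  df
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged to one Ct per (sample, gene); per
#' sample, dCt = Ct_gene - Ct_reference; ddCt subtracts the mean dCt of
#' the calibrator group (per gene); fold = 2^-ddCt. Samples lacking the
#' reference gene are excluded with a warning. By construction, the
#' calibrator group's mean ddCt is 0 and its geometric-mean fold is 1 for
#' every gene.
#'
#' @param data Ct data.frame (`sample_id`, `group`, `gene`, `replicate`,
#'   `ct`), e.g. from [read_ct_table()].
#' @param reference_gene housekeeping gene used for normalization
#'   (GAPDH in the motivating study).
#' @param calibrator_group group whose mean dCt defines fold = 1
#'   (healthy controls by default).
#' @return data.frame with one row per (sample, gene) excluding the
#'   reference gene: `sample_id`, `group`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `fold`.
#' @export
delta_delta_ct <- function(data, reference_gene = "GAPDH",
                           calibrator_group = "healthy_control") {
  reference_gene <- toupper(reference_gene)
  data$gene <- toupper(data$gene)
  if (!reference_gene %in% data$gene)
    stop("reference gene ", reference_gene, " absent from the data")
  if (!calibrator_group %in% data$group)
    stop("calibrator group ", calibrator_group, " absent from the data")
  # average technical replicates
  avg <- stats::aggregate(ct ~ sample_id + group + gene, data = data,
                          FUN = mean)
  ref <- avg[avg$gene == reference_gene,
             c("sample_id", "ct"), drop = FALSE]
  names(ref)[2] <- "ct_ref"
  tgt <- avg[avg$gene != reference_gene, , drop = FALSE]
  merged <- merge(tgt, ref, by = "sample_id")
  dropped <- setdiff(unique(tgt$sample_id), unique(ref$sample_id))
  if (length(dropped))
    warning(length(dropped),
            " sample(s) lacking the reference gene excluded: ",
            paste(dropped, collapse = ", "))
  merged$delta_ct <- merged$ct - merged$ct_ref
  cal <- merged[merged$group == calibrator_group, , drop = FALSE]
  if (!nrow(cal)) stop("calibrator group is empty after exclusions")
  cal_mean <- tapply(cal$delta_ct, cal$gene, mean)
  missing_cal <- setdiff(unique(merged$gene), names(cal_mean))
  if (length(missing_cal))
    stop("calibrator group has no measurements for gene(s): ",
         paste(missing_cal, collapse = ", "))
  merged$delta_delta_ct <- merged$delta_ct -
    as.numeric(cal_mean[merged$gene])
  merged$fold <- 2^(-merged$delta_delta_ct)
  out <- merged[order(merged$gene, merged$group, merged$sample_id),
                c("sample_id", "group", "gene", "delta_ct",
                  "delta_delta_ct", "fold")]
  rownames(out) <- NULL
  out
}

#' Per-group fold-change summary
#'
#' @param folds a [delta_delta_ct()] result.
#' @return data.frame per (gene, group): `n`, arithmetic `mean_fold` and
#'   `sd_fold` (what bar charts of relative expression display), and
#'   `geomean_fold` = 2^-mean(ddCt), the scale on which planted fold
#'   changes are recovered.
#' @export
group_fold_summary <- function(folds) {
  agg <- function(f) stats::aggregate(
    folds[c("fold", "delta_delta_ct")],
    by = folds[c("gene", "group")], FUN = f)
  m <- agg(mean); s <- agg(stats::sd); n <- agg(length)
  out <- data.frame(gene = m$gene, group = m$group, n = n$fold,
                    mean_fold = m$fold, sd_fold = s$fold,
                    geomean_fold = 2^(-m$delta_delta_ct),
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$group), ]
}

.check_groups <- function(values_by_group) {
  if (length(values_by_group) < 2L) stop("need at least 2 groups")
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 values: ",
         paste(names(values_by_group)[sizes < 2L], collapse = ", "))
  invisible(sizes)
}

.long_format <- function(values_by_group) {
  data.frame(
    y = unlist(values_by_group, use.names = FALSE),
    g = factor(rep(names(values_by_group), lengths(values_by_group)),
               levels = names(values_by_group))
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA: F is the between-group mean square over
#' the within-group mean square with (G - 1, sum n_g - G) degrees of
#' freedom; p is the upper tail of the F distribution.
#'
#' @param values_by_group named list: group -> numeric vector (>= 2
#'   groups of >= 2 values).
#' @return list: `F`, `p`, `df_between`, `df_within`, `group_stats`
#'   (data.frame of n/mean/sd per group).
#' @export
one_way_anova <- function(values_by_group) {
  .check_groups(values_by_group)
  d <- .long_format(values_by_group)
  tab <- summary(stats::aov(y ~ g, data = d))[[1]]
  gs <- data.frame(
    group = names(values_by_group),
    n = lengths(values_by_group),
    mean = vapply(values_by_group, mean, numeric(1)),
    sd = vapply(values_by_group, stats::sd, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  f <- tab[["F value"]][1]; p <- tab[["Pr(>F)"]][1]
  if (!is.finite(f)) { f <- 0; p <- 1 }   # zero within variance edge
  list(F = f, p = p,
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
       group_stats = gs)
}

#' Tukey HSD post-hoc comparisons
#'
#' All-pairs comparisons after one-way ANOVA using the studentized-range
#' distribution (Tukey-Kramer for unequal group sizes): for groups i, j
#' the statistic is
#' `q = |mean_i - mean_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))`
#' with (G, sum n_g - G) parameters.
#'
#' @inheritParams one_way_anova
#' @return data.frame per pair: `group_i`, `group_j`, `diff`
#'   (mean_j - mean_i), `q`, `p_adjusted`.
#' @export
tukey_hsd <- function(values_by_group) {
  .check_groups(values_by_group)
  d <- .long_format(values_by_group)
  fit <- stats::aov(y ~ g, data = d)
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  msw <- sum(stats::resid(fit)^2) / fit$df.residual
  ns <- lengths(values_by_group)
  qstat <- mapply(function(pr, diff) {
    se <- sqrt(msw / 2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    if (se == 0) return(if (diff == 0) 0 else Inf)
    abs(diff) / se
  }, pairs, tk[, "diff"])
  out <- data.frame(
    group_i = vapply(pairs, `[`, character(1), 2),
    group_j = vapply(pairs, `[`, character(1), 1),
    diff = unname(tk[, "diff"]),
    q = unname(qstat),
    p_adjusted = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Full group comparison for one gene or analyte
#'
#' Bundles the per-group summary, the one-way ANOVA and the Tukey HSD
#' table, plus unadjusted pooled-variance pairwise t-test p-values
#' (figures in this field sometimes star unadjusted comparisons; both are
#' reported so either convention can be checked).
#'
#' @inheritParams one_way_anova
#' @param label analyte name carried into the result.
#' @param alpha significance threshold recorded in the result.
#' @return object of class `group_comparison`.
#' @export
group_comparison <- function(values_by_group, label = NA_character_,
                             alpha = 0.05) {
  an <- one_way_anova(values_by_group)
  tk <- tukey_hsd(values_by_group)
  d <- .long_format(values_by_group)
  pt <- stats::pairwise.t.test(d$y, d$g, p.adjust.method = "none",
                               pool.sd = TRUE)$p.value
  lookup <- function(a, b) {        # pt is lower-triangular in levels
    if (a %in% rownames(pt) && b %in% colnames(pt) &&
        !is.na(pt[a, b])) pt[a, b] else pt[b, a]
  }
  tk$p_unadjusted <- mapply(lookup, tk$group_j, tk$group_i)
  tk$significant <- tk$p_adjusted < alpha
  structure(
    list(label = label, group_stats = an$group_stats, F = an$F,
         p_anova = an$p, df = c(an$df_between, an$df_within),
         tukey = tk, alpha = alpha),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison", if (!is.na(x$label)) paste0("(", x$label, ")"),
      sprintf(": F(%d, %d) = %.3f, p = %.4g\n", x$df[1], x$df[2], x$F,
              x$p_anova))
  print(x$tukey, digits = 4)
  invisible(x)
}

#' Group statistics for every gene in a fold-change table
#'
#' @param folds a [delta_delta_ct()] result.
#' @param value which per-sample quantity to analyze: `"fold"` (matching
#'   relative-expression figures) or `"delta_ct"` (the statistically
#'   better-behaved alternative).
#' @param alpha significance threshold.
#' @return named list of [group_comparison()] objects, one per gene.
#' @export
expression_group_stats <- function(folds, value = c("fold", "delta_ct"),
                                   alpha = 0.05) {
  value <- match.arg(value)
  genes <- sort(unique(folds$gene))
  stats::setNames(lapply(genes, function(g) {
    sub <- folds[folds$gene == g, , drop = FALSE]
    vbg <- split(sub[[value]], sub$group)
    vbg <- vbg[unique(sub$group)]       # preserve study group order
    group_comparison(vbg, label = g, alpha = alpha)
  }), genes)
}
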