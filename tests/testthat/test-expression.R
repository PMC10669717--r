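make_ct <- function(samples) {
  # samples: list(sample_id = list(group, gene = ct, ...))
  rows <- list()
  for (sid in names(samples)) {
    s <- samples[[sid]]
    for (g in setdiff(names(s), "group"))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = s$group, gene = g, replicate = 1L,
        ct = s[[g]], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("ddCt arithmetic matches the textbook cases", {
  ct <- make_ct(list(
    cal = list(group = "healthy_control", GAPDH = 20, BDNF = 24),
    s1  = list(group = "treated", GAPDH = 20, BDNF = 24),
    s2  = list(group = "treated", GAPDH = 21, BDNF = 24)))
  res <- delta_delta_ct(ct, "GAPDH", "healthy_control")
  r1 <- res[res$sample_id == "s1", ]
  expect_equal(r1$delta_ct, 4)
  expect_equal(r1$delta_delta_ct, 0)
  expect_equal(r1$fold, 1)
  r2 <- res[res$sample_id == "s2", ]           # dCt 3 vs calibrator 4
  expect_equal(r2$delta_delta_ct, -1)
  expect_equal(r2$fold, 2)
})

test_that("replicates average before dCt and missing reference drops sample", {
  ct <- rbind(
    data.frame(sample_id = "s1", group = "healthy_control",
               gene = "GAPDH", replicate = 1:2, ct = c(19, 21)),
    data.frame(sample_id = "s1", group = "healthy_control",
               gene = "BDNF", replicate = 1:2, ct = c(23, 25)),
    data.frame(sample_id = "s2", group = "treated",
               gene = "BDNF", replicate = 1L, ct = 25))
  expect_warning(res <- delta_delta_ct(ct, "GAPDH", "healthy_control"),
                 "lacking the reference")
  expect_equal(nrow(res), 1L)
  expect_equal(res$delta_ct, 4)
  expect_error(delta_delta_ct(ct[1:2, ], "GAPDH", "nope"), "calibrator")
})

test_that("calibrator group self-normalizes to geometric-mean fold 1", {
  for (seed in 1:5) {
    sim <- simulate_expression(default_expression_spec(seed))
    folds <- delta_delta_ct(sim$data, "GAPDH", "healthy_control")
    summ <- group_fold_summary(folds)
    cal <- summ[summ$group == "healthy_control", ]
    expect_equal(cal$geomean_fold, rep(1, nrow(cal)), tolerance = 1e-12)
    mean_ddct <- tapply(
      folds$delta_delta_ct[folds$group == "healthy_control"],
      folds$gene[folds$group == "healthy_control"], mean)
    expect_equal(as.numeric(mean_ddct), rep(0, length(mean_ddct)),
                 tolerance = 1e-12)
  }
})

test_that("fold changes are invariant to per-sample Ct shifts", {
  sim <- simulate_expression(default_expression_spec(7))
  folds1 <- delta_delta_ct(sim$data, "GAPDH", "healthy_control")
  shifted <- sim$data
  shift <- stats::setNames(
    seq_along(unique(shifted$sample_id)) %% 5,
    unique(shifted$sample_id))
  shifted$ct <- shifted$ct + shift[shifted$sample_id]
  folds2 <- delta_delta_ct(shifted, "GAPDH", "healthy_control")
  expect_equal(folds2$fold, folds1$fold, tolerance = 1e-12)
})

test_that("one-way ANOVA matches its defining identities", {
  # identical group means with nonzero spread: F = 0, p = 1
  vbg <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  an <- one_way_anova(vbg)
  expect_equal(an$F, 0, tolerance = 1e-12)
  expect_equal(an$p, 1, tolerance = 1e-12)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 6)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(15)
  x <- rnorm(12); y <- rnorm(15, mean = 0.8)
  an2 <- one_way_anova(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(an2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an2$p, tt$p.value, tolerance = 1e-9)

  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "fewer than 2")
  expect_error(one_way_anova(list(a = c(1, 2))), "at least 2 groups")
})

test_that("ANOVA F is invariant to shifts and to rescaling", {
  set.seed(31)
  vbg <- lapply(1:4, function(i) rnorm(10, mean = i / 2))
  names(vbg) <- paste0("g", 1:4)
  f0 <- one_way_anova(vbg)$F
  f_shift <- one_way_anova(lapply(vbg, `+`, 100))$F
  f_scale <- one_way_anova(lapply(vbg, `*`, 3.7))$F
  expect_equal(f_shift, f0, tolerance = 1e-9)
  expect_equal(f_scale, f0, tolerance = 1e-9)
})

test_that("Tukey HSD is exact against a numerically integrated
           studentized-range CDF", {
  set.seed(8)
  vbg <- list(g1 = rnorm(8), g2 = rnorm(8, 1), g3 = rnorm(8, 2))
  tk <- tukey_hsd(vbg)
  df <- 24 - 3
  for (i in seq_len(nrow(tk))) {
    p_oracle <- 1 - oracle_ptukey(tk$q[i], k = 3, df = df)
    expect_equal(tk$p_adjusted[i], p_oracle, tolerance = 1e-6)
  }
})

test_that("identical groups give all Tukey p = 1; q uses Tukey-Kramer", {
  vbg <- list(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(2, 3, 1, 4))
  tk <- tukey_hsd(vbg)
  expect_equal(nrow(tk), choose(3, 2))
  expect_equal(tk$p_adjusted, rep(1, 3), tolerance = 1e-9)
  expect_equal(tk$q, rep(0, 3), tolerance = 1e-12)

  # unequal n: q recomputed from first principles
  set.seed(4)
  vbg2 <- list(a = rnorm(5), b = rnorm(9, 1), c = rnorm(7, 0.3))
  tk2 <- tukey_hsd(vbg2)
  fit <- stats::aov(y ~ g, data = data.frame(
    y = unlist(vbg2),
    g = factor(rep(names(vbg2), lengths(vbg2)))))
  msw <- sum(stats::resid(fit)^2) / fit$df.residual
  for (i in seq_len(nrow(tk2))) {
    ni <- lengths(vbg2)[[tk2$group_i[i]]]
    nj <- lengths(vbg2)[[tk2$group_j[i]]]
    q_manual <- abs(tk2$diff[i]) / sqrt(msw / 2 * (1 / ni + 1 / nj))
    expect_equal(tk2$q[i], q_manual, tolerance = 1e-12)
  }
})

test_that("Tukey adjusted p protects relative to unadjusted pairwise t", {
  set.seed(19)
  for (i in 1:10) {
    vbg <- lapply(1:4, function(j) rnorm(8, mean = runif(1, 0, 1)))
    names(vbg) <- paste0("g", 1:4)
    gc <- group_comparison(vbg)
    expect_true(all(gc$tukey$p_adjusted >=
                      gc$tukey$p_unadjusted - 1e-12))
  }
})

test_that("a +3 SD shifted group is flagged only in its own pairs", {
  flagged_ok <- 0L
  for (seed in 1:50) {
    set.seed(seed + 2000)
    vbg <- list(g1 = rnorm(30), g2 = rnorm(30), g3 = rnorm(30),
                shifted = rnorm(30, mean = 3))
    tk <- tukey_hsd(vbg)
    hit <- tk$p_adjusted < 0.05
    involves <- tk$group_i == "shifted" | tk$group_j == "shifted"
    if (all(hit[involves]) && !any(hit[!involves]))
      flagged_ok <- flagged_ok + 1L
  }
  expect_gte(flagged_ok, 45L)
})

test_that("linear ELISA curves invert exactly and refuse extrapolation", {
  std <- data.frame(concentration = c(0, 1, 2),
                    absorbance = c(0, 0.5, 1.0))
  curve <- fit_standard_curve(std, "linear")
  res <- interpolate_concentration(curve, 0.75)
  expect_equal(res$concentration, 1.5, tolerance = 1e-12)
  expect_false(res$out_of_range)

  hi <- interpolate_concentration(curve, 1.2)
  expect_true(hi$out_of_range)
  expect_true(is.na(hi$concentration))

  expect_error(fit_standard_curve(
    data.frame(concentration = c(1, 1), absorbance = c(0, 1)), "linear"),
    "strictly increasing")
  expect_error(fit_standard_curve(std[1, , drop = FALSE], "linear"),
               ">= 2")
  expect_error(fit_standard_curve(std, "4pl"), ">= 4")
})

test_that("4PL fits recover concentrations within 5% mid-range", {
  true <- list(model = "4pl", a = 0.02, d = 3.2, c = 18, b = 1.4)
  respond <- function(x) true$d + (true$a - true$d) /
    (1 + (x / true$c)^true$b)
  conc <- c(0, 2, 5, 10, 20, 40, 80)
  ok <- 0L
  for (seed in 1:100) {
    set.seed(seed + 500)
    std <- data.frame(concentration = conc,
                      absorbance = respond(conc) + rnorm(7, 0, 0.01))
    curve <- fit_standard_curve(std, "4pl")
    mid <- c(8, 15, 25)
    est <- interpolate_concentration(curve, respond(mid))$concentration
    if (all(abs(est - mid) / mid < 0.05)) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("ELISA sample quantification averages replicates per sample", {
  sim <- simulate_elisa(99, n_per_group = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sim$data, path, row.names = FALSE, quote = FALSE)
  e <- read_elisa(path)
  curve <- fit_standard_curve(e$standards, "linear")
  conc <- elisa_sample_concentrations(e, curve)
  expect_equal(nrow(conc), 20L)
  inr <- !conc$out_of_range
  expect_gt(mean(inr), 0.8)
  truth <- sim$truth$sample_concentration[conc$id[inr]]
  expect_lt(max(abs(conc$concentration[inr] - truth)), 1.5)
})
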