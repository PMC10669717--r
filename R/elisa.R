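#' Read an ELISA CSV (standards and samples blocks)
#'
#' One file, one `type` column: rows with `type == "standard"` carry
#' `concentration` and `absorbance`; rows with `type == "sample"` carry
#' `id`, `group` and `absorbance` (one row per replicate read).
#'
#' @param path file path.
#' @return list with `standards` (data.frame `concentration`,
#'   `absorbance`) and `samples` (data.frame `id`, `group`,
#'   `absorbance`).
#' @export
read_elisa <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("type", "id", "group", "concentration", "absorbance")
  if (!all(need %in% names(df)))
    stop("ELISA file must have columns: ", paste(need, collapse = ", "))
  std <- df[df$type == "standard", c("concentration", "absorbance")]
  smp <- df[df$type == "sample", c("id", "group", "absorbance")]
  rownames(std) <- rownames(smp) <- NULL
  list(standards = std, samples = smp)
}

#' Fit an ELISA standard curve
#'
#' Linear curves are ordinary least squares. The four-parameter logistic
#' (4PL), the kit's true sigmoidal response
#' \deqn{A(c) = d + \frac{a - d}{1 + (c/c_{50})^{b}}}
#' is fitted by Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]) from data-driven starting values: `a` = the
#' blank's absorbance, `d` = 1.05 x the top standard's absorbance,
#' `c50` = the concentration nearest half-maximal response, `b` = 1.
#' The quantifiable range is the absorbance span of the standards;
#' interpolation outside it is refused rather than extrapolated.
#'
#' @param standards data.frame with `concentration` (ng/mL, non-negative,
#'   strictly increasing) and `absorbance`.
#' @param model `"linear"` (>= 2 standards) or `"4pl"` (>= 4 standards).
#' @return object of class `elisa_curve`: `model`, `coef`, `standards`,
#'   `response_range`, `concentration_range`.
#' @export
fit_standard_curve <- function(standards, model = c("linear", "4pl")) {
  model <- match.arg(model)
  conc <- standards$concentration; resp <- standards$absorbance
  if (any(conc < 0) || any(diff(conc) <= 0))
    stop("standard concentrations must be non-negative, strictly increasing")
  if (model == "linear" && length(conc) < 2)
    stop("linear curve needs >= 2 standards")
  if (model == "4pl" && length(conc) < 4)
    stop("4PL curve needs >= 4 standards")
  if (model == "linear") {
    fit <- stats::lm(absorbance ~ concentration, data = standards)
    coefs <- c(intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]))
    if (coefs[["slope"]] == 0) stop("degenerate flat standard curve")
  } else {
    half <- (min(resp) + max(resp)) / 2
    start <- list(a = resp[1], d = 1.05 * max(resp),
                  c50 = conc[which.min(abs(resp - half))], b = 1)
    if (start$c50 <= 0) start$c50 <- mean(range(conc[conc > 0]))
    fit <- minpack.lm::nlsLM(
      absorbance ~ d + (a - d) / (1 + (concentration / c50)^b),
      data = standards, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    coefs <- stats::coef(fit)
  }
  structure(list(model = model, coef = coefs, standards = standards,
                 response_range = range(resp),
                 concentration_range = range(conc)),
            class = "elisa_curve")
}

#' @export
print.elisa_curve <- function(x, ...) {
  cat("elisa_curve (", x$model, "): ",
      paste(names(x$coef), signif(x$coef, 4), sep = "=",
            collapse = ", "),
      "; quantifiable absorbance ",
      paste(signif(x$response_range, 4), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Interpolate concentrations from absorbances
#'
#' Inverts the fitted standard curve. Absorbances outside the
#' standards' response range are flagged `out_of_range` and get `NA`
#' rather than an extrapolated number.
#'
#' @param curve an [fit_standard_curve()] result.
#' @param absorbance numeric vector.
#' @return data.frame: `absorbance`, `concentration` (ng/mL),
#'   `out_of_range`.
#' @export
interpolate_concentration <- function(curve, absorbance) {
  lo <- curve$response_range[1]; hi <- curve$response_range[2]
  out <- absorbance < lo | absorbance > hi
  conc <- rep(NA_real_, length(absorbance))
  inr <- which(!out)
  if (length(inr)) {
    y <- absorbance[inr]
    conc[inr] <- if (curve$model == "linear") {
      (y - curve$coef[["intercept"]]) / curve$coef[["slope"]]
    } else {
      a <- curve$coef[["a"]]; d <- curve$coef[["d"]]
      c50 <- curve$coef[["c50"]]; b <- curve$coef[["b"]]
      ratio <- pmax((a - d) / (y - d) - 1, 0)
      c50 * ratio^(1 / b)
    }
  }
  data.frame(absorbance = absorbance, concentration = conc,
             out_of_range = out)
}

#' Quantify ELISA samples against a fitted curve
#'
#' Replicate absorbances are averaged per sample before interpolation.
#'
#' @param elisa a [read_elisa()] result (or equivalent list).
#' @param curve an [fit_standard_curve()] result.
#' @return data.frame per sample: `id`, `group`, `absorbance` (replicate
#'   mean), `concentration`, `out_of_range`.
#' @export
elisa_sample_concentrations <- function(elisa, curve) {
  smp <- elisa$samples
  agg <- stats::aggregate(absorbance ~ id + group, data = smp,
                          FUN = mean)
  res <- interpolate_concentration(curve, agg$absorbance)
  out <- data.frame(id = agg$id, group = agg$group,
                    absorbance = agg$absorbance,
                    concentration = res$concentration,
                    out_of_range = res$out_of_range,
                    stringsAsFactors = FALSE)
  out[order(out$group, out$id), ]
}
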