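#' Logistic-regression presence test between two cell types
#'
#' Tests whether the proportion of cells containing at least one target
#' speckle differs between two cell types (conditions) while regressing out
#' the donor (biological replicate) effect. Each cell is one row of the
#' long-format table; the response is speckle presence (1 = at least one
#' speckle), the predictors are a cell-type indicator and, when more than one
#' donor is present, donor indicators (fixed effects, reference coding). The
#' reported p-value is the Wald test of the cell-type coefficient
#' (a likelihood-ratio alternative is available).
#'
#' Complete separation (a group entirely empty or entirely positive) is
#' flagged — the coefficient diverges and the Wald p-value is meaningless —
#' rather than silently reported.
#'
#' @param records Tibble with columns `donor`, `cell_type` and either
#'   `present` (1 = at least one speckle) or `empty` (1 = no speckle, the
#'   published column convention; it is inverted on input).
#' @param cell_types Length-2 character: the pair to compare (default: the
#'   two types present, error if more). The second level's coefficient is
#'   reported relative to the first.
#' @param donor_covariate Include donor fixed effects (default TRUE; requires
#'   at least 2 donors to have any effect).
#' @param test `"wald"` (default) or `"lrt"`.
#' @return Object of class `presence_test`; `tidy()` gives a one-row tibble
#'   with `estimate` (log-odds), `std_error`, `p_value`, `n_1`, `n_2`,
#'   `separation`.
#' @export
fit_presence_test <- function(records, cell_types = NULL,
                              donor_covariate = TRUE,
                              test = c("wald", "lrt")) {
  test <- match.arg(test)
  records <- tibble::as_tibble(records)
  if (!"present" %in% names(records)) {
    if (!"empty" %in% names(records)) {
      stop("records need a `present` or `empty` column", call. = FALSE)
    }
    records$present <- 1L - as.integer(records$empty)
  }
  if (is.null(cell_types)) {
    cell_types <- sort(unique(records$cell_type))
  }
  if (length(cell_types) != 2) {
    stop("exactly two cell types must be compared", call. = FALSE)
  }
  d <- dplyr::filter(records, .data$cell_type %in% cell_types)
  stopifnot(all(cell_types %in% d$cell_type))
  d$cell_type <- factor(d$cell_type, levels = cell_types)
  d$donor <- factor(d$donor)
  use_donor <- donor_covariate && nlevels(d$donor) >= 2
  form <- if (use_donor) present ~ cell_type + donor else present ~ cell_type
  fit <- suppressWarnings(
    glm(form, family = binomial(), data = d,
        control = list(epsilon = 1e-10, maxit = 100))
  )
  sm <- summary(fit)$coefficients
  term <- paste0("cell_type", cell_types[2])
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  # complete/quasi-separation: fitted probabilities at the boundary or a
  # diverging coefficient
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    abs(est) > 15
  p <- if (test == "wald") {
    2 * pnorm(-abs(est / se))
  } else {
    fit0 <- suppressWarnings(glm(
      if (use_donor) present ~ donor else present ~ 1,
      family = binomial(), data = d
    ))
    stats::pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  }
  structure(
    list(cell_types = cell_types, estimate = est, std_error = se,
         p_value = p, test = test,
         n = table(d$cell_type), separation = separation,
         donor_covariate = use_donor, model = fit),
    class = "presence_test"
  )
}

#' @export
print.presence_test <- function(x, ...) {
  cat("<presence_test> ", x$cell_types[2], " vs ", x$cell_types[1],
      ": log-odds ", round(x$estimate, 3), " (SE ", round(x$std_error, 3),
      "), p = ", format.pval(x$p_value), if (x$separation)
        " [WARNING: separation, estimate unbounded]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.presence_test <- function(x, ...) {
  tibble::tibble(
    cell_type_1 = x$cell_types[1], cell_type_2 = x$cell_types[2],
    estimate = x$estimate, std_error = x$std_error, p_value = x$p_value,
    n_1 = as.integer(x$n[1]), n_2 = as.integer(x$n[2]),
    separation = x$separation
  )
}

#' @export
glance.presence_test <- function(x, ...) {
  tibble::tibble(
    deviance = x$model$deviance, null_deviance = x$model$null.deviance,
    df_residual = x$model$df.residual, converged = x$model$converged,
    separation = x$separation
  )
}

#' All pairwise presence tests with Bonferroni correction
#'
#' Fits [fit_presence_test()] for every pair of cell types in the table and
#' adjusts the p-values with [bonferroni_adjust()] across the pairs.
#'
#' @inheritParams fit_presence_test
#' @return Tibble, one row per pair, with `p_adjusted`.
#' @export
pairwise_presence_tests <- function(records, donor_covariate = TRUE,
                                    test = c("wald", "lrt")) {
  test <- match.arg(test)
  types <- sort(unique(records$cell_type))
  stopifnot(length(types) >= 2)
  pairs <- utils::combn(types, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    tidy(fit_presence_test(records, p, donor_covariate, test))
  })
  out$p_adjusted <- bonferroni_adjust(out$p_value)
  out
}

#' Bonferroni correction
#'
#' Each p-value is multiplied by the number of tests and clipped at 1
#' (`p.adjust(method = "bonferroni")` semantics). Idempotent on a vector of
#' already-clipped values only when all are 0 or from a single test;
#' order-preserving always.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "bonferroni")
}

#' Normalized fold change against a reporter
#'
#' Double ratio used to compare over-expression readouts across constructs:
#' the target readout (percent positive, or MFI) in the test condition over
#' the reporter-only condition, normalized by the same ratio for the
#' transfection reporter:
#' `[(target_cond / target_ref) / (reporter_cond / reporter_ref)]`.
#'
#' @param target_cond,target_ref Target readout in the test and reporter-only
#'   conditions.
#' @param reporter_cond,reporter_ref Reporter readout (percent positive) in
#'   the same two conditions.
#' @return Scalar fold change; `NA` with a warning flag when any denominator
#'   is zero.
#' @export
normalized_fold_change <- function(target_cond, target_ref,
                                   reporter_cond, reporter_ref) {
  if (any(c(target_ref, reporter_ref, reporter_cond) == 0)) {
    return(NA_real_)
  }
  (target_cond / target_ref) / (reporter_cond / reporter_ref)
}
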