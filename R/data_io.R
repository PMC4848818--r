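#' Construct a respondent-by-item response table
#'
#' Holds raw ordinal responses (categories `1:n_categories`, `NA` for missing
#' cells) for the items of an instrument, plus optional per-respondent
#' covariates. Item columns are reordered to the instrument's item order.
#'
#' @param responses matrix or data frame of ordinal categories with item keys
#'   as column names; one row per respondent.
#' @param spec an `"instrument"` object.
#' @param covariates optional data frame of per-respondent covariates with
#'   the same number of rows.
#' @return an object of class `"response_table"`: list with `responses`
#'   (integer matrix), `covariates` (data frame or `NULL`) and
#'   `n_categories`.
#' @export
response_table <- function(responses, spec, covariates = NULL) {
  validate_instrument(spec)
  responses <- as.matrix(responses)
  missing_cols <- setdiff(spec$items$item, colnames(responses))
  if (length(missing_cols) > 0) {
    stop("response table lacks item column(s): ", paste(missing_cols, collapse = ", "))
  }
  responses <- responses[, spec$items$item, drop = FALSE]
  if (!is.numeric(responses)) {
    stop("item responses must be numeric categories 1..", spec$n_categories)
  }
  bad <- !is.na(responses) & (responses < 1 | responses > spec$n_categories |
                                responses != round(responses))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("response out of range 1..", spec$n_categories, " at row ", w[1],
         ", item '", colnames(responses)[w[2]], "'")
  }
  storage.mode(responses) <- "integer"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(responses)) {
      stop("covariates have ", nrow(covariates), " rows but responses have ",
           nrow(responses))
    }
    if ("age" %in% names(covariates) && !is.numeric(covariates$age)) {
      stop("covariate 'age' must be numeric")
    }
  }
  structure(list(responses = responses, covariates = covariates,
                 n_categories = spec$n_categories),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table> %d respondents x %d items (%d categories), %d missing cell(s)\n",
              nrow(x$responses), ncol(x$responses), x$n_categories,
              sum(is.na(x$responses))))
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read respondent data from delimited text
#'
#' Reads a header-rowed delimited file whose columns include every item of
#' the instrument; any remaining columns are kept as covariates. The count of
#' missing item cells is reported via `message()`.
#'
#' @param path file path.
#' @param spec an `"instrument"` object.
#' @param sep field separator (default `","`).
#' @param dec decimal mark (default `"."`).
#' @param na_token missing-value token (default `"NA"`).
#' @return a `"response_table"`.
#' @export
read_responses <- function(path, spec, sep = ",", dec = ".", na_token = "NA") {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                      na.strings = na_token, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop("cannot read responses from '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(df) == 0) stop("responses file '", path, "' contains no data rows")
  item_cols <- intersect(names(df), spec$items$item)
  cov_cols <- setdiff(names(df), spec$items$item)
  for (ic in item_cols) {
    if (!is.numeric(df[[ic]])) {
      bad_row <- which(!is.na(df[[ic]]) & is.na(suppressWarnings(as.numeric(df[[ic]]))))[1]
      stop("non-numeric response at row ", bad_row, ", item '", ic, "'")
    }
  }
  rt <- response_table(df[item_cols],
                       spec,
                       covariates = if (length(cov_cols)) df[cov_cols] else NULL)
  message(sum(is.na(rt$responses)), " missing item cell(s) in '", path, "'")
  rt
}

#' Write a response table to delimited text
#'
#' @param x a `"response_table"`.
#' @param path file path.
#' @param sep field separator.
#' @param na_token token written for missing cells.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path, sep = ",", na_token = "NA") {
  df <- as.data.frame(x$responses)
  if (!is.null(x$covariates)) df <- cbind(df, x$covariates)
  utils::write.table(df, path, sep = sep, na = na_token, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# reversal-recoded item matrix (higher = more of the construct)
recoded_items <- function(x, spec) {
  m <- x$responses
  rev_items <- spec$items$item[spec$items$reversed]
  if (length(rev_items)) {
    m[, rev_items] <- spec$n_categories + 1L - m[, rev_items]
  }
  m
}

#' Reversal-recode a response table
#'
#' Returns a `"response_table"` whose reverse-keyed items have been recoded
#' so that higher always means more of the measured construct — the scale on
#' which the latent factor model is defined. Recoding is recorded on the
#' table and applying it twice is a no-op.
#'
#' @param x a `"response_table"`.
#' @param spec an `"instrument"` object.
#' @return a recoded `"response_table"` with `$recoded = TRUE`.
#' @export
recode_responses <- function(x, spec) {
  if (isTRUE(x$recoded)) return(x)
  x$responses <- recoded_items(x, spec)
  x$recoded <- TRUE
  x
}

#' Classical 0-100 scale scores
#'
#' Per respondent and factor, the reversal-recoded item mean rescaled
#' linearly from the category range `[1, n_categories]` to `[0, 100]`
#' (the Whoqol-bref transformed-domain convention):
#' `(mean(items) - 1) / (n_categories - 1) * 100`, the mean taken over the
#' factor's non-missing items. A factor score is missing only when all of
#' the factor's items are missing for that respondent.
#'
#' @param x a `"response_table"`.
#' @param spec an `"instrument"` object.
#' @return data frame, one column per factor, values in `[0, 100]` or `NA`.
#' @export
scale_scores <- function(x, spec) {
  m <- recoded_items(x, spec)
  out <- vapply(spec$factors$factor, function(f) {
    it <- spec$items$item[spec$items$factor == f]
    mu <- rowMeans(m[, it, drop = FALSE], na.rm = TRUE)
    mu[!is.finite(mu)] <- NA_real_
    (mu - 1) / (spec$n_categories - 1) * 100
  }, numeric(nrow(m)))
  out <- as.data.frame(matrix(out, nrow = nrow(m),
                              dimnames = list(NULL, spec$factors$factor)))
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))` for a matrix
#' of k >= 2 (already reversal-recoded) items. Rows with any missing item are
#' dropped. Alpha may be negative; fewer than 2 complete rows or a
#' zero-variance item sum yields `NA` with a warning.
#'
#' @param x numeric matrix/data frame, respondents by items (k >= 2 columns).
#' @return scalar alpha, or `NA_real_`.
#' @examples
#' cronbach_alpha(cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))  # 1
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) {
    warning("fewer than 2 complete rows; alpha undefined")
    return(NA_real_)
  }
  vtot <- stats::var(rowSums(x))
  if (vtot == 0) {
    warning("zero variance of the item sum; alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vtot)
}

#' Per-factor Cronbach's alpha for an instrument
#'
#' @param x a `"response_table"`.
#' @param spec an `"instrument"` object.
#' @return named numeric vector of alphas, one per factor.
#' @export
factor_alphas <- function(x, spec) {
  m <- recoded_items(x, spec)
  vapply(spec$factors$factor, function(f) {
    it <- spec$items$item[spec$items$factor == f]
    cronbach_alpha(m[, it, drop = FALSE])
  }, numeric(1))
}

#' Descriptive subgroup table for scale scores
#'
#' Mirrors the classical mean(sd)/p layout of descriptive tables: for each
#' factor, group means and standard deviations with a p-value from a Welch
#' two-sample t-test (2 levels) or one-way ANOVA (3+ levels); for a
#' continuous covariate the Pearson correlation coefficient with its t-test
#' p-value. No multiplicity correction is applied. Groups with fewer than 2
#' members keep their mean but have sd flagged unavailable, and the factor's
#' p-value is `NA`.
#'
#' @param scores data frame of per-respondent factor scores
#'   (from [scale_scores()]).
#' @param covariates data frame of per-respondent covariates.
#' @param by name of the grouping covariate (categorical with 2+ levels, or
#'   numeric for a correlation test).
#' @param test for categorical groupings, `"auto"` (Welch t for 2 levels,
#'   ANOVA otherwise), `"t"`, or `"anova"`.
#' @return data frame of class `"subgroup_table"`. Categorical groupings give
#'   columns `factor, level, n, mean, sd, p_value` (the p repeated across a
#'   factor's levels); numeric groupings give `factor, estimate, p_value`
#'   where `estimate` is the Pearson correlation.
#' @export
subgroup_table <- function(scores, covariates, by, test = c("auto", "t", "anova")) {
  test <- match.arg(test)
  if (!by %in% names(covariates)) stop("covariate '", by, "' not found")
  g <- covariates[[by]]
  if (is.numeric(g)) {
    rows <- lapply(names(scores), function(f) {
      ok <- stats::complete.cases(scores[[f]], g)
      ct <- if (sum(ok) >= 3 && stats::sd(scores[[f]][ok]) > 0 && stats::sd(g[ok]) > 0) {
        stats::cor.test(scores[[f]][ok], g[ok])
      } else NULL
      data.frame(factor = f,
                 estimate = if (is.null(ct)) NA_real_ else unname(ct$estimate),
                 p_value = if (is.null(ct)) NA_real_ else ct$p.value,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "by") <- by
    class(out) <- c("subgroup_table", "data.frame")
    return(out)
  }
  g <- factor(g)
  if (nlevels(g) < 2) stop("grouping '", by, "' has fewer than 2 levels")
  rows <- lapply(names(scores), function(f) {
    s <- scores[[f]]
    ok <- !is.na(s) & !is.na(g)
    s <- s[ok]; gi <- droplevels(g[ok])
    ns <- tapply(s, gi, length)
    mus <- tapply(s, gi, mean)
    sds <- tapply(s, gi, stats::sd)  # NA for singleton groups
    p <- NA_real_
    if (nlevels(gi) >= 2 && all(ns >= 2)) {
      vars_ok <- tapply(s, gi, stats::var)
      if (all(vars_ok == 0)) {
        # degenerate: identical within groups; separation decided by the means
        p <- if (length(unique(mus)) == 1) 1 else 0
      } else if ((nlevels(gi) == 2 && test != "anova") || test == "t") {
        p <- tryCatch(stats::t.test(s ~ gi)$p.value, error = function(e) NA_real_)
      } else {
        p <- summary(stats::aov(s ~ gi))[[1]][["Pr(>F)"]][1]
      }
    }
    data.frame(factor = f, level = levels(gi), n = as.integer(ns),
               mean = as.numeric(mus), sd = as.numeric(sds), p_value = p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "by") <- by
  class(out) <- c("subgroup_table", "data.frame")
  out
}

#' @export
print.subgroup_table <- function(x, digits = 3, ...) {
  cat("Scale scores by '", attr(x, "by"), "'\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", ""))))
}

#' Pairwise correlations between factor scale scores
#'
#' Pearson correlations over pairwise-complete observations, with
#' significance stars at p < 0.05 (*), < 0.01 (**) and < 0.001 (***) from
#' the correlation t-test. Cells with fewer than `min_pairs` complete pairs
#' are flagged missing.
#'
#' @param scores data frame of per-respondent factor scores.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return object of class `"score_correlations"`: list with matrices `r`
#'   (unit diagonal, symmetric), `p`, `n` and `stars`.
#' @export
score_correlations <- function(scores, min_pairs = 3) {
  scores <- as.data.frame(scores)
  f <- names(scores)
  k <- length(f)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(f, f))
  n <- matrix(0L, k, k, dimnames = list(f, f))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j >= i) next
    ok <- stats::complete.cases(scores[[i]], scores[[j]])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) >= min_pairs &&
        stats::sd(scores[[i]][ok]) > 0 && stats::sd(scores[[j]][ok]) > 0) {
      ct <- stats::cor.test(scores[[i]][ok], scores[[j]][ok])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n, stars = significance_stars(p)),
            class = "score_correlations")
}

#' Write the classical descriptive layer to plain-text files
#'
#' Emits the descriptive tables for a response table as delimited text:
#' `scale_scores.csv` (per-respondent 0-100 factor scores),
#' `alphas.csv` (per-factor Cronbach's alpha), `score_correlations.csv`
#' (pairwise correlations with significance stars), one
#' `scores_by_<covariate>.csv` per requested grouping, and a
#' machine-readable `summary.yaml` with sample size, missingness and the
#' per-factor score means and sds.
#'
#' @param x a `"response_table"`.
#' @param spec an `"instrument"` object.
#' @param dir output directory (created if absent).
#' @param by character vector of covariate names to tabulate scores by
#'   (default: all covariates present).
#' @return `dir`, invisibly.
#' @export
write_descriptives <- function(x, spec, dir, by = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scores <- scale_scores(x, spec)
  utils::write.csv(scores, file.path(dir, "scale_scores.csv"), row.names = FALSE)
  alphas <- factor_alphas(x, spec)
  utils::write.csv(data.frame(factor = names(alphas), alpha = unname(alphas)),
                   file.path(dir, "alphas.csv"), row.names = FALSE)
  sc <- score_correlations(scores)
  corr <- as.data.frame(round(sc$r, 4))
  corr$stars <- apply(sc$stars, 1, paste0, collapse = "")
  utils::write.csv(cbind(factor = rownames(sc$r), corr),
                   file.path(dir, "score_correlations.csv"), row.names = FALSE)
  if (is.null(by) && !is.null(x$covariates)) by <- names(x$covariates)
  for (b in by) {
    tab <- subgroup_table(scores, x$covariates, b)
    utils::write.csv(tab, file.path(dir, sprintf("scores_by_%s.csv", b)),
                     row.names = FALSE)
  }
  yaml::write_yaml(list(
    n_respondents = nrow(x$responses),
    n_missing_cells = sum(is.na(x$responses)),
    factors = lapply(stats::setNames(nm = names(scores)), function(f) {
      list(mean = mean(scores[[f]], na.rm = TRUE),
           sd = stats::sd(scores[[f]], na.rm = TRUE),
           alpha = unname(alphas[f]))
    })
  ), file.path(dir, "summary.yaml"))
  invisible(dir)
}

#' @export
print.score_correlations <- function(x, digits = 3, ...) {
  k <- ncol(x$r)
  out <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) {
      out[i, j] <- if (is.na(x$r[i, j])) "." else
        paste0(format(round(x$r[i, j], digits)), x$stars[i, j])
    } else if (i == j) out[i, j] <- "1"
  }
  cat("Correlation matrix of factor scale scores (pairwise complete)\n")
  print(out[, -k, drop = FALSE], quote = FALSE)
  cat("Significance: * p<0.05, ** p<0.01, *** p<0.001\n")
  invisible(x)
}
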