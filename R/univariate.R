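# --- univariate screening (Table-2-style) and exact Mann-Whitney -----------

#' Exact / approximate two-sided Mann-Whitney U test
#'
#' For small samples the null distribution of U is built by full
#' enumeration of the C(n1+n2, n1) group assignments of the pooled values
#' (midranks for ties), so the test stays exact in the presence of ties —
#' unlike [stats::wilcox.test()], which falls back to a normal
#' approximation when ties occur. Above the enumeration limit a normal
#' approximation with tie correction is used. Two-sided p =
#' min(1, 2 * min(P(U <= u), P(U >= u))).
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` enumerates when both groups have at most `exact_limit`
#'   observations.
#' @param exact_limit per-group size limit for the default exact rule.
#' @return list with `U` (statistic for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL, exact_limit = 8L) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (anyNA(x) || anyNA(y)) stop("missing values in Mann-Whitney input")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  do_exact <- if (is.null(exact)) (n1 <= exact_limit && n2 <= exact_limit)
    else isTRUE(exact)
  if (do_exact) {
    sel <- utils::combn(n1 + n2, n1)
    uvals <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(uvals <= u + eps), mean(uvals >= u - eps)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig <- sqrt(n1 * n2 / 12 *
                  ((n1 + n2 + 1) - sum(ties^3 - ties) /
                     ((n1 + n2) * (n1 + n2 - 1))))
    z <- (u - mu) / sig
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = u, p_value = p, method = method)
}

#' Default clinical covariate roster
#'
#' The variables screened in the univariate analysis, with their test type:
#' continuous variables get a Mann-Whitney U test, categorical (binary 0/1)
#' variables a chi-square test with Fisher fallback when any expected cell
#' count is below 5.
#'
#' @return data.frame with columns `variable`, `type`.
#' @export
tam_covariate_roster <- function() {
  data.frame(
    variable = c("age", "sex_male", "tumor_number", "max_size_mm",
                 "neoadjuvant", "cea_elevated", "ca199_elevated", "t34",
                 "n_positive", "synchronous", "g34", "ras_mutated",
                 "bilobar", "rectum_primary", "mean_tam_area"),
    type = c("continuous", "categorical", "continuous", "continuous",
             "categorical", "categorical", "categorical", "categorical",
             "categorical", "categorical", "categorical", "categorical",
             "categorical", "categorical", "continuous"),
    stringsAsFactors = FALSE)
}

#' Univariate screen of cohort variables against recurrence
#'
#' Produces a Table-2-shaped report: for each variable a per-group summary
#' (median and range for continuous variables, count and percentage of
#' positives for binary ones) and a raw two-sided p-value (Mann-Whitney U
#' for continuous; chi-square, or Fisher's exact test when any expected
#' cell is < 5, for categorical). Percentages are computed from the data at
#' hand, and no multiplicity correction is applied, mirroring conventional
#' univariate screening practice.
#'
#' @param cohort data.frame with one row per patient.
#' @param group_col name of the binary grouping column (default the
#'   recurrence flag `dfs_event`).
#' @param roster data.frame of `variable`/`type` pairs; see
#'   [tam_covariate_roster()]. Variables absent from `cohort` are skipped.
#' @return data.frame: variable, type, test, per-group summaries, p_value.
#' @export
univariate_table <- function(cohort, group_col = "dfs_event",
                             roster = tam_covariate_roster()) {
  stopifnot(is.data.frame(cohort), group_col %in% names(cohort))
  g <- as.logical(cohort[[group_col]])
  if (length(unique(g)) < 2L) stop("grouping column has a single level")
  rows <- list()
  for (k in seq_len(nrow(roster))) {
    vn <- roster$variable[k]; ty <- roster$type[k]
    if (!vn %in% names(cohort)) next
    if (!ty %in% c("continuous", "categorical"))
      stop("unknown variable type '", ty, "' for '", vn, "'")
    v <- cohort[[vn]]
    ok <- !is.na(v) & !is.na(g)
    v <- v[ok]; gg <- g[ok]
    if (ty == "continuous") {
      mw <- suppressWarnings(stats::wilcox.test(v[gg], v[!gg]))
      summ <- function(z) sprintf("%.1f (%.1f-%.1f)", stats::median(z),
                                  min(z), max(z))
      test <- "Mann-Whitney U"
      p <- mw$p.value
    } else {
      tab <- table(factor(v != 0, levels = c(FALSE, TRUE)),
                   factor(gg, levels = c(FALSE, TRUE)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        test <- "Fisher exact"
        p <- stats::fisher.test(tab)$p.value
      } else {
        test <- "chi-square"
        p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
      }
      summ <- function(z) sprintf("%d (%.0f%%)", sum(z != 0),
                                  100 * mean(z != 0))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = vn, type = ty, test = test,
      no_event = summ(v[!gg]), event = summ(v[gg]),
      p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
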