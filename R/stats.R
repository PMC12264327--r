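#' Paired two-tailed t test
#'
#' Classical paired t on the within-pair differences, `df = n - 1`, p from
#' the t distribution (two-sided). Identical vectors (all differences zero)
#' return `t = 0, p = 1`; constant non-zero differences are degenerate (the
#' statistic is infinite) and raise an error.
#'
#' @param x,y paired numeric vectors of equal length `>= 2`.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t_two_tailed <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must be paired vectors of equal length >= 2", call. = FALSE)
  }
  d <- x - y
  if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1))
  if (stats::sd(d) == 0) {
    stop("differences have zero variance: paired t statistic is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#' `df_rounded` rounds the df to an integer for reporting in the
#' conventional `t(df)` style.
#'
#' @param x,y numeric vectors, each of length `>= 2`.
#' @return list with `t`, `df`, `df_rounded`, `p`.
#' @export
welch_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need >= 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both groups have zero variance: Welch t is undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  df <- unname(ht$parameter)
  list(t = unname(ht$statistic), df = df, df_rounded = round(df),
       p = unname(ht$p.value))
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject decomposition for a complete balanced design with two
#' within-subject factors (e.g. 4 skylight colors x 2 outline conditions),
#' one value per cell per subject. Each effect is tested against its own
#' subject-by-effect interaction error term (fitted via `stats::aov` with
#' `Error(subject/(A*B))` strata), giving the conventional df pattern - for
#' 12 subjects and a 4 x 2 design the factor-A test is F(3, 33). Effects
#' whose sum of squares is numerically zero (all cells equal) are reported
#' as `F = 0, p = 1` rather than 0/0.
#'
#' @param data data.frame in long format.
#' @param value,subject,factor_a,factor_b column names.
#' @return data.frame with one row per effect (`A`, `B`, `A:B`): columns
#'   `effect`, `df1`, `df2`, `ss`, `F`, `p`.
#' @export
rm_anova_two_way <- function(data, value = "ci", subject = "observer",
                             factor_a = "skylight", factor_b = "outline") {
  for (col in c(value, subject, factor_a, factor_b)) {
    if (!col %in% names(data)) stop("missing column '", col, "'", call. = FALSE)
  }
  d <- data.frame(
    y = as.numeric(data[[value]]),
    S = factor(data[[subject]]),
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  if (anyNA(d$y)) stop("missing values in '", value, "'", call. = FALSE)
  counts <- table(d$S, d$A, d$B)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    stop("design must be complete and balanced with one value per ",
         "subject x cell; offending cells: ",
         paste(apply(bad, 1, function(i) {
           paste(dimnames(counts)[[1]][i[1]], dimnames(counts)[[2]][i[2]],
                 dimnames(counts)[[3]][i[3]], sep = "/")
         }), collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(y ~ A * B + Error(S / (A * B)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    eff <- tab[rn == term, , drop = FALSE]
    res <- tab[rn == "Residuals", , drop = FALSE]
    ss <- eff[["Sum Sq"]]
    ss_err <- res[["Sum Sq"]]
    df1 <- eff[["Df"]]
    df2 <- res[["Df"]]
    if (ss < 1e-12 * max(ss_err, 1)) {
      Fv <- 0; p <- 1
    } else {
      Fv <- (ss / df1) / (ss_err / df2)
      p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    }
    data.frame(effect = term, df1 = df1, df2 = df2, ss = ss, F = Fv, p = p,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    pull("Error: S:A", "A"),
    pull("Error: S:B", "B"),
    pull("Error: S:A:B", "A:B")
  )
  out$effect <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  rownames(out) <- NULL
  out
}
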