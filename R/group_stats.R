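#' Attach stage/organ metadata to per-character indices
#'
#' Joins a per-character index table (e.g. [character_stats()] or the
#' `per_character` element of [average_over_trees()]) with character
#' metadata and adds the numeric stage code D (egg = 1, L1 = 2, L2 = 3,
#' L3 = 4, pupa = 5, adult = 6; `stage_offset` shifts the origin for
#' sensitivity analyses).
#'
#' @param stats tibble with `char_id` and index columns
#' @param char_meta tibble with `char_id`, `stage`, `organ`
#' @param stage_offset constant added to D - 1 (default 1, so D starts at 1)
#' @return tibble with added `stage`, `organ`, `D`
#' @export
stage_series <- function(stats, char_meta, stage_offset = 1) {
  out <- dplyr::left_join(stats,
                          dplyr::select(char_meta, "char_id", "stage",
                                        "organ"),
                          by = "char_id")
  out$stage <- factor(out$stage, levels = STAGE_LEVELS)
  out$D <- as.integer(out$stage) - 1L + stage_offset
  out
}

#' Kruskal-Wallis rank-sum test of an index across groups
#'
#' Thin wrapper over [stats::kruskal.test()] (rank-based statistic with tie
#' correction, df = groups - 1) that returns a tidy one-row tibble.
#'
#' @param values numeric vector
#' @param groups group labels, same length
#' @return tibble with `statistic`, `df`, `p_value`, `n`, `n_groups`
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  kt <- kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value,
                 n = length(values), n_groups = nlevels(groups))
}

#' Wilcoxon rank-sum test between two groups
#'
#' Wrapper over [stats::wilcox.test()] (Mann-Whitney, normal approximation
#' with tie correction for large samples). W is the rank-sum statistic of
#' the first group.
#'
#' @param a,b numeric vectors (first group, second group)
#' @return tibble with `W`, `p_value`, `n_a`, `n_b`
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b))
  tibble::tibble(W = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(a), n_b = length(b))
}

#' Stage and organ tests of per-character homoplasy
#'
#' Runs the three standard comparisons on a [stage_series()] table: the
#' chosen index across the six developmental stages (Kruskal-Wallis), across
#' the five adult body parts (Kruskal-Wallis), and terminalia (male +
#' female) versus somatic organs (head + thorax + abdomen; Wilcoxon, with
#' terminalia as the first group).
#'
#' @param series a [stage_series()] tibble
#' @param index column to test (default `"r_ic"`, the retention index with
#'   autapomorphic-only characters set to 1)
#' @param autapomorphies `"include"` keeps every character with a defined
#'   index value; `"exclude"` drops autapomorphic-only characters first
#'   (requires an `autapomorphic_only` column)
#' @return tibble with one row per test (`test`, `statistic`, `df`,
#'   `p_value`, `n`)
#' @export
stage_organ_tests <- function(series, index = "r_ic",
                              autapomorphies = c("include", "exclude")) {
  autapomorphies <- match.arg(autapomorphies)
  if (autapomorphies == "exclude") {
    series <- dplyr::filter(series, !.data$autapomorphic_only)
  }
  y <- series[[index]]
  keep <- !is.na(y)
  series <- series[keep, ]
  y <- y[keep]
  kw_stage <- kruskal_wallis(y, series$stage)
  adult <- series$stage == "adult" & !is.na(series$organ) &
    series$organ != "none"
  kw_organ <- kruskal_wallis(y[adult], series$organ[adult])
  term <- adult & series$organ %in% c("male_terminalia", "female_terminalia")
  soma <- adult & series$organ %in% c("head", "thorax", "abdomen")
  wx <- wilcoxon_rank_sum(y[term], y[soma])
  tibble::tibble(
    test = c("stage_kruskal_wallis", "organ_kruskal_wallis",
             "terminalia_vs_somatic_wilcoxon"),
    statistic = c(kw_stage$statistic, kw_organ$statistic, wx$W),
    df = c(kw_stage$df, kw_organ$df, NA_real_),
    p_value = c(kw_stage$p_value, kw_organ$p_value, wx$p_value),
    n = c(kw_stage$n, kw_organ$n, wx$n_a + wx$n_b)
  )
}

#' Developmental-hourglass regression
#'
#' Least-squares fits of a per-character index on the stage code D, linear
#' (`y ~ D`) and quadratic (`y ~ D + D^2`), compared by AIC (full Gaussian
#' log-likelihood, as [stats::AIC()] computes it). A concave quadratic with a
#' vertex at intermediate stages — the minimum of homoplasy resistance in
#' mid-development — is the hourglass signature.
#'
#' @param series a [stage_series()] tibble
#' @param index column to regress (default `"r_ic"`)
#' @return object of class `hourglass_fit`: list with `quadratic` and
#'   `linear` `lm` fits, `aic_quadratic`, `aic_linear`, `delta_aic`
#'   (linear - quadratic; positive favours the quadratic), `vertex`
#'   (stage code at the fitted extremum, -b/2c), `p_quadratic` (t-test
#'   p-value of the squared term) and `n`
#' @export
hourglass_regression <- function(series, index = "r_ic") {
  df <- tibble::tibble(y = series[[index]], D = series$D)
  df <- df[complete.cases(df), ]
  if (length(unique(df$D)) < 3) stop("need >= 3 distinct stage codes")
  quad <- lm(y ~ D + I(D^2), data = df)
  lin <- lm(y ~ D, data = df)
  cf <- coef(quad)
  structure(list(
    quadratic = quad, linear = lin,
    coefficients = cf,
    aic_quadratic = AIC(quad), aic_linear = AIC(lin),
    delta_aic = AIC(lin) - AIC(quad),
    vertex = unname(-cf[2] / (2 * cf[3])),
    p_quadratic = summary(quad)$coefficients["I(D^2)", 4],
    n = nrow(df)
  ), class = "hourglass_fit")
}

#' @export
print.hourglass_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<hourglass_fit> y = %.3f %+.3f D %+.3f D^2  (n = %d)\n",
              cf[1], cf[2], cf[3], x$n))
  cat(sprintf("  AIC quadratic %.2f vs linear %.2f (delta %.2f); vertex D* = %.2f; P(D^2) = %.3g\n",
              x$aic_quadratic, x$aic_linear, x$delta_aic, x$vertex,
              x$p_quadratic))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.hourglass_fit <- function(x, ...) {
  sq <- summary(x$quadratic)$coefficients
  sl <- summary(x$linear)$coefficients
  dplyr::bind_rows(
    tibble::tibble(model = "quadratic", term = rownames(sq),
                   estimate = sq[, 1], std_error = sq[, 2],
                   statistic = sq[, 3], p_value = sq[, 4]),
    tibble::tibble(model = "linear", term = rownames(sl),
                   estimate = sl[, 1], std_error = sl[, 2],
                   statistic = sl[, 3], p_value = sl[, 4])
  )
}

#' @export
glance.hourglass_fit <- function(x, ...) {
  tibble::tibble(
    aic_quadratic = x$aic_quadratic, aic_linear = x$aic_linear,
    delta_aic = x$delta_aic, vertex = x$vertex,
    p_quadratic = x$p_quadratic,
    r_squared = summary(x$quadratic)$r.squared, n = x$n
  )
}

#' @export
tidy.permutation_null <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null), HI = x$null)
}

#' @export
glance.permutation_null <- function(x, ...) {
  tibble::tibble(observed_HI = x$observed, null_mean = x$null_mean,
                 null_sd = x$null_sd, p_value = x$p_value, n_perm = x$n_perm)
}

#' @export
tidy.tree_averaged_indices <- function(x, ...) x$per_tree

#' @export
glance.tree_averaged_indices <- function(x, ...) x$summary
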