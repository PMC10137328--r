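#' Mean and standard error of a group sample
#'
#' SEM is the sample standard deviation (n - 1 denominator) over the square
#' root of n; it is reported as `NA` for a single observation.
#'
#' @param x numeric vector of per-object metric values (finite, n >= 1).
#' @return list with `mean`, `sem`, `n`.
#' @export
summarize_group <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty sample")
  if (any(!is.finite(x))) stop("sample values must be finite")
  n <- length(x)
  list(mean = mean(x), sem = if (n > 1) sd(x) / sqrt(n) else NA_real_, n = n)
}

#' One-way fixed-effects ANOVA across groups
#'
#' Classical F test of equal group means, as used to compare the three
#' treatment groups (e.g. NTG, APP/PS1, APP/PS1 + CP2).
#'
#' @param samples named list of numeric vectors, one per group; every group
#'   needs at least 2 observations.
#' @return object of class `test_result`: `test`, `statistic` (F),
#'   `df` (between, within), `p_value`, `groups`.
#' @export
one_way_anova <- function(samples) {
  if (!is.list(samples) || length(samples) < 2)
    stop("need a list of at least 2 groups")
  nm <- names(samples) %||% paste0("group", seq_along(samples))
  nm[nm == ""] <- paste0("group", which(nm == ""))
  sizes <- lengths(samples)
  if (any(sizes < 2))
    stop("group '", nm[which(sizes < 2)[1]], "' has fewer than 2 values")
  df <- data.frame(
    value = unlist(samples, use.names = FALSE),
    group = factor(rep(nm, sizes), levels = nm)
  )
  a <- anova(lm(value ~ group, data = df))
  structure(list(test = "one-way ANOVA", statistic = a[["F value"]][1],
                 df = c(a$Df[1], a$Df[2]), p_value = a[["Pr(>F)"]][1],
                 direction = NA_character_, groups = nm),
            class = "test_result")
}

#' One-sided unpaired Student's t-test
#'
#' Pooled-variance (Student) unpaired t-test by default, matching the named
#' test; Welch's unequal-variance form is available via `var_equal = FALSE`,
#' and a two-sided p-value via `two_sided = TRUE`. The direction of the
#' one-sided alternative must be stated explicitly: `"greater"` tests
#' mean(a) > mean(b), `"less"` tests mean(a) < mean(b). When both samples
#' are constant and equal the statistic is defined as 0 with one-sided
#' p = 0.5, flagged.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param direction `"greater"` or `"less"` (alternative for mean(a) vs
#'   mean(b)); required.
#' @param var_equal pooled variance (default) or Welch.
#' @param two_sided report the two-sided p instead.
#' @return object of class `test_result`: `test`, `statistic` (t), `df`,
#'   `p_value`, `direction`, `flags`.
#' @export
one_sided_t <- function(a, b, direction = c("greater", "less"),
                        var_equal = TRUE, two_sided = FALSE) {
  direction <- match.arg(direction)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  flags <- character(0)
  pooled_var <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(test = "one-sided unpaired t", statistic = 0,
                            df = length(a) + length(b) - 2,
                            p_value = if (two_sided) 1 else 0.5,
                            direction = direction,
                            flags = "zero_pooled_variance"),
                       class = "test_result"))
    }
    bigger <- mean(a) > mean(b)
    p <- if (two_sided) 0 else if ((direction == "greater") == bigger) 0 else 1
    return(structure(list(test = "one-sided unpaired t",
                          statistic = if (bigger) Inf else -Inf,
                          df = length(a) + length(b) - 2, p_value = p,
                          direction = direction,
                          flags = "zero_pooled_variance"),
                     class = "test_result"))
  }
  alt <- if (two_sided) "two.sided" else direction
  tt <- stats::t.test(a, b, alternative = alt, var.equal = var_equal)
  structure(list(test = if (var_equal) "one-sided unpaired t (pooled)"
                        else "one-sided unpaired t (Welch)",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, direction = direction, flags = flags),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, df %s, p = %.4g\n",
              x$test, x$statistic, paste(x$df, collapse = "/"), x$p_value))
  invisible(x)
}

#' All pairwise one-sided t-tests between groups
#'
#' Runs [one_sided_t()] for every ordered pair implied by `direction` and
#' returns one row per comparison. No multiple-testing correction is applied
#' by default (per-comparison tests are reported as such); Holm's step-down
#' correction is available via `adjust = "holm"` and the chosen policy is
#' recorded in the output.
#'
#' @param samples named list of numeric vectors (each n >= 2).
#' @param direction `"greater"` or `"less"`, applied as first-named vs
#'   second-named group for every pair.
#' @param adjust `"none"` (default) or `"holm"`.
#' @param var_equal pooled variance (default) or Welch.
#' @return data.frame with `group_a`, `group_b`, `statistic`, `df`,
#'   `p_value`, `p_adjusted`, `direction`, `adjust`.
#' @export
pairwise_tests <- function(samples, direction = c("greater", "less"),
                           adjust = c("none", "holm"), var_equal = TRUE) {
  direction <- match.arg(direction)
  adjust <- match.arg(adjust)
  nm <- names(samples)
  if (is.null(nm) || any(nm == ""))
    stop("samples must be a fully named list")
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    r <- one_sided_t(samples[[p[1]]], samples[[p[2]]], direction,
                     var_equal = var_equal)
    data.frame(group_a = p[1], group_b = p[2], statistic = r$statistic,
               df = r$df, p_value = r$p_value, direction = direction)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "holm") stats::p.adjust(out$p_value, "holm")
                    else out$p_value
  out$adjust <- adjust
  out
}
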