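#' Group summary (n, mean, SD)
#'
#' @param label group label.
#' @param n sample size (>= 2).
#' @param mean,sd group mean and standard deviation.
#' @return list of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(label = label, n = n, mean = mean, sd = sd),
            class = "group_summary")
}

#' Pooled-variance two-sample t-test from group summaries
#'
#' Computes the classical equal-variance two-sample t statistic from
#' summary statistics, with df = n1 + n2 - 2 and a two-sided p-value.
#'
#' @param a,b [group_summary()] objects.
#' @return list with `t`, `df`, `p`, and `degenerate` (TRUE when the pooled
#'   SD is zero: t is 0 for equal means, +/-Inf otherwise).
#' @export
pooled_t_test <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  dm <- a$mean - b$mean
  if (sp2 == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
    return(list(t = t, df = df, p = if (dm == 0) 1 else 0, degenerate = TRUE))
  }
  t <- dm / (sqrt(sp2) * sqrt(1 / a$n + 1 / b$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Paired t-test
#'
#' Standard paired t on the within-pair differences `after - before`,
#' df = n - 1, two-sided p.
#'
#' @param before,after equal-length paired numeric vectors (n >= 2).
#' @return list with `t`, `df`, `p`, `mean_diff`, and `degenerate` (TRUE
#'   when the differences have zero variance).
#' @export
paired_t_test <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  d <- after - before
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    return(list(t = t, df = n - 1, p = if (md == 0) 1 else 0,
                mean_diff = md, degenerate = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = md, degenerate = FALSE)
}

#' Body condition index
#'
#' Mass-to-length ratio: body mass (g) over nose-anus length (cm).
#'
#' @param mass_g body mass in grams (>= 0).
#' @param length_cm nose-anus length in cm (> 0).
#' @return condition index, g/cm.
#' @export
body_condition_index <- function(mass_g, length_cm) {
  if (any(length_cm <= 0)) stop("length must be positive", call. = FALSE)
  stopifnot(all(mass_g >= 0))
  mass_g / length_cm
}

#' Univariate group comparisons for a cohort metadata table
#'
#' Reproduces the habitat comparisons of body mass (before/after housing),
#' body condition index, weight change within habitat (paired), and, when
#' supplied, time spent outside the nest box.
#'
#' @param metadata metadata table with `id`, `habitat`, `mass_start_g`,
#'   `mass_end_g`, `length_cm`.
#' @param time_outside_h optional named-by-id numeric vector of mean hours
#'   outside the nest box per measurement day.
#' @return data.frame with one row per comparison: `comparison`, `test`,
#'   `t`, `df`, `p`.
#' @export
group_stats_report <- function(metadata, time_outside_h = NULL) {
  g <- split(metadata, metadata$habitat)
  stopifnot(all(c("forest", "urban") %in% names(g)))
  smry <- function(x, lab) group_summary(lab, length(x), mean(x), stats::sd(x))
  cmp <- function(name, xf, xu) {
    r <- pooled_t_test(smry(xf, "forest"), smry(xu, "urban"))
    data.frame(comparison = name, test = "pooled t", t = r$t, df = r$df,
               p = r$p)
  }
  rows <- list(
    cmp("body_mass_before", g$forest$mass_start_g, g$urban$mass_start_g),
    cmp("body_mass_after", g$forest$mass_end_g, g$urban$mass_end_g),
    cmp("bci_before",
        body_condition_index(g$forest$mass_start_g, g$forest$length_cm),
        body_condition_index(g$urban$mass_start_g, g$urban$length_cm)),
    cmp("bci_after",
        body_condition_index(g$forest$mass_end_g, g$forest$length_cm),
        body_condition_index(g$urban$mass_end_g, g$urban$length_cm))
  )
  for (hb in c("forest", "urban")) {
    r <- paired_t_test(g[[hb]]$mass_start_g, g[[hb]]$mass_end_g)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste0("weight_change_", hb), test = "paired t",
      t = r$t, df = r$df, p = r$p)
  }
  if (!is.null(time_outside_h)) {
    to <- time_outside_h[metadata$id]
    rows[[length(rows) + 1]] <-
      cmp("time_outside", to[metadata$habitat == "forest"],
          to[metadata$habitat == "urban"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
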