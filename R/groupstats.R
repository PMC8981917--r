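# shared validation for long measurement tables
check_table <- function(table, min_n = 2L) {
  if (!is.data.frame(table)) stop("table must be a data.frame")
  need <- c("group", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(table$group)) stop("missing group labels")
  if (anyNA(table$value)) stop("missing values")
  groups <- split(table$value, table$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < min_n))
    stop(sprintf("every group needs >= %d values (smallest has %d)",
                 min_n, min(ns)))
  groups
}

#' Normality / homoscedasticity gate
#'
#' Chooses the parametric or non-parametric branch of the battery:
#' parametric only if the group-centred residuals pass Shapiro-Wilk at
#' `alpha` and Levene's test (median-centred) passes at `alpha`.
#' Normality is assessed on the pooled residuals rather than per group:
#' testing k groups separately compounds to a 1 - 0.95^k false-alarm
#' rate under normality, and it is the residual distribution that the
#' one-way model assumes.  A zero-variance group forces the
#' non-parametric route with a warning.  The gate is advisory; either
#' branch can be run directly.
#'
#' @param table Long data.frame with columns `group`, `value`.
#' @param alpha Gate level (default 0.05).
#' @return List: `route` ("parametric"/"nonparametric"), `shapiro_p`
#'   (pooled residuals), `levene_p`.
#' @export
normality_gate <- function(table, alpha = 0.05) {
  groups <- check_table(table, min_n = 3L)
  if (any(vapply(groups, stats::var, 0) == 0)) {
    warning("zero-variance group: forcing non-parametric route")
    return(list(route = "nonparametric",
                shapiro_p = NA_real_, levene_p = NA_real_))
  }
  resid <- unlist(lapply(groups, function(v) v - mean(v)), use.names = FALSE)
  sw <- stats::shapiro.test(resid)$p.value
  lev <- car::leveneTest(table$value, factor(table$group))
  lev_p <- lev[["Pr(>F)"]][1]
  route <- if (sw > alpha && lev_p > alpha) "parametric" else "nonparametric"
  list(route = route, shapiro_p = sw, levene_p = lev_p)
}

# assemble the common comparison object
new_group_comparison <- function(method, statistic, p_value, pairwise_p,
                                 alpha, group_means) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 pairwise_p = pairwise_p,
                 letters = compact_letters(pairwise_p, alpha),
                 alpha = alpha, group_means = group_means),
            class = "group_comparison")
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Parametric branch of the battery: one-way F test, pairwise Tukey
#' honest-significant-difference p-values from the studentized-range
#' distribution, and a compact letter display.
#'
#' @param table Long data.frame with columns `group`, `value`.
#' @param alpha Significance level for the letters (default 0.05).
#' @return Object of class `group_comparison`: `method`, `statistic`
#'   (F), `p_value`, `pairwise_p` (symmetric, unit diagonal),
#'   `letters`, `alpha`.
#' @export
anova_tukey <- function(table, alpha = 0.05) {
  groups <- check_table(table, min_n = 2L)
  if (stats::var(table$value) == 0) stop("all values identical")
  g <- names(groups)
  df <- data.frame(value = table$value, group = factor(table$group, levels = g))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  pmat <- diag(1, length(g)); dimnames(pmat) <- list(g, g)
  tk <- stats::TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  new_group_comparison("anova_tukey",
                       statistic = an[["F value"]][1],
                       p_value = an[["Pr(>F)"]][1],
                       pairwise_p = pmat, alpha = alpha,
                       group_means = vapply(groups, mean, 0))
}

#' Kruskal-Wallis with Conover-Iman post-hoc
#'
#' Non-parametric branch: tie-corrected Kruskal-Wallis H with a
#' chi-square p-value (df = k - 1), followed by Conover-Iman pairwise
#' comparisons -- t statistics on the pooled ranks with the pooled rank
#' variance and N - k degrees of freedom.
#'
#' @param table Long data.frame with columns `group`, `value`.
#' @param alpha Significance level for the letters (default 0.05).
#' @param p_adjust Multiplicity adjustment for the pairwise p-values
#'   (a [stats::p.adjust()] method; default `"none"`, `"holm"`
#'   available).
#' @return Object of class `group_comparison` (statistic is H).
#' @export
kruskal_conover <- function(table, alpha = 0.05, p_adjust = "none") {
  groups <- check_table(table, min_n = 2L)
  if (stats::var(table$value) == 0) stop("all values identical")
  g <- names(groups)
  ns <- lengths(groups)
  N <- sum(ns); k <- length(g)
  if (N < 5) warning("total n < 5: asymptotic p-values unreliable")

  kw <- stats::kruskal.test(table$value, factor(table$group, levels = g))
  H <- unname(kw$statistic)

  r <- rank(table$value)                       # average ranks on ties
  rbar <- vapply(split(r, factor(table$group, levels = g)), mean, 0)
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  scale2 <- s2 * (N - 1 - H) / (N - k)
  pmat <- diag(1, k); dimnames(pmat) <- list(g, g)
  praw <- c(); labs <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tstat <- (rbar[i] - rbar[j]) / sqrt(scale2 * (1 / ns[i] + 1 / ns[j]))
    praw <- c(praw, 2 * stats::pt(-abs(tstat), df = N - k))
    labs <- c(labs, paste(i, j))
  }
  padj <- stats::p.adjust(praw, method = p_adjust)
  idx <- 1L
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pmat[i, j] <- pmat[j, i] <- padj[idx]; idx <- idx + 1L
  }
  new_group_comparison("kruskal_conover",
                       statistic = H, p_value = unname(kw$p.value),
                       pairwise_p = pmat, alpha = alpha,
                       group_means = vapply(groups, mean, 0))
}

#' Compare groups, routing by the normality gate
#'
#' @param table Long data.frame with `group`, `value`.
#' @param method `"auto"` (route via [normality_gate()]), `"anova"` or
#'   `"kw"`.
#' @param alpha Significance level.
#' @param ... Passed to the chosen test.
#' @return A `group_comparison`; `$route` records the gate decision
#'   when `method = "auto"`.
#' @export
compare_groups <- function(table, method = c("auto", "anova", "kw"),
                           alpha = 0.05, ...) {
  method <- match.arg(method)
  route <- NULL
  if (method == "auto") {
    gate <- normality_gate(table, alpha)
    route <- gate$route
    method <- if (gate$route == "parametric") "anova" else "kw"
  }
  out <- if (method == "anova") anova_tukey(table, alpha, ...)
         else kruskal_conover(table, alpha, ...)
  out$route <- route
  out
}

#' Spearman rank correlation matrix with Bonferroni correction
#'
#' Spearman's rho as the Pearson correlation of average ranks, computed
#' on pairwise-complete observations; raw p-values from the
#' t approximation; Bonferroni adjustment across all unique
#' off-diagonal pairs.  A constant variable yields NA for its pairs.
#'
#' @param data data.frame of numeric variables (columns).
#' @param variables Optional subset of column names.
#' @return Object of class `correlation_matrix`: `variables`, `rho`,
#'   `p_raw`, `p_adjusted`, `n` (pairwise complete counts),
#'   `m_comparisons`.
#' @export
spearman_matrix <- function(data, variables = NULL) {
  if (!is.null(variables)) data <- data[, variables, drop = FALSE]
  data <- as.data.frame(data)
  v <- names(data)
  p <- length(v)
  if (p < 2) stop("need at least 2 variables")
  rho <- diag(1, p); praw <- matrix(NA_real_, p, p); nmat <- matrix(NA_real_, p, p)
  dimnames(rho) <- dimnames(praw) <- dimnames(nmat) <- list(v, v)
  diag(praw) <- 0
  m <- p * (p - 1) / 2
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    x <- data[[i]]; y <- data[[j]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    if (n < 3 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      rho[i, j] <- rho[j, i] <- NA_real_
      next
    }
    r <- stats::cor(rank(x[ok]), rank(y[ok]))
    rho[i, j] <- rho[j, i] <- r
    if (abs(r) >= 1) {
      praw[i, j] <- praw[j, i] <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      praw[i, j] <- praw[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  padj <- praw
  padj[] <- pmin(m * praw, 1)
  diag(padj) <- 0
  structure(list(variables = v, rho = rho, p_raw = praw,
                 p_adjusted = padj, n = nmat, m_comparisons = m),
            class = "correlation_matrix")
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb assignment: groups sharing any letter are not
#' significantly different (pairwise p >= alpha) and groups sharing no
#' letter differ (p < alpha), exactly.
#'
#' @param pairwise_p Symmetric p-value matrix with group dimnames.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(pairwise_p, alpha = 0.05) {
  k <- nrow(pairwise_p)
  g <- rownames(pairwise_p)
  if (is.null(g)) g <- paste0("g", seq_len(k))
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (is.na(pairwise_p[i, j]) || pairwise_p[i, j] >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop any set contained in another (first copy wins on ties)
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      if (length(new_sets[[a]]) == 0) { keep[a] <- FALSE; next }
      for (b in seq_along(new_sets)) {
        if (a == b || !keep[b]) next
        subset_ab <- all(new_sets[[a]] %in% new_sets[[b]])
        proper <- subset_ab && length(new_sets[[a]]) < length(new_sets[[b]])
        duplicate <- subset_ab && length(new_sets[[a]]) == length(new_sets[[b]]) && a > b
        if (proper || duplicate) { keep[a] <- FALSE; break }
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[order(vapply(sets, min, 0))]
  out <- vapply(seq_len(k), function(grp) {
    paste(letters[which(vapply(sets, function(s) grp %in% s, TRUE))],
          collapse = "")
  }, "")
  names(out) <- g
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (x$method == "anova_tukey") "One-way ANOVA + Tukey HSD (F"
         else "Kruskal-Wallis + Conover-Iman (H"
  cat(sprintf("%s = %.4g, p = %.4g)\n", lab, x$statistic, x$p_value))
  df <- data.frame(group = names(x$letters),
                   mean = round(unname(x$group_means), 4),
                   letters = unname(x$letters))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Spearman correlation matrix (%d variables, Bonferroni m = %d)\n",
              length(x$variables), x$m_comparisons))
  print(round(x$rho, 3))
  invisible(x)
}
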