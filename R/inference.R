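#' Two-sample Student t-test
#'
#' Classical equal-variance two-sided test (Welch available via
#' `welch = TRUE`); the unqualified "two-sample t-test" convention.
#'
#' @param a,b numeric vectors (at least 2 values each).
#' @param welch use the Welch-Satterthwaite unequal-variance form.
#' @return List with `t`, `p` and `df`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) stop("need >= 2 values per group", call. = FALSE)
  va <- var(a)
  vb <- var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) stop("zero variance in both groups", call. = FALSE)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    t <- (mean(a) - mean(b)) / sqrt(se2)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
    df <- na + nb - 2
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q`: flags are `TRUE` for every p-value no
#' larger than the largest `p_(k)` with `p_(k) <= k q / m`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q FDR level.
#' @return Logical vector of significance flags, aligned with `pvalues`.
#' @export
fdr_correct <- function(pvalues, q = 0.01) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  m <- sum(!is.na(pvalues))
  flags <- rep(FALSE, length(pvalues))
  if (m == 0L) return(flags)
  ok <- which(!is.na(pvalues))
  p <- pvalues[ok]
  o <- order(p)
  passed <- which(p[o] <= seq_len(m) * q / m)
  if (length(passed)) {
    cut <- p[o][max(passed)]
    flags[ok] <- p <= cut
  }
  flags
}

#' Permutation test on a difference of group means
#'
#' Observed statistic `mean(a) - mean(b)`; for each of `P` random group
#' relabelings the statistic is recomputed, and
#' `p = (1 + #(|d_perm| >= |d_obs|)) / (P + 1)` (add-one convention, so the
#' smallest attainable p is `1/(P+1)`).
#'
#' @param a,b numeric vectors.
#' @param P permutation count.
#' @param seed integer seed of the permutation substream.
#' @return List with `delta` (observed difference) and `p`.
#' @export
permutation_test_difference <- function(a, b, P = 100L, seed = 1L) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  stopifnot(P >= 1L, length(a) >= 1L, length(b) >= 1L)
  pool <- c(a, b)
  na <- length(a)
  n <- length(pool)
  d_obs <- mean(a) - mean(b)
  total <- sum(pool)
  exceed <- with_stage_seed(seed, {
    cnt <- 0L
    for (i in seq_len(P)) {
      ia <- sample.int(n, na)
      sa <- sum(pool[ia])
      d <- sa / na - (total - sa) / (n - na)
      if (abs(d) >= abs(d_obs) - 1e-15) cnt <- cnt + 1L
    }
    cnt
  })
  list(delta = d_obs, p = (1 + exceed) / (P + 1))
}

#' Spearman rank correlation
#'
#' Average ranks for ties; two-sided p-value from the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom. Incomplete
#' pairs are dropped.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `rho`, `p` and `n` (complete pairs used).
#' @export
spearman_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  rho <- cor(rank(x), rank(y))
  if (is.na(rho)) stop("constant ranks: correlation undefined", call. = FALSE)
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(t), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  n <- na + nb
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  list(U = U, z = z, p = 2 * pnorm(-abs(z)))
}

chi_square_2x2 <- function(tab, correct = FALSE) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expd == 0)) return(list(statistic = 0, p = 1))
  dev <- abs(tab - expd)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expd)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Demographics comparison table
#'
#' Sex by 2x2 chi-square (no continuity correction, switchable); age and
#' education by Mann-Whitney U with normal approximation and tie
#' correction. Covariates entirely missing in either group are skipped with
#' a WARN log line.
#'
#' @param manifest a subject manifest (see [read_manifest()]).
#' @param yates apply the Yates continuity correction to the sex table.
#' @return Data frame with columns `variable`, `test`, `statistic`, `p`.
#' @export
demographics_table <- function(manifest, yates = FALSE) {
  g <- manifest$group
  stopifnot(all(c("patient", "control") %in% g))
  rows <- list()
  if (!is.null(manifest$sex)) {
    tab <- table(factor(g, c("patient", "control")),
                 factor(manifest$sex))
    if (ncol(tab) == 2L) {
      cs <- chi_square_2x2(unclass(tab), correct = yates)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = "sex", test = "chi_square",
        statistic = cs$statistic, p = cs$p)
    }
  }
  for (v in c("age", "education")) {
    if (is.null(manifest[[v]])) next
    a <- manifest[[v]][g == "patient"]
    b <- manifest[[v]][g == "control"]
    if (all(is.na(a)) || all(is.na(b))) {
      log_msg("WARN", sprintf("covariate %s all-missing in a group; skipped", v))
      next
    }
    mw <- mann_whitney_u(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = "mann_whitney_u", statistic = mw$U, p = mw$p)
  }
  do.call(rbind, rows)
}

metric_families <- c("eglo", "eloc", "cp", "lp", "gamma", "lambda", "sigma")

profiles_long <- function(profiles) {
  do.call(rbind, lapply(profiles, function(pr) {
    m <- pr$metrics
    out <- do.call(rbind, lapply(metric_families, function(f) {
      data.frame(subject_id = pr$subject_id, sparsity = m$sparsity,
                 metric = f, value = m[[f]], stringsAsFactors = FALSE)
    }))
    out
  }))
}

#' Full between-group comparison
#'
#' Per metric and sparsity level, a two-sample t-test (patient vs control)
#' with Benjamini-Hochberg FDR at `config$fdr_q` applied within each
#' metric's family of sparsity levels; permutation tests
#' (`config$n_permutations` label permutations) on the three connection-
#' strength classes; and Spearman correlations of each network summary
#' (grid-mean of each metric and the class strengths) against disease
#' duration and ACTH within the patient group. Metric families that are
#' entirely `NA` (e.g. gamma/lambda/sigma when profiles were computed
#' without null models) are omitted.
#'
#' @param profiles list of `metric_profile` objects (all subjects).
#' @param strengths data frame with columns `subject_id`, `rich_club`,
#'   `feeder`, `local` (from [connection_strengths()]), or `NULL` to skip.
#' @param manifest the cohort manifest.
#' @param config an [analysis_config()].
#' @return A `group_comparison`: list of data frames `metrics` (metric,
#'   sparsity, t, p, fdr_significant), `strengths` (class, delta, p),
#'   `demographics`, and `spearman` (parameter, clinical, rho, p, n).
#' @export
compare_groups <- function(profiles, strengths = NULL, manifest,
                           config = analysis_config()) {
  validate_config(config)
  grp <- manifest$group
  names(grp) <- manifest$subject_id
  long <- profiles_long(profiles)
  long$group <- grp[long$subject_id]
  if (anyNA(long$group)) {
    stop("profiles contain subjects missing from the manifest", call. = FALSE)
  }

  metric_rows <- list()
  for (f in unique(long$metric)) {
    sub <- long[long$metric == f, ]
    if (all(is.na(sub$value))) next
    levels_s <- sort(unique(sub$sparsity))
    tt <- lapply(levels_s, function(s) {
      sl <- sub[sub$sparsity == s, ]
      a <- sl$value[sl$group == "patient"]
      b <- sl$value[sl$group == "control"]
      # levels where a metric is undefined for most subjects are skipped
      if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L) return(NULL)
      r <- two_sample_t(a, b)
      data.frame(metric = f, sparsity = s, t = r$t, p = r$p)
    })
    fam <- do.call(rbind, tt)
    if (is.null(fam)) next
    fam$fdr_significant <- fdr_correct(fam$p, config$fdr_q)
    metric_rows[[f]] <- fam
  }
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL

  strength_tab <- NULL
  if (!is.null(strengths)) {
    # canonical subject order so results are invariant to input ordering
    strengths <- strengths[order(strengths$subject_id), ]
    sgrp <- grp[strengths$subject_id]
    # permutation substream keyed on sorted subject ids for order invariance
    key <- string_index(paste(sort(strengths$subject_id), collapse = ","))
    strength_tab <- do.call(rbind, lapply(
      c("rich_club", "feeder", "local"), function(cls) {
        pt <- permutation_test_difference(
          strengths[[cls]][sgrp == "patient"],
          strengths[[cls]][sgrp == "control"],
          P = config$n_permutations,
          seed = stage_seed(config$seed, paste0("perm_", cls), key))
        data.frame(class = cls, delta = pt$delta, p = pt$p)
      }))
  }

  demo <- demographics_table(manifest)

  spear <- NULL
  pat <- manifest[manifest$group == "patient", ]
  clin_vars <- intersect(c("duration", "acth"), names(pat))
  if (length(clin_vars)) {
    summaries <- list()
    for (f in unique(long$metric)) {
      sub <- long[long$metric == f & long$group == "patient", ]
      if (all(is.na(sub$value))) next
      summaries[[f]] <- tapply(sub$value, sub$subject_id,
                               mean, na.rm = TRUE)
    }
    if (!is.null(strengths)) {
      for (cls in c("rich_club", "feeder", "local")) {
        v <- strengths[[cls]]
        names(v) <- strengths$subject_id
        summaries[[paste0("strength_", cls)]] <- v
      }
    }
    rows <- list()
    for (pn in names(summaries)) {
      for (cv in clin_vars) {
        x <- summaries[[pn]][pat$subject_id]
        y <- pat[[cv]]
        ok <- sum(!is.na(x) & !is.na(y))
        if (ok < 3L) next
        sc <- spearman_correlation(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = pn, clinical = cv, rho = sc$rho, p = sc$p, n = sc$n)
      }
    }
    spear <- do.call(rbind, rows)
  }

  structure(list(metrics = metrics, strengths = strength_tab,
                 demographics = demo, spearman = spear,
                 config = config),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  if (!is.null(x$metrics)) {
    sig <- tapply(x$metrics$fdr_significant, x$metrics$metric, sum)
    cat("  FDR-flagged sparsity levels per metric:\n")
    for (nm in names(sig)) cat(sprintf("    %-8s %d\n", nm, sig[[nm]]))
  }
  if (!is.null(x$strengths)) {
    cat("  connection-strength permutation tests:\n")
    for (i in seq_len(nrow(x$strengths))) {
      cat(sprintf("    %-10s delta = %8.4f  p = %.4f\n",
                  x$strengths$class[i], x$strengths$delta[i],
                  x$strengths$p[i]))
    }
  }
  invisible(x)
}
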