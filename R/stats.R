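#' Group difference adjusted for age (OLS)
#'
#' Ordinary least squares \code{y ~ intercept + group + age}: the group
#' coefficient (case minus control), its t statistic and two-tailed
#' p-value. This is the model used for pit-count and per-cluster
#' pit-depth comparisons. A constant response returns a zero effect with
#' p = 1, flagged \code{constant}.
#'
#' @param y numeric response, one value per subject.
#' @param records data frame with columns \code{group} (values "case" /
#'   "control") and \code{age} (years), rows aligned with \code{y}.
#' @return one-row data frame: estimate, t, p, n, note.
#' @export
group_age_regression <- function(y, records) {
  y <- as.numeric(y)
  if (length(y) != nrow(records)) stop("y and records are not aligned")
  grp <- factor(records$group, levels = c("control", "case"))
  if (anyNA(grp)) stop("group must be 'case' or 'control' for every subject")
  if (anyNA(y)) stop("missing responses; subset before calling")
  if (min(table(grp)) < 3L) stop("need at least 3 subjects per group")
  if (stats::var(y) == 0)
    return(data.frame(estimate = 0, t = 0, p = 1, n = length(y), note = "constant",
                      stringsAsFactors = FALSE))
  fit <- stats::lm(y ~ grp + age, data = data.frame(grp = grp, age = records$age))
  co <- summary(fit)$coefficients
  if (!"grpcase" %in% rownames(co)) stop("singular design: group effect not estimable")
  data.frame(estimate = co["grpcase", 1], t = co["grpcase", 3],
             p = co["grpcase", 4], n = length(y), note = "",
             stringsAsFactors = FALSE)
}

#' Simple linear age effect (OLS)
#'
#' \code{y ~ intercept + age}; returns the age slope, t and two-tailed p.
#'
#' @inheritParams group_age_regression
#' @export
age_regression <- function(y, records) {
  y <- as.numeric(y)
  if (length(y) != nrow(records)) stop("y and records are not aligned")
  if (anyNA(y)) stop("missing responses; subset before calling")
  if (stats::var(y) == 0)
    return(data.frame(estimate = 0, t = 0, p = 1, n = length(y), note = "constant",
                      stringsAsFactors = FALSE))
  fit <- stats::lm(y ~ age, data = data.frame(age = records$age))
  co <- summary(fit)$coefficients
  data.frame(estimate = co["age", 1], t = co["age", 3], p = co["age", 4],
             n = length(y), note = "", stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values over a fixed family size
#'
#' Step-up FDR adjustment where the family may be larger than the number
#' of computed p-values (skipped tests still count in the family, as if
#' their p-values were 1).
#'
#' @param p numeric vector of p-values (may contain NA for skipped tests).
#' @param family_size total number of tests in the family
#'   (default \code{length(p)}).
#' @return q-values aligned with \code{p} (NA where p is NA).
#' @export
bh_adjust <- function(p, family_size = length(p)) {
  if (family_size < sum(!is.na(p))) stop("family_size smaller than the number of p-values")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH", n = family_size)
  q
}

#' Per-cluster group comparisons with FDR correction
#'
#' Runs \code{\link{group_age_regression}} for every cluster column of a
#' subject-by-cluster table, using only the subjects with a value in
#' that cluster (subjects without a pit there are excluded listwise per
#' cluster). Clusters with fewer than 3 subjects in either group are
#' skipped with a warning but still count in the FDR family.
#'
#' @param depth_table numeric matrix, rows = subjects (aligned with
#'   \code{records}), columns = clusters, NA = no pit.
#' @param records subject data frame (group, age).
#' @param family_size FDR family size (default: number of clusters).
#' @param alpha significance level for the significant flag (default 0.05).
#' @return data frame, one row per cluster: cluster, estimate, t, p, q,
#'   n, significant, skipped.
#' @export
per_cluster_tests <- function(depth_table, records, family_size = ncol(depth_table),
                              alpha = 0.05) {
  depth_table <- as.matrix(depth_table)
  if (nrow(depth_table) != nrow(records)) stop("table rows and records are not aligned")
  cl_names <- colnames(depth_table)
  if (is.null(cl_names)) cl_names <- as.character(seq_len(ncol(depth_table)))
  grp <- factor(records$group, levels = c("control", "case"))
  out <- data.frame(cluster = cl_names, estimate = NA_real_, t = NA_real_,
                    p = NA_real_, q = NA_real_, n = 0L,
                    significant = FALSE, skipped = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(depth_table))) {
    ok <- !is.na(depth_table[, j])
    tab <- table(grp[ok])
    if (length(tab) < 2L || min(tab) < 3L) {
      out$skipped[j] <- TRUE
      next
    }
    r <- group_age_regression(depth_table[ok, j], records[ok, , drop = FALSE])
    out$estimate[j] <- r$estimate
    out$t[j] <- r$t
    out$p[j] <- r$p
    out$n[j] <- r$n
  }
  if (any(out$skipped))
    warning(sprintf("%d cluster(s) skipped (fewer than 3 subjects per group); still counted in the FDR family",
                    sum(out$skipped)))
  out$q <- bh_adjust(out$p, family_size)
  out$significant <- !is.na(out$q) & out$q < alpha
  out
}

#' Asymmetry index
#'
#' AI = (L - R) / (L + R) on paired left/right depth measurements:
#' -1 is completely right-lateralized, +1 completely left-lateralized,
#' 0 symmetric. Defined only when L + R > 0 (otherwise NA). Vectorized.
#'
#' @param L,R non-negative left / right deepest-pit depths.
#' @return numeric AI values in [-1, 1] (NA where L + R <= 0).
#' @export
asymmetry_index <- function(L, R) {
  L <- as.numeric(L)
  R <- as.numeric(R)
  ai <- (L - R) / (L + R)
  ai[!is.na(L + R) & (L + R) <= 0] <- NA_real_
  ai
}

#' Group comparisons of depth asymmetry per symmetric cluster
#'
#' Computes each subject's AI per symmetric cluster from the left and
#' right deepest-pit depth tables, then runs the age-adjusted group
#' regression per cluster with BH-FDR over the symmetric family.
#' Subject-clusters missing either hemisphere (or with L + R <= 0) are
#' excluded from that cluster's test.
#'
#' @param left_table,right_table subject-by-cluster depth tables on the
#'   symmetric parcellation (same dimensions, aligned columns).
#' @inheritParams per_cluster_tests
#' @export
ai_group_tests <- function(left_table, right_table, records,
                           family_size = ncol(left_table), alpha = 0.05) {
  left_table <- as.matrix(left_table)
  right_table <- as.matrix(right_table)
  if (!all(dim(left_table) == dim(right_table)))
    stop("left and right tables must have identical dimensions")
  ai <- asymmetry_index(left_table, right_table)
  dim(ai) <- dim(left_table)
  colnames(ai) <- colnames(left_table)
  per_cluster_tests(ai, records, family_size = family_size, alpha = alpha)
}

#' Within-group hemispheric difference per symmetric cluster (RM-ANOVA)
#'
#' For each symmetric cluster, a one-within-factor (hemisphere)
#' repeated-measures ANOVA on the subjects of one group having both
#' hemisphere values, fitted with \code{aov} and an \code{Error(subject)}
#' stratum. With two levels this F equals the squared paired t
#' statistic. Clusters with fewer than 3 complete pairs are skipped;
#' zero within-subject variance is flagged degenerate (p = 0 for a
#' nonzero mean difference, p = 1 otherwise). BH-FDR across clusters.
#'
#' @param left_table,right_table subject-by-cluster depth tables
#'   (symmetric parcellation).
#' @param records subject data frame (rows aligned with the tables).
#' @param group which group to analyse ("control" or "case").
#' @param family_size FDR family size (default: number of clusters).
#' @param alpha significance level.
#' @return data frame per cluster: cluster, mean_diff (L - R), F, p, q,
#'   n_pairs, significant, skipped, degenerate.
#' @export
within_group_hemisphere_test <- function(left_table, right_table, records,
                                         group = c("control", "case"),
                                         family_size = ncol(left_table),
                                         alpha = 0.05) {
  group <- match.arg(group)
  left_table <- as.matrix(left_table)
  right_table <- as.matrix(right_table)
  if (!all(dim(left_table) == dim(right_table)))
    stop("left and right tables must have identical dimensions")
  sel <- records$group == group
  cl_names <- colnames(left_table)
  if (is.null(cl_names)) cl_names <- as.character(seq_len(ncol(left_table)))
  out <- data.frame(cluster = cl_names, mean_diff = NA_real_, F = NA_real_,
                    p = NA_real_, q = NA_real_, n_pairs = 0L,
                    significant = FALSE, skipped = FALSE, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(left_table))) {
    L <- left_table[sel, j]
    R <- right_table[sel, j]
    ok <- !is.na(L) & !is.na(R)
    n <- sum(ok)
    if (n < 3L) {
      out$skipped[j] <- TRUE
      next
    }
    L <- L[ok]
    R <- R[ok]
    out$n_pairs[j] <- n
    out$mean_diff[j] <- mean(L - R)
    if (stats::var(L - R) == 0) {
      out$degenerate[j] <- TRUE
      out$F[j] <- if (out$mean_diff[j] == 0) 0 else Inf
      out$p[j] <- if (out$mean_diff[j] == 0) 1 else 0
      next
    }
    d <- data.frame(value = c(L, R),
                    hemi = factor(rep(c("L", "R"), each = n)),
                    subj = factor(rep(seq_len(n), 2)))
    fit <- stats::aov(value ~ hemi + Error(subj), data = d)
    s <- summary(fit)[["Error: Within"]][[1]]
    out$F[j] <- s["hemi", "F value"]
    out$p[j] <- s["hemi", "Pr(>F)"]
  }
  out$q <- bh_adjust(out$p, family_size)
  out$significant <- !is.na(out$q) & out$q < alpha
  out
}

#' Compare case subtypes on a measurement, adjusted for age
#'
#' Within the case group only: OLS \code{y ~ subtype + age}, the subtype
#' dummy contrasting "combined" against "inattentive". Errors if either
#' subtype is absent.
#'
#' @param y numeric response per subject (all subjects; controls are
#'   dropped internally).
#' @param records data frame with \code{group}, \code{subtype}
#'   ("combined"/"inattentive" for cases) and \code{age}.
#' @return one-row data frame: estimate (combined minus inattentive), t,
#'   p, n, note.
#' @export
subtype_comparison <- function(y, records) {
  sel <- records$group == "case"
  y <- as.numeric(y)[sel]
  sub <- factor(records$subtype[sel], levels = c("inattentive", "combined"))
  if (anyNA(sub) || length(unique(sub)) < 2L)
    stop("both subtypes (combined, inattentive) must be present among cases")
  if (min(table(sub)) < 3L) stop("need at least 3 cases per subtype")
  if (stats::var(y) == 0)
    return(data.frame(estimate = 0, t = 0, p = 1, n = length(y), note = "constant",
                      stringsAsFactors = FALSE))
  fit <- stats::lm(y ~ sub + age, data = data.frame(sub = sub, age = records$age[sel]))
  co <- summary(fit)$coefficients
  data.frame(estimate = co["subcombined", 1], t = co["subcombined", 3],
             p = co["subcombined", 4], n = length(y), note = "",
             stringsAsFactors = FALSE)
}
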