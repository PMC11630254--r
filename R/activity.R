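#' Scale relative abundances to absolute cell abundances
#'
#' Multiplies each sample's relative phylotype abundances by that sample's
#' qPCR estimate of total amoA copies per g soil, so that column sums equal
#' the qPCR totals.
#'
#' @param rel Relative [abundance_matrix()] (`kind = "relative"`).
#' @param qpcr_totals Named numeric vector of total copies g^-1 per sample;
#'   every column of `rel` must have a total.
#' @return Absolute [abundance_matrix()].
#' @export
to_cell_abundance <- function(rel, qpcr_totals) {
  if (!identical(attr(rel, "kind"), "relative"))
    stop("'rel' must be a relative abundance matrix", call. = FALSE)
  miss <- setdiff(colnames(rel), names(qpcr_totals))
  if (length(miss))
    stop("missing qPCR total for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tot <- qpcr_totals[colnames(rel)]
  if (any(!is.finite(tot)) || any(tot < 0))
    stop("qPCR totals must be finite and >= 0", call. = FALSE)
  abs <- sweep(unclass(rel), 2, tot, `*`)
  abundance_matrix(abs, kind = "absolute")
}

.activity_table <- function(ids, values, method, start, end) {
  data.frame(phylotype_id = ids, method = method,
             interval_start = start, interval_end = end,
             value = values, row.names = NULL)
}

#' Growth of each phylotype between two time points
#'
#' Growth (DNA-based activity) is the differential absolute abundance
#' between the final and initial time points; negative differentials are
#' reported as null (0), since a decline is not growth.
#'
#' @param initial,final Named numeric vectors of absolute abundances
#'   (copies g^-1) over the same phylotype set.
#' @param interval Length-2 numeric, the (start, end) days of the interval.
#' @return Activity table with columns `phylotype_id`, `method`,
#'   `interval_start`, `interval_end`, `value` (all values >= 0).
#' @export
growth <- function(initial, final, interval = c(0, 30)) {
  if (is.null(names(initial)) || is.null(names(final)) ||
      !setequal(names(initial), names(final)))
    stop("'initial' and 'final' must be named over the same phylotypes",
         call. = FALSE)
  final <- final[names(initial)]
  .activity_table(names(initial), pmax(0, final - initial),
                  "growth", interval[1], interval[2])
}

#' Transcriptional activity from an RNA time series
#'
#' Per-interval truncated differences of transcript abundance between
#' successive time points (negative differentials reported as null), plus
#' their sum as the total activity over the incubation.
#'
#' @param series Matrix of absolute transcript abundances, rows =
#'   phylotypes, columns = time points in increasing day order; column
#'   names are the days.
#' @return List with `per_interval` (activity table over all successive
#'   intervals) and `total` (activity table of per-phylotype sums).
#' @export
transcriptional_activity <- function(series) {
  series <- as.matrix(series)
  if (ncol(series) < 2)
    stop("need >= 2 time points", call. = FALSE)
  days <- as.numeric(colnames(series))
  if (anyNA(days) || is.unsorted(days, strictly = TRUE))
    stop("column names must be strictly increasing day numbers",
         call. = FALSE)
  per <- lapply(seq_len(ncol(series) - 1), function(k)
    .activity_table(rownames(series),
                    pmax(0, series[, k + 1] - series[, k]),
                    "transcription", days[k], days[k + 1]))
  per <- do.call(rbind, per)
  tot <- stats::aggregate(value ~ phylotype_id, per, sum)
  list(per_interval = per,
       total = .activity_table(tot$phylotype_id, tot$value, "transcription",
                               days[1], days[length(days)]))
}

#' Sum activity within each niche-breadth phenotype
#'
#' Phylotype activities (or abundances) are summed within specialist,
#' generalist and putative-specialist classes to compare the collective
#' fitness of the phenotypes; the three totals conserve the input total
#' exactly.
#'
#' @param activity Activity table (or any data frame with `phylotype_id`
#'   and `value`).
#' @param classes Classification data frame from
#'   [classify_niche_breadth()].
#' @return Named numeric vector with elements `specialist`, `generalist`,
#'   `putative_specialist`.
#' @export
phenotype_sums <- function(activity, classes) {
  cls <- classes$nb_class[match(activity$phylotype_id,
                                classes$phylotype_id)]
  if (anyNA(cls))
    stop("unclassified phylotype(s): ",
         paste(unique(activity$phylotype_id[is.na(cls)]), collapse = ", "),
         call. = FALSE)
  lev <- c("specialist", "generalist", "putative_specialist")
  out <- vapply(lev, function(l) sum(activity$value[cls == l]), numeric(1))
  names(out) <- lev
  out
}

#' Combined dormancy and death fraction
#'
#' The inactive proportion of a community: the complement of the ratio of
#' active to resident cell numbers, clipped to \[0, 1\]. Active counts
#' exceeding resident counts (possible with noisy qPCR) are clipped to a
#' fraction of 0 with a warning.
#'
#' @param active_total,resident_total Total active and resident cell
#'   abundances (copies g^-1); `resident_total` must be > 0.
#' @return Fraction in \[0, 1\].
#' @export
dormancy_fraction <- function(active_total, resident_total) {
  if (any(resident_total <= 0))
    stop("resident total must be > 0: dormancy undefined", call. = FALSE)
  r <- 1 - active_total / resident_total
  if (any(r < 0))
    warning("active exceeds resident abundance; dormancy clipped to 0 ",
            "[code AC01]", call. = FALSE)
  pmin(1, pmax(0, r))
}

#' Shannon diversity index (natural log, no rarefaction)
#'
#' @param x Nonnegative abundance vector with positive sum.
#' @return H in nats, \eqn{-\sum p_i \ln p_i} over positive abundances.
#' @export
shannon <- function(x) {
  if (any(x < 0) || sum(x) <= 0)
    stop("abundances must be >= 0 with positive sum", call. = FALSE)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' @param x,y Equal-length nonnegative vectors, not both all-zero.
#' @return \eqn{\sum |x_i - y_i| / \sum (x_i + y_i)}, in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("abundances must be >= 0", call. = FALSE)
  s <- sum(x + y)
  if (s == 0) stop("both vectors all-zero", call. = FALSE)
  sum(abs(x - y)) / s
}

#' Pairwise Bray-Curtis distance matrix over samples
#'
#' @param mat Abundance matrix (phylotypes x samples).
#' @return Symmetric square matrix of Bray-Curtis distances between sample
#'   columns.
#' @export
bray_curtis_matrix <- function(mat) {
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- bray_curtis(mat[, i], mat[, j])
  d
}

#' Assumption-gated two-group comparison
#'
#' A Welch two-sample t-test is used if both groups pass a Shapiro-Wilk
#' normality test and a Bartlett homogeneity-of-variance test (each at
#' `alpha`); otherwise a Kruskal-Wallis test is used. (Welch's test does
#' not itself require equal variances; the Bartlett gate is nonetheless
#' part of the protocol and its outcome is reported.)
#'
#' @param group_a,group_b Numeric samples, each of size >= 3.
#' @param alpha Gate significance level (default 0.05).
#' @return List with `test_used` ("welch" or "kruskal"), `statistic`,
#'   `p_value`, and `gates` (the Shapiro p for each group and Bartlett p).
#' @export
gated_group_test <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs n >= 3", call. = FALSE)
  sw_a <- stats::shapiro.test(group_a)$p.value
  sw_b <- stats::shapiro.test(group_b)$p.value
  bt <- stats::bartlett.test(list(group_a, group_b))$p.value
  gates <- list(shapiro_a = sw_a, shapiro_b = sw_b, bartlett = bt)
  if (sw_a > alpha && sw_b > alpha && bt > alpha) {
    tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
    list(test_used = "welch", statistic = unname(tt$statistic),
         p_value = tt$p.value, gates = gates)
  } else {
    kw <- stats::kruskal.test(list(group_a, group_b))
    list(test_used = "kruskal", statistic = unname(kw$statistic),
         p_value = kw$p.value, gates = gates)
  }
}

#' Split soils into extreme and classical pH ranges
#'
#' Soils with pH at or below `low` or at or above `high` approach the
#' limits of the soil pH range and are grouped as "extreme"; the rest are
#' "classical".
#'
#' @param ph Numeric vector of soil pH.
#' @param low,high Extreme-range bounds (defaults 5.0 and 8.5).
#' @return Factor in \{extreme, classical\}.
#' @export
extreme_ph_split <- function(ph, low = 5.0, high = 8.5) {
  factor(ifelse(ph <= low | ph >= high, "extreme", "classical"),
         levels = c("classical", "extreme"))
}
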