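#' Convert pH to hydrogen-ion concentration
#'
#' Niche breadth is computed on the hydrogen-ion concentration scale rather
#' than on pH, avoiding the distortion of working on a logarithmic trait.
#'
#' @param ph Numeric vector of pH values.
#' @return Numeric vector of \[H+\] in mol L^-1, `10^(-ph)`.
#' @examples
#' ph_to_hplus(7)    # 1e-7
#' ph_to_hplus(4.5)  # 3.16e-5
#' @export
ph_to_hplus <- function(ph) {
  if (!is.numeric(ph) || any(!is.finite(ph)))
    stop("'ph' must be finite numeric", call. = FALSE)
  10^(-ph)
}

#' Construct a validated phylotype-by-sample abundance matrix
#'
#' @param values Numeric matrix, rows = phylotypes, columns = samples; row
#'   and column names are the identifiers.
#' @param kind Either `"relative"` (each non-empty column sums to 1) or
#'   `"absolute"` (e.g. amoA copies per g soil).
#' @return The matrix with class `"abundance_matrix"` and a `kind` attribute.
#'   Columns summing to zero are permitted and flagged in the
#'   `empty_samples` attribute.
#' @export
abundance_matrix <- function(values, kind = c("absolute", "relative")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs phylotype rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate phylotype ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("abundance values must be finite numeric", call. = FALSE)
  if (any(values < 0))
    stop("abundance values must be >= 0", call. = FALSE)
  cs <- colSums(values)
  empty <- colnames(values)[cs == 0]
  if (kind == "relative" && any(cs > 0 & abs(cs - 1) > 1e-9))
    stop("relative abundance columns must sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  structure(values, class = c("abundance_matrix", class(values)),
            kind = kind, empty_samples = empty)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix (%s): %d phylotypes x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' Sample occupancy of a phylotype
#'
#' Number of samples in which a phylotype is observed, i.e. has abundance
#' strictly above the presence threshold.
#'
#' @param mat Abundance matrix (phylotypes x samples).
#' @param phylotype Phylotype id (row name); if `NULL`, occupancy of every
#'   row is returned.
#' @param presence_threshold Values must exceed this to count as presence
#'   (default 0, i.e. any positive abundance).
#' @return Integer count(s), named by phylotype.
#' @export
occupancy <- function(mat, phylotype = NULL, presence_threshold = 0) {
  if (!is.null(phylotype)) {
    if (!all(phylotype %in% rownames(mat)))
      stop("unknown phylotype(s): ",
           paste(setdiff(phylotype, rownames(mat)), collapse = ", "),
           call. = FALSE)
    mat <- mat[phylotype, , drop = FALSE]
  }
  n <- rowSums(mat > presence_threshold)
  storage.mode(n) <- "integer"
  n
}

#' Modified Levins pH niche-breadth index for one phylotype
#'
#' \deqn{B_j = \frac{1}{\sqrt{n_j}} \cdot \frac{\sigma_j^2}{\mu_j^2}}
#'
#' where \eqn{\mu_j} and \eqn{\sigma_j^2} are the mean and variance of the
#' hydrogen-ion concentrations of the \eqn{n_j} occupied samples. Small B
#' means a narrow pH niche (specialist), large B a wide one (generalist).
#' The 1/sqrt(n) factor keeps the index homogeneous across the abundance
#' (occupancy) gradient, unlike the raw standard deviation or standard
#' error (see [nb_index_diagnostics()]).
#'
#' @param abund Per-sample abundances of the phylotype.
#' @param hplus Per-sample hydrogen-ion concentrations (mol L^-1, > 0).
#' @param weighted If `TRUE`, moments are abundance-weighted (frequency
#'   weights); default is unweighted with the n-1 variance denominator, in
#'   which case abundances enter only through presence/absence.
#' @param presence_threshold Presence cut-off as in [occupancy()].
#' @return Scalar B >= 0. B = 0 exactly when all occupied samples share one
#'   \[H+\] value.
#' @examples
#' niche_breadth_index(c(1, 1), ph_to_hplus(c(5, 7)))  # 1.35876
#' @export
niche_breadth_index <- function(abund, hplus, weighted = FALSE,
                                presence_threshold = 0) {
  if (length(abund) != length(hplus))
    stop("'abund' and 'hplus' lengths differ", call. = FALSE)
  if (any(!is.finite(hplus)) || any(hplus <= 0))
    stop("'hplus' must be finite and > 0", call. = FALSE)
  occ <- abund > presence_threshold
  n <- sum(occ)
  if (n < 2)
    stop("putative-specialist: phylotype present in < 2 samples, B undefined",
         call. = FALSE)
  h <- hplus[occ]
  if (weighted) {
    w <- abund[occ]
    mu <- sum(w * h) / sum(w)
    # frequency-weight variance with the (n-1)-style bias correction
    s2 <- sum(w * (h - mu)^2) / (sum(w) * (n - 1) / n)
  } else {
    mu <- mean(h)
    s2 <- stats::var(h)
  }
  (1 / sqrt(n)) * s2 / mu^2
}

#' Per-phylotype niche-breadth records for a whole matrix
#'
#' Computes occupancy, \[H+\] moments and the B index for every phylotype,
#' leaving `B = NA` (and later class putative-specialist) for phylotypes
#' present in a single sample.
#'
#' @param mat Abundance matrix (phylotypes x samples).
#' @param meta Sample metadata data frame with columns `sample_id` and `pH`
#'   (see [read_sample_meta()]); every column of `mat` must have a pH.
#' @inheritParams niche_breadth_index
#' @return Data frame with columns `phylotype_id`, `n_j`, `mu_hplus`,
#'   `sigma2_hplus`, `B`.
#' @export
niche_breadth_table <- function(mat, meta, weighted = FALSE,
                                presence_threshold = 0) {
  idx <- match(colnames(mat), meta$sample_id)
  if (anyNA(idx))
    stop("samples without metadata: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "), call. = FALSE)
  ph <- meta$pH[idx]
  if (anyNA(ph)) stop("pH required for all samples", call. = FALSE)
  hplus <- ph_to_hplus(ph)
  recs <- lapply(rownames(mat), function(p) {
    x <- mat[p, ]
    occ <- x > presence_threshold
    n <- sum(occ)
    if (n == 0)
      return(data.frame(phylotype_id = p, n_j = 0L, mu_hplus = NA_real_,
                        sigma2_hplus = NA_real_, B = NA_real_))
    h <- hplus[occ]
    if (n == 1)
      return(data.frame(phylotype_id = p, n_j = 1L, mu_hplus = h,
                        sigma2_hplus = NA_real_, B = NA_real_))
    if (weighted) {
      w <- x[occ]
      mu <- sum(w * h) / sum(w)
      s2 <- sum(w * (h - mu)^2) / (sum(w) * (n - 1) / n)
    } else {
      mu <- mean(h)
      s2 <- stats::var(h)
    }
    data.frame(phylotype_id = p, n_j = as.integer(n), mu_hplus = mu,
               sigma2_hplus = s2, B = (1 / sqrt(n)) * s2 / mu^2)
  })
  do.call(rbind, recs)
}

#' Median-split classification into specialists and generalists
#'
#' The median of the defined niche-breadth values is the cut-off: phylotypes
#' at or below it are pH specialists, above it pH generalists. Phylotypes
#' present in a single sample (B undefined) are putative specialists.
#'
#' @param records Data frame from [niche_breadth_table()].
#' @param tie How B values exactly equal to the median are classified:
#'   `"le"` (default, ties to specialist) or `"lt"` (ties to generalist).
#' @return `records` with an added factor column `nb_class` in
#'   \{specialist, generalist, putative_specialist\}; class counts are in
#'   the `"counts"` attribute.
#' @export
classify_by_median <- function(records, tie = c("le", "lt")) {
  tie <- match.arg(tie)
  defined <- !is.na(records$B)
  if (any(records$n_j[defined] < 2))
    stop("records with defined B must have n_j >= 2", call. = FALSE)
  cls <- rep("putative_specialist", nrow(records))
  if (!any(defined)) {
    if (nrow(records) == 0)
      stop("no records: cannot place the median cut-off", call. = FALSE)
    # every phylotype is a single-soil putative specialist; no cut-off needed
    med <- NA_real_
  } else {
    med <- stats::median(records$B[defined])
    spec <- if (tie == "le") records$B[defined] <= med else
      records$B[defined] < med
    cls[defined] <- ifelse(spec, "specialist", "generalist")
  }
  records$nb_class <- factor(cls, levels = c("specialist", "generalist",
                                             "putative_specialist"))
  attr(records, "median_B") <- med
  attr(records, "counts") <- table(records$nb_class)
  records
}

#' Endemic / cosmopolitan range class from occupancy
#'
#' Phylotypes recorded in up to `endemic_max` sites (default 3) are endemic
#' (geographically restricted); phylotypes present in more sites are
#' cosmopolitan.
#'
#' @param n_j Integer occupancy (>= 1).
#' @param endemic_max Largest occupancy still counted as endemic.
#' @return Factor in \{endemic, cosmopolitan\}.
#' @export
range_class <- function(n_j, endemic_max = 3L) {
  if (any(!is.finite(n_j)) || any(n_j < 1))
    stop("'n_j' must be >= 1", call. = FALSE)
  factor(ifelse(n_j <= endemic_max, "endemic", "cosmopolitan"),
         levels = c("endemic", "cosmopolitan"))
}

#' Full niche-breadth classification of an abundance matrix
#'
#' Convenience wrapper: [niche_breadth_table()] then [classify_by_median()]
#' and [range_class()]. This is the table the downstream activity and
#' diversification stages consume.
#'
#' @inheritParams niche_breadth_table
#' @inheritParams classify_by_median
#' @inheritParams range_class
#' @return Data frame with columns `phylotype_id`, `n_j`, `mu_hplus`,
#'   `sigma2_hplus`, `B`, `nb_class`, `range_class`. Phylotypes absent from
#'   every sample are dropped with a warning.
#' @export
classify_niche_breadth <- function(mat, meta, weighted = FALSE,
                                   presence_threshold = 0, tie = "le",
                                   endemic_max = 3L) {
  rec <- niche_breadth_table(mat, meta, weighted = weighted,
                             presence_threshold = presence_threshold)
  if (any(rec$n_j == 0)) {
    warning(sum(rec$n_j == 0), " phylotype(s) absent everywhere dropped ",
            "[code NB01]", call. = FALSE)
    rec <- rec[rec$n_j > 0, , drop = FALSE]
  }
  rec <- classify_by_median(rec, tie = tie)
  rec$range_class <- range_class(rec$n_j, endemic_max = endemic_max)
  rec
}

#' Candidate niche-breadth indices across the abundance gradient
#'
#' Diagnostic behind the choice of index: tabulates, per phylotype, the
#' \[H+\] standard deviation, the standard error (sd / sqrt(n)) and the B
#' index against the rank of mean abundance. A suitable index should be
#' homogeneously distributed across the abundance gradient; sd and se are
#' each skewed toward one side. No automatic selection is performed.
#'
#' @inheritParams niche_breadth_table
#' @return Data frame with columns `phylotype_id`, `n_j`, `mean_abund`,
#'   `abund_rank`, `sd_hplus`, `se_hplus`, `B`, plus the Spearman
#'   correlation of each candidate with abundance rank in the
#'   `"rank_correlations"` attribute.
#' @export
nb_index_diagnostics <- function(mat, meta, presence_threshold = 0) {
  rec <- niche_breadth_table(mat, meta,
                             presence_threshold = presence_threshold)
  rec <- rec[rec$n_j >= 2, , drop = FALSE]
  ma <- rowMeans(mat)[rec$phylotype_id]
  out <- data.frame(phylotype_id = rec$phylotype_id, n_j = rec$n_j,
                    mean_abund = ma, abund_rank = rank(ma),
                    sd_hplus = sqrt(rec$sigma2_hplus),
                    se_hplus = sqrt(rec$sigma2_hplus) / sqrt(rec$n_j),
                    B = rec$B)
  cors <- vapply(c(sd_hplus = "sd_hplus", se_hplus = "se_hplus", B = "B"),
                 function(v) stats::cor(out$abund_rank, out[[v]],
                                        method = "spearman"),
                 numeric(1))
  attr(out, "rank_correlations") <- cors
  out
}
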