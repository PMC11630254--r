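#' Read a phylotype-by-sample abundance matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of phylotype ids
#' (or the transpose with `orientation = "samples_in_rows"`). Lines
#' starting with `#` are treated as provenance metadata and skipped.
#'
#' @param path File path; tab-separated by default, comma-separated
#'   accepted (sniffed from the header line).
#' @param kind `"absolute"` or `"relative"`; relative columns are
#'   validated to sum to 1 within 1e-9.
#' @param orientation `"phylotypes_in_rows"` (default) or
#'   `"samples_in_rows"`.
#' @return Validated [abundance_matrix()].
#' @export
read_abundance <- function(path, kind = c("absolute", "relative"),
                           orientation = c("phylotypes_in_rows",
                                           "samples_in_rows")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path,
                           call. = FALSE)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative value at data row ", bad[1, 1], ", column ",
         colnames(m)[bad[1, 2]], " of ", path, call. = FALSE)
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  abundance_matrix(m, kind = kind)
}

# '#'-prefixed provenance header lines written at the top of outputs
.provenance <- function(seed = NULL) {
  c(sprintf("# phniche %s", as.character(utils::packageVersion("phniche"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
}

#' Write an abundance matrix (or any table) as TSV with provenance header
#'
#' @param x Matrix or data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header, if any.
#' @export
write_tsv <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed), con)
  if (is.matrix(x))
    x <- data.frame(id = rownames(x), as.data.frame(unclass(x)),
                    check.names = FALSE)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV/CSV with columns `sample_id` and `pH` (required), and optionally
#' `qpcr_total`, `timepoint_days`, `condition`, `assay`. A derived `hplus`
#' column (mol L^-1) is added.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_meta <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "pH") %in% names(df)))
    stop("metadata needs 'sample_id' and 'pH' columns", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(df$pH)))
    stop("non-finite pH", call. = FALSE)
  df$hplus <- ph_to_hplus(df$pH)
  df
}

#' Read a rooted phylogeny from newick
#'
#' @param path Newick file.
#' @param require_lengths Insist on branch lengths (default TRUE).
#' @return `phylo` object.
#' @export
read_tree <- function(path, require_lengths = TRUE) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse error in ",
                                            path, ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("newick parse error in ", path, call. = FALSE)
  if (require_lengths && is.null(tree$edge.length))
    stop("tree in ", path, " has no branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  tree
}

#' Read tip states for the diversification stage
#'
#' Two-column TSV `tip_id`, `state`; states are ES/CS/EG/CG, with
#' ambiguous sets comma-joined (e.g. `"ES,CS"`).
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_tip_states <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("tip_id", "state") %in% names(df)))
    stop("tip-state file needs 'tip_id' and 'state' columns",
         call. = FALSE)
  stats::setNames(df$state, df$tip_id)
}

#' Write the niche-breadth classification table
#'
#' Columns `phylotype_id`, `n_j`, `mu_hplus`, `sigma2_hplus`, `B`,
#' `nb_class`, `range_class`, as produced by [classify_niche_breadth()].
#'
#' @param classes Classification data frame.
#' @param path Output path.
#' @param seed Seed recorded in the provenance header.
#' @export
write_classification <- function(classes, path, seed = NULL) {
  write_tsv(classes, path, seed = seed)
}
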