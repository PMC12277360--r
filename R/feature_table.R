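#' Genus-level feature tables: I/O, rarefaction, alpha diversity
#'
#' A feature table is a samples x genera matrix of non-negative integer
#' counts with unique sample ids as row names.
#'
#' @name feature_table
NULL

.check_table <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("negative counts")
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) stop("sample ids must be unique")
  m
}

#' Read / write a feature table TSV
#'
#' Samples as rows, first column the sample id, remaining columns genus
#' counts. A BIOM-style TSV whose first header field is `#OTU ID` (taxa as
#' rows) is detected and transposed.
#'
#' @param path TSV file path.
#' @return integer matrix, samples x genera.
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1)
  biom <- startsWith(first, "#OTU ID")
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (biom) m <- t(m)
  storage.mode(m) <- "integer"
  .check_table(m)
}

#' @rdname read_feature_table
#' @param table samples x genera count matrix.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy samples to a common depth
#'
#' Without-replacement subsampling of each sample's counts to exactly
#' `depth` reads; samples with fewer total reads than `depth` are dropped
#' and recorded. Deterministic for a given seed.
#'
#' @param table samples x genera count matrix.
#' @param depth target depth (default 1391).
#' @param seed integer seed.
#' @return rarefied integer matrix with attributes `rarefaction_depth` and
#'   `dropped_samples`.
#' @export
rarefy <- function(table, depth = 1391, seed = 1L) {
  m <- .check_table(table)
  stopifnot(depth >= 1)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) stop("rarefaction depth ", depth, " exceeds every sample total")
  set.seed(seed)
  # counts are validated above; silence vegan's count-plausibility heuristic
  out <- withCallingHandlers(
    vegan::rrarefy(m[keep, , drop = FALSE], depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  attr(out, "rarefaction_depth") <- as.integer(depth)
  attr(out, "dropped_samples") <- rownames(m)[!keep]
  out
}

#' Convert counts to relative abundances
#'
#' @param table samples x genera count matrix.
#' @return matrix of row-proportions (rows sum to 1).
#' @export
relative_abundance <- function(table) {
  m <- .check_table(table)
  sweep(m, 1, rowSums(m), "/")
}

#' Per-sample alpha diversity
#'
#' Observed genera, bias-corrected Chao1
#' (`S + F1 (F1 - 1) / (2 (F2 + 1))`), Shannon entropy in bits (log base 2),
#' Gini-Simpson (`1 - sum p^2`) and Pielou evenness (`H / log2(S)`).
#' Pielou is undefined (NA) for single-taxon samples; an all-zero sample
#' yields NA for every index.
#'
#' @param table samples x genera count matrix (typically rarefied).
#' @return data.frame with columns `observed`, `chao1`, `shannon`,
#'   `simpson`, `pielou`.
#' @export
alpha_diversity <- function(table) {
  m <- .check_table(table)
  observed <- rowSums(m > 0)
  f1 <- rowSums(m == 1)
  f2 <- rowSums(m == 2)
  chao1 <- observed + f1 * (f1 - 1) / (2 * (f2 + 1))
  shannon <- vegan::diversity(m, index = "shannon", base = 2)
  simpson <- vegan::diversity(m, index = "simpson")
  pielou <- ifelse(observed > 1, shannon / log2(observed), NA_real_)
  empty <- rowSums(m) == 0
  out <- data.frame(observed = as.numeric(observed), chao1 = chao1,
                    shannon = as.numeric(shannon),
                    simpson = as.numeric(simpson), pielou = pielou,
                    row.names = rownames(m))
  out[empty, ] <- NA_real_
  out
}
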