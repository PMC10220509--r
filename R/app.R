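#' Read a two-species ortholog expression table
#'
#' Expects a TSV with a `gene_id` column followed by per-condition
#' log-scale expression columns for each species, named `sp1_<cond>` and
#' `sp2_<cond>`.  By input convention Species 1 must be the species
#' carrying the ancestral state (e.g. the ancestral chromosomal arm),
#' because the model mean is asymmetric in the two species.  Extra
#' columns (lineage, arm metadata, ...) are preserved.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame`; the number of conditions `m` is available via
#'   [ortholog_table_m()].
#' @export
read_ortholog_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_ortholog_table(tab)
  tab
}

#' @rdname read_ortholog_table
#' @param table An ortholog expression table.
#' @export
write_ortholog_table <- function(table, path) {
  validate_ortholog_table(table)
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sp_cols <- function(table, species) {
  grep(sprintf("^sp%d_", species), names(table), value = TRUE)
}

validate_ortholog_table <- function(table) {
  if (!"gene_id" %in% names(table))
    stop("ortholog table must have a 'gene_id' column")
  if (anyDuplicated(table$gene_id))
    stop("duplicate gene ids in ortholog table")
  c1 <- sp_cols(table, 1)
  c2 <- sp_cols(table, 2)
  if (length(c1) == 0)
    stop("no sp1_/sp2_ expression columns found")
  if (length(c1) != length(c2))
    stop("species 1 has ", length(c1), " condition columns but species 2 has ",
         length(c2))
  vals <- as.matrix(table[, c(c1, c2)])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("expression columns must be finite numeric values")
  invisible(table)
}

#' Number of expression conditions in an ortholog table
#'
#' @inheritParams write_ortholog_table
#' @return Integer `m`.
#' @export
ortholog_table_m <- function(table) length(sp_cols(table, 1))

#' Drop genes below an expression floor in every condition
#'
#' A gene is removed iff all of its `m` values are below `floor` in
#' Species 1 or all are below `floor` in Species 2 (the quantile-normalized
#' FPKM < 1 rule of the motivating *Drosophila* analysis); the filter is
#' applied to the values as provided, and is idempotent.
#'
#' @inheritParams write_ortholog_table
#' @param floor Expression floor, on the same scale as the table values.
#' @return The filtered table, original row order preserved.
#' @export
filter_min_expression <- function(table, floor = 1) {
  validate_ortholog_table(table)
  s1 <- as.matrix(table[, sp_cols(table, 1), drop = FALSE])
  s2 <- as.matrix(table[, sp_cols(table, 2), drop = FALSE])
  drop <- apply(s1 < floor, 1, all) | apply(s2 < floor, 1, all)
  table[!drop, , drop = FALSE]
}

#' Apply trained models to an empirical ortholog table
#'
#' Assembles the interleaved feature vector of each gene
#' (`e1_c1, e2_c1, ...`), predicts its class and divergence score with the
#' classifier, and its `2m` expression optima with the regressor.  Output
#' is deterministic given fixed models and input.
#'
#' @param classifier A classification `"divergence_model"`.
#' @param regressor A regression `"divergence_model"`, or `NULL` to skip
#'   optimum estimation.
#' @inheritParams write_ortholog_table
#' @param path Optional path; when given, the records are also written as
#'   TSV.
#' @return A `data.frame` with columns `gene_id`, `label`, `score`, and
#'   (with a regressor) `theta1_c1 ... theta2_cm`.
#' @export
apply_model <- function(classifier, regressor = NULL, table, path = NULL) {
  validate_ortholog_table(table)
  m <- ortholog_table_m(table)
  if (classifier$m != m)
    stop("table has m = ", m, " conditions but the classifier expects ",
         classifier$m)
  s1 <- as.matrix(table[, sp_cols(table, 1), drop = FALSE])
  s2 <- as.matrix(table[, sp_cols(table, 2), drop = FALSE])
  x <- matrix(NA_real_, nrow(table), 2 * m)
  x[, seq(1, 2 * m, by = 2)] <- s1
  x[, seq(2, 2 * m, by = 2)] <- s2
  pred <- predict_labels(classifier, x)
  out <- data.frame(gene_id = table$gene_id, label = pred$label,
                    score = pred$score)
  if (!is.null(regressor)) {
    if (regressor$m != m)
      stop("table has m = ", m, " conditions but the regressor expects ",
           regressor$m)
    out <- cbind(out, as.data.frame(predict_optima(regressor, x)))
  }
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Two-tailed exact binomial test
#'
#' Two-tailed P-value of observing `x` successes in `n` trials at success
#' probability `p`, summing the probabilities of all outcomes whose point
#' probability does not exceed that of `x` (the convention of R's
#' `binom.test()`, through which this is computed).
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param p Success probability, strictly between 0 and 1.
#' @return P-value in `(0, 1]`.
#' @examples
#' binom_two_tailed(13, 23, 53 / 102)
#' @export
binom_two_tailed <- function(x, n, p) {
  stopifnot(n >= 1, x >= 0, x <= n, p > 0, p < 1)
  binom.test(x, n, p, alternative = "two.sided")$p.value
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Two-tailed P-value summing the hypergeometric point probabilities not
#' exceeding the observed table's (via R's `fisher.test()`).
#'
#' @param counts 2x2 matrix of nonnegative integer counts with at least
#'   one positive margin.
#' @return P-value in `(0, 1]`.
#' @examples
#' fisher_two_tailed(matrix(c(5, 5, 5, 5), 2))
#' @export
fisher_two_tailed <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0),
            all(counts == round(counts)))
  if (sum(counts) == 0) stop("all-zero contingency table")
  fisher.test(counts)$p.value
}
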