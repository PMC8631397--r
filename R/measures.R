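#' The twelve network measures and their domains
#'
#' The analysis operates on six neurocognitive battery scores (verbal memory
#' VM, digit sequencing DS, token motor task TMT, verbal fluency VF, symbol
#' coding SC, Tower of London TL) and six oculomotor summary measures
#' (antisaccade latency median ASLs, antisaccade error-latency median ASELs,
#' antisaccade error proportion ASEs, Go latency median GnGLs, NoGo
#' error-latency median GnGELs, NoGo error proportion GnGEs).
#'
#' @return A data frame with columns `measure` and `domain`
#'   (`"cognitive"` or `"oculomotor"`), one row per measure, in canonical
#'   order.
#' @export
#' @examples
#' measure_info()
measure_info <- function() {
  data.frame(
    measure = c("VM", "DS", "TMT", "VF", "SC", "TL",
                "ASLs", "ASELs", "ASEs", "GnGLs", "GnGELs", "GnGEs"),
    domain = rep(c("cognitive", "oculomotor"), each = 6),
    stringsAsFactors = FALSE
  )
}

.measure_domain <- function(measure) {
  info <- measure_info()
  idx <- match(measure, info$measure)
  if (anyNA(idx)) {
    stop("unknown measure(s): ", paste(measure[is.na(idx)], collapse = ", "))
  }
  info$domain[idx]
}

#' Significance codes used in the published correlation tables
#'
#' Codes are ordered from weakest to strongest evidence:
#' `ns`, `.1` (p < 0.1), `.05`, `.01`, `.001`.
#' @keywords internal
.sig_levels <- c("ns", ".1", ".05", ".01", ".001")

#' Convert a p-value to a table significance code
#'
#' @param p numeric vector of p-values.
#' @return Character vector of codes in `{ns, .1, .05, .01, .001}`.
#' @export
sig_code_from_p <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA_character_, length(p))
  out[!is.na(p)] <- "ns"
  out[!is.na(p) & p < 0.1]   <- ".1"
  out[!is.na(p) & p < 0.05]  <- ".05"
  out[!is.na(p) & p < 0.01]  <- ".01"
  out[!is.na(p) & p < 0.001] <- ".001"
  out
}

# numeric p upper bound implied by a code (used when only codes are available)
.sig_code_bound <- function(code) {
  bounds <- c(ns = 1, ".1" = 0.1, ".05" = 0.05, ".01" = 0.01, ".001" = 0.001)
  unname(bounds[code])
}

.new_corr_table <- function(df) {
  stopifnot(all(c("measure1", "measure2", "r") %in% names(df)))
  if (is.null(df$p)) df$p <- NA_real_
  if (is.null(df$n)) df$n <- NA_integer_
  if (is.null(df$sig_code)) df$sig_code <- sig_code_from_p(df$p)
  df$domain1 <- .measure_domain(df$measure1)
  df$domain2 <- .measure_domain(df$measure2)
  bad <- !is.na(df$r) & abs(df$r) > 1
  if (any(bad)) stop("correlation coefficients outside [-1, 1]")
  dup <- duplicated(t(apply(cbind(df$measure1, df$measure2), 1, sort)))
  if (any(dup)) stop("duplicated measure pairs in correlation table")
  rownames(df) <- NULL
  class(df) <- c("corr_table", "data.frame")
  df[c("measure1", "measure2", "domain1", "domain2", "r", "p", "n", "sig_code")]
}

#' Load the packaged published correlation tables
#'
#' Reads the three fixture CSVs shipped with the package: the cognitive
#' within-domain table, the oculomotor within-domain table, and the
#' rectangular cognitive-by-oculomotor cross table. Each cell carries the
#' printed two-decimal Pearson coefficient and a significance code.
#'
#' @param dir Directory holding `table5_cognitive.csv`,
#'   `table6_oculomotor.csv` and `table7_cross.csv`. Defaults to the
#'   package's `extdata` directory.
#' @return A list with elements `cognitive`, `oculomotor` and `cross`, each a
#'   `corr_table` data frame with columns `measure1`, `measure2`, `domain1`,
#'   `domain2`, `r`, `p` (`NA`: the sources print codes, not p-values), `n`
#'   and `sig_code`.
#' @export
#' @examples
#' tabs <- load_correlation_tables()
#' subset(tabs$cognitive, measure1 == "DS" & measure2 == "SC")
load_correlation_tables <- function(dir = system.file("extdata", package = "oculonet")) {
  files <- c(cognitive = "table5_cognitive.csv",
             oculomotor = "table6_oculomotor.csv",
             cross = "table7_cross.csv")
  out <- lapply(files, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("fixture file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("row_label", "col_label", "r", "sig_code")
    if (!all(need %in% names(df))) {
      stop("corrupt fixture (missing columns): ", path)
    }
    if (!all(df$sig_code %in% .sig_levels)) {
      stop("corrupt fixture (bad significance code): ", path)
    }
    .new_corr_table(data.frame(measure1 = df$row_label,
                               measure2 = df$col_label,
                               r = as.numeric(df$r),
                               sig_code = df$sig_code,
                               stringsAsFactors = FALSE))
  })
  names(out) <- names(files)
  out
}

#' Combine per-domain correlation tables into one table over all 12 measures
#'
#' @param tables A list as returned by [load_correlation_tables()], or any
#'   list of `corr_table` data frames with disjoint pairs.
#' @return A single `corr_table` covering the union of pairs.
#' @export
combine_correlation_tables <- function(tables) {
  df <- do.call(rbind, lapply(tables, as.data.frame))
  .new_corr_table(df)
}

#' Assemble a symmetric correlation matrix from a correlation table
#'
#' Pairs absent from the table are left `NA`; the diagonal is 1.
#'
#' @param corr A `corr_table`.
#' @param measures Measure names defining row/column order; defaults to the
#'   canonical 12 measures.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(corr, measures = measure_info()$measure) {
  k <- length(measures)
  m <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  diag(m) <- 1
  i <- match(corr$measure1, measures)
  j <- match(corr$measure2, measures)
  keep <- !is.na(i) & !is.na(j)
  m[cbind(i[keep], j[keep])] <- corr$r[keep]
  m[cbind(j[keep], i[keep])] <- corr$r[keep]
  m
}

#' Target correlation matrix assembled from the packaged tables
#'
#' Convenience wrapper: loads the three fixture tables, combines them, and
#' (optionally) repairs the result to the nearest positive-semidefinite
#' correlation matrix for use as a simulation target. The shipped tables
#' already form a positive-definite matrix, so the repair is a no-op there.
#'
#' @param repair If `TRUE` (default), apply [nearest_correlation()].
#' @return A 12 x 12 correlation matrix in canonical measure order.
#' @export
target_correlation_matrix <- function(repair = TRUE) {
  m <- correlation_matrix(combine_correlation_tables(load_correlation_tables()))
  if (anyNA(m)) stop("combined fixture tables do not cover all measure pairs")
  if (repair) nearest_correlation(m) else m
}

#' Repair a symmetric matrix to a valid correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `floor` are raised to `floor`, the
#' matrix is reconstructed and rescaled to unit diagonal. Deterministic, and
#' the identity on matrices that are already positive semidefinite (up to the
#' floor).
#'
#' @param m Symmetric numeric matrix with unit diagonal and entries in
#'   \[-1, 1\].
#' @param floor Smallest admissible eigenvalue (default `1e-6`).
#' @return A symmetric positive-definite correlation matrix.
#' @export
nearest_correlation <- function(m, floor = 1e-6) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!isSymmetric(m, tol = 1e-8)) stop("matrix must be symmetric")
  if (any(abs(m) > 1 + 1e-8)) stop("entries must lie in [-1, 1]")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) return(m)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}
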