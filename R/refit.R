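#' Read an ID-signature definition matrix
#'
#' Tab-separated, first column the 83 channel labels (either
#' `1:Del:C:0`-style or `DEL_C_1_0`-style spellings), remaining columns
#' one signature each.  Rows are reordered to the canonical catalog
#' order; every channel must be present exactly once, entries must be
#' nonnegative, and each column must sum to 1 within 1e-6.
#'
#' @param path TSV path.
#' @return A numeric 83 x K matrix of class `"signature_matrix"` with
#'   canonical channel rownames and signature colnames.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- normalize_channel_label(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- labs
  as_signature_matrix(mat)
}

#' @rdname read_signature_matrix
#' @param x numeric matrix with channel rownames and signature colnames.
#' @export
as_signature_matrix <- function(x) {
  channels <- .id83_table$label
  labs <- normalize_channel_label(rownames(x))
  if (anyDuplicated(labs))
    stop("duplicated channel row(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  missing <- setdiff(channels, labs)
  if (length(missing))
    stop("signature matrix is missing channel(s): ",
         paste(missing, collapse = ", "))
  rownames(x) <- labs
  x <- x[channels, , drop = FALSE]
  if (any(x < 0)) stop("signature matrix has negative entries")
  cs <- colSums(x)
  off <- abs(cs - 1) > 1e-6
  if (any(off))
    stop("signature column(s) do not sum to 1: ",
         paste(sprintf("%s (%.6f)", colnames(x)[off], cs[off]), collapse = ", "))
  class(x) <- c("signature_matrix", class(x))
  x
}

#' @rdname read_signature_matrix
#' @param sigs a `signature_matrix`.
#' @export
write_signature_matrix <- function(sigs, path) {
  df <- data.frame(MutationType = rownames(sigs), unclass(sigs),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Refit signature exposures by non-negative least squares
#'
#' For each sample, estimates nonnegative signature activities e
#' minimizing the Euclidean norm of (counts - S e), where S is the
#' signature matrix — the global optimum of the convex NNLS problem
#' (solved by the Lawson-Hanson active-set algorithm).  Exposures are in
#' attributed-mutation-count units and are not renormalized; an all-zero
#' catalog yields all-zero exposures.
#'
#' @param catalog an [build_catalog()] matrix (or any samples x 83
#'   matrix in canonical channel order), or a single 83-vector.
#' @param sigs a `signature_matrix` (see [read_signature_matrix()]);
#'   use `subset` to restrict to named signatures.
#' @param subset optional character vector of signature names to refit
#'   against.
#' @return An object of class `"exposure_fit"`: list with `exposures`
#'   (samples x K matrix), `residual_norm` (per-sample Euclidean residual
#'   norm), `catalog_norm`, and `signatures` (the matrix used).
#' @export
nnls_refit <- function(catalog, sigs, subset = NULL) {
  if (is.null(dim(catalog)))
    catalog <- matrix(catalog, nrow = 1,
                      dimnames = list("sample", names(catalog)))
  if (ncol(catalog) != 83L)
    stop("catalog must have 83 channel columns")
  if (!is.null(colnames(catalog)) &&
      !identical(normalize_channel_label(colnames(catalog)), rownames(sigs)))
    stop("catalog channel order does not match the signature matrix")
  if (!is.null(subset)) {
    bad <- setdiff(subset, colnames(sigs))
    if (length(bad)) stop("unknown signature(s): ", paste(bad, collapse = ", "))
    sigs <- sigs[, subset, drop = FALSE]
  }
  S <- unclass(sigs)
  if (qr(S)$rank < ncol(S))
    warning("signature columns are collinear; exposures may be non-unique")
  n <- nrow(catalog)
  expo <- matrix(0, n, ncol(S), dimnames = list(rownames(catalog), colnames(S)))
  rn <- numeric(n)
  for (i in seq_len(n)) {
    y <- as.numeric(catalog[i, ])
    if (all(y == 0)) { rn[i] <- 0; next }
    sol <- pracma::lsqnonneg(S, y)
    expo[i, ] <- sol$x
    rn[i] <- sqrt(sum((y - S %*% sol$x)^2))
  }
  structure(list(exposures = expo, residual_norm = rn,
                 catalog_norm = sqrt(rowSums(catalog^2)),
                 signatures = sigs),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("NNLS signature refit: ", nrow(x$exposures), " sample(s) x ",
      ncol(x$exposures), " signature(s)\n", sep = "")
  cat("  mean residual norm: ", format(mean(x$residual_norm), digits = 4),
      "\n", sep = "")
  if ("ID8" %in% colnames(x$exposures))
    cat("  ID8 exposure range: ",
        paste(format(range(x$exposures[, "ID8"]), digits = 4),
              collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' @method coef exposure_fit
#' @export
coef.exposure_fit <- function(object, ...) object$exposures

#' Extract the absolute ID8 exposure
#'
#' @param fit an `exposure_fit`.
#' @return Named numeric vector of unrounded per-sample ID8 exposures.
#' @export
id8_exposure <- function(fit) {
  e <- if (inherits(fit, "exposure_fit")) fit$exposures else fit
  if (!"ID8" %in% colnames(e))
    stop("signature matrix does not contain an 'ID8' signature")
  stats::setNames(e[, "ID8"], rownames(e))
}

#' Write an exposure table as TSV
#'
#' Samples x signatures plus a `residual_norm` column.
#'
#' @param fit an `exposure_fit`.
#' @param path TSV path.
#' @export
write_exposures <- function(fit, path) {
  df <- data.frame(sample_id = rownames(fit$exposures), fit$exposures,
                   residual_norm = fit$residual_norm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
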