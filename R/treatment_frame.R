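# Potential-outcomes data structures and delimited-file I/O.

#' Observed treatment-outcome dataset
#'
#' Bundles the observed data consumed by every estimator in the package:
#' covariates `X`, the treatment quantity matrix `T` (exactly one nonzero
#' entry per row, the assigned arm; binary/categorical arms carry quantity 1,
#' continuous arms the dose), the one-hot assignment indicator `M`, the
#' assigned-arm index `eta` and the factual outcome `Y_f`.  The untreated
#' condition is modelled as an arm of its own (with quantity 1), never as an
#' all-zero row.
#'
#' @param X numeric matrix, n x q covariates.
#' @param eta integer vector of assigned-arm indices in `1..K` (1-based; all
#'   reports also use 1-based arms).
#' @param Y_f numeric factual outcomes; binary outcomes coded 0/1.
#' @param K number of arms; defaults to `max(eta)`.
#' @param dose optional numeric vector of treatment quantities for the
#'   assigned arm; defaults to 1 (binary/categorical arms).
#' @param arm_labels optional character labels for the arms.
#' @param outcome_type `"binary"` or `"continuous"`; `"auto"` detects binary
#'   0/1 outcomes.
#' @return An object of class `treatment_frame` with elements `X`, `T`, `M`,
#'   `eta`, `Y_f`, `K`, `q`, `n`, `arm_labels`, `outcome_type`.
#' @examples
#' fr <- treatment_frame(X = matrix(rnorm(20), 10), eta = rep(1:2, 5),
#'                       Y_f = rbinom(10, 1, 0.5))
#' fr$M[1:2, ]
#' @export
treatment_frame <- function(X, eta, Y_f, K = max(eta), dose = NULL,
                            arm_labels = NULL,
                            outcome_type = c("auto", "binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  eta <- as.integer(eta)
  Y_f <- as.numeric(Y_f)
  if (is.null(dose)) dose <- rep(1, n)
  stopifnot(length(eta) == n, length(Y_f) == n, length(dose) == n)
  if (anyNA(X) || anyNA(eta) || anyNA(Y_f) || anyNA(dose))
    stop("treatment_frame: missing values are not allowed")
  if (n < 1L || K < 2L || ncol(X) < 1L)
    stop("treatment_frame: need n >= 1, K >= 2, q >= 1")
  if (any(eta < 1L) || any(eta > K))
    stop("treatment_frame: eta out of range 1..K")
  M <- matrix(0, n, K)
  M[cbind(seq_len(n), eta)] <- 1
  Tm <- matrix(0, n, K)
  Tm[cbind(seq_len(n), eta)] <- dose
  if (is.null(arm_labels)) arm_labels <- paste0("arm", seq_len(K))
  if (outcome_type == "auto")
    outcome_type <- if (all(Y_f %in% c(0, 1))) "binary" else "continuous"
  structure(list(X = X, T = Tm, M = M, eta = eta, Y_f = Y_f,
                 K = as.integer(K), q = ncol(X), n = n,
                 arm_labels = as.character(arm_labels),
                 outcome_type = outcome_type),
            class = "treatment_frame")
}

#' @export
print.treatment_frame <- function(x, ...) {
  cat(sprintf("<treatment_frame> n=%d, q=%d covariates, K=%d arms (%s), %s outcome\n",
              x$n, x$q, x$K, paste(x$arm_labels, collapse = ", "),
              x$outcome_type))
  cat("assigned per arm:", paste(colSums(x$M), collapse = " / "), "\n")
  invisible(x)
}

#' @noRd
validate_frame <- function(frame) {
  stopifnot(inherits(frame, "treatment_frame"))
  if (!all(rowSums(frame$M) == 1))
    stop("invalid frame: each row of M must sum to exactly 1")
  if (!all(frame$M[cbind(seq_len(frame$n), frame$eta)] == 1))
    stop("invalid frame: M[i, eta[i]] must be 1")
  if (any(frame$T[frame$M == 0] != 0))
    stop("invalid frame: T must be zero wherever M is zero")
  invisible(frame)
}

#' Read a treatment frame from a delimited file
#'
#' Loads a CSV/TSV with one row per subject.  Arm labels are mapped to arm
#' indices deterministically in lexicographic order; rows with a dose column
#' keep the dose as the treatment quantity, otherwise arms get quantity 1.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, otherwise
#'   comma-separated.
#' @param covariates character vector of covariate column names.
#' @param arm column name holding the assigned arm (label or integer index).
#' @param outcome column name of the factual outcome.
#' @param dose optional column name of the treatment quantity.
#' @param outcome_type passed to [treatment_frame()].
#' @return A [treatment_frame()].
#' @export
load_frame <- function(path, covariates, arm, outcome, dose = NULL,
                       outcome_type = "auto") {
  if (!file.exists(path)) stop("load_frame: no such file: ", path)
  df <- if (grepl("\\.(tsv|txt)$", path)) read.delim(path) else read.csv(path)
  need <- c(covariates, arm, outcome, dose)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("load_frame: missing columns: ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(df[covariates])
  if (!is.numeric(X)) stop("load_frame: non-numeric covariate column")
  arms <- df[[arm]]
  labels <- sort(unique(as.character(arms)))
  eta <- match(as.character(arms), labels)
  d <- if (is.null(dose)) NULL else as.numeric(df[[dose]])
  treatment_frame(X, eta, as.numeric(df[[outcome]]), K = length(labels),
                  dose = d, arm_labels = labels, outcome_type = outcome_type)
}

#' Write a treatment frame to a delimited file
#'
#' Inverse of [load_frame()]: writes covariates, arm label, dose and outcome.
#'
#' @param frame a [treatment_frame()].
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  validate_frame(frame)
  df <- as.data.frame(frame$X)
  names(df) <- paste0("x", seq_len(frame$q))
  df$arm <- frame$arm_labels[frame$eta]
  df$dose <- frame$T[cbind(seq_len(frame$n), frame$eta)]
  df$outcome <- frame$Y_f
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Matrix of potential outcomes with provenance
#'
#' An n x K matrix of potential outcomes together with its provenance:
#' `"generated"` for raw generator output, `"complete"` once the factual
#' slots have been overwritten with the observed outcomes, `"ite_sample"`
#' for draws of the ITE-block generator.
#'
#' @param values numeric n x K matrix.
#' @param provenance one of `"generated"`, `"complete"`, `"ite_sample"`.
#' @param factual_mask the one-hot assignment matrix `M`.
#' @return An object of class `po_matrix`.
#' @export
po_matrix <- function(values,
                      provenance = c("generated", "complete", "ite_sample"),
                      factual_mask = NULL) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  structure(list(values = values, provenance = provenance,
                 factual_mask = factual_mask),
            class = "po_matrix")
}

#' @export
print.po_matrix <- function(x, ...) {
  cat(sprintf("<po_matrix> %d x %d, provenance: %s\n",
              nrow(x$values), ncol(x$values), x$provenance))
  invisible(x)
}

#' Export a potential-outcome matrix
#'
#' Writes the n x K outcome values with a provenance column.
#'
#' @param po a [po_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_po_matrix <- function(po, path) {
  stopifnot(inherits(po, "po_matrix"))
  df <- as.data.frame(po$values)
  names(df) <- paste0("y_arm", seq_len(ncol(po$values)))
  df$provenance <- po$provenance
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Factual outcome from a potential-outcome matrix
#'
#' Row-wise one-hot selection `sum_k M[i,k] * Y[i,k]`: the observed outcome is
#' the potential outcome of the assigned arm.
#'
#' @param Y numeric n x K matrix (or a [po_matrix()]).
#' @param M one-hot indicator matrix of the same shape.
#' @return length-n numeric vector.
#' @examples
#' factual_outcome(rbind(c(3, 7)), rbind(c(1, 0)))  # 3
#' @export
factual_outcome <- function(Y, M) {
  if (inherits(Y, "po_matrix")) Y <- Y$values
  Y <- as.matrix(Y)
  M <- as.matrix(M)
  if (!all(dim(Y) == dim(M))) stop("factual_outcome: shape mismatch")
  rowSums(Y * M)
}

#' Complete dataset: factual slots overwritten with observed outcomes
#'
#' Replaces column `eta[i]` of row `i` of a generated potential-outcome
#' matrix with the factual outcome `Y_f[i]`, exactly.  The result carries
#' provenance `"complete"`, and `factual_outcome(make_complete(Y, fr)$values,
#' fr$M)` reproduces `fr$Y_f` bitwise.
#'
#' @param Y_tilde a `po_matrix` with provenance `"generated"`.
#' @param frame the [treatment_frame()] that produced it.
#' @return A `po_matrix` with provenance `"complete"`.
#' @export
make_complete <- function(Y_tilde, frame) {
  stopifnot(inherits(Y_tilde, "po_matrix"))
  if (Y_tilde$provenance == "complete")
    stop("make_complete: input is already complete")
  vals <- Y_tilde$values
  if (!all(dim(vals) == dim(frame$M))) stop("make_complete: shape mismatch")
  vals[cbind(seq_len(frame$n), frame$eta)] <- frame$Y_f
  po_matrix(vals, "complete", factual_mask = frame$M)
}
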